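#' Build the packaged fixture instrument
#'
#' Deterministically constructs the screening instrument shipped with the
#' package: 13 diagnostic screening modules with a 65-item screener, follow-up
#' sections covering every criterion, and a 28-entry diagnosis catalog.
#'
#' The published structure is reproduced exactly: the six depression screener
#' items (three depressed-mood items, three loss-of-interest items of which
#' two are reverse-scored); a single lifetime panic-attack yes/no screener;
#' four yes/no trauma-exposure screeners for PTSD; a 30-day drinking-days
#' count for alcohol; single 30-day yes/no use screeners for cannabis and
#' other substances; and Likert screeners for the remaining modules, with the
#' psychotic module split into hallucination and delusion sub-scales. Item
#' texts beyond the handful of published examples are authored from DSM-5
#' symptom labels in the same style (single concept, no idioms, simple
#' wording) and are not normative.
#'
#' Screen-in thresholds default to the sensitive "at least sometimes" level
#' (reverse-scored items: "at most sometimes"); the "I felt sad" threshold is
#' raised to "at least often". The major-depressive-episode rule requires 5
#' of 9 criteria with at least one of depressed mood or loss of interest, on
#' a 14-day window. The alcohol module screens in at 5 or more drinking days
#' in 30 (a configurable fixture choice; the same cut is the item's
#' endorsement cut).
#'
#' @return A validated `screen_instrument`.
#' @export
build_fixture_instrument <- function() {
  items <- list()
  add <- function(...) items[[length(items) + 1]] <<- screen_item(...)

  ## -- depressive disorders -------------------------------------------------
  add("dep_felt_sad", "I felt sad.", "depressive", "screener",
      symptom_tag = "depressed_mood")
  add("dep_felt_depressed", "I felt depressed.", "depressive", "screener",
      symptom_tag = "depressed_mood")
  add("dep_felt_hopeless", "I felt hopeless.", "depressive", "screener",
      symptom_tag = "depressed_mood")
  add("dep_enjoyed_life", "I enjoyed life.", "depressive", "screener",
      reverse_scored = TRUE, symptom_tag = "anhedonia")
  add("dep_difficulty_enjoying",
      "I had difficulty enjoying things that I used to enjoy.",
      "depressive", "screener", symptom_tag = "anhedonia")
  add("dep_interested_usual", "I was interested in my usual activities.",
      "depressive", "screener", reverse_scored = TRUE,
      symptom_tag = "anhedonia")
  dep_lead <- "During the time(s) when I felt sad or down…"
  add("dep_appetite", "My appetite was much smaller or much larger than usual.",
      "depressive", "followup", timeframe_days = 14,
      symptom_tag = "appetite_change", lead_prompt = dep_lead)
  add("dep_sleep", "I had trouble sleeping, or I slept much more than usual.",
      "depressive", "followup", timeframe_days = 14,
      symptom_tag = "sleep_disturbance", lead_prompt = dep_lead)
  add("dep_slowed", "I moved or spoke much more slowly than usual.",
      "depressive", "followup", timeframe_days = 14,
      symptom_tag = "psychomotor_change", lead_prompt = dep_lead)
  add("dep_fatigue", "I felt tired all the time.",
      "depressive", "followup", timeframe_days = 14,
      symptom_tag = "fatigue", lead_prompt = dep_lead)
  add("dep_worthless", "I felt worthless.",
      "depressive", "followup", timeframe_days = 14,
      symptom_tag = "worthlessness", lead_prompt = dep_lead)
  add("dep_concentrate", "I had trouble concentrating.",
      "depressive", "followup", timeframe_days = 14,
      symptom_tag = "poor_concentration", lead_prompt = dep_lead)
  add("dep_death", "I thought about death a lot.",
      "depressive", "followup", timeframe_days = 14,
      symptom_tag = "thoughts_of_death", lead_prompt = dep_lead)

  ## -- manic and hypomanic disorders ---------------------------------------
  add("man_elevated", "I felt extremely happy for no reason.",
      "manic", "screener", symptom_tag = "elevated_mood")
  add("man_irritable", "I felt much more irritable than usual.",
      "manic", "screener", symptom_tag = "irritable_mood")
  add("man_energy", "I had much more energy than usual.",
      "manic", "screener", symptom_tag = "increased_energy")
  add("man_less_sleep", "I needed much less sleep than usual.",
      "manic", "screener", symptom_tag = "decreased_need_for_sleep")
  add("man_racing", "My thoughts raced.",
      "manic", "screener", symptom_tag = "racing_thoughts")
  add("man_talkative", "I talked much more than usual.",
      "manic", "screener", symptom_tag = "talkativeness")
  add("man_confident", "I felt much more confident than usual.",
      "manic", "screener", symptom_tag = "grandiosity")
  add("man_active", "I started many more projects than usual.",
      "manic", "screener", symptom_tag = "goal_directed_activity")
  man_lead <- "During the time(s) when I had much more energy than usual…"
  add("man_fu_powers", "I felt like I had special powers.",
      "manic", "followup", timeframe_days = 7,
      symptom_tag = "grandiosity", lead_prompt = man_lead)
  add("man_fu_distracted", "I was easily distracted.",
      "manic", "followup", timeframe_days = 7,
      symptom_tag = "distractibility", lead_prompt = man_lead)
  add("man_fu_risky", "I did risky things without thinking.",
      "manic", "followup", timeframe_days = 7,
      symptom_tag = "risky_behavior", lead_prompt = man_lead)

  ## -- generalized anxiety disorder ----------------------------------------
  add("gad_anxiety", "I had anxiety.", "gad", "screener",
      symptom_tag = "excessive_worry")
  add("gad_worry", "I worried about many different things.", "gad", "screener",
      symptom_tag = "excessive_worry")
  add("gad_control", "I could not stop worrying.", "gad", "screener",
      symptom_tag = "uncontrollable_worry")
  add("gad_restless", "I felt restless.", "gad", "screener",
      symptom_tag = "restlessness")
  add("gad_edge", "I felt on edge.", "gad", "screener",
      symptom_tag = "restlessness")
  add("gad_tense", "My muscles felt tense.", "gad", "screener",
      symptom_tag = "muscle_tension")
  add("gad_irritable", "Little things made me irritable.", "gad", "screener",
      symptom_tag = "irritability")
  gad_lead <- "During the time(s) when I felt anxious…"
  add("gad_fu_fatigue", "I got tired easily.", "gad", "followup",
      timeframe_days = 14, symptom_tag = "easily_fatigued",
      lead_prompt = gad_lead)
  add("gad_fu_blank", "My mind went blank.", "gad", "followup",
      timeframe_days = 14, symptom_tag = "difficulty_concentrating",
      lead_prompt = gad_lead)
  add("gad_fu_sleep", "I had trouble falling asleep.", "gad", "followup",
      timeframe_days = 14, symptom_tag = "sleep_disturbance",
      lead_prompt = gad_lead)

  ## -- panic disorder -------------------------------------------------------
  add("pan_attack_ever", "I have had a panic attack.", "panic", "screener",
      response_kind = "yes_no", timeframe_days = NA,
      symptom_tag = "panic_attacks")
  pan_lead <- "Thinking about my panic attacks…"
  add("pan_fu_sudden", "My panic attacks came on suddenly.",
      "panic", "followup", symptom_tag = "abrupt_onset",
      lead_prompt = pan_lead)
  add("pan_fu_heart", "During a panic attack, my heart pounded.",
      "panic", "followup", symptom_tag = "palpitations",
      lead_prompt = pan_lead)
  add("pan_fu_breath", "During a panic attack, I had trouble breathing.",
      "panic", "followup", symptom_tag = "shortness_of_breath",
      lead_prompt = pan_lead)
  add("pan_fu_die", "During a panic attack, I was afraid I might die.",
      "panic", "followup", symptom_tag = "fear_of_dying",
      lead_prompt = pan_lead)
  add("pan_fu_worry", "I worried about having another panic attack.",
      "panic", "followup", symptom_tag = "anticipatory_worry",
      lead_prompt = pan_lead)
  add("pan_fu_avoid",
      "I avoided places because I was afraid of having a panic attack.",
      "panic", "followup", symptom_tag = "attack_avoidance",
      lead_prompt = pan_lead)

  ## -- agoraphobia ----------------------------------------------------------
  add("ago_crowds", "I was afraid of crowds.", "agoraphobia", "screener",
      symptom_tag = "fear_crowds")
  add("ago_transport", "I was afraid to use public transportation.",
      "agoraphobia", "screener", symptom_tag = "fear_public_transport")
  add("ago_open", "I was afraid of open spaces.", "agoraphobia", "screener",
      symptom_tag = "fear_open_spaces")
  add("ago_enclosed", "I was afraid of enclosed places.",
      "agoraphobia", "screener", symptom_tag = "fear_enclosed_places")
  add("ago_lines", "I was afraid to stand in line.",
      "agoraphobia", "screener", symptom_tag = "fear_crowds")
  add("ago_alone_out", "I was afraid to leave home alone.",
      "agoraphobia", "screener", symptom_tag = "fear_outside_alone")
  add("ago_avoid", "I avoided places where I might feel trapped.",
      "agoraphobia", "screener", symptom_tag = "avoidance")
  ago_lead <- "Thinking about the situations that scared me…"
  add("ago_fu_help", "I was afraid help would not be available if I panicked.",
      "agoraphobia", "followup", symptom_tag = "fear_no_help",
      lead_prompt = ago_lead)
  add("ago_fu_companion", "I needed someone with me to go out.",
      "agoraphobia", "followup", symptom_tag = "need_companion",
      lead_prompt = ago_lead)
  add("ago_fu_dispro", "My fear was stronger than the real danger.",
      "agoraphobia", "followup", symptom_tag = "disproportionate_fear",
      lead_prompt = ago_lead)

  ## -- social anxiety disorder ----------------------------------------------
  add("soc_judged", "I was afraid people would judge me.",
      "social_anxiety", "screener", symptom_tag = "fear_of_scrutiny")
  add("soc_embarrass", "I was afraid I would embarrass myself.",
      "social_anxiety", "screener", symptom_tag = "fear_of_scrutiny")
  add("soc_meeting", "Meeting new people scared me.",
      "social_anxiety", "screener", symptom_tag = "fear_social_situations")
  add("soc_speaking", "Speaking in front of people scared me.",
      "social_anxiety", "screener", symptom_tag = "fear_social_situations")
  add("soc_watched", "I felt nervous when people watched me.",
      "social_anxiety", "screener", symptom_tag = "fear_of_scrutiny")
  add("soc_eat", "I was afraid to eat in front of other people.",
      "social_anxiety", "screener", symptom_tag = "fear_social_situations")
  add("soc_avoid", "I avoided social events.",
      "social_anxiety", "screener", symptom_tag = "social_avoidance")
  soc_lead <- "During the time(s) when social situations scared me…"
  add("soc_fu_endure", "I felt strong fear the whole time I was with people.",
      "social_anxiety", "followup", symptom_tag = "endured_with_distress",
      lead_prompt = soc_lead)
  add("soc_fu_dispro", "My fear was stronger than the real situation.",
      "social_anxiety", "followup", symptom_tag = "disproportionate_fear",
      lead_prompt = soc_lead)
  add("soc_fu_interfere", "My fear of people got in the way of my daily life.",
      "social_anxiety", "followup", symptom_tag = "interference",
      lead_prompt = soc_lead)

  ## -- obsessive-compulsive disorder ---------------------------------------
  add("ocd_unwanted", "I had unwanted thoughts that kept coming back.",
      "ocd", "screener", symptom_tag = "obsessions")
  add("ocd_upset", "My repeated thoughts upset me.",
      "ocd", "screener", symptom_tag = "obsessions")
  add("ocd_suppress", "I tried to push unwanted thoughts away.",
      "ocd", "screener", symptom_tag = "obsessions")
  add("ocd_check", "I checked things over and over.",
      "ocd", "screener", symptom_tag = "compulsions")
  add("ocd_wash", "I washed my hands over and over.",
      "ocd", "screener", symptom_tag = "compulsions")
  add("ocd_repeat", "I repeated actions a set number of times.",
      "ocd", "screener", symptom_tag = "compulsions")
  add("ocd_order", "I needed things to be in a certain order.",
      "ocd", "screener", symptom_tag = "compulsions")
  ocd_lead <- "Thinking about my repeated thoughts or actions…"
  add("ocd_fu_time",
      "My repeated thoughts or actions took up more than an hour a day.",
      "ocd", "followup", symptom_tag = "time_consuming",
      lead_prompt = ocd_lead)
  add("ocd_fu_interfere",
      "My repeated thoughts or actions got in the way of my daily life.",
      "ocd", "followup", symptom_tag = "interference",
      lead_prompt = ocd_lead)

  ## -- posttraumatic stress disorder ---------------------------------------
  add("pts_experienced", "I have experienced serious trauma.",
      "ptsd", "screener", response_kind = "yes_no", timeframe_days = NA,
      symptom_tag = "trauma_exposure")
  add("pts_witnessed", "I have witnessed serious trauma.",
      "ptsd", "screener", response_kind = "yes_no", timeframe_days = NA,
      symptom_tag = "trauma_exposure")
  add("pts_close",
      "A close friend or relative of mine was seriously traumatized.",
      "ptsd", "screener", response_kind = "yes_no", timeframe_days = NA,
      symptom_tag = "trauma_exposure")
  add("pts_work", "My work has repeatedly exposed me to trauma.",
      "ptsd", "screener", response_kind = "yes_no", timeframe_days = NA,
      symptom_tag = "trauma_exposure")
  pts_lead <- "Thinking about the trauma…"
  add("pts_fu_memories", "Unwanted memories of the trauma came back to me.",
      "ptsd", "followup", symptom_tag = "intrusion", lead_prompt = pts_lead)
  add("pts_fu_nightmares", "I had nightmares about the trauma.",
      "ptsd", "followup", symptom_tag = "intrusion", lead_prompt = pts_lead)
  add("pts_fu_avoid", "I avoided things that reminded me of the trauma.",
      "ptsd", "followup", symptom_tag = "trauma_avoidance",
      lead_prompt = pts_lead)
  add("pts_fu_cutoff", "I felt cut off from other people.",
      "ptsd", "followup", symptom_tag = "negative_mood",
      lead_prompt = pts_lead)
  add("pts_fu_startle", "I startled easily.",
      "ptsd", "followup", symptom_tag = "hyperarousal",
      lead_prompt = pts_lead)
  add("pts_fu_guard", "I was always on guard.",
      "ptsd", "followup", symptom_tag = "hyperarousal",
      lead_prompt = pts_lead)

  ## -- adult ADHD -----------------------------------------------------------
  add("adh_mistakes", "I made careless mistakes.", "adhd", "screener",
      symptom_tag = "inattention")
  add("adh_attention", "I had trouble keeping my attention on tasks.",
      "adhd", "screener", symptom_tag = "inattention")
  add("adh_wander", "My mind wandered when people spoke to me.",
      "adhd", "screener", symptom_tag = "inattention")
  add("adh_finish", "I had trouble finishing tasks.", "adhd", "screener",
      symptom_tag = "inattention")
  add("adh_lose", "I lost things I needed.", "adhd", "screener",
      symptom_tag = "inattention")
  add("adh_sit", "I had difficulty sitting still.", "adhd", "screener",
      symptom_tag = "hyperactivity")
  add("adh_interrupt", "I interrupted people.", "adhd", "screener",
      symptom_tag = "impulsivity")
  add("adh_wait", "I had trouble waiting my turn.", "adhd", "screener",
      symptom_tag = "impulsivity")
  adh_lead <- "Thinking about my attention and activity…"
  add("adh_fu_organize", "I had trouble organizing tasks.",
      "adhd", "followup", timeframe_days = 180,
      symptom_tag = "disorganization", lead_prompt = adh_lead)
  add("adh_fu_forget", "I forgot daily tasks.",
      "adhd", "followup", timeframe_days = 180,
      symptom_tag = "forgetfulness", lead_prompt = adh_lead)
  add("adh_fu_seated", "I could not stay seated when I needed to.",
      "adhd", "followup", timeframe_days = 180,
      symptom_tag = "restlessness", lead_prompt = adh_lead)
  add("adh_fu_talk", "I talked nonstop.",
      "adhd", "followup", timeframe_days = 180,
      symptom_tag = "excessive_talking", lead_prompt = adh_lead)

  ## -- psychotic disorders --------------------------------------------------
  add("psy_voices", "I heard voices when no one was there.",
      "psychotic", "screener", symptom_tag = "hallucinations")
  add("psy_sounds", "I heard sounds that other people could not hear.",
      "psychotic", "screener", symptom_tag = "hallucinations")
  add("psy_visions", "I saw things that other people could not see.",
      "psychotic", "screener", symptom_tag = "hallucinations")
  add("psy_touch", "I felt things on my skin that were not there.",
      "psychotic", "screener", symptom_tag = "hallucinations")
  add("psy_control", "I felt like my thoughts were being controlled against my will.",
      "psychotic", "screener", symptom_tag = "delusions")
  add("psy_punish", "I thought I deserved to be punished.",
      "psychotic", "screener", symptom_tag = "delusions")
  add("psy_spy", "I thought people were spying on me.",
      "psychotic", "screener", symptom_tag = "delusions")
  psy_lead <- "During the time(s) when I had unusual experiences…"
  add("psy_fu_speech", "My speech got mixed up so others could not follow it.",
      "psychotic", "followup", symptom_tag = "disorganized_speech",
      lead_prompt = psy_lead)
  add("psy_fu_behavior", "I acted in ways that others found very strange.",
      "psychotic", "followup", symptom_tag = "disorganized_behavior",
      lead_prompt = psy_lead)
  add("psy_fu_flat", "I stopped showing my feelings.",
      "psychotic", "followup", symptom_tag = "negative_symptoms",
      lead_prompt = psy_lead)
  add("psy_fu_motivation", "I stopped doing my daily activities.",
      "psychotic", "followup", symptom_tag = "negative_symptoms",
      lead_prompt = psy_lead)

  ## -- alcohol use ----------------------------------------------------------
  add("alc_days", "On how many days did you drink alcohol?",
      "alcohol", "screener", response_kind = "count_days",
      timeframe_days = 30, symptom_tag = "alcohol_use", endorse_cut = 5)
  alc_lead <- "Thinking about my drinking…"
  add("alc_fu_more", "I drank more than I planned.",
      "alcohol", "followup", symptom_tag = "larger_amounts",
      lead_prompt = alc_lead)
  add("alc_fu_cut", "I tried to cut down on drinking but could not.",
      "alcohol", "followup", symptom_tag = "failed_cutdown",
      lead_prompt = alc_lead)
  add("alc_fu_crave", "I had strong cravings for alcohol.",
      "alcohol", "followup", symptom_tag = "craving",
      lead_prompt = alc_lead)
  add("alc_fu_role", "Drinking got in the way of my work or home duties.",
      "alcohol", "followup", symptom_tag = "role_failure",
      lead_prompt = alc_lead)
  add("alc_fu_tolerance", "I needed more alcohol to get the same effect.",
      "alcohol", "followup", symptom_tag = "tolerance",
      lead_prompt = alc_lead)
  add("alc_fu_withdraw", "I felt sick when I stopped drinking.",
      "alcohol", "followup", symptom_tag = "withdrawal",
      lead_prompt = alc_lead)

  ## -- cannabis use ---------------------------------------------------------
  add("can_use", "I used cannabis.", "cannabis", "screener",
      response_kind = "yes_no", timeframe_days = 30,
      symptom_tag = "cannabis_use")
  can_lead <- "Thinking about my cannabis use…"
  add("can_fu_more", "I used more cannabis than I planned.",
      "cannabis", "followup", symptom_tag = "larger_amounts",
      lead_prompt = can_lead)
  add("can_fu_cut", "I tried to cut down on cannabis but could not.",
      "cannabis", "followup", symptom_tag = "failed_cutdown",
      lead_prompt = can_lead)
  add("can_fu_crave", "I had strong cravings for cannabis.",
      "cannabis", "followup", symptom_tag = "craving",
      lead_prompt = can_lead)
  add("can_fu_role", "Cannabis got in the way of my work or home duties.",
      "cannabis", "followup", symptom_tag = "role_failure",
      lead_prompt = can_lead)
  add("can_fu_tolerance", "I needed more cannabis to get the same effect.",
      "cannabis", "followup", symptom_tag = "tolerance",
      lead_prompt = can_lead)
  add("can_fu_withdraw", "I felt sick when I stopped using cannabis.",
      "cannabis", "followup", symptom_tag = "withdrawal",
      lead_prompt = can_lead)

  ## -- other substance use --------------------------------------------------
  add("osu_use", "I used drugs other than alcohol or cannabis.",
      "other_substance", "screener", response_kind = "yes_no",
      timeframe_days = 30, symptom_tag = "other_substance_use")
  osu_lead <- "Thinking about my drug use…"
  substances <- c(inhalant = "inhalants",
                  hallucinogen = "hallucinogens",
                  opioid = "opioids or pain pills that were not prescribed to me",
                  pcp = "phencyclidine (PCP)",
                  sedative = "sedatives or sleeping pills that were not prescribed to me",
                  stimulant = "stimulants such as cocaine or amphetamines",
                  other = "another drug")
  for (s in names(substances)) {
    add(paste0("osu_fu_", s), sprintf("I used %s.", substances[[s]]),
        "other_substance", "followup", response_kind = "yes_no",
        timeframe_days = 30, symptom_tag = paste0("used_", s),
        lead_prompt = osu_lead)
  }
  add("osu_fu_more", "I used more of the drug than I planned.",
      "other_substance", "followup", symptom_tag = "larger_amounts",
      lead_prompt = osu_lead)
  add("osu_fu_cut", "I tried to cut down on the drug but could not.",
      "other_substance", "followup", symptom_tag = "failed_cutdown",
      lead_prompt = osu_lead)
  add("osu_fu_crave", "I had strong cravings for the drug.",
      "other_substance", "followup", symptom_tag = "craving",
      lead_prompt = osu_lead)
  add("osu_fu_role", "The drug got in the way of my work or home duties.",
      "other_substance", "followup", symptom_tag = "role_failure",
      lead_prompt = osu_lead)
  add("osu_fu_tolerance", "I needed more of the drug to get the same effect.",
      "other_substance", "followup", symptom_tag = "tolerance",
      lead_prompt = osu_lead)
  add("osu_fu_withdraw", "I felt sick when I stopped using the drug.",
      "other_substance", "followup", symptom_tag = "withdrawal",
      lead_prompt = osu_lead)

  ## -- modules --------------------------------------------------------------
  item_ids <- vapply(items, `[[`, "", "item_id")
  ids_of <- function(mod, section) {
    keep <- vapply(items, function(it) {
      it$module_id == mod && it$section == section
    }, logical(1))
    item_ids[keep]
  }
  # Sensitive default: any Likert screener at >= sometimes (reverse-scored
  # at <= sometimes) screens the module in.
  likert_any_rule <- function(mod, overrides = list()) {
    ids <- ids_of(mod, "screener")
    threshold_rule(lapply(ids, function(id) {
      it <- items[[match(id, item_ids)]]
      if (!is.null(overrides[[id]])) return(overrides[[id]])
      if (it$reverse_scored) clause(id, "<=", 3L) else clause(id, ">=", 3L)
    }), connective = "any")
  }

  modules <- list(
    screen_module("depressive", "depressive disorders",
                  ids_of("depressive", "screener"),
                  likert_any_rule("depressive", overrides = list(
                    # Published adjustment: "I felt sad" over-included at
                    # "sometimes"; raised to at least "often".
                    dep_felt_sad = clause("dep_felt_sad", ">=", 4L))),
                  ids_of("depressive", "followup")),
    screen_module("manic", "manic and hypomanic disorders",
                  ids_of("manic", "screener"), likert_any_rule("manic"),
                  ids_of("manic", "followup")),
    screen_module("gad", "generalized anxiety disorder",
                  ids_of("gad", "screener"), likert_any_rule("gad"),
                  ids_of("gad", "followup")),
    screen_module("panic", "panic disorder",
                  "pan_attack_ever",
                  threshold_rule(list(clause("pan_attack_ever", "==", TRUE))),
                  ids_of("panic", "followup")),
    screen_module("agoraphobia", "agoraphobia",
                  ids_of("agoraphobia", "screener"),
                  likert_any_rule("agoraphobia"),
                  ids_of("agoraphobia", "followup")),
    screen_module("social_anxiety", "social anxiety disorder",
                  ids_of("social_anxiety", "screener"),
                  likert_any_rule("social_anxiety"),
                  ids_of("social_anxiety", "followup")),
    screen_module("ocd", "obsessive-compulsive disorder",
                  ids_of("ocd", "screener"), likert_any_rule("ocd"),
                  ids_of("ocd", "followup")),
    screen_module("ptsd", "posttraumatic stress disorder",
                  ids_of("ptsd", "screener"),
                  threshold_rule(lapply(ids_of("ptsd", "screener"),
                                        clause, "==", TRUE)),
                  ids_of("ptsd", "followup")),
    screen_module("adhd", "adult attention-deficit/hyperactivity disorder",
                  ids_of("adhd", "screener"), likert_any_rule("adhd"),
                  ids_of("adhd", "followup")),
    screen_module("psychotic", "psychotic disorders",
                  ids_of("psychotic", "screener"),
                  likert_any_rule("psychotic"),
                  ids_of("psychotic", "followup")),
    screen_module("alcohol", "alcohol use disorder",
                  "alc_days",
                  threshold_rule(list(clause("alc_days", ">=", 5L))),
                  ids_of("alcohol", "followup")),
    screen_module("cannabis", "cannabis use disorder",
                  "can_use",
                  threshold_rule(list(clause("can_use", "==", TRUE))),
                  ids_of("cannabis", "followup")),
    screen_module("other_substance", "other substance use disorders",
                  "osu_use",
                  threshold_rule(list(clause("osu_use", "==", TRUE))),
                  ids_of("other_substance", "followup"))
  )

  ## -- criteria -------------------------------------------------------------
  cr <- list()
  addc <- function(...) cr[[length(cr) + 1]] <<- criterion_def(...)

  addc("crit_depressed_mood", "depressed mood",
       c("dep_felt_sad", "dep_felt_depressed", "dep_felt_hopeless"),
       cardinal = TRUE)
  addc("crit_anhedonia", "loss of interest or pleasure",
       c("dep_enjoyed_life", "dep_difficulty_enjoying",
         "dep_interested_usual"), cardinal = TRUE)
  addc("crit_appetite_change", "appetite or weight change", "dep_appetite")
  addc("crit_sleep_disturbance", "insomnia or hypersomnia", "dep_sleep")
  addc("crit_psychomotor_change", "psychomotor retardation or agitation",
       "dep_slowed")
  addc("crit_fatigue", "fatigue or loss of energy", "dep_fatigue")
  addc("crit_worthlessness", "worthlessness or excessive guilt",
       "dep_worthless")
  addc("crit_poor_concentration", "diminished concentration",
       "dep_concentrate")
  addc("crit_thoughts_of_death", "recurrent thoughts of death", "dep_death")

  addc("crit_elevated_or_irritable_mood", "elevated, expansive, or irritable mood",
       c("man_elevated", "man_irritable"), cardinal = TRUE)
  addc("crit_increased_energy", "increased energy or activity", "man_energy")
  addc("crit_decreased_need_for_sleep", "decreased need for sleep",
       "man_less_sleep")
  addc("crit_racing_thoughts", "flight of ideas or racing thoughts",
       "man_racing")
  addc("crit_talkativeness", "more talkative than usual", "man_talkative")
  addc("crit_grandiosity", "inflated self-esteem or grandiosity",
       c("man_confident", "man_fu_powers"))
  addc("crit_goal_activity", "increase in goal-directed activity",
       "man_active")
  addc("crit_distractibility", "distractibility", "man_fu_distracted")
  addc("crit_risky_behavior", "excessive involvement in risky activities",
       "man_fu_risky")

  addc("crit_excessive_worry", "excessive anxiety and worry",
       c("gad_anxiety", "gad_worry"), cardinal = TRUE)
  addc("crit_uncontrollable_worry", "difficulty controlling the worry",
       "gad_control")
  addc("crit_gad_restlessness", "restlessness or feeling keyed up",
       c("gad_restless", "gad_edge"))
  addc("crit_easily_fatigued", "being easily fatigued", "gad_fu_fatigue")
  addc("crit_difficulty_concentrating", "difficulty concentrating or mind blank",
       "gad_fu_blank")
  addc("crit_gad_irritability", "irritability", "gad_irritable")
  addc("crit_muscle_tension", "muscle tension", "gad_tense")
  addc("crit_gad_sleep", "sleep disturbance", "gad_fu_sleep")

  addc("crit_panic_attacks", "recurrent unexpected panic attacks",
       "pan_attack_ever", cardinal = TRUE)
  addc("crit_abrupt_onset", "abrupt surge of intense fear", "pan_fu_sudden")
  addc("crit_palpitations", "palpitations or pounding heart", "pan_fu_heart")
  addc("crit_shortness_of_breath", "shortness of breath", "pan_fu_breath")
  addc("crit_fear_of_dying", "fear of dying", "pan_fu_die")
  addc("crit_anticipatory_worry", "persistent concern about additional attacks",
       "pan_fu_worry")
  addc("crit_attack_avoidance", "maladaptive change in behavior to avoid attacks",
       "pan_fu_avoid")

  addc("crit_fear_public_transport", "fear of public transportation",
       "ago_transport")
  addc("crit_fear_open_spaces", "fear of open spaces", "ago_open")
  addc("crit_fear_enclosed_places", "fear of enclosed places", "ago_enclosed")
  addc("crit_fear_crowds", "fear of crowds or standing in line",
       c("ago_crowds", "ago_lines"))
  addc("crit_fear_outside_alone", "fear of being outside the home alone",
       "ago_alone_out")
  addc("crit_agoraphobic_avoidance", "active avoidance of feared situations",
       "ago_avoid", cardinal = TRUE)
  addc("crit_fear_no_help", "fear that help would not be available",
       "ago_fu_help")
  addc("crit_need_companion", "requiring a companion", "ago_fu_companion")
  addc("crit_ago_disproportionate", "fear out of proportion to actual danger",
       "ago_fu_dispro")

  addc("crit_fear_of_scrutiny", "fear of negative evaluation by others",
       c("soc_judged", "soc_embarrass", "soc_watched"), cardinal = TRUE)
  addc("crit_fear_social_situations", "fear of social or performance situations",
       c("soc_meeting", "soc_speaking", "soc_eat"))
  addc("crit_social_avoidance", "avoidance of social situations", "soc_avoid")
  addc("crit_endured_with_distress", "social situations endured with distress",
       "soc_fu_endure")
  addc("crit_soc_disproportionate", "fear out of proportion to actual threat",
       "soc_fu_dispro")
  addc("crit_soc_interference", "significant interference with functioning",
       "soc_fu_interfere")

  addc("crit_obsessions", "recurrent intrusive thoughts",
       c("ocd_unwanted", "ocd_upset", "ocd_suppress"), cardinal = TRUE)
  addc("crit_compulsions", "repetitive behaviors or mental acts",
       c("ocd_check", "ocd_wash", "ocd_repeat", "ocd_order"), cardinal = TRUE)
  addc("crit_ocd_time", "obsessions or compulsions are time-consuming",
       "ocd_fu_time")
  addc("crit_ocd_interference", "significant interference with functioning",
       "ocd_fu_interfere")

  addc("crit_trauma_exposure", "exposure to actual or threatened trauma",
       c("pts_experienced", "pts_witnessed", "pts_close", "pts_work"),
       cardinal = TRUE)
  addc("crit_intrusion", "intrusion symptoms",
       c("pts_fu_memories", "pts_fu_nightmares"))
  addc("crit_trauma_avoidance", "avoidance of trauma reminders",
       "pts_fu_avoid")
  addc("crit_negative_mood", "negative alterations in cognitions and mood",
       "pts_fu_cutoff")
  addc("crit_hyperarousal", "marked alterations in arousal and reactivity",
       c("pts_fu_startle", "pts_fu_guard"))

  addc("crit_inattention", "inattention symptom cluster",
       c("adh_mistakes", "adh_attention", "adh_wander", "adh_finish",
         "adh_lose"), cardinal = TRUE)
  addc("crit_hyperactivity_impulsivity", "hyperactivity-impulsivity cluster",
       c("adh_sit", "adh_interrupt", "adh_wait"), cardinal = TRUE)
  addc("crit_disorganization", "difficulty organizing tasks",
       "adh_fu_organize")
  addc("crit_forgetfulness", "forgetful in daily activities", "adh_fu_forget")
  addc("crit_adh_restlessness", "leaves seat or feels restless",
       "adh_fu_seated")
  addc("crit_excessive_talking", "talks excessively", "adh_fu_talk")

  addc("crit_hallucinations", "hallucinations",
       c("psy_voices", "psy_sounds", "psy_visions", "psy_touch"),
       cardinal = TRUE)
  addc("crit_delusions", "delusions",
       c("psy_control", "psy_punish", "psy_spy"), cardinal = TRUE)
  addc("crit_disorganized_speech", "disorganized speech", "psy_fu_speech")
  addc("crit_disorganized_behavior", "grossly disorganized behavior",
       "psy_fu_behavior")
  addc("crit_negative_symptoms", "negative symptoms",
       c("psy_fu_flat", "psy_fu_motivation"))

  addc("crit_alcohol_use", "recurrent alcohol use", "alc_days",
       cardinal = TRUE)
  addc("crit_alc_larger", "alcohol taken in larger amounts than intended",
       "alc_fu_more")
  addc("crit_alc_cutdown", "unsuccessful efforts to cut down", "alc_fu_cut")
  addc("crit_alc_craving", "craving for alcohol", "alc_fu_crave")
  addc("crit_alc_role", "failure to fulfill major role obligations",
       "alc_fu_role")
  addc("crit_alc_tolerance", "tolerance", "alc_fu_tolerance")
  addc("crit_alc_withdrawal", "withdrawal", "alc_fu_withdraw")

  addc("crit_cannabis_use", "recurrent cannabis use", "can_use",
       cardinal = TRUE)
  addc("crit_can_larger", "cannabis taken in larger amounts than intended",
       "can_fu_more")
  addc("crit_can_cutdown", "unsuccessful efforts to cut down", "can_fu_cut")
  addc("crit_can_craving", "craving for cannabis", "can_fu_crave")
  addc("crit_can_role", "failure to fulfill major role obligations",
       "can_fu_role")
  addc("crit_can_tolerance", "tolerance", "can_fu_tolerance")
  addc("crit_can_withdrawal", "withdrawal", "can_fu_withdraw")

  addc("crit_other_substance_use", "recurrent use of another substance",
       "osu_use", cardinal = TRUE)
  for (s in names(substances)) {
    addc(paste0("crit_used_", s), sprintf("use of %s", substances[[s]]),
         paste0("osu_fu_", s))
  }
  addc("crit_osu_larger", "substance taken in larger amounts than intended",
       "osu_fu_more")
  addc("crit_osu_cutdown", "unsuccessful efforts to cut down", "osu_fu_cut")
  addc("crit_osu_craving", "craving for the substance", "osu_fu_crave")
  addc("crit_osu_role", "failure to fulfill major role obligations",
       "osu_fu_role")
  addc("crit_osu_tolerance", "tolerance", "osu_fu_tolerance")
  addc("crit_osu_withdrawal", "withdrawal", "osu_fu_withdraw")

  ## -- diagnosis rules ------------------------------------------------------
  dep9 <- c("crit_depressed_mood", "crit_anhedonia", "crit_appetite_change",
            "crit_sleep_disturbance", "crit_psychomotor_change",
            "crit_fatigue", "crit_worthlessness", "crit_poor_concentration",
            "crit_thoughts_of_death")
  man9 <- c("crit_elevated_or_irritable_mood", "crit_increased_energy",
            "crit_decreased_need_for_sleep", "crit_racing_thoughts",
            "crit_talkativeness", "crit_grandiosity", "crit_goal_activity",
            "crit_distractibility", "crit_risky_behavior")
  psy5 <- c("crit_delusions", "crit_hallucinations",
            "crit_disorganized_speech", "crit_disorganized_behavior",
            "crit_negative_symptoms")
  psy_cardinal <- c("crit_delusions", "crit_hallucinations")
  sud <- function(prefix, extra = character()) {
    c(extra, paste0("crit_", prefix,
                    c("_larger", "_cutdown", "_craving", "_role",
                      "_tolerance", "_withdrawal")))
  }

  rules <- list(
    diagnosis_rule("Major depressive episode", "depressive", dep9, 5,
                   cardinal_criteria = c("crit_depressed_mood",
                                         "crit_anhedonia"),
                   window_days = 14,
                   notes = paste("Symptoms must co-occur in the same 2-week",
                                 "window (anchored by the lead prompts) and",
                                 "represent a change from prior functioning.")),
    diagnosis_rule("Major depressive disorder", "depressive", dep9, 5,
                   cardinal_criteria = c("crit_depressed_mood",
                                         "crit_anhedonia"),
                   window_days = 14,
                   notes = paste("As major depressive episode; exclusion of",
                                 "manic/hypomanic history and of medical or",
                                 "substance-induced etiologies is clinician",
                                 "judgment, not machine-evaluated.")),
    diagnosis_rule("Persistent depressive disorder", "depressive",
                   c("crit_depressed_mood", "crit_appetite_change",
                     "crit_sleep_disturbance", "crit_fatigue",
                     "crit_worthlessness", "crit_poor_concentration"), 3,
                   cardinal_criteria = "crit_depressed_mood",
                   window_days = 730,
                   notes = "Two-year chronicity is clinician-confirmed."),
    diagnosis_rule("Other specified depressive disorder", "depressive",
                   dep9, 2,
                   cardinal_criteria = c("crit_depressed_mood",
                                         "crit_anhedonia"),
                   window_days = 14,
                   notes = paste("Subthreshold depressive presentation with",
                                 "clinically significant distress.")),
    diagnosis_rule("Manic episode", "manic", man9, 4,
                   cardinal_criteria = "crit_elevated_or_irritable_mood",
                   window_days = 7,
                   notes = paste("One-week duration and marked impairment are",
                                 "clinician-confirmed. A manic episode plus",
                                 "history composes bipolar I disorder; past",
                                 "episode collection is out of scope.")),
    diagnosis_rule("Hypomanic episode", "manic", man9, 4,
                   cardinal_criteria = "crit_elevated_or_irritable_mood",
                   window_days = 4,
                   notes = paste("Four-day duration without marked impairment",
                                 "is clinician-confirmed. A hypomanic episode",
                                 "plus a major depressive episode composes",
                                 "bipolar II disorder; past episode",
                                 "collection is out of scope.")),
    diagnosis_rule("Panic disorder", "panic",
                   c("crit_panic_attacks", "crit_abrupt_onset",
                     "crit_palpitations", "crit_shortness_of_breath",
                     "crit_fear_of_dying", "crit_anticipatory_worry",
                     "crit_attack_avoidance"), 4,
                   cardinal_criteria = "crit_panic_attacks",
                   window_days = 30,
                   notes = "One month of concern or avoidance after attacks."),
    diagnosis_rule("Agoraphobia", "agoraphobia",
                   c("crit_fear_public_transport", "crit_fear_open_spaces",
                     "crit_fear_enclosed_places", "crit_fear_crowds",
                     "crit_fear_outside_alone", "crit_agoraphobic_avoidance",
                     "crit_fear_no_help", "crit_need_companion",
                     "crit_ago_disproportionate"), 4,
                   cardinal_criteria = "crit_agoraphobic_avoidance",
                   window_days = 180,
                   notes = paste("Marked fear in two or more situation types;",
                                 "six-month duration clinician-confirmed.")),
    diagnosis_rule("Social anxiety disorder", "social_anxiety",
                   c("crit_fear_of_scrutiny", "crit_fear_social_situations",
                     "crit_social_avoidance", "crit_endured_with_distress",
                     "crit_soc_disproportionate", "crit_soc_interference"), 4,
                   cardinal_criteria = "crit_fear_of_scrutiny",
                   window_days = 180,
                   notes = "Six-month duration clinician-confirmed."),
    diagnosis_rule("Generalized anxiety disorder", "gad",
                   c("crit_excessive_worry", "crit_uncontrollable_worry",
                     "crit_gad_restlessness", "crit_easily_fatigued",
                     "crit_difficulty_concentrating", "crit_gad_irritability",
                     "crit_muscle_tension", "crit_gad_sleep"), 5,
                   cardinal_criteria = "crit_excessive_worry",
                   window_days = 180,
                   notes = paste("Excessive worry more days than not for six",
                                 "months, with associated symptoms.")),
    diagnosis_rule("Obsessive-compulsive disorder", "ocd",
                   c("crit_obsessions", "crit_compulsions", "crit_ocd_time",
                     "crit_ocd_interference"), 2,
                   cardinal_criteria = c("crit_obsessions",
                                         "crit_compulsions"),
                   window_days = 30,
                   notes = "Obsessions or compulsions plus burden."),
    diagnosis_rule("Posttraumatic stress disorder", "ptsd",
                   c("crit_trauma_exposure", "crit_intrusion",
                     "crit_trauma_avoidance", "crit_negative_mood",
                     "crit_hyperarousal"), 5,
                   cardinal_criteria = "crit_trauma_exposure",
                   window_days = 30,
                   notes = paste("All symptom clusters present for more than",
                                 "one month after exposure.")),
    diagnosis_rule("Attention-deficit/hyperactivity disorder", "adhd",
                   c("crit_inattention", "crit_hyperactivity_impulsivity",
                     "crit_disorganization", "crit_forgetfulness",
                     "crit_adh_restlessness", "crit_excessive_talking"), 4,
                   cardinal_criteria = c("crit_inattention",
                                         "crit_hyperactivity_impulsivity"),
                   window_days = 180,
                   notes = "Childhood onset is clinician-confirmed."),
    diagnosis_rule("Schizophrenia", "psychotic", psy5, 2,
                   cardinal_criteria = psy_cardinal, window_days = 30,
                   notes = paste("Six-month course with functional decline is",
                                 "clinician-confirmed.")),
    diagnosis_rule("Schizophreniform disorder", "psychotic", psy5, 2,
                   cardinal_criteria = psy_cardinal, window_days = 30,
                   notes = "One-to-six-month course clinician-confirmed."),
    diagnosis_rule("Schizoaffective disorder", "psychotic", psy5, 2,
                   cardinal_criteria = psy_cardinal, window_days = 30,
                   notes = paste("Concurrent major mood episode and psychosis",
                                 "without mood symptoms are",
                                 "clinician-confirmed.")),
    diagnosis_rule("Delusional disorder", "psychotic",
                   "crit_delusions", 1,
                   cardinal_criteria = "crit_delusions", window_days = 30,
                   notes = paste("One month of delusions without other active",
                                 "phase symptoms clinician-confirmed.")),
    diagnosis_rule("Brief psychotic disorder", "psychotic",
                   c("crit_delusions", "crit_hallucinations",
                     "crit_disorganized_speech",
                     "crit_disorganized_behavior"), 1,
                   cardinal_criteria = c("crit_delusions",
                                         "crit_hallucinations"),
                   window_days = 30,
                   notes = paste("Duration under one month",
                                 "clinician-confirmed; the pure",
                                 "disorganized-speech presentation needs",
                                 "clinician review.")),
    diagnosis_rule("Other specified psychotic disorder", "psychotic",
                   psy5, 1, cardinal_criteria = psy_cardinal,
                   window_days = 30,
                   notes = "Subthreshold psychotic presentation."),
    diagnosis_rule("Alcohol use disorder", "alcohol",
                   c("crit_alcohol_use", sud("alc")), 3,
                   cardinal_criteria = "crit_alcohol_use",
                   window_days = 365,
                   notes = "Symptom count within a 12-month window."),
    diagnosis_rule("Cannabis use disorder", "cannabis",
                   c("crit_cannabis_use", sud("can")), 3,
                   cardinal_criteria = "crit_cannabis_use",
                   window_days = 365,
                   notes = "Symptom count within a 12-month window."),
    diagnosis_rule("Inhalant use disorder", "other_substance",
                   c("crit_other_substance_use", "crit_used_inhalant",
                     sud("osu")), 4,
                   cardinal_criteria = "crit_other_substance_use",
                   window_days = 365,
                   notes = paste("Substance identity items count toward the",
                                 "total; clinician confirms the specific",
                                 "substance.")),
    diagnosis_rule("Other hallucinogen use disorder", "other_substance",
                   c("crit_other_substance_use", "crit_used_hallucinogen",
                     sud("osu")), 4,
                   cardinal_criteria = "crit_other_substance_use",
                   window_days = 365,
                   notes = "See inhalant use disorder notes."),
    diagnosis_rule("Opioid use disorder", "other_substance",
                   c("crit_other_substance_use", "crit_used_opioid",
                     sud("osu")), 4,
                   cardinal_criteria = "crit_other_substance_use",
                   window_days = 365,
                   notes = "See inhalant use disorder notes."),
    diagnosis_rule("Phencyclidine use disorder", "other_substance",
                   c("crit_other_substance_use", "crit_used_pcp",
                     sud("osu")), 4,
                   cardinal_criteria = "crit_other_substance_use",
                   window_days = 365,
                   notes = "See inhalant use disorder notes."),
    diagnosis_rule("Sedative, hypnotic, or anxiolytic use disorder",
                   "other_substance",
                   c("crit_other_substance_use", "crit_used_sedative",
                     sud("osu")), 4,
                   cardinal_criteria = "crit_other_substance_use",
                   window_days = 365,
                   notes = "See inhalant use disorder notes."),
    diagnosis_rule("Stimulant use disorder", "other_substance",
                   c("crit_other_substance_use", "crit_used_stimulant",
                     sud("osu")), 4,
                   cardinal_criteria = "crit_other_substance_use",
                   window_days = 365,
                   notes = "See inhalant use disorder notes."),
    diagnosis_rule("Other or unknown substance use disorder",
                   "other_substance",
                   c("crit_other_substance_use", "crit_used_other",
                     sud("osu")), 4,
                   cardinal_criteria = "crit_other_substance_use",
                   window_days = 365,
                   notes = "See inhalant use disorder notes.")
  )

  catalog <- vapply(rules, `[[`, "", "diagnosis_name")

  instr <- new_instrument(items, modules, cr, rules, catalog,
                          name = "packaged fixture screener")
  issues <- validate_instrument(instr)
  if (length(issues)) {
    stop("internal error: fixture instrument fails validation:\n",
         paste0("  - ", issues, collapse = "\n"))
  }
  instr
}
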