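# Shared fixtures built in code. The packaged instrument is deterministic,
# so one copy serves the whole suite.

fixture <- build_fixture_instrument()

# Minimal single-module, single-item instrument.
toy_instrument <- function() {
  it <- screen_item("t1", "I felt worried.", "m1", "screener")
  mod <- screen_module("m1", "toy category", "t1",
                       threshold_rule(list(clause("t1", ">=", 3L))))
  cr <- criterion_def("c1", "worry", "t1", cardinal = TRUE)
  dr <- diagnosis_rule("Toy disorder", "m1", "c1", 1,
                       cardinal_criteria = "c1", window_days = 14)
  new_instrument(list(it), list(mod), list(cr), list(dr), "Toy disorder",
                 name = "toy")
}

# Four-Likert-item module (3 forward + 1 reverse) for summary-score tests.
toy4_instrument <- function() {
  items <- list(
    screen_item("q1", "Forward one.", "m1", "screener"),
    screen_item("q2", "Forward two.", "m1", "screener"),
    screen_item("q3", "Forward three.", "m1", "screener"),
    screen_item("q4", "Reverse one.", "m1", "screener",
                reverse_scored = TRUE)
  )
  mod <- screen_module("m1", "toy category", c("q1", "q2", "q3", "q4"),
                       threshold_rule(list(clause("q1", ">=", 3L),
                                           clause("q2", ">=", 3L),
                                           clause("q3", ">=", 3L),
                                           clause("q4", "<=", 3L))))
  cr <- criterion_def("c1", "symptom", c("q1", "q2", "q3", "q4"),
                      cardinal = TRUE)
  dr <- diagnosis_rule("Toy disorder", "m1", "c1", 1,
                       cardinal_criteria = "c1")
  new_instrument(items, mod = list(mod), list(cr), list(dr), "Toy disorder",
                 name = "toy4")
}

screener_item_ids_of <- function(instr) {
  unlist(lapply(instr$modules, `[[`, "screener_item_ids"), use.names = FALSE)
}

# Floor response for an item: symptom-absent answer.
floor_response <- function(item) {
  switch(item$response_kind,
         likert5 = if (item$reverse_scored) 5L else 1L,
         yes_no = FALSE,
         count_days = 0L)
}

# Complete symptom-absent script over a whole instrument.
all_floor_script <- function(instr) {
  stats::setNames(lapply(instr$items, floor_response), names(instr$items))
}

# A scripted respondent with a clear major depressive picture and nothing
# else; hand-traced in the administration/scoring tests.
depressed_script <- function(instr) {
  script <- all_floor_script(instr)
  script[c("dep_felt_sad", "dep_felt_depressed")] <- list(4L, 4L)
  script[["dep_felt_hopeless"]] <- 3L
  script[["dep_enjoyed_life"]] <- 2L       # reverse-scored: endorsed
  script[["dep_difficulty_enjoying"]] <- 4L
  script[["dep_interested_usual"]] <- 2L   # reverse-scored: endorsed
  script[c("dep_appetite", "dep_sleep", "dep_fatigue",
           "dep_concentrate")] <- list(4L, 4L, 5L, 4L)
  script[c("dep_slowed", "dep_worthless", "dep_death")] <- list(1L, 1L, 1L)
  script
}

# Random complete response vector over every item of an instrument.
random_full_responses <- function(instr) {
  stats::setNames(lapply(instr$items, function(it) {
    switch(it$response_kind,
           likert5 = sample.int(5, 1),
           yes_no = stats::runif(1) < 0.5,
           count_days = sample.int(it$timeframe_days + 1, 1) - 1L)
  }), names(instr$items))
}

# Direct m-of-n + cardinal evaluation used as the enumeration oracle.
oracle_diagnosis <- function(rule, endorsed) {
  sum(endorsed[rule$criterion_ids]) >= rule$required_count &&
    (length(rule$cardinal_criteria) == 0 ||
       any(endorsed[rule$cardinal_criteria]))
}

# Build a complete session directly from a full response script.
full_session <- function(instr, script, id = "scripted") {
  replay_responses(instr, script, session_id = id)
}
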