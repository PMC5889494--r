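test_that("the endorsement mapping is exact over all levels and polarities", {
  fwd <- screen_item("f", "x", "m", "screener")
  rev <- screen_item("r", "x", "m", "screener", reverse_scored = TRUE)
  # forward: endorsed iff often/always; reverse: iff never/rarely
  expect_equal(vapply(1:5, function(v) to_endorsement(fwd, v), logical(1)),
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(vapply(1:5, function(v) to_endorsement(rev, v), logical(1)),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))

  yn <- screen_item("y", "x", "m", "screener", response_kind = "yes_no",
                    timeframe_days = NA)
  expect_true(to_endorsement(yn, TRUE))
  expect_false(to_endorsement(yn, FALSE))

  cd <- screen_item("c", "x", "m", "screener", response_kind = "count_days",
                    timeframe_days = 30, endorse_cut = 5)
  expect_false(to_endorsement(cd, 4L))
  expect_true(to_endorsement(cd, 5L))

  expect_error(to_endorsement(fwd, TRUE), class = "adaptscreen_range_error")
})

test_that("criterion evaluation aggregates mapped items with severity", {
  resp <- all_floor_script(fixture)
  resp[["dep_felt_depressed"]] <- 5L
  ce <- evaluate_criterion(fixture, "crit_depressed_mood", resp)
  expect_true(ce$endorsed)
  expect_equal(ce$supporting_item_ids, "dep_felt_depressed")
  expect_equal(ce$max_frequency_level, 5L)

  # all mapped items at floor: not endorsed, severity level 1
  ce0 <- evaluate_criterion(fixture, "crit_depressed_mood",
                            all_floor_script(fixture))
  expect_false(ce0$endorsed)
  expect_length(ce0$supporting_item_ids, 0)
  expect_equal(ce0$max_frequency_level, 1L)

  # reverse items contribute 6 - value to the severity signal
  resp2 <- all_floor_script(fixture)
  resp2[["dep_enjoyed_life"]] <- 2L
  ce2 <- evaluate_criterion(fixture, "crit_anhedonia", resp2)
  expect_true(ce2$endorsed)
  expect_equal(ce2$supporting_item_ids, "dep_enjoyed_life")
  expect_equal(ce2$max_frequency_level, 4L)

  expect_error(evaluate_criterion(fixture, "crit_depressed_mood",
                                  list(dep_felt_sad = 1L)),
               class = "adaptscreen_incomplete_error")
})

test_that("the depression rule needs five criteria including a cardinal one", {
  rule <- fixture$diagnosis_rules[["Major depressive episode"]]
  base <- stats::setNames(rep(FALSE, 9), rule$criterion_ids)

  five_with_cardinal <- base
  five_with_cardinal[c("crit_depressed_mood", "crit_appetite_change",
                       "crit_sleep_disturbance", "crit_fatigue",
                       "crit_worthlessness")] <- TRUE
  expect_true(evaluate_diagnosis(rule, five_with_cardinal))

  five_no_cardinal <- base
  five_no_cardinal[c("crit_appetite_change", "crit_sleep_disturbance",
                     "crit_psychomotor_change", "crit_fatigue",
                     "crit_worthlessness")] <- TRUE
  expect_false(evaluate_diagnosis(rule, five_no_cardinal))

  four_with_cardinal <- base
  four_with_cardinal[c("crit_depressed_mood", "crit_anhedonia",
                       "crit_fatigue", "crit_worthlessness")] <- TRUE
  expect_false(evaluate_diagnosis(rule, four_with_cardinal))

  expect_error(evaluate_diagnosis(rule, base[-1]),
               class = "adaptscreen_incomplete_error")
})

test_that("rule evaluation equals brute-force enumeration for every fixture rule", {
  # exhaustive over all 2^n endorsement vectors, n <= 9 in the fixture
  for (rule in fixture$diagnosis_rules) {
    n <- length(rule$criterion_ids)
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    colnames(grid) <- rule$criterion_ids
    engine <- apply(grid, 1, function(row) evaluate_diagnosis(rule, row))
    oracle <- apply(grid, 1, function(row) oracle_diagnosis(rule, row))
    expect_identical(engine, oracle)
  }

  # the depression enumeration: 227 accepted of 512; minimum accepted
  # endorsement count is 5
  rule <- fixture$diagnosis_rules[["Major depressive episode"]]
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 9)))
  colnames(grid) <- rule$criterion_ids
  accepted <- apply(grid, 1, function(row) evaluate_diagnosis(rule, row))
  expect_equal(sum(accepted), 227)
  expect_equal(min(rowSums(grid[accepted, ])), 5)
})

test_that("adding an endorsement never removes a diagnosis", {
  set.seed(11)
  for (rep in 1:100) {
    rule <- fixture$diagnosis_rules[[sample(length(fixture$diagnosis_rules),
                                            1)]]
    e <- stats::setNames(stats::runif(length(rule$criterion_ids)) < 0.5,
                         rule$criterion_ids)
    if (!evaluate_diagnosis(rule, e) || all(e)) next
    flip <- sample(names(e)[!e], 1)
    e[flip] <- TRUE
    expect_true(evaluate_diagnosis(rule, e))
  }
})

test_that("the differential report is hand-traceable from a scripted session", {
  s <- full_session(fixture, depressed_script(fixture))
  rep <- build_differential(fixture, s)

  expect_equal(unname(rep$screen_status[["depressive"]]), "screened_in")
  expect_length(rep$incomplete_modules, 0)
  dx <- vapply(rep$included_diagnoses, `[[`, "", "diagnosis_name")
  expect_true("Major depressive episode" %in% dx)
  mde <- rep$included_diagnoses[[match("Major depressive episode", dx)]]
  # endorsed: depressed mood, anhedonia, appetite, sleep, fatigue,
  # concentration
  expect_equal(mde$endorsed_criteria_count, 6)
  expect_equal(mde$required_count, 5)
  expect_true(mde$cardinal_satisfied)
  # no diagnosis outside the depressive module
  expect_true(all(vapply(rep$included_diagnoses, `[[`, "", "module_id") ==
                    "depressive"))
  # severity inventory covers exactly the administered items
  expect_setequal(rep$severity_inventory$item_id, names(s$responses))

  # an all-floor respondent: everything screened out, empty differential
  rep0 <- build_differential(fixture, full_session(fixture,
                                                   all_floor_script(fixture)))
  expect_length(rep0$included_diagnoses, 0)
  expect_true(all(rep0$screen_status == "screened_out"))

  # screened in with subthreshold follow-ups: module listed, no diagnosis
  sub <- all_floor_script(fixture)
  sub[["dep_felt_depressed"]] <- 3L
  reps <- build_differential(fixture, full_session(fixture, sub))
  expect_equal(unname(reps$screen_status[["depressive"]]), "screened_in")
  expect_length(reps$included_diagnoses, 0)

  # an unfinished session is reported incomplete, never silently scored
  partial <- start_session(fixture)
  script <- depressed_script(fixture)
  for (iid in screener_item_ids_of(fixture)) {
    partial <- record_response(partial, iid, script[[iid]])
  }
  rep_part <- build_differential(fixture, partial)
  expect_true("depressive" %in% rep_part$incomplete_modules)
  expect_length(rep_part$included_diagnoses, 0)
})

test_that("anyone meeting a diagnosis rule would also have screened in", {
  # property over random complete response vectors: whenever a fixture
  # diagnosis rule fires on the full vector, the module's screen-in rule
  # fires too (cardinal criteria map to screener items at thresholds no
  # looser than screen-in)
  set.seed(2024)
  n <- 10000
  draws <- list()
  endorse_lookup <- list()
  for (iid in names(fixture$items)) {
    it <- fixture$items[[iid]]
    draws[[iid]] <- switch(it$response_kind,
      likert5 = sample.int(5, n, replace = TRUE),
      yes_no = stats::runif(n) < 0.3,
      count_days = sample.int(it$timeframe_days + 1, n,
                              replace = TRUE) - 1L)
    # endorsement is a pure per-level function of the item
    endorse_lookup[[iid]] <- if (it$response_kind == "likert5") {
      vapply(1:5, function(v) to_endorsement(it, v), logical(1))[draws[[iid]]]
    } else if (it$response_kind == "yes_no") {
      draws[[iid]]
    } else {
      draws[[iid]] >= it$endorse_cut
    }
  }
  crit_endorsed <- vapply(fixture$criteria, function(cr) {
    Reduce(`|`, endorse_lookup[cr$mapped_item_ids])
  }, logical(n))

  screen_in <- vapply(fixture$modules, function(mod) {
    fired <- vapply(mod$screen_in_rule$clauses, function(cl) {
      v <- draws[[cl$item_id]]
      switch(cl$comparator, ">=" = v >= cl$level, "<=" = v <= cl$level,
             "==" = v == cl$level)
    }, logical(n))
    rowSums(fired) > 0
  }, logical(n))

  for (rule in fixture$diagnosis_rules) {
    sub <- crit_endorsed[, rule$criterion_ids, drop = FALSE]
    fires <- rowSums(sub) >= rule$required_count &
      rowSums(sub[, rule$cardinal_criteria, drop = FALSE]) > 0
    expect_true(all(screen_in[fires, rule$module_id]))
  }

  # the vectorized screen-in evaluation above agrees with the engine on a
  # subsample
  idx <- sample.int(n, 50)
  for (i in idx) {
    resp <- lapply(draws, `[[`, i)
    for (mid in names(fixture$modules)) {
      expect_identical(unname(screen_in[i, mid]),
                       evaluate_screen_in(fixture, mid, resp))
    }
  }
})

test_that("module summary scores sum Likert levels with reverse mirroring", {
  toy4 <- toy4_instrument()
  expect_equal(module_summary_score(toy4, "m1",
                                    list(q1 = 2L, q2 = 3L, q3 = 4L,
                                         q4 = 2L)), 13)
  # floor: all-never forward, all-always reverse
  expect_equal(module_summary_score(toy4, "m1",
                                    list(q1 = 1L, q2 = 1L, q3 = 1L,
                                         q4 = 5L)), 4)
  # ceiling
  expect_equal(module_summary_score(toy4, "m1",
                                    list(q1 = 5L, q2 = 5L, q3 = 5L,
                                         q4 = 1L)), 20)
  expect_error(module_summary_score(toy4, "m1", list(q1 = 1L)),
               class = "adaptscreen_incomplete_error")
  # non-Likert modules take the categorical (kappa) path instead
  expect_error(module_summary_score(fixture, "panic",
                                    list(pan_attack_ever = TRUE)),
               class = "adaptscreen_unsupported_module_error")
  # psychotic sub-scales score only the tagged items
  resp <- all_floor_script(fixture)
  resp[["psy_voices"]] <- 3L
  expect_equal(module_summary_score(fixture, "psychotic", resp,
                                    symptom_tag = "hallucinations"), 6)
  expect_equal(module_summary_score(fixture, "psychotic", resp,
                                    symptom_tag = "delusions"), 3)
})

test_that("the rescreen form collects the differential's Likert items once", {
  s <- full_session(fixture, depressed_script(fixture))
  rep <- build_differential(fixture, s)
  form <- build_rescreen_form(rep, fixture)
  # the depressive differential pulls exactly the depression items (the
  # report includes several depressive diagnoses sharing items: no
  # duplicates, instrument order)
  expect_true(all(grepl("^dep_", form)))
  expect_false(any(duplicated(form)))
  expect_identical(form, names(fixture$items)[names(fixture$items) %in% form])
  expect_true(all(c("dep_felt_sad", "dep_appetite") %in% form))

  rep0 <- build_differential(fixture, full_session(fixture,
                                                   all_floor_script(fixture)))
  expect_identical(build_rescreen_form(rep0, fixture), character())
})
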