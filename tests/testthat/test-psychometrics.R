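test_that("icc_a1 matches a two-way ANOVA oracle on random matrices", {
  # oracle: mean squares from aov(), plugged into the absolute-agreement
  # single-measure formula
  oracle_icc <- function(m) {
    n <- nrow(m); k <- ncol(m)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     occ = factor(rep(seq_len(k), each = n)))
    a <- stats::anova(stats::aov(y ~ subj + occ, data = df))
    msr <- a["subj", "Mean Sq"]; msc <- a["occ", "Mean Sq"]
    mse <- a["Residuals", "Mean Sq"]
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    m <- matrix(stats::rnorm(2 * n), n, 2)
    expect_equal(icc_a1(m)$estimate, oracle_icc(m), tolerance = 1e-10)
  }
})

test_that("icc_a1 hits the agreement limits and degenerates gracefully", {
  # identical columns with row variance: perfect agreement
  m <- cbind(1:8, 1:8)
  r <- icc_a1(m)
  expect_equal(r$estimate, 1)
  expect_equal(r$band, "excellent")

  # independently permuted columns at large n: no agreement
  set.seed(5)
  x <- stats::rnorm(4000)
  r0 <- icc_a1(cbind(sample(x), sample(x)))
  expect_lt(abs(r0$estimate), 0.06)

  # no variance at all: not analyzable, not an exception
  rc <- icc_a1(cbind(rep(2, 6), rep(2, 6)))
  expect_equal(rc$band, "not_analyzable")
  expect_true(is.na(rc$estimate))

  # the CI bounds bracket the estimate
  set.seed(8)
  m <- simulate_retest_pairs_continuous(30, 0.7, seed = 17)
  r <- icc_a1(m)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  expect_true(r$p_value < 0.05)
})

test_that("cohen_kappa equals hand computation on exhaustive small tables", {
  # every 2x2 agreement table with n up to 20, compared against the
  # direct (p_o - p_e) / (1 - p_e) computation
  table_to_pairs <- function(a, b, c, d) {
    x <- c(rep("y", a + b), rep("n", c + d))
    y <- c(rep("y", a), rep("n", b), rep("y", c), rep("n", d))
    cbind(x, y)
  }
  checked <- 0
  for (n in c(4, 9, 14, 20)) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      p <- table_to_pairs(a, b, c, d)
      x_const <- (a + b) %in% c(0, n)
      y_const <- (a + c) %in% c(0, n)
      r <- cohen_kappa(p)
      if (x_const || y_const) {
        expect_equal(r$band, "not_analyzable")
        next
      }
      po <- (a + d) / n
      pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
      expect_equal(r$estimate, (po - pe) / (1 - pe), tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 1000)
})

test_that("kappa reproduces the worked 2x2 example and its boundaries", {
  # [[20, 5], [5, 12]] at n = 42: p_o = 32/42, p_e = (25/42)^2 + (17/42)^2
  x <- c(rep("y", 25), rep("n", 17))
  y <- c(rep("y", 20), rep("n", 5), rep("y", 5), rep("n", 12))
  r <- cohen_kappa(cbind(x, y))
  expect_equal(r$estimate, 0.50588235, tolerance = 1e-6)
  expect_true(r$p_value < 0.01)

  # perfect agreement across two categories
  expect_equal(cohen_kappa(cbind(c(1, 1, 2, 2), c(1, 1, 2, 2)))$estimate, 1)

  # a constant column (the single stable endorser case) is not analyzable
  const <- cbind(rep("yes", 10), rep("yes", 10))
  expect_equal(cohen_kappa(const)$band, "not_analyzable")
})

test_that("the percentile bootstrap is seeded, bounded, and degrades at low base rates", {
  perfect <- cbind(rep(c(TRUE, FALSE), 21), rep(c(TRUE, FALSE), 21))
  stat <- function(m) kappa_estimate(m[, 1], m[, 2])
  ci <- bootstrap_ci(perfect, stat, B = 500, seed = 7)
  expect_equal(ci$ci_high, 1)
  expect_true(ci$available)

  # identical seed, identical interval
  m <- simulate_retest_pairs_binary(42, 0.3, 0.6, seed = 2)
  ci1 <- bootstrap_ci(m, stat, B = 500, seed = 11)
  ci2 <- bootstrap_ci(m, stat, B = 500, seed = 11)
  expect_identical(ci1, ci2)

  # a single positive respondent: most resamples are degenerate and the
  # interval is reported unavailable
  rare <- cbind(c(TRUE, rep(FALSE, 41)), c(TRUE, rep(FALSE, 41)))
  ci3 <- bootstrap_ci(rare, stat, B = 500, seed = 3)
  expect_false(ci3$available)
  expect_true(is.na(ci3$ci_low))
})

test_that("the log transform zeroes the floor and tames right skew", {
  x <- c(7, 9, 12, 30)
  expect_identical(apply_transform(x, "none"), x)
  expect_equal(apply_transform(7, "log", floor = 7), 0)
  set.seed(21)
  skewed <- 7 + stats::rlnorm(500, 1, 0.9)
  expect_gt(sample_skew <- mean(((skewed - mean(skewed)) /
                                   stats::sd(skewed))^3), 1)
  transformed <- apply_transform(skewed, "log", floor = 7)
  skew_after <- mean(((transformed - mean(transformed)) /
                        stats::sd(transformed))^3)
  expect_lt(abs(skew_after), abs(sample_skew))
  expect_error(apply_transform(5, "log", floor = 7),
               class = "adaptscreen_range_error")
})

test_that("interpretation banding is piecewise, monotone and total", {
  expect_equal(band(0.50), "fair")
  expect_equal(band(0.67), "good")
  expect_equal(band(0.90), "excellent")
  expect_equal(band(0.90, cut_high = 0.80), "excellent")
  # boundary semantics: .60 is good; the high cut itself is excellent
  expect_equal(band(0.60), "good")
  expect_equal(band(0.75), "excellent")
  expect_equal(band(0.75, cut_high = 0.80), "good")
  expect_equal(band(NA), "not_analyzable")

  grid <- seq(-1, 1, by = 0.01)
  bands <- band(grid)
  expect_true(all(bands %in% c("fair", "good", "excellent")))
  ord <- c(fair = 1, good = 2, excellent = 3)
  expect_true(all(diff(ord[bands]) >= 0))
})

test_that("the reliability table mirrors the published row structure", {
  study <- simulate_study(retest_spec(n = 42), fixture, seed = 31)
  tab <- reliability_table(study, fixture, B = 300, seed = 9)

  # 17 published coefficient rows (8 Likert modules + 2 psychotic
  # sub-scales + alcohol count + panic/cannabis kappas + 4 trauma
  # kappas) plus the other-substance row
  expect_equal(nrow(tab), 18)
  expect_equal(sum(tab$coefficient_type == "kappa"), 7)
  expect_equal(sum(tab$coefficient_type == "icc_a1"), 11)
  expect_equal(sum(tab$module_id == "ptsd"), 4)
  expect_equal(sum(tab$module_id == "psychotic"), 3)
  # agoraphobia's skewed scores get the log transform
  expect_equal(tab$transform[tab$module_id == "agoraphobia"], "log")
  expect_true(all(tab$transform[tab$module_id != "agoraphobia"] == "none"))

  # duplicated occasions: every analyzable coefficient is exactly 1
  dup <- retest_study(study$occ1, study$occ1)
  tdup <- reliability_table(dup, fixture, B = 300, seed = 9)
  ok <- !is.na(tdup$estimate)
  expect_true(any(ok))
  expect_true(all(abs(tdup$estimate[ok] - 1) < 1e-12))
})

test_that("a single stable endorser leaves the module not analyzable", {
  # other-substance use answered no by everyone except one respondent who
  # says yes at both occasions: empty cells, kappa undefined
  script <- all_floor_script(fixture)
  yes_script <- script
  yes_script[["osu_use"]] <- TRUE
  yes_script[paste0("osu_fu_",
                    c("inhalant", "hallucinogen", "opioid", "pcp",
                      "sedative", "stimulant", "other"))] <- FALSE
  occ <- lapply(1:10, function(i) {
    full_session(fixture, if (i == 1) yes_script else script,
                 id = sprintf("r%02d", i))
  })
  study <- retest_study(occ, occ)
  tab <- reliability_table(study, fixture, B = 300, seed = 1)
  osu <- tab[tab$module_id == "other_substance", ]
  expect_equal(osu$band, "not_analyzable")
  expect_true(is.na(osu$estimate))
})

test_that("screening consistency isolates threshold-sensitive items", {
  script <- all_floor_script(fixture)
  s_base <- full_session(fixture, script, id = "r1-t1")
  # occasion 2 differs only in "I felt sad": sometimes vs often
  sometimes <- script; sometimes[["dep_felt_sad"]] <- 3L
  often <- script; often[["dep_felt_sad"]] <- 4L
  # under the published adjustment "sometimes" no longer screens in
  study <- retest_study(list(full_session(fixture, often, id = "a1")),
                        list(full_session(fixture, sometimes, id = "a2")))
  sc <- screening_consistency(study, fixture)
  dep <- sc[sc$module_id == "depressive", ]
  expect_equal(dep$one, 1)
  expect_equal(dep$solo_items, "dep_felt_sad")

  # duplicated occasions: no single-occasion screen-ins anywhere
  st <- simulate_study(retest_spec(n = 12), fixture, seed = 3)
  dup <- retest_study(st$occ1, st$occ1)
  sc2 <- screening_consistency(dup, fixture)
  expect_true(all(sc2$one == 0))

  # all-floor study: every module "neither"
  floor_study <- retest_study(list(s_base), list(s_base))
  sc3 <- screening_consistency(floor_study, fixture)
  expect_true(all(sc3$neither == 1))
  expect_true(all(sc3$both == 0))
})

test_that("over-endorsement review flags rates strictly above 15%", {
  toy <- toy_instrument()
  make_sessions <- function(n_endorsed, n_total) {
    lapply(seq_len(n_total), function(i) {
      replay_responses(toy, list(t1 = if (i <= n_endorsed) 4L else 1L),
                       session_id = sprintf("s%03d", i))
    })
  }
  expect_equal(flag_overendorsed(make_sessions(16, 100), toy), "t1")
  # boundary: exactly 15% is not flagged
  expect_identical(flag_overendorsed(make_sessions(15, 100), toy),
                   character())
  expect_identical(flag_overendorsed(make_sessions(0, 100), toy),
                   character())
})
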