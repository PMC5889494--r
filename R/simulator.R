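#' Synthetic respondents with known ground truth
#'
#' The simulator makes every stage of the engine testable without patient
#' data. Two layers are provided: a graded-response style session generator
#' driven by per-module latent severities (for engine and scoring tests),
#' and reliability-targeted paired-study generators whose cross-occasion
#' agreement matches a requested ICC or kappa in closed form (for
#' psychometric parameter-recovery tests). Every simulated study carries a
#' ground-truth ledger of its generating parameters.
#'
#' @name simulator
NULL

#' Construct a respondent profile
#'
#' @param theta Named numeric vector of latent severities in `[0, 1]`, one
#'   per module of the instrument.
#' @param diagnoses Character vector of diagnosis names the respondent
#'   "truly" has; the corresponding module severities are raised to at
#'   least 0.85 so flags imply elevated severity.
#' @param population `"nonclinical"` or `"clinical"` (metadata).
#' @param instr Instrument used to resolve diagnosis -> module links.
#' @return A list of class `respondent_profile`.
#' @export
respondent_profile <- function(theta, diagnoses = character(),
                               population = c("nonclinical", "clinical"),
                               instr = NULL) {
  population <- match.arg(population)
  theta <- pmin(pmax(theta, 0), 1)
  if (length(diagnoses) && !is.null(instr)) {
    for (d in diagnoses) {
      rule <- instr$diagnosis_rules[[d]]
      if (!is.null(rule)) {
        theta[[rule$module_id]] <- max(theta[[rule$module_id]], 0.85)
      }
    }
  }
  structure(list(theta = theta, diagnoses = diagnoses,
                 population = population),
            class = "respondent_profile")
}

#' Draw respondent profiles from a population prior
#'
#' Latent severities are drawn per module from Beta(1, 4) for the
#' nonclinical population (mostly low severity) and Beta(2, 2) for the
#' clinical population — a declared modeling convenience, not a claim about
#' real response distributions.
#'
#' @param instr A `screen_instrument`.
#' @param n Number of profiles.
#' @param population `"nonclinical"` or `"clinical"`.
#' @param seed RNG seed.
#' @return List of `respondent_profile` objects.
#' @export
sample_profiles <- function(instr, n, population = c("nonclinical",
                                                     "clinical"),
                            seed = 1) {
  population <- match.arg(population)
  shape <- if (population == "nonclinical") c(1, 4) else c(2, 2)
  mods <- names(instr$modules)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      respondent_profile(
        stats::setNames(stats::rbeta(length(mods), shape[1], shape[2]),
                        mods),
        population = population)
    })
  })
}

# One response draw for an item given module severity theta.
# Likert levels come from multiplicative log-normal noise on theta with
# fixed cut-points at 0.2/0.4/0.6/0.8 (theta = 0 answers "never" with
# certainty); reverse items mirror the level; yes/no are Bernoulli(theta);
# day counts are Binomial(timeframe, theta / 2).
draw_response <- function(item, theta, likert_sd = 0.25) {
  if (item$response_kind == "likert5") {
    x <- theta * exp(stats::rnorm(1, 0, likert_sd))
    lev <- 1L + findInterval(x, c(0.2, 0.4, 0.6, 0.8))
    lev <- min(lev, 5L)
    if (item$reverse_scored) 6L - lev else lev
  } else if (item$response_kind == "yes_no") {
    stats::runif(1) < theta
  } else {
    stats::rbinom(1, item$timeframe_days, theta / 2)
  }
}

#' Simulate one complete adaptive session
#'
#' Runs the session engine, answering every requested item from the
#' profile's latent severity for that item's module. Fully reproducible
#' given the seed.
#'
#' @param instr A `screen_instrument`.
#' @param profile A `respondent_profile`.
#' @param seed RNG seed.
#' @param session_id Session identifier.
#' @return A complete `screen_session`.
#' @export
simulate_session <- function(instr, profile, seed = 1,
                             session_id = "simulated") {
  with_seed(seed, {
    s <- start_session(instr, session_id)
    while (length(s$pending)) {
      iid <- s$pending[[1]]
      it <- instr$items[[iid]]
      s <- record_response(s, iid, draw_response(it, profile$theta[[it$module_id]]))
    }
    s
  })
}

#' Simulate paired continuous scores with a target absolute-agreement ICC
#'
#' Generates `y_ij = b_i + e_ij` with `b ~ N(0, rho)` and
#' `e ~ N(0, 1 - rho)` and no occasion effect, so the population
#' absolute-agreement ICC equals `rho` exactly. An optional occasion shift
#' stress-tests the absolute-agreement vs consistency distinction.
#'
#' @param n Number of respondents.
#' @param true_icc Generating reliability in `[0, 1)`.
#' @param seed RNG seed.
#' @param occasion_shift Additive shift applied to occasion 2 (default 0).
#' @return An `n x 2` score matrix.
#' @export
simulate_retest_pairs_continuous <- function(n, true_icc, seed = 1,
                                             occasion_shift = 0) {
  if (true_icc < 0 || true_icc >= 1) {
    stop_adaptscreen("true_icc must lie in [0, 1)", "adaptscreen_range_error")
  }
  with_seed(seed, {
    b <- stats::rnorm(n, 0, sqrt(true_icc))
    e <- matrix(stats::rnorm(2 * n, 0, sqrt(1 - true_icc)), n, 2)
    m <- b + e
    m[, 2] <- m[, 2] + occasion_shift
    m
  })
}

# Exchangeable 2x2 joint for binary pairs with marginal p and agreement
# kappa: p11 = p^2 + kappa p(1-p), p10 = p01 = (1-kappa) p(1-p).
binary_joint <- function(p, kappa) {
  q <- 1 - p
  probs <- c(p11 = p^2 + kappa * p * q,
             p10 = (1 - kappa) * p * q,
             p01 = (1 - kappa) * p * q,
             p00 = q^2 + kappa * p * q)
  if (any(probs < -1e-12)) {
    stop_adaptscreen(
      sprintf("infeasible (p = %.3f, kappa = %.3f) combination", p, kappa),
      "adaptscreen_range_error")
  }
  pmax(probs, 0)
}

#' Simulate paired binary responses with target prevalence and kappa
#'
#' Draws i.i.d. pairs from the exchangeable 2x2 joint distribution with
#' both marginals equal to `prevalence` and population Cohen's kappa equal
#' to `true_kappa`.
#'
#' @param n Number of respondents.
#' @param prevalence Marginal endorsement probability in (0, 1).
#' @param true_kappa Generating agreement in `[-1, 1]` (must yield a valid
#'   joint).
#' @param seed RNG seed.
#' @return An `n x 2` logical matrix.
#' @export
simulate_retest_pairs_binary <- function(n, prevalence, true_kappa,
                                         seed = 1) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop_adaptscreen("prevalence must lie in (0, 1)",
                     "adaptscreen_range_error")
  }
  probs <- binary_joint(prevalence, true_kappa)
  with_seed(seed, {
    cell <- sample.int(4, n, replace = TRUE, prob = probs)
    cbind(cell %in% c(1, 2), cell %in% c(1, 3))
  })
}

#' Specify a reliability-targeted retest study
#'
#' Default targets reproduce the published coefficient table at the
#' published paired sample size (n = 42): summary-score ICC targets for the
#' Likert modules (with hallucination/delusion sub-scale targets for the
#' psychotic module and a right-skewed score distribution for agoraphobia),
#' an ICC target for the drinking-days count, and kappa-with-prevalence
#' targets for the categorical screeners. Prevalences are not published;
#' the defaults are plausible for a young nonclinical sample, with the
#' other-substance prevalence set so that a single stable endorser is
#' expected (the degenerate case the analysis must tolerate) and a low
#' work-trauma base rate under which the bootstrap fails.
#'
#' @param n Respondents per occasion.
#' @param icc_targets Named ICC targets (modules and `psychotic_*`
#'   sub-scales).
#' @param kappa_targets Named list of `c(kappa, prevalence)` per
#'   categorical screener item.
#' @param B Bootstrap resamples used downstream.
#' @return A list of class `retest_spec`.
#' @export
retest_spec <- function(n = 42,
                        icc_targets = c(depressive = 0.67, manic = 0.50,
                                        gad = 0.60, agoraphobia = 0.90,
                                        social_anxiety = 0.83, ocd = 0.68,
                                        adhd = 0.63,
                                        psychotic_hallucinations = 0.65,
                                        psychotic_delusions = 0.74,
                                        alcohol = 0.70),
                        kappa_targets = list(
                          pan_attack_ever = c(0.86, 0.30),
                          pts_experienced = c(0.86, 0.50),
                          pts_witnessed = c(0.60, 0.35),
                          pts_close = c(0.76, 0.50),
                          pts_work = c(0.79, 0.06),
                          can_use = c(0.84, 0.20),
                          osu_use = c(1.00, 1 / 42)),
                        B = 2000) {
  stopifnot(all(icc_targets >= 0 & icc_targets < 1))
  for (kt in kappa_targets) {
    stopifnot(kt[1] >= -1, kt[1] <= 1, kt[2] > 0, kt[2] < 1)
    binary_joint(kt[2], kt[1])  # errors on infeasible combinations
  }
  structure(list(n = n, icc_targets = icc_targets,
                 kappa_targets = kappa_targets, B = B),
            class = "retest_spec")
}

# Distribute an integer summary score S in [k, 5k] over k Likert levels as
# evenly as possible; reverse items store the mirrored level.
decompose_score <- function(S, items_rev) {
  k <- length(items_rev)
  S <- max(k, min(5 * k, round(S)))
  base <- S %/% k
  rem <- S - base * k
  lev <- rep(base, k) + c(rep(1, rem), rep(0, k - rem))
  ifelse(items_rev, 6 - lev, lev)
}

#' Simulate a full paired test-retest study
#'
#' Builds complete paired sessions whose module-level agreement matches the
#' spec's targets. Likert-module summary scores are generated as correlated
#' continuous pairs (agreement = the target ICC) centred mid-scale, then
#' decomposed into item responses summing to the (rounded, clamped) score;
#' the agoraphobia score uses a log-normal shape so its distribution is
#' right-skewed, as observed for that domain. Categorical screeners are
#' drawn from the exchangeable joint with the target kappa and prevalence;
#' the drinking-days count uses a correlated integer pair on 0..30.
#' Follow-up responses of screened-in modules are drawn from a severity
#' proxy derived from the screener score, so every session completes. The
#' generating parameters travel with the study as its ground-truth ledger.
#'
#' @param spec A `retest_spec`.
#' @param instr A `screen_instrument` (the packaged fixture layout:
#'   module ids as in [build_fixture_instrument()]).
#' @param seed RNG seed.
#' @return A `retest_study` with a `truth` ledger.
#' @export
simulate_study <- function(spec, instr, seed = 1) {
  n <- spec$n
  with_seed(seed, {
    resp1 <- vector("list", n)
    resp2 <- vector("list", n)
    for (i in seq_len(n)) {
      resp1[[i]] <- list()
      resp2[[i]] <- list()
    }
    put <- function(occ, i, iid, v) {
      if (occ == 1) resp1[[i]][[iid]] <<- v else resp2[[i]][[iid]] <<- v
    }

    for (mid in names(instr$modules)) {
      mod <- instr$modules[[mid]]
      kinds <- vapply(mod$screener_item_ids,
                      function(x) instr$items[[x]]$response_kind, "")
      if (all(kinds == "likert5")) {
        if (mid == "psychotic") {
          for (tag in c("hallucinations", "delusions")) {
            ids <- mod$screener_item_ids[vapply(mod$screener_item_ids,
              function(x) identical(instr$items[[x]]$symptom_tag, tag),
              logical(1))]
            rho <- icc_target_of(spec, paste0("psychotic_", tag))
            k <- length(ids)
            b <- stats::rnorm(n, 0, sqrt(rho))
            z <- b + matrix(stats::rnorm(2 * n, 0, sqrt(1 - rho)), n, 2)
            S <- 1.8 * k + 0.75 * k * z
            rev <- vapply(ids, function(x) instr$items[[x]]$reverse_scored,
                          logical(1))
            for (i in seq_len(n)) {
              for (occ in 1:2) {
                lev <- decompose_score(S[i, occ], rev)
                for (j in seq_along(ids)) put(occ, i, ids[j], as.integer(lev[j]))
              }
            }
          }
        } else {
          rho <- icc_target_of(spec, mid)
          ids <- mod$screener_item_ids
          k <- length(ids)
          rev <- vapply(ids, function(x) instr$items[[x]]$reverse_scored,
                        logical(1))
          b <- stats::rnorm(n, 0, sqrt(rho))
          z <- b + matrix(stats::rnorm(2 * n, 0, sqrt(1 - rho)), n, 2)
          if (mid == "agoraphobia") {
            # right-skewed scores hugging the floor
            S <- k + exp(0.55 + 0.85 * z) - exp(0.55)
          } else {
            S <- 2.2 * k + (0.8 * k) * z
          }
          for (i in seq_len(n)) {
            for (occ in 1:2) {
              lev <- decompose_score(S[i, occ], rev)
              for (j in seq_along(ids)) put(occ, i, ids[j], as.integer(lev[j]))
            }
          }
        }
      } else if (all(kinds == "count_days")) {
        rho <- icc_target_of(spec, mid)
        iid <- mod$screener_item_ids[1]
        top <- instr$items[[iid]]$timeframe_days
        b <- stats::rnorm(n, 0, sqrt(rho))
        z <- b + matrix(stats::rnorm(2 * n, 0, sqrt(1 - rho)), n, 2)
        cnt <- pmin(pmax(round(6 + 5 * z), 0), top)
        for (i in seq_len(n)) {
          for (occ in 1:2) put(occ, i, iid, as.integer(cnt[i, occ]))
        }
      } else {
        for (iid in mod$screener_item_ids) {
          kt <- spec$kappa_targets[[iid]]
          if (is.null(kt)) kt <- c(0.8, 0.2)
          pairs <- simulate_retest_pairs_binary(n, kt[2], kt[1],
                                                seed = NULL)
          for (i in seq_len(n)) {
            put(1, i, iid, pairs[i, 1])
            put(2, i, iid, pairs[i, 2])
          }
        }
      }
    }

    # Complete the adaptive sessions: answer follow-ups of screened-in
    # modules from a severity proxy derived from the screener responses.
    finish <- function(resp, rid) {
      s <- start_session(instr, rid)
      for (iid in screener_item_ids(instr)) {
        s <- record_response(s, iid, resp[[iid]])
      }
      while (length(s$pending)) {
        iid <- s$pending[[1]]
        it <- instr$items[[iid]]
        mod <- instr$modules[[it$module_id]]
        theta <- module_theta_proxy(instr, mod, resp)
        s <- record_response(s, iid, draw_response(it, theta))
      }
      s
    }
    occ1 <- lapply(seq_len(n), function(i) {
      finish(resp1[[i]], sprintf("r%03d-t1", i))
    })
    occ2 <- lapply(seq_len(n), function(i) {
      finish(resp2[[i]], sprintf("r%03d-t2", i))
    })

    retest_study(occ1, occ2,
                 retest_interval_days = round(stats::runif(n, 2, 7)),
                 truth = list(seed = seed, n = n,
                              icc_targets = as.list(spec$icc_targets),
                              kappa_targets = spec$kappa_targets))
  })
}

# Target lookup tolerating missing names (defaults to 0.7).
icc_target_of <- function(spec, name) {
  v <- unname(spec$icc_targets[name])
  if (length(v) != 1 || is.na(v)) 0.7 else v
}

# Severity proxy in [0, 1] from a module's screener responses; drives
# follow-up draws when completing simulated sessions.
module_theta_proxy <- function(instr, mod, resp) {
  ids <- mod$screener_item_ids
  kinds <- vapply(ids, function(x) instr$items[[x]]$response_kind, "")
  if (all(kinds == "likert5")) {
    k <- length(ids)
    sc <- sum(vapply(ids, function(x) {
      v <- as.numeric(resp[[x]])
      if (instr$items[[x]]$reverse_scored) 6 - v else v
    }, numeric(1)))
    (sc - k) / (4 * k)
  } else if (all(kinds == "count_days")) {
    min(1, as.numeric(resp[[ids[1]]]) / 15)
  } else {
    mean(vapply(ids, function(x) as.numeric(resp[[x]]), numeric(1)))
  }
}
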