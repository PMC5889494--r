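#' Test-retest reliability analysis
#'
#' Implements the quantitative validation toolkit: single-measure
#' absolute-agreement intraclass correlation (two-way model, the coefficient
#' appropriate when the "rater" — the respondent — is the same at test and
#' retest), Cohen's kappa for categorical screeners with percentile
#' bootstrap confidence intervals, a log transform for skewed summary
#' scores, fair/good/excellent interpretation bands, screening-consistency
#' summaries and over-endorsement review flags.
#'
#' @name psychometrics
NULL

#' Reliability result container
#' @noRd
reliability_result <- function(label, coefficient_type, estimate = NA_real_,
                               ci_low = NA_real_, ci_high = NA_real_,
                               p_value = NA_real_, band = "not_analyzable",
                               transform_applied = "none", n = NA_integer_,
                               note = NULL) {
  structure(list(
    label = label, coefficient_type = coefficient_type,
    estimate = estimate, ci_low = ci_low, ci_high = ci_high,
    p_value = p_value, band = band, transform_applied = transform_applied,
    n = n, note = note
  ), class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  if (x$band == "not_analyzable" && is.na(x$estimate)) {
    cat(sprintf("<reliability_result> %s: not analyzable (%s)\n",
                x$label, x$note %||% "degenerate data"))
    return(invisible(x))
  }
  ci <- if (is.na(x$ci_low)) "CI unavailable" else {
    sprintf("95%% CI %.2f-%.2f", x$ci_low, x$ci_high)
  }
  cat(sprintf("<reliability_result> %s: %s = %.3f (%s), p = %.2g, %s\n",
              x$label, x$coefficient_type, x$estimate, ci, x$p_value,
              x$band))
  invisible(x)
}

# Two-way ANOVA mean squares for an n x k score matrix (rows = subjects,
# columns = occasions): rows, columns, error.
anova_mean_squares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Single-measure absolute-agreement intraclass correlation
#'
#' Two-way model, absolute agreement, single measure — ICC(A,1) in the
#' McGraw-Wong taxonomy:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with subjects as rows and the k occasions as columns. The p-value tests
#' the null of zero reliability with `F = MS_R / MS_E` on `(n-1,
#' (n-1)(k-1))` degrees of freedom; the two-sided 95% confidence interval
#' uses the F-distribution interval with Satterthwaite degrees of freedom.
#'
#' @param pairs An `n x 2` (generally `n x k`) numeric score matrix.
#' @param label Row label carried into reliability tables.
#' @param cut_high Banding cut between good and excellent (0.75 or 0.80).
#' @param transform_applied Recorded transform tag (`"none"` or `"log"`).
#' @param conf_level Confidence level for the interval.
#' @return A `reliability_result`. Degenerate inputs (constant rows overall
#'   or zero variance) yield a `not_analyzable` result rather than an error.
#' @export
icc_a1 <- function(pairs, label = "scores", cut_high = 0.75,
                   transform_applied = "none", conf_level = 0.95) {
  m <- as.matrix(pairs)
  if (nrow(m) < 3 || ncol(m) < 2 || anyNA(m)) {
    return(reliability_result(label, "icc_a1", n = nrow(m),
                              transform_applied = transform_applied,
                              note = "need >= 3 complete score pairs"))
  }
  ms <- anova_mean_squares(m)
  n <- ms$n; k <- ms$k
  denom <- ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse)
  if (!is.finite(denom) || denom <= 0 ||
      (ms$msr == 0 && ms$mse == 0 && ms$msc == 0)) {
    return(reliability_result(label, "icc_a1", n = n,
                              transform_applied = transform_applied,
                              note = "degenerate ANOVA (no variance)"))
  }
  est <- (ms$msr - ms$mse) / denom

  # H0: ICC = 0 via F = MSR/MSE.
  p <- if (ms$mse == 0) {
    0
  } else {
    stats::pf(ms$msr / ms$mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }

  # McGraw & Wong F interval for ICC(A,1).
  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_)
  if (ms$mse == 0 && ms$msc == ms$mse) {
    ci <- c(1, 1)
  } else if (est < 1) {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v_num <- (a * ms$msc + b * ms$mse)^2
    v_den <- (a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1))
    v <- v_num / v_den
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - f_l * ms$mse) /
      (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (f_u * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
    ci <- c(max(-1, lo), min(1, hi))
  } else {
    ci <- c(NA_real_, NA_real_)
  }

  reliability_result(label, "icc_a1", estimate = est,
                     ci_low = ci[1], ci_high = ci[2], p_value = p,
                     band = band(est, cut_high), n = n,
                     transform_applied = transform_applied)
}

#' Cohen's kappa for paired categorical responses
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between
#' two occasions. The p-value tests the null of chance agreement with the
#' large-sample standard error of kappa under independence (Fleiss). A
#' constant column (an empty cell structure, as when only one respondent
#' ever endorses use and does so at both occasions) yields a
#' `not_analyzable` result rather than an error.
#'
#' @param pairs An `n x 2` matrix/data frame of categorical (or logical)
#'   responses.
#' @param label Row label.
#' @param cut_high Banding cut between good and excellent.
#' @return A `reliability_result`.
#' @export
cohen_kappa <- function(pairs, label = "screener", cut_high = 0.75) {
  m <- as.matrix(pairs)
  if (nrow(m) < 2 || anyNA(m)) {
    return(reliability_result(label, "kappa", n = nrow(m),
                              note = "need >= 2 complete pairs"))
  }
  x <- as.character(m[, 1])
  y <- as.character(m[, 2])
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(reliability_result(label, "kappa", n = nrow(m),
                              note = "constant column: empty cells in the 2-way table"))
  }
  est <- kappa_estimate(x, y)
  n <- length(x)
  cats <- union(x, y)
  px <- vapply(cats, function(c) mean(x == c), numeric(1))
  py <- vapply(cats, function(c) mean(y == c), numeric(1))
  pe <- sum(px * py)
  # Fleiss large-sample SE of kappa under H0: independence.
  se0 <- sqrt((pe + pe^2 - sum(px * py * (px + py))) / (n * (1 - pe)^2))
  z <- est / se0
  p <- 2 * stats::pnorm(-abs(z))
  reliability_result(label, "kappa", estimate = est, p_value = p,
                     band = band(est, cut_high), n = n)
}

# Point estimate of kappa; NA when a column is constant.
kappa_estimate <- function(x, y) {
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  po <- mean(x == y)
  cats <- union(x, y)
  pe <- sum(vapply(cats, function(c) mean(x == c) * mean(y == c), numeric(1)))
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Percentile bootstrap confidence interval over respondent-level resamples
#'
#' Resamples rows of the paired data with replacement, recomputes the
#' statistic, and returns the percentile interval. Resamples on which the
#' statistic is undefined (e.g., a constant column for kappa) are skipped
#' and counted; when more than `degenerate_limit` of the resamples are
#' degenerate — as happens at very low base rates — the interval is
#' reported unavailable. The default limit of 25% cleanly separates a
#' single endorser (whose exclusion probability under respondent
#' resampling is about `exp(-1)`, 37%) from two or more (at most about
#' 14%): with a quarter of the resamples failing, the percentile
#' endpoints would be estimated from a heavily censored distribution.
#'
#' @param pairs `n x 2` paired data (rows are respondents).
#' @param statistic Function taking a two-column matrix and returning a
#'   scalar (NA for degenerate resamples).
#' @param B Number of bootstrap resamples (>= 200).
#' @param seed RNG seed; resampling is reproducible given the seed.
#' @param conf_level Confidence level.
#' @param degenerate_limit Fraction of degenerate resamples above which
#'   the interval is reported unavailable.
#' @return List with `ci_low`, `ci_high`, `available` (logical),
#'   `n_degenerate`, `B`.
#' @export
bootstrap_ci <- function(pairs, statistic, B = 2000, seed = 1,
                         conf_level = 0.95, degenerate_limit = 0.25) {
  stopifnot(B >= 200)
  m <- as.matrix(pairs)
  n <- nrow(m)
  stats_b <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    vapply(seq_len(B), function(b) statistic(m[idx[b, ], , drop = FALSE]),
           numeric(1))
  })
  degen <- sum(is.na(stats_b))
  if (degen > B * degenerate_limit) {
    return(list(ci_low = NA_real_, ci_high = NA_real_, available = FALSE,
                n_degenerate = degen, B = B))
  }
  alpha <- 1 - conf_level
  qs <- stats::quantile(stats_b, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2], available = TRUE,
       n_degenerate = degen, B = B)
}

#' Transform summary scores before ICC analysis
#'
#' The log transform maps `x` to `log(x - floor + 1)` where `floor` is the
#' theoretical minimum of the score (the item count for a Likert sum), so a
#' floor-valued score maps to 0. Used for strongly right-skewed score
#' distributions.
#'
#' @param scores Numeric vector or matrix.
#' @param kind `"none"` or `"log"`.
#' @param floor Theoretical minimum of the score scale; defaults to the
#'   observed minimum.
#' @return Transformed scores with the same shape.
#' @export
apply_transform <- function(scores, kind = c("none", "log"),
                            floor = min(scores)) {
  kind <- match.arg(kind)
  if (kind == "none") return(scores)
  shifted <- scores - floor + 1
  if (any(shifted <= 0)) {
    stop_adaptscreen("log transform needs scores at or above the floor",
                     "adaptscreen_range_error")
  }
  out <- log(shifted)
  attributes(out) <- attributes(scores)
  out
}

#' Interpretation band for a reliability coefficient
#'
#' Coefficients below .60 are "fair" (questionable); from .60 up to
#' `cut_high` (.75 by one convention, .80 by another) "good"; at or above
#' `cut_high` "excellent".
#'
#' @param estimate Coefficient in `[-1, 1]` (NA allowed).
#' @param cut_high Good/excellent boundary: 0.75 (default) or 0.80.
#' @return `"fair"`, `"good"`, `"excellent"`, or `"not_analyzable"` for NA.
#' @export
band <- function(estimate, cut_high = 0.75) {
  stopifnot(cut_high %in% c(0.75, 0.80))
  vapply(estimate, function(e) {
    if (is.na(e)) return("not_analyzable")
    if (e < 0.60) "fair" else if (e < cut_high) "good" else "excellent"
  }, "")
}

#' Bundle paired test-retest sessions into a study
#'
#' @param occ1,occ2 Lists of complete `screen_session` objects, paired by
#'   position, both administered with the same instrument.
#' @param respondent_ids Respondent identifiers (defaults to positions).
#' @param retest_interval_days Per-respondent retest interval metadata.
#' @param truth Optional ground-truth ledger (attached by the simulator).
#' @return A list of class `retest_study`.
#' @export
retest_study <- function(occ1, occ2, respondent_ids = NULL,
                         retest_interval_days = NA_real_, truth = NULL) {
  if (length(occ1) != length(occ2)) {
    stop("occasions must pair the same respondents")
  }
  n <- length(occ1)
  structure(list(
    respondent_ids = respondent_ids %||% sprintf("r%03d", seq_len(n)),
    occ1 = occ1, occ2 = occ2,
    retest_interval_days = rep_len(retest_interval_days, n),
    truth = truth
  ), class = "retest_study")
}

#' @export
print.retest_study <- function(x, ...) {
  cat(sprintf("<retest_study> %d respondents, 2 occasions\n",
              length(x$occ1)))
  if (!all(is.na(x$retest_interval_days))) {
    cat(sprintf("  mean retest interval %.2f days\n",
                mean(x$retest_interval_days, na.rm = TRUE)))
  }
  if (!is.null(x$truth)) cat("  ground-truth ledger attached\n")
  invisible(x)
}

# Paired scores/values for one scoring function over a study.
study_pairs <- function(study, f) {
  cbind(vapply(study$occ1, f, numeric(1)),
        vapply(study$occ2, f, numeric(1)))
}

#' Test-retest reliability table for a study
#'
#' Reproduces the published analysis plan over the 13 screening modules:
#' Likert modules get a summary-score ICC (with the psychotic module
#' additionally reported as hallucination and delusion sub-scales, and a log
#' transform applied automatically to strongly right-skewed score
#' distributions, |skewness| > 1); the day-count alcohol screener gets an
#' ICC on the raw counts; the single yes/no screeners (panic, cannabis,
#' other substance) and the four trauma-exposure questions get Cohen's
#' kappa with percentile bootstrap confidence intervals. Rows where the
#' coefficient is undefined (constant columns) are carried as
#' `not_analyzable`.
#'
#' @param study A `retest_study` of complete sessions.
#' @param instr The instrument both occasions used.
#' @param cut_high Banding cut between good and excellent.
#' @param B Bootstrap resamples for kappa intervals.
#' @param seed Seed for the bootstrap.
#' @return A data frame of class `reliability_table` with one row per
#'   coefficient (module, sub-scale, or categorical item), in instrument
#'   order.
#' @export
reliability_table <- function(study, instr, cut_high = 0.75, B = 2000,
                              seed = 1) {
  rows <- list()
  boot_i <- 0
  add_icc <- function(label, module_id, scores1, scores2, floor_value) {
    m <- cbind(scores1, scores2)
    transform <- "none"
    if (sample_skewness(as.vector(m)) > 1) {
      m <- apply_transform(m, "log", floor = floor_value)
      transform <- "log"
    }
    r <- icc_a1(m, label = label, cut_high = cut_high,
                transform_applied = transform)
    r$module_id <- module_id
    rows[[length(rows) + 1]] <<- r
  }
  add_kappa <- function(label, module_id, item_id) {
    v <- study_pairs(study, function(s) {
      as.numeric(s$responses[[item_id]])
    })
    # base-rate guard: a category carried by a single respondent leaves
    # empty cells in the 2-way table, so the coefficient is reported as
    # not analyzable even though kappa is formally defined
    min_count <- min(table(v[, 1]), table(v[, 2]))
    r <- if (length(unique(v[, 1])) < 2 || length(unique(v[, 2])) < 2 ||
             min_count < 2) {
      reliability_result(label, "kappa", n = nrow(v),
                         note = "empty cells: category endorsed by fewer than 2 respondents")
    } else {
      cohen_kappa(v, label = label, cut_high = cut_high)
    }
    boot_i <<- boot_i + 1
    if (!is.na(r$estimate)) {
      ci <- bootstrap_ci(v, function(m) kappa_estimate(m[, 1], m[, 2]),
                         B = B, seed = child_seed(seed, boot_i))
      if (ci$available) {
        r$ci_low <- ci$ci_low
        r$ci_high <- ci$ci_high
      } else {
        r$note <- "bootstrap failed: low base rate"
      }
    }
    r$module_id <- module_id
    rows[[length(rows) + 1]] <<- r
  }

  for (mid in names(instr$modules)) {
    mod <- instr$modules[[mid]]
    kinds <- vapply(mod$screener_item_ids,
                    function(i) instr$items[[i]]$response_kind, "")
    if (all(kinds == "likert5")) {
      k <- length(mod$screener_item_ids)
      sc <- study_pairs(study, function(s) {
        module_summary_score(instr, mid, s$responses)
      })
      add_icc(mod$category_name, mid, sc[, 1], sc[, 2], floor_value = k)
      if (mid == "psychotic") {
        for (tag in c("hallucinations", "delusions")) {
          ids <- mod$screener_item_ids[vapply(mod$screener_item_ids,
            function(i) identical(instr$items[[i]]$symptom_tag, tag),
            logical(1))]
          sc <- study_pairs(study, function(s) {
            module_summary_score(instr, mid, s$responses, symptom_tag = tag)
          })
          add_icc(paste0(mod$category_name, " - ", tag), mid,
                  sc[, 1], sc[, 2], floor_value = length(ids))
        }
      }
    } else if (all(kinds == "count_days")) {
      sc <- study_pairs(study, function(s) {
        as.numeric(s$responses[[mod$screener_item_ids[1]]])
      })
      add_icc(mod$category_name, mid, sc[, 1], sc[, 2], floor_value = 0)
    } else {
      # categorical yes/no screeners: one kappa per item
      for (iid in mod$screener_item_ids) {
        label <- if (length(mod$screener_item_ids) > 1) {
          paste0(mod$category_name, " - ", instr$items[[iid]]$text)
        } else {
          mod$category_name
        }
        add_kappa(label, mid, iid)
      }
    }
  }

  out <- data.frame(
    module_id = vapply(rows, `[[`, "", "module_id"),
    label = vapply(rows, `[[`, "", "label"),
    coefficient_type = vapply(rows, `[[`, "", "coefficient_type"),
    estimate = vapply(rows, `[[`, numeric(1), "estimate"),
    ci_low = vapply(rows, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(rows, `[[`, numeric(1), "ci_high"),
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    band = vapply(rows, `[[`, "", "band"),
    transform = vapply(rows, `[[`, "", "transform_applied"),
    n = vapply(rows, function(r) as.integer(r$n), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("reliability_table", class(out))
  out
}

#' @export
print.reliability_table <- function(x, ...) {
  cat(sprintf("Test-retest reliability (%d coefficients)\n", nrow(x)))
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 2)
  df$ci_low <- round(df$ci_low, 2)
  df$ci_high <- round(df$ci_high, 2)
  df$p_value <- signif(df$p_value, 2)
  print(df[, c("label", "coefficient_type", "estimate", "ci_low",
               "ci_high", "p_value", "band", "transform")], row.names = FALSE)
  invisible(x)
}

#' Screening-consistency summary across occasions
#'
#' For each module, counts respondents screening in at both, exactly one, or
#' neither occasion, and identifies items solely responsible for
#' single-occasion screen-ins (respondents for whom exactly one screen-in
#' clause fired at the screening occasion) — the threshold-sensitivity
#' diagnostic that motivated raising an over-inclusive screener threshold.
#'
#' @param study A `retest_study`.
#' @param instr The instrument.
#' @return Data frame with columns `module_id`, `both`, `one`, `neither`,
#'   `solo_items` (comma-separated item ids, possibly empty).
#' @export
screening_consistency <- function(study, instr) {
  n <- length(study$occ1)
  out <- lapply(names(instr$modules), function(mid) {
    mod <- instr$modules[[mid]]
    s1 <- vapply(study$occ1, function(s) isTRUE(s$screen_in[[mid]]),
                 logical(1))
    s2 <- vapply(study$occ2, function(s) isTRUE(s$screen_in[[mid]]),
                 logical(1))
    solo <- character()
    for (i in which(xor(s1, s2))) {
      sess <- if (s1[i]) study$occ1[[i]] else study$occ2[[i]]
      fired <- fired_clauses(mod$screen_in_rule, sess$responses)
      if (sum(fired) == 1) {
        solo <- c(solo, mod$screen_in_rule$clauses[[which(fired)]]$item_id)
      }
    }
    data.frame(module_id = mid, both = sum(s1 & s2), one = sum(xor(s1, s2)),
               neither = sum(!s1 & !s2),
               solo_items = paste(unique(solo), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Flag items endorsed above threshold too often in a sample
#'
#' Items whose above-threshold endorsement rate (per the endorsement
#' mapping) strictly exceeds `threshold_fraction` across the sessions in
#' which they were administered are returned for expert review.
#'
#' @param sessions List of `screen_session` objects.
#' @param instr The instrument.
#' @param threshold_fraction Review threshold (default 0.15).
#' @return Character vector of flagged item ids.
#' @export
flag_overendorsed <- function(sessions, instr, threshold_fraction = 0.15) {
  stopifnot(length(sessions) >= 1)
  counts <- list()
  for (s in sessions) {
    for (iid in names(s$responses)) {
      e <- to_endorsement(instr$items[[iid]], s$responses[[iid]])
      c0 <- counts[[iid]] %||% c(0, 0)
      counts[[iid]] <- c(c0[1] + e, c0[2] + 1)
    }
  }
  flagged <- names(counts)[vapply(counts, function(c) {
    c[1] / c[2] > threshold_fraction
  }, logical(1))]
  names(instr$items)[names(instr$items) %in% flagged]
}
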