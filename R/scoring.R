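#' Endorsement mapping from a response to a binary criterion contribution
#'
#' Forward-scored Likert items are endorsed at "often" (4) or "always" (5);
#' reverse-scored items at "never" (1) or "rarely" (2). Yes/no items are
#' endorsed when answered yes; day-count items at or above the item's
#' documented endorsement cut.
#'
#' @param item A `screen_item`.
#' @param value Response value valid for the item.
#' @return Logical: does the response endorse the symptom?
#' @export
to_endorsement <- function(item, value) {
  value <- check_response_value(item, value)
  switch(item$response_kind,
         likert5 = if (item$reverse_scored) value <= 2 else value >= 4,
         yes_no = isTRUE(value),
         count_days = value >= item$endorse_cut)
}

#' Evaluate a symptom criterion over responses
#'
#' A criterion is endorsed when any of its mapped items is endorsed. The
#' maximum frequency level over mapped Likert items (reverse-scored items
#' contribute `6 - value`) is retained as a severity signal.
#'
#' @param instr A `screen_instrument`.
#' @param criterion_id Criterion to evaluate.
#' @param responses Named list/vector of responses covering every mapped
#'   item.
#' @return A list of class `criterion_endorsement` with fields
#'   `criterion_id`, `endorsed`, `supporting_item_ids`,
#'   `max_frequency_level` (NA when no Likert item is mapped).
#' @export
evaluate_criterion <- function(instr, criterion_id, responses) {
  cr <- instr$criteria[[criterion_id]]
  if (is.null(cr)) {
    stop_adaptscreen(sprintf("unknown criterion '%s'", criterion_id),
                     "adaptscreen_unknown_criterion_error")
  }
  missing <- setdiff(cr$mapped_item_ids, names(responses))
  if (length(missing)) {
    stop_adaptscreen(
      sprintf("criterion '%s' incomplete; missing: %s", criterion_id,
              paste(missing, collapse = ", ")),
      "adaptscreen_incomplete_error")
  }
  endorsed_items <- character()
  levels <- integer()
  for (iid in cr$mapped_item_ids) {
    it <- instr$items[[iid]]
    v <- responses[[iid]]
    if (to_endorsement(it, v)) endorsed_items <- c(endorsed_items, iid)
    if (it$response_kind == "likert5") {
      levels <- c(levels, if (it$reverse_scored) 6L - v else as.integer(v))
    }
  }
  structure(list(
    criterion_id = criterion_id,
    endorsed = length(endorsed_items) > 0,
    supporting_item_ids = endorsed_items,
    max_frequency_level = if (length(levels)) max(levels) else NA_integer_
  ), class = "criterion_endorsement")
}

#' Evaluate a diagnosis rule over criterion endorsements
#'
#' True when at least `required_count` of the rule's criteria are endorsed
#' and, for a nonempty cardinal subset, at least one cardinal criterion is
#' among them (e.g., five of nine symptoms of which one is depressed mood or
#' loss of interest).
#'
#' @param rule A `diagnosis_rule`.
#' @param endorsements Named logical vector (or list of
#'   `criterion_endorsement`) covering `rule$criterion_ids`.
#' @return Logical.
#' @export
evaluate_diagnosis <- function(rule, endorsements) {
  if (is.list(endorsements) && length(endorsements) &&
      inherits(endorsements[[1]], "criterion_endorsement")) {
    endorsements <- stats::setNames(
      vapply(endorsements, `[[`, logical(1), "endorsed"),
      vapply(endorsements, `[[`, "", "criterion_id"))
  }
  missing <- setdiff(rule$criterion_ids, names(endorsements))
  if (length(missing)) {
    stop_adaptscreen(
      sprintf("diagnosis '%s' missing criteria: %s", rule$diagnosis_name,
              paste(missing, collapse = ", ")),
      "adaptscreen_incomplete_error")
  }
  e <- unlist(endorsements[rule$criterion_ids])
  count_ok <- sum(e) >= rule$required_count
  cardinal_ok <- length(rule$cardinal_criteria) == 0 ||
    any(unlist(endorsements[rule$cardinal_criteria]))
  count_ok && cardinal_ok
}

#' Build the differential-diagnosis report for a session
#'
#' Only screened-in modules whose follow-up sections are complete contribute
#' diagnoses; screened-in modules with unanswered items are reported as
#' incomplete and never silently scored. Screen-in thresholds are the
#' sensitive end of the design; the endorsement mapping (at least "often")
#' used by the diagnosis rules is strictly more specific.
#'
#' @param instr A `screen_instrument`.
#' @param session A `screen_session` (complete or partial).
#' @return A list of class `differential_report` with per-module screen
#'   status, included diagnoses (with endorsed/required counts and cardinal
#'   satisfaction), per-criterion endorsements, a severity inventory over
#'   administered items, and the list of incomplete modules.
#' @export
build_differential <- function(instr, session) {
  responses <- session$responses
  screen_status <- character()
  incomplete <- character()
  for (mid in names(instr$modules)) {
    mod <- instr$modules[[mid]]
    if (!all(mod$screener_item_ids %in% names(responses))) {
      screen_status[mid] <- "incomplete"
      incomplete <- c(incomplete, mid)
    } else if (!evaluate_screen_in(instr, mid, responses)) {
      screen_status[mid] <- "screened_out"
    } else if (!all(mod$followup_item_ids %in% names(responses))) {
      screen_status[mid] <- "screened_in"
      incomplete <- c(incomplete, mid)
    } else {
      screen_status[mid] <- "screened_in"
    }
  }

  scorable <- names(screen_status)[screen_status == "screened_in" &
                                     !names(screen_status) %in% incomplete]

  endorsements <- list()
  included <- list()
  for (rule in instr$diagnosis_rules) {
    if (!rule$module_id %in% scorable) next
    ce <- lapply(rule$criterion_ids, function(cid) {
      if (is.null(endorsements[[cid]])) {
        endorsements[[cid]] <<- evaluate_criterion(instr, cid, responses)
      }
      endorsements[[cid]]
    })
    e <- stats::setNames(vapply(ce, `[[`, logical(1), "endorsed"),
                         rule$criterion_ids)
    if (evaluate_diagnosis(rule, e)) {
      included[[length(included) + 1]] <- list(
        diagnosis_name = rule$diagnosis_name,
        module_id = rule$module_id,
        endorsed_criteria_count = sum(e),
        required_count = rule$required_count,
        cardinal_satisfied = length(rule$cardinal_criteria) == 0 ||
          any(e[rule$cardinal_criteria]),
        endorsed_criteria = names(e)[e]
      )
    }
  }

  administered <- names(responses)
  severity <- data.frame(
    item_id = administered,
    module_id = vapply(administered,
                       function(i) instr$items[[i]]$module_id, ""),
    response_kind = vapply(administered,
                           function(i) instr$items[[i]]$response_kind, ""),
    value = vapply(administered, function(i) as.numeric(responses[[i]]),
                   numeric(1)),
    endorsed = vapply(administered, function(i) {
      to_endorsement(instr$items[[i]], responses[[i]])
    }, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(
    session_id = session$session_id,
    screen_status = screen_status,
    included_diagnoses = included,
    criterion_endorsements = endorsements,
    severity_inventory = severity,
    incomplete_modules = incomplete
  ), class = "differential_report")
}

#' @export
print.differential_report <- function(x, ...) {
  cat(sprintf("<differential_report> session %s\n", x$session_id))
  ins <- names(x$screen_status)[x$screen_status == "screened_in"]
  cat(sprintf("  screened in: %s\n",
              if (length(ins)) paste(ins, collapse = ", ") else "(none)"))
  if (length(x$incomplete_modules)) {
    cat(sprintf("  incomplete: %s\n",
                paste(x$incomplete_modules, collapse = ", ")))
  }
  if (length(x$included_diagnoses)) {
    cat("  differential diagnosis:\n")
    for (d in x$included_diagnoses) {
      cat(sprintf("    - %s (%d endorsed, %d required%s)\n", d$diagnosis_name,
                  d$endorsed_criteria_count, d$required_count,
                  if (d$cardinal_satisfied) ", cardinal met" else ""))
    }
  } else {
    cat("  differential diagnosis: (empty)\n")
  }
  invisible(x)
}

#' Summary score for a Likert screening module
#'
#' Sum of Likert levels over the module's screener items, with
#' reverse-scored items counted as `6 - value`; the range is `[k, 5k]` for
#' `k` items. Used as the per-module score entering test-retest ICC
#' analysis. Optionally restricted to a symptom-tag sub-scale (e.g.,
#' hallucinations within the psychotic module).
#'
#' @param instr A `screen_instrument`.
#' @param module_id Module to score.
#' @param responses Named responses covering the module's Likert screeners.
#' @param symptom_tag Optional tag restricting the items scored.
#' @return Numeric summary score.
#' @export
module_summary_score <- function(instr, module_id, responses,
                                 symptom_tag = NULL) {
  mod <- instr$modules[[module_id]]
  if (is.null(mod)) {
    stop_adaptscreen(sprintf("unknown module '%s'", module_id),
                     "adaptscreen_unknown_module_error")
  }
  ids <- mod$screener_item_ids
  kinds <- vapply(ids, function(i) instr$items[[i]]$response_kind, "")
  if (!all(kinds == "likert5")) {
    stop_adaptscreen(
      sprintf("module '%s' is not a Likert screening module", module_id),
      "adaptscreen_unsupported_module_error")
  }
  if (!is.null(symptom_tag)) {
    ids <- ids[vapply(ids, function(i) {
      identical(instr$items[[i]]$symptom_tag, symptom_tag)
    }, logical(1))]
    if (length(ids) == 0) {
      stop_adaptscreen(
        sprintf("module '%s' has no screener items tagged '%s'", module_id,
                symptom_tag),
        "adaptscreen_unsupported_module_error")
    }
  }
  missing <- setdiff(ids, names(responses))
  if (length(missing)) {
    stop_adaptscreen(
      sprintf("module '%s' summary score incomplete; missing: %s", module_id,
              paste(missing, collapse = ", ")),
      "adaptscreen_incomplete_error")
  }
  sum(vapply(ids, function(i) {
    v <- as.numeric(responses[[i]])
    if (instr$items[[i]]$reverse_scored) 6 - v else v
  }, numeric(1)))
}

#' Build a focused rescreen form from a differential report
#'
#' For outcome tracking, the Likert items mapped to the criteria of the
#' diagnoses included in the differential are collected (deduplicated, in
#' instrument order) so the most relevant symptoms can be re-administered at
#' regular intervals.
#'
#' @param report A `differential_report`.
#' @param instr The instrument the report was scored against.
#' @return Character vector of item ids (empty when the differential is
#'   empty).
#' @export
build_rescreen_form <- function(report, instr) {
  if (length(report$included_diagnoses) == 0) return(character())
  wanted <- character()
  for (d in report$included_diagnoses) {
    rule <- instr$diagnosis_rules[[d$diagnosis_name]]
    for (cid in rule$criterion_ids) {
      wanted <- c(wanted, instr$criteria[[cid]]$mapped_item_ids)
    }
  }
  wanted <- unique(wanted)
  likert <- wanted[vapply(wanted, function(i) {
    instr$items[[i]]$response_kind == "likert5"
  }, logical(1))]
  names(instr$items)[names(instr$items) %in% likert]
}

# Serialize a differential report for the CLI / JSON output.
report_to_list <- function(report) {
  list(
    session_id = report$session_id,
    screen_status = as.list(report$screen_status),
    included_diagnoses = lapply(report$included_diagnoses, function(d) {
      list(diagnosis_name = d$diagnosis_name,
           module_id = d$module_id,
           endorsed_criteria_count = d$endorsed_criteria_count,
           required_count = d$required_count,
           cardinal_satisfied = d$cardinal_satisfied,
           endorsed_criteria = as.list(d$endorsed_criteria))
    }),
    incomplete_modules = as.list(report$incomplete_modules),
    severity_inventory = lapply(seq_len(nrow(report$severity_inventory)),
                                function(i) {
      as.list(report$severity_inventory[i, ])
    })
  )
}
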