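#' @name instrument-model
#' @title Declarative screening-instrument data model
#'
#' @description
#' An instrument is a versioned, declarative description of a two-part
#' adaptive assessment: an always-administered screener whose modules each
#' carry a threshold ("screen-in") rule, follow-up item sections unlocked by
#' screen-in, diagnosis-agnostic symptom criteria mapping criteria to items,
#' and symptom-counting diagnosis rules that assemble criteria into a
#' differential diagnosis.
#'
#' Items come in three response kinds:
#' \describe{
#'   \item{likert5}{5 ordered frequency levels: 1 never, 2 rarely,
#'     3 sometimes, 4 often, 5 always. May be reverse-scored (low
#'     frequency indicates symptom presence).}
#'   \item{yes_no}{logical endorsement (e.g., lifetime trauma exposure).}
#'   \item{count_days}{integer day count in \code{0..timeframe_days}
#'     (e.g., days drinking in the last 30); an \code{endorse_cut} gives
#'     the count treated as symptom endorsement.}
#' }
NULL

LIKERT_LEVELS <- c(never = 1, rarely = 2, sometimes = 3, often = 4, always = 5)

INSTRUMENT_SCHEMA_VERSION <- "1.0"

#' Construct an item definition
#'
#' @param item_id Stable slug identifying the item.
#' @param text Display text shown to the respondent.
#' @param module_id Module the item belongs to.
#' @param section `"screener"` or `"followup"`.
#' @param response_kind `"likert5"`, `"yes_no"`, or `"count_days"`.
#' @param reverse_scored Logical; only valid for `likert5` items.
#' @param timeframe_days Reference window in days (`NA` means lifetime).
#' @param symptom_tag Optional DSM-criterion label used for sub-scales.
#' @param lead_prompt Optional concurrency framing shown before the item.
#' @param endorse_cut For `count_days` items, the count at or above which the
#'   response counts as an endorsement.
#' @return A list of class `screen_item`.
#' @export
screen_item <- function(item_id, text, module_id, section,
                        response_kind = "likert5", reverse_scored = FALSE,
                        timeframe_days = 30L, symptom_tag = NULL,
                        lead_prompt = NULL, endorse_cut = NULL) {
  structure(list(
    item_id = as.character(item_id),
    text = as.character(text),
    module_id = as.character(module_id),
    section = match.arg(section, c("screener", "followup")),
    response_kind = match.arg(response_kind,
                              c("likert5", "yes_no", "count_days")),
    reverse_scored = isTRUE(reverse_scored),
    timeframe_days = if (is.null(timeframe_days) || is.na(timeframe_days))
      NA_integer_ else as.integer(timeframe_days),
    symptom_tag = symptom_tag,
    lead_prompt = lead_prompt,
    endorse_cut = if (is.null(endorse_cut)) NULL else as.integer(endorse_cut)
  ), class = "screen_item")
}

#' Construct a threshold rule
#'
#' Clauses are `(item_id, comparator, level)` atoms; the connective is
#' `"any"` (at least one clause true), `"all"`, or `"at_least"` with count
#' `k`. Comparators are `">="`, `"<="`, `"=="`. Levels are Likert levels for
#' likert5 items, `TRUE`/`FALSE` for yes_no items, and integer cuts for
#' count_days items.
#'
#' @param clauses List of clause lists with fields `item_id`, `comparator`,
#'   `level`.
#' @param connective `"any"`, `"all"`, or `"at_least"`.
#' @param k Required clause count when `connective = "at_least"`.
#' @return A list of class `threshold_rule`.
#' @export
threshold_rule <- function(clauses, connective = "any", k = NULL) {
  connective <- match.arg(connective, c("any", "all", "at_least"))
  if (connective == "at_least" && (is.null(k) || k < 1)) {
    stop("'at_least' rules need a positive k")
  }
  structure(list(
    connective = connective,
    k = if (is.null(k)) NULL else as.integer(k),
    clauses = lapply(clauses, function(cl) {
      list(item_id = as.character(cl$item_id),
           comparator = match.arg(cl$comparator, c(">=", "<=", "==")),
           level = cl$level)
    })
  ), class = "threshold_rule")
}

# Shorthand used when authoring fixtures.
clause <- function(item_id, comparator, level) {
  list(item_id = item_id, comparator = comparator, level = level)
}

#' Construct a screening module
#'
#' @param module_id Stable slug.
#' @param category_name Diagnostic category covered by the module.
#' @param screener_item_ids Ordered screener item ids.
#' @param screen_in_rule A [threshold_rule()] over the screener items.
#' @param followup_item_ids Ordered follow-up item ids unlocked by screen-in.
#' @return A list of class `screen_module`.
#' @export
screen_module <- function(module_id, category_name, screener_item_ids,
                          screen_in_rule, followup_item_ids = character()) {
  structure(list(
    module_id = as.character(module_id),
    category_name = as.character(category_name),
    screener_item_ids = as.character(screener_item_ids),
    screen_in_rule = screen_in_rule,
    followup_item_ids = as.character(followup_item_ids)
  ), class = "screen_module")
}

#' Construct a symptom-criterion definition
#'
#' A criterion is a diagnosis-agnostic DSM symptom label mapped to one or
#' more items; it is endorsed when any mapped item is endorsed under the
#' endorsement mapping (see [to_endorsement()]).
#'
#' @param criterion_id Stable slug.
#' @param label Human-readable symptom label.
#' @param mapped_item_ids Items whose endorsement endorses the criterion.
#' @param cardinal Logical flag marking criteria that serve as cardinal
#'   symptoms in some diagnosis rule.
#' @return A list of class `criterion_def`.
#' @export
criterion_def <- function(criterion_id, label, mapped_item_ids,
                          cardinal = FALSE) {
  structure(list(
    criterion_id = as.character(criterion_id),
    label = as.character(label),
    mapped_item_ids = as.character(mapped_item_ids),
    cardinal = isTRUE(cardinal)
  ), class = "criterion_def")
}

#' Construct a diagnosis rule
#'
#' A diagnosis enters the differential when at least `required_count` of its
#' criteria are endorsed and, when `cardinal_criteria` is nonempty, at least
#' one of those cardinal criteria is among the endorsed ones (e.g., depressed
#' mood or loss of interest for a major depressive episode).
#'
#' @param diagnosis_name Catalog entry the rule decides.
#' @param module_id Screening module whose screen-in gates the rule.
#' @param criterion_ids Criteria counted by the rule.
#' @param required_count Minimum endorsed criteria (m of n).
#' @param cardinal_criteria At-least-one-of subset of `criterion_ids`
#'   (may be empty).
#' @param window_days Concurrency window metadata in days.
#' @param notes Clinician-judgment components not machine-evaluated
#'   (exclusions, duration qualifiers, episode composition).
#' @return A list of class `diagnosis_rule`.
#' @export
diagnosis_rule <- function(diagnosis_name, module_id, criterion_ids,
                           required_count, cardinal_criteria = character(),
                           window_days = 14L, notes = NULL) {
  structure(list(
    diagnosis_name = as.character(diagnosis_name),
    module_id = as.character(module_id),
    criterion_ids = as.character(criterion_ids),
    required_count = as.integer(required_count),
    cardinal_criteria = as.character(cardinal_criteria),
    window_days = as.integer(window_days),
    notes = notes
  ), class = "diagnosis_rule")
}

#' Assemble an instrument
#'
#' @param items List of [screen_item()] definitions in presentation order.
#' @param modules List of [screen_module()] definitions in presentation
#'   order.
#' @param criteria List of [criterion_def()] definitions.
#' @param diagnosis_rules List of [diagnosis_rule()] definitions.
#' @param catalog Character vector of diagnosis names the instrument can
#'   return.
#' @param schema_version Instrument format version string.
#' @param name Optional instrument name.
#' @return A list of class `screen_instrument`.
#' @export
new_instrument <- function(items, modules, criteria, diagnosis_rules, catalog,
                           schema_version = INSTRUMENT_SCHEMA_VERSION,
                           name = "unnamed instrument") {
  instr <- structure(list(
    schema_version = schema_version,
    name = name,
    items = stats::setNames(items, vapply(items, `[[`, "", "item_id")),
    modules = stats::setNames(modules, vapply(modules, `[[`, "", "module_id")),
    criteria = stats::setNames(criteria,
                               vapply(criteria, `[[`, "", "criterion_id")),
    diagnosis_rules = stats::setNames(
      diagnosis_rules, vapply(diagnosis_rules, `[[`, "", "diagnosis_name")),
    catalog = as.character(catalog)
  ), class = "screen_instrument")
  instr
}

screener_item_ids <- function(instr) {
  unlist(lapply(instr$modules, `[[`, "screener_item_ids"), use.names = FALSE)
}

followup_item_ids <- function(instr) {
  unlist(lapply(instr$modules, `[[`, "followup_item_ids"), use.names = FALSE)
}

#' Validate an instrument
#'
#' Checks every structural invariant: referential integrity of all id
#' references, unique ids, item/module membership, response-kind constraints
#' (reverse scoring only for likert5, endorsement cuts only for count_days),
#' threshold-rule well-formedness, non-empty criterion mappings, and
#' diagnosis rules with `1 <= required_count <= n` and cardinal subsets of
#' their criteria.
#'
#' @param instr A `screen_instrument`.
#' @return Character vector of human-readable issues; empty when the
#'   instrument is valid. Issues are data, not errors.
#' @export
validate_instrument <- function(instr) {
  issues <- character()
  say <- function(...) issues <<- c(issues, sprintf(...))

  item_ids <- names(instr$items)
  if (anyDuplicated(item_ids)) {
    for (d in unique(item_ids[duplicated(item_ids)])) {
      say("duplicate item_id '%s'", d)
    }
  }
  dup_raw <- vapply(instr$items, `[[`, "", "item_id")
  if (anyDuplicated(dup_raw)) {
    for (d in unique(dup_raw[duplicated(dup_raw)])) {
      say("duplicate item_id '%s'", d)
    }
  }

  for (it in instr$items) {
    if (!it$module_id %in% names(instr$modules)) {
      say("item '%s' references missing module '%s'", it$item_id, it$module_id)
    }
    if (it$reverse_scored && it$response_kind != "likert5") {
      say("item '%s' is reverse_scored but not likert5", it$item_id)
    }
    if (it$response_kind == "count_days") {
      if (is.na(it$timeframe_days) || it$timeframe_days < 1) {
        say("count_days item '%s' needs a positive timeframe_days", it$item_id)
      }
      if (is.null(it$endorse_cut)) {
        say("count_days item '%s' needs an endorse_cut", it$item_id)
      }
    }
    if (!is.na(it$timeframe_days) && it$timeframe_days < 1) {
      say("item '%s' has non-positive timeframe_days", it$item_id)
    }
  }

  seen_screener <- character()
  for (m in instr$modules) {
    for (sid in m$screener_item_ids) {
      if (!sid %in% item_ids) {
        say("module '%s' screener references missing item '%s'",
            m$module_id, sid)
      } else {
        it <- instr$items[[sid]]
        if (it$module_id != m$module_id) {
          say("screener item '%s' listed in module '%s' but belongs to '%s'",
              sid, m$module_id, it$module_id)
        }
        if (it$section != "screener") {
          say("item '%s' listed as screener in '%s' but has section '%s'",
              sid, m$module_id, it$section)
        }
      }
      if (sid %in% seen_screener) {
        say("screener item '%s' appears in more than one module", sid)
      }
      seen_screener <- c(seen_screener, sid)
    }
    for (fid in m$followup_item_ids) {
      if (!fid %in% item_ids) {
        say("module '%s' followup references missing item '%s'",
            m$module_id, fid)
      } else if (instr$items[[fid]]$section != "followup") {
        say("item '%s' listed as followup in '%s' but has section '%s'",
            fid, m$module_id, instr$items[[fid]]$section)
      }
    }
    if (length(m$screener_item_ids) == 0) {
      say("module '%s' has no screener items", m$module_id)
    }
    for (cl in m$screen_in_rule$clauses) {
      if (!cl$item_id %in% item_ids) {
        say("screen-in rule of '%s' references missing item '%s'",
            m$module_id, cl$item_id)
      } else if (!cl$item_id %in% m$screener_item_ids) {
        say("screen-in rule of '%s' references non-screener item '%s'",
            m$module_id, cl$item_id)
      }
    }
    if (m$screen_in_rule$connective == "at_least" &&
        (is.null(m$screen_in_rule$k) ||
         m$screen_in_rule$k > length(m$screen_in_rule$clauses))) {
      say("screen-in rule of '%s' has infeasible at_least k", m$module_id)
    }
  }

  for (cr in instr$criteria) {
    if (length(cr$mapped_item_ids) == 0) {
      say("criterion '%s' maps no items", cr$criterion_id)
    }
    for (iid in cr$mapped_item_ids) {
      if (!iid %in% item_ids) {
        say("criterion '%s' references missing item '%s'",
            cr$criterion_id, iid)
      }
    }
  }

  for (dr in instr$diagnosis_rules) {
    n <- length(dr$criterion_ids)
    if (dr$required_count < 1 || dr$required_count > n) {
      say("diagnosis '%s' has required_count %d outside 1..%d",
          dr$diagnosis_name, dr$required_count, n)
    }
    if (!all(dr$cardinal_criteria %in% dr$criterion_ids)) {
      bad <- setdiff(dr$cardinal_criteria, dr$criterion_ids)
      say("diagnosis '%s' cardinal criteria not in criterion_ids: %s",
          dr$diagnosis_name, paste(bad, collapse = ", "))
    }
    for (cid in dr$criterion_ids) {
      if (!cid %in% names(instr$criteria)) {
        say("diagnosis '%s' references missing criterion '%s'",
            dr$diagnosis_name, cid)
      }
    }
    if (!dr$module_id %in% names(instr$modules)) {
      say("diagnosis '%s' references missing module '%s'",
          dr$diagnosis_name, dr$module_id)
    }
    if (!dr$diagnosis_name %in% instr$catalog) {
      say("diagnosis '%s' is not in the catalog", dr$diagnosis_name)
    }
  }

  if (anyDuplicated(instr$catalog)) {
    say("catalog contains duplicate entries")
  }

  issues
}

#' Check a single response value against an item definition
#' @noRd
check_response_value <- function(item, value) {
  kind <- item$response_kind
  if (kind == "likert5") {
    if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
        value != as.integer(value) || value < 1 || value > 5) {
      stop_adaptscreen(
        sprintf("item '%s': likert5 response must be an integer in 1..5, got %s",
                item$item_id, deparse(value)),
        "adaptscreen_range_error")
    }
    as.integer(value)
  } else if (kind == "yes_no") {
    if (!is.logical(value) || length(value) != 1 || is.na(value)) {
      stop_adaptscreen(
        sprintf("item '%s': yes_no response must be TRUE or FALSE",
                item$item_id),
        "adaptscreen_range_error")
    }
    value
  } else {
    top <- item$timeframe_days
    if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
        value != as.integer(value) || value < 0 || value > top) {
      stop_adaptscreen(
        sprintf("item '%s': count_days response must be an integer in 0..%d",
                item$item_id, top),
        "adaptscreen_range_error")
    }
    as.integer(value)
  }
}

#' Evaluate a threshold rule over complete responses
#'
#' @param rule A [threshold_rule()].
#' @param responses Named list or vector of response values keyed by item id;
#'   must cover every item the rule references.
#' @return Logical scalar.
#' @export
evaluate_threshold_rule <- function(rule, responses) {
  fired <- vapply(rule$clauses, function(cl) {
    if (!cl$item_id %in% names(responses)) {
      stop_adaptscreen(
        sprintf("threshold rule needs a response for item '%s'", cl$item_id),
        "adaptscreen_incomplete_error")
    }
    v <- responses[[cl$item_id]]
    switch(cl$comparator,
           ">=" = v >= cl$level,
           "<=" = v <= cl$level,
           "==" = identical(as.vector(v), as.vector(cl$level)) || v == cl$level)
  }, logical(1))
  switch(rule$connective,
         any = any(fired),
         all = all(fired),
         at_least = sum(fired) >= rule$k)
}

# Which clauses of a rule fire (used by screening-consistency diagnostics).
fired_clauses <- function(rule, responses) {
  vapply(rule$clauses, function(cl) {
    v <- responses[[cl$item_id]]
    switch(cl$comparator,
           ">=" = v >= cl$level,
           "<=" = v <= cl$level,
           "==" = v == cl$level)
  }, logical(1))
}

#' @export
print.screen_instrument <- function(x, ...) {
  n_screen <- length(screener_item_ids(x))
  cat(sprintf("<screen_instrument> %s (schema %s)\n", x$name,
              x$schema_version))
  cat(sprintf("  %d items (%d screener, %d follow-up) in %d modules\n",
              length(x$items), n_screen, length(x$items) - n_screen,
              length(x$modules)))
  cat(sprintf("  %d criteria, %d diagnosis rules, %d catalog entries\n",
              length(x$criteria), length(x$diagnosis_rules),
              length(x$catalog)))
  invisible(x)
}

#' @export
summary.screen_instrument <- function(object, ...) {
  df <- data.frame(
    module_id = names(object$modules),
    category = vapply(object$modules, `[[`, "", "category_name"),
    n_screener = vapply(object$modules,
                        function(m) length(m$screener_item_ids), 0L),
    n_followup = vapply(object$modules,
                        function(m) length(m$followup_item_ids), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  df
}
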