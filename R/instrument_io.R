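# On-disk instrument format: a single versioned JSON document with arrays of
# item / module / criterion / diagnosis-rule objects in presentation order.
# Keys are written sorted-stable by construction so that save(load(f)) is
# equivalent to f modulo key ordering.

item_to_list <- function(it) {
  out <- list(
    item_id = it$item_id,
    text = it$text,
    module_id = it$module_id,
    section = it$section,
    response_kind = it$response_kind,
    reverse_scored = it$reverse_scored,
    timeframe_days = if (is.na(it$timeframe_days)) NULL else it$timeframe_days
  )
  if (!is.null(it$symptom_tag)) out$symptom_tag <- it$symptom_tag
  if (!is.null(it$lead_prompt)) out$lead_prompt <- it$lead_prompt
  if (!is.null(it$endorse_cut)) out$endorse_cut <- it$endorse_cut
  out
}

rule_to_list <- function(r) {
  out <- list(connective = r$connective)
  if (!is.null(r$k)) out$k <- r$k
  out$clauses <- lapply(r$clauses, function(cl) {
    list(item_id = cl$item_id, comparator = cl$comparator, level = cl$level)
  })
  out
}

instrument_to_list <- function(instr) {
  list(
    schema_version = instr$schema_version,
    name = instr$name,
    items = unname(lapply(instr$items, item_to_list)),
    modules = unname(lapply(instr$modules, function(m) {
      list(module_id = m$module_id,
           category_name = m$category_name,
           screener_item_ids = as.list(m$screener_item_ids),
           screen_in_rule = rule_to_list(m$screen_in_rule),
           followup_item_ids = as.list(m$followup_item_ids))
    })),
    criteria = unname(lapply(instr$criteria, function(cr) {
      list(criterion_id = cr$criterion_id,
           label = cr$label,
           mapped_item_ids = as.list(cr$mapped_item_ids),
           cardinal = cr$cardinal)
    })),
    diagnosis_rules = unname(lapply(instr$diagnosis_rules, function(dr) {
      out <- list(diagnosis_name = dr$diagnosis_name,
                  module_id = dr$module_id,
                  criterion_ids = as.list(dr$criterion_ids),
                  required_count = dr$required_count,
                  cardinal_criteria = as.list(dr$cardinal_criteria),
                  window_days = dr$window_days)
      if (!is.null(dr$notes)) out$notes <- dr$notes
      out
    })),
    catalog = as.list(instr$catalog)
  )
}

list_to_rule <- function(x) {
  threshold_rule(
    clauses = lapply(x$clauses, function(cl) {
      lvl <- cl$level
      if (!is.logical(lvl)) lvl <- as.integer(lvl)
      clause(cl$item_id, cl$comparator, lvl)
    }),
    connective = x$connective,
    k = x$k
  )
}

list_to_instrument <- function(x) {
  if (is.null(x$schema_version)) {
    stop_adaptscreen("instrument file is missing schema_version",
                     "adaptscreen_parse_error")
  }
  items <- lapply(x$items, function(i) {
    screen_item(i$item_id, i$text, i$module_id, i$section,
                response_kind = i$response_kind,
                reverse_scored = isTRUE(i$reverse_scored),
                timeframe_days = i$timeframe_days %||% NA_integer_,
                symptom_tag = i$symptom_tag,
                lead_prompt = i$lead_prompt,
                endorse_cut = i$endorse_cut)
  })
  modules <- lapply(x$modules, function(m) {
    screen_module(m$module_id, m$category_name,
                  unlist(m$screener_item_ids),
                  list_to_rule(m$screen_in_rule),
                  unlist(m$followup_item_ids) %||% character())
  })
  criteria <- lapply(x$criteria, function(cr) {
    criterion_def(cr$criterion_id, cr$label, unlist(cr$mapped_item_ids),
                  cardinal = isTRUE(cr$cardinal))
  })
  rules <- lapply(x$diagnosis_rules, function(dr) {
    diagnosis_rule(dr$diagnosis_name, dr$module_id,
                   unlist(dr$criterion_ids), dr$required_count,
                   cardinal_criteria = unlist(dr$cardinal_criteria) %||%
                     character(),
                   window_days = dr$window_days,
                   notes = dr$notes)
  })
  new_instrument(items, modules, criteria, rules, unlist(x$catalog),
                 schema_version = x$schema_version,
                 name = x$name %||% "unnamed instrument")
}

#' Write an instrument to a JSON file
#'
#' @param instr A validated `screen_instrument`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instr, path) {
  json <- jsonlite::toJSON(instrument_to_list(instr), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load and validate an instrument from a JSON file
#'
#' @param path Path to an instrument JSON document.
#' @return A validated `screen_instrument`.
#' @details Fails with a parse error for malformed JSON and with a
#'   validation error listing every broken reference or invariant for
#'   structurally invalid instruments.
#' @export
load_instrument <- function(path) {
  if (!file.exists(path)) {
    stop_adaptscreen(sprintf("instrument file not found: %s", path),
                     "adaptscreen_parse_error")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop_adaptscreen(sprintf("could not parse instrument file: %s",
                               conditionMessage(e)),
                       "adaptscreen_parse_error")
    })
  instr <- list_to_instrument(raw)
  issues <- validate_instrument(instr)
  if (length(issues)) {
    stop_adaptscreen(
      sprintf("invalid instrument (%d issues):\n%s", length(issues),
              paste0("  - ", issues, collapse = "\n")),
      "adaptscreen_validation_error")
  }
  instr
}
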