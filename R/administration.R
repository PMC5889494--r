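#' Adaptive session engine
#'
#' A session administers the instrument in two phases. The screener phase
#' presents every screener item in authored order. When the last screener
#' response arrives, each module's screen-in rule is evaluated and the
#' follow-up sections of screened-in modules are queued, in instrument
#' order, each item carrying its module's lead prompt. Sessions are
#' resumable: responses may arrive across calls, and scoring treats modules
#' with unanswered items as incomplete rather than silently scoring them.
#'
#' @name administration
NULL

#' Start an adaptive session
#'
#' @param instr A validated `screen_instrument`.
#' @param session_id Identifier for the session.
#' @return A `screen_session` with phase `"screener"` and every screener
#'   item pending.
#' @export
start_session <- function(instr, session_id = "session-1") {
  issues <- validate_instrument(instr)
  if (length(issues)) {
    stop_adaptscreen(
      sprintf("cannot start a session on an invalid instrument (%d issues)",
              length(issues)),
      "adaptscreen_validation_error")
  }
  structure(list(
    session_id = session_id,
    instrument = instr,
    phase = "screener",
    responses = list(),
    screen_in = stats::setNames(rep(NA, length(instr$modules)),
                                names(instr$modules)),
    pending = screener_item_ids(instr)
  ), class = "screen_session")
}

#' Record one response and advance the session
#'
#' @param session A `screen_session`.
#' @param item_id Identifier of a pending item.
#' @param value Response value (Likert level 1..5, logical, or day count)
#'   matching the item's response kind.
#' @return The updated session; phase transitions (screener complete,
#'   session complete) are applied.
#' @export
record_response <- function(session, item_id, value) {
  instr <- session$instrument
  if (!item_id %in% names(instr$items)) {
    stop_adaptscreen(sprintf("unknown item '%s'", item_id),
                     "adaptscreen_unknown_item_error")
  }
  if (!item_id %in% session$pending) {
    stop_adaptscreen(sprintf("item '%s' is not pending in this session",
                             item_id),
                     "adaptscreen_not_pending_error")
  }
  value <- check_response_value(instr$items[[item_id]], value)
  session$responses[[item_id]] <- value
  session$pending <- setdiff(session$pending, item_id)

  if (session$phase == "screener" && length(session$pending) == 0) {
    for (mid in names(instr$modules)) {
      session$screen_in[[mid]] <-
        evaluate_screen_in(instr, mid, session$responses)
    }
    queued <- unlist(lapply(instr$modules[session$screen_in],
                            `[[`, "followup_item_ids"), use.names = FALSE)
    session$pending <- queued %||% character()
    session$phase <- if (length(session$pending)) "followup" else "complete"
  } else if (session$phase == "followup" && length(session$pending) == 0) {
    session$phase <- "complete"
  }
  session
}

#' Evaluate a module's screen-in rule
#'
#' Pure function of the responses and the module's threshold rule; requires
#' every screener item of the module to be answered.
#'
#' @param instr A `screen_instrument`.
#' @param module_id Module to evaluate.
#' @param responses Named list/vector of responses keyed by item id.
#' @return Logical: does the respondent screen in to the module's follow-up
#'   section?
#' @export
evaluate_screen_in <- function(instr, module_id, responses) {
  mod <- instr$modules[[module_id]]
  if (is.null(mod)) {
    stop_adaptscreen(sprintf("unknown module '%s'", module_id),
                     "adaptscreen_unknown_module_error")
  }
  missing <- setdiff(mod$screener_item_ids, names(responses))
  if (length(missing)) {
    stop_adaptscreen(
      sprintf("module '%s' screener incomplete; missing: %s", module_id,
              paste(missing, collapse = ", ")),
      "adaptscreen_incomplete_error")
  }
  evaluate_threshold_rule(mod$screen_in_rule, responses)
}

#' Items still to be administered, in presentation order
#'
#' @param session A `screen_session`.
#' @return A data frame with columns `item_id`, `text`, `module_id`,
#'   `lead_prompt` (empty string when none); zero rows for a complete
#'   session.
#' @export
next_items <- function(session) {
  instr <- session$instrument
  ids <- session$pending
  data.frame(
    item_id = ids,
    text = vapply(ids, function(i) instr$items[[i]]$text, ""),
    module_id = vapply(ids, function(i) instr$items[[i]]$module_id, ""),
    lead_prompt = vapply(ids, function(i) {
      instr$items[[i]]$lead_prompt %||% ""
    }, ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Replay a scripted set of responses through the engine
#'
#' Administers the instrument adaptively, answering each requested item from
#' the supplied script. Items the script does not cover are left unanswered
#' (the session is then resumable / reported incomplete).
#'
#' @param instr A `screen_instrument`.
#' @param responses Named list/vector of response values keyed by item id,
#'   or a data frame with columns `item_id` and `value`.
#' @param session_id Session identifier.
#' @return A `screen_session`.
#' @export
replay_responses <- function(instr, responses, session_id = "scripted") {
  if (is.data.frame(responses)) {
    responses <- stats::setNames(as.list(responses$value),
                                 responses$item_id)
  }
  s <- start_session(instr, session_id)
  repeat {
    ask <- intersect(s$pending, names(responses))
    if (length(ask) == 0) break
    s <- record_response(s, ask[[1]], responses[[ask[[1]]]])
  }
  s
}

#' @export
print.screen_session <- function(x, ...) {
  cat(sprintf("<screen_session> %s — phase: %s\n", x$session_id, x$phase))
  cat(sprintf("  %d responses recorded, %d items pending\n",
              length(x$responses), length(x$pending)))
  if (!anyNA(x$screen_in)) {
    ins <- names(x$screen_in)[x$screen_in]
    cat(sprintf("  screened in: %s\n",
                if (length(ins)) paste(ins, collapse = ", ") else "(none)"))
  }
  invisible(x)
}

# Serialize a session (responses + screen-in map) for the CLI.
session_to_list <- function(session) {
  list(
    session_id = session$session_id,
    instrument = session$instrument$name,
    schema_version = session$instrument$schema_version,
    phase = session$phase,
    responses = lapply(seq_along(session$responses), function(i) {
      list(item_id = names(session$responses)[i],
           value = session$responses[[i]])
    }),
    screen_in = as.list(session$screen_in)
  )
}
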