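#' MIRROR event-type vocabulary (LEC-5)
#'
#' The closed vocabulary of event categories used by MIRROR's event-context
#' part: the 16 named categories of the Life Events Checklist for DSM-5 plus
#' the catch-all "another very stressful event" category.
#'
#' @return Character vector of 17 event-type codes.
#' @export
lec5_event_types <- function() {
  c("natural_disaster",
    "fire_or_explosion",
    "transportation_accident",
    "serious_accident",
    "toxic_substance_exposure",
    "physical_assault",
    "assault_with_weapon",
    "sexual_assault",
    "other_unwanted_sexual_experience",
    "combat_or_war_zone",
    "captivity",
    "life_threatening_illness_or_injury",
    "severe_human_suffering",
    "sudden_violent_death",
    "sudden_accidental_death",
    "serious_injury_or_death_caused_by_you",
    "another_very_stressful_event")
}

#' @rdname lec5_event_types
#' @export
relation_levels <- function() {
  c("happened_to_me", "witnessed", "learned_about", "work_related",
    "other_specified")
}

#' @rdname lec5_event_types
#' @export
time_phase_levels <- function() {
  c("under_1_week", "one_to_4_weeks", "over_4_weeks", "recurring")
}

# canonical English item labels (paraphrased item bank, fixed order)
mirror_item_labels <- function() {
  c(ptsd_intrusion   = "Are you troubled by images of or thoughts about the event?",
    ptsd_arousal     = "Have you become jumpy and/or vigilant since the event?",
    ptsd_avoid_things = "Do you try to avoid things that are related to the event?",
    ptsd_avoid_thoughts = "Do you try to avoid thinking about the event?",
    functioning      = "How would you rate your present functioning (at work/home)?",
    res_support      = "Do you experience support from those close to you?",
    res_confidence   = "Are you confident in yourself?",
    res_problem_solving = "Are you able to deal with any problems you encounter?")
}

#' MIRROR respondent-record column schema
#'
#' Canonical column names of a respondent-level cohort table. The eight MIRROR
#' items are \code{mirror_q1..mirror_q4} (PTSD section, 1-5),
#' \code{mirror_functioning} (1-10) and \code{mirror_q6..mirror_q8}
#' (resilience section, 1-5), followed by the event context and bookkeeping
#' flags.
#'
#' @return Character vector of mandatory column names.
#' @export
mirror_columns <- function() {
  c("respondent_id",
    "mirror_q1", "mirror_q2", "mirror_q3", "mirror_q4",
    "mirror_functioning",
    "mirror_q6", "mirror_q7", "mirror_q8",
    "event_type", "relation", "weeks_since_event", "recurring",
    "is_repeat")
}

ptsd_item_columns <- function() paste0("mirror_q", 1:4)
resilience_item_columns <- function() paste0("mirror_q", 6:8)

is_whole <- function(x) {
  is.numeric(x) & is.finite(x) & x == round(x)
}

#' Collect validation violations for a raw respondent record
#'
#' Checks one raw key-value record against the MIRROR response contract:
#' all eight items present and in range (PTSD and resilience items 1-5,
#' functioning 1-10), the event type drawn from the LEC-5 vocabulary, the
#' relation from its closed set, and a usable time specification
#' (non-negative weeks and/or a recurring flag).
#'
#' @param record A named list or one-row data frame with the columns of
#'   \code{\link{mirror_columns}} (\code{respondent_id} and \code{is_repeat}
#'   may be absent; they default).
#' @return Character vector of violation messages; empty when valid. Each
#'   message is prefixed with its class: \code{"incomplete record"},
#'   \code{"range violation"} or \code{"vocabulary violation"}.
#' @seealso [validate_response()] which turns a clean record into a
#'   \code{mirror_response}.
#' @export
response_violations <- function(record) {
  record <- as.list(record)
  bad <- character(0)
  item_cols <- c(ptsd_item_columns(), "mirror_functioning",
                 resilience_item_columns())
  hi <- c(rep(5L, 4L), 10L, rep(5L, 3L))
  for (i in seq_along(item_cols)) {
    col <- item_cols[[i]]
    v <- record[[col]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      bad <- c(bad, sprintf("incomplete record: missing item '%s'", col))
    } else if (!is_whole(v) || v < 1 || v > hi[[i]]) {
      bad <- c(bad, sprintf("range violation: '%s' = %s outside 1..%d",
                            col, format(v), hi[[i]]))
    }
  }
  et <- record$event_type
  if (is.null(et) || length(et) != 1L || is.na(et)) {
    bad <- c(bad, "incomplete record: missing event_type")
  } else if (!et %in% lec5_event_types()) {
    bad <- c(bad, sprintf("vocabulary violation: unknown event_type '%s'", et))
  }
  rel <- record$relation
  if (is.null(rel) || length(rel) != 1L || is.na(rel)) {
    bad <- c(bad, "incomplete record: missing relation")
  } else if (!rel %in% relation_levels()) {
    bad <- c(bad, sprintf("vocabulary violation: unknown relation '%s'", rel))
  }
  wk <- record$weeks_since_event
  rec <- record$recurring
  rec_known <- !is.null(rec) && length(rec) == 1L && !is.na(rec)
  wk_known <- !is.null(wk) && length(wk) == 1L && !is.na(wk)
  if (!wk_known && !(rec_known && isTRUE(as.logical(rec)))) {
    bad <- c(bad, "incomplete record: no time specification (weeks or recurring)")
  } else if (wk_known && (!is.numeric(wk) || !is.finite(wk) || wk < 0)) {
    bad <- c(bad, sprintf("range violation: 'weeks_since_event' = %s is negative or non-numeric",
                          format(wk)))
  }
  bad
}

#' Validate a raw record into a MIRROR response
#'
#' @inheritParams response_violations
#' @return An object of class \code{mirror_response}: a list with
#'   \code{ptsd_items} (length 4), \code{functioning}, \code{resilience_items}
#'   (length 3), \code{context} (event type, relation, weeks, recurring),
#'   \code{respondent_id} and \code{is_repeat}.
#' @examples
#' rec <- list(mirror_q1 = 4, mirror_q2 = 5, mirror_q3 = 3, mirror_q4 = 4,
#'             mirror_functioning = 5, mirror_q6 = 4, mirror_q7 = 3,
#'             mirror_q8 = 3, event_type = "physical_assault",
#'             relation = "happened_to_me", weeks_since_event = 2,
#'             recurring = FALSE)
#' resp <- validate_response(rec)
#' score_mirror_scales(resp)
#' @export
validate_response <- function(record) {
  bad <- response_violations(record)
  if (length(bad)) {
    stop(structure(
      class = c("mirror_validation_error", "error", "condition"),
      list(message = paste0("invalid MIRROR record:\n  ",
                            paste(bad, collapse = "\n  ")),
           call = sys.call(-1), violations = bad)))
  }
  record <- as.list(record)
  rec <- isTRUE(as.logical(record$recurring))
  structure(list(
    ptsd_items = as.integer(unlist(record[ptsd_item_columns()])),
    functioning = as.integer(record$mirror_functioning),
    resilience_items = as.integer(unlist(record[resilience_item_columns()])),
    context = list(
      event_type = record$event_type,
      relation = record$relation,
      weeks_since_event = if (is.null(record$weeks_since_event) ||
                              is.na(record$weeks_since_event)) NA_real_
                          else as.numeric(record$weeks_since_event),
      recurring = rec),
    respondent_id = if (is.null(record$respondent_id)) NA_character_
                    else as.character(record$respondent_id),
    is_repeat = isTRUE(as.logical(record$is_repeat))),
    class = "mirror_response")
}

#' Score the MIRROR scales
#'
#' The PTSD scale score is the sum of the four PTSD items (range 4-20), the
#' resilience scale score the sum of the three resilience items (range 3-15);
#' the single functioning rating (1-10) is passed through.
#'
#' @param x A \code{mirror_response}, or a data frame carrying the MIRROR item
#'   columns (see \code{\link{mirror_columns}}).
#' @return For a single response, a list of class \code{mirror_scores} with
#'   \code{ptsd_total}, \code{functioning}, \code{resilience_total}. For a
#'   data frame, the same three columns as a data frame with one row per
#'   input row.
#' @export
score_mirror_scales <- function(x) {
  if (is.data.frame(x)) {
    ptsd <- as.matrix(x[ptsd_item_columns()])
    res <- as.matrix(x[resilience_item_columns()])
    return(data.frame(
      ptsd_total = as.integer(rowSums(ptsd)),
      functioning = as.integer(x$mirror_functioning),
      resilience_total = as.integer(rowSums(res))))
  }
  stopifnot(inherits(x, "mirror_response"))
  structure(list(
    ptsd_total = sum(x$ptsd_items),
    functioning = x$functioning,
    resilience_total = sum(x$resilience_items)),
    class = "mirror_scores")
}

#' Time phase of the event context
#'
#' MIRROR distinguishes three phases of time passed since the event --
#' less than 1 week, between 1 and 4 weeks (closed interval), and more than 4
#' weeks -- with a recurring event dominating any week count.
#'
#' @param weeks Non-negative number of weeks since the event (vectorised).
#'   May be \code{NA} when \code{recurring} is \code{TRUE}.
#' @param recurring Logical; does the event happen repeatedly?
#' @return Factor with levels \code{\link{time_phase_levels}}.
#' @export
time_phase <- function(weeks, recurring = FALSE) {
  n <- max(length(weeks), length(recurring))
  weeks <- rep_len(as.numeric(weeks), n)
  recurring <- rep_len(as.logical(recurring), n)
  if (any(!recurring & (is.na(weeks) | weeks < 0)))
    stop("range violation: weeks_since_event must be non-negative when not recurring")
  out <- ifelse(recurring, "recurring",
         ifelse(weeks < 1, "under_1_week",
         ifelse(weeks <= 4, "one_to_4_weeks", "over_4_weeks")))
  factor(out, levels = time_phase_levels())
}

#' @export
print.mirror_scores <- function(x, ...) {
  cat(sprintf("MIRROR scale scores: PTSD %d (4-20), functioning %d (1-10), resilience %d (3-15)\n",
              x$ptsd_total, x$functioning, x$resilience_total))
  invisible(x)
}

#' @export
print.mirror_response <- function(x, ...) {
  cat("MIRROR response", if (!is.na(x$respondent_id)) paste0("[", x$respondent_id, "]"), "\n")
  cat("  PTSD items:      ", paste(x$ptsd_items, collapse = " "), "\n")
  cat("  functioning:     ", x$functioning, "\n")
  cat("  resilience items:", paste(x$resilience_items, collapse = " "), "\n")
  cat("  event:", x$context$event_type, "/", x$context$relation,
      "/", if (x$context$recurring) "recurring"
           else sprintf("%.1f weeks ago", x$context$weeks_since_event), "\n")
  invisible(x)
}
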