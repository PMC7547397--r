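level3 <- function() c("low", "moderate", "high")
level2 <- function() c("low", "high")
colors3 <- function() c("green", "orange", "red")

#' Triage threshold configuration
#'
#' Bundles the scale cutoffs and the full 36-cell decision table that drive
#' MIRROR's triage algorithm. The PTSD scale (4-20) and the functioning item
#' (1-10) are banded into low/moderate/high; resilience (3-15) into low/high.
#' Cutoffs are the closed upper bound of the lower band: a total exactly at a
#' cutoff falls in the lower band.
#'
#' The exact cutoffs and outcome grid of the deployed instrument are not part
#' of the published text; the defaults are scale-range terciles combined with
#' a decision table built from the published verbal rules (low functioning
#' always refers to care; complaints with moderate functioning are normalized
#' while the event is recent but refer to care past 4 weeks or when the event
#' recurs). Both are data, not code: supply your own via
#' \code{triage_config()} or a JSON document.
#'
#' @param ptsd_cutoffs Two increasing integers: upper bounds of the low and
#'   moderate PTSD bands on the 4-20 scale.
#' @param functioning_cutoffs Two increasing integers on the 1-10 scale.
#' @param resilience_cutoff One integer on the 3-15 scale: upper bound of the
#'   low band.
#' @param decision_table Data frame with columns \code{ptsd_level},
#'   \code{functioning_level}, \code{phase}, \code{color} covering all
#'   3 x 3 x 4 = 36 cells exactly once.
#' @return Object of class \code{triage_config}.
#' @export
triage_config <- function(ptsd_cutoffs, functioning_cutoffs, resilience_cutoff,
                          decision_table) {
  stopifnot(length(ptsd_cutoffs) == 2, length(functioning_cutoffs) == 2,
            length(resilience_cutoff) == 1)
  if (!(ptsd_cutoffs[1] < ptsd_cutoffs[2] &&
        ptsd_cutoffs[1] >= 4 && ptsd_cutoffs[2] < 20))
    stop("configuration error: ptsd_cutoffs must be strictly increasing within 4..20")
  if (!(functioning_cutoffs[1] < functioning_cutoffs[2] &&
        functioning_cutoffs[1] >= 1 && functioning_cutoffs[2] < 10))
    stop("configuration error: functioning_cutoffs must be strictly increasing within 1..10")
  if (!(resilience_cutoff >= 3 && resilience_cutoff < 15))
    stop("configuration error: resilience_cutoff must lie within 3..15")
  dt <- as.data.frame(decision_table, stringsAsFactors = FALSE)
  need <- c("ptsd_level", "functioning_level", "phase", "color")
  if (!all(need %in% names(dt)))
    stop("configuration error: decision_table lacks columns ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  key <- paste(dt$ptsd_level, dt$functioning_level, dt$phase, sep = "|")
  full <- expand.grid(ptsd_level = level3(), functioning_level = level3(),
                      phase = time_phase_levels(), stringsAsFactors = FALSE)
  full_key <- paste(full$ptsd_level, full$functioning_level, full$phase, sep = "|")
  missing_cells <- setdiff(full_key, key)
  if (length(missing_cells))
    stop("configuration error: decision_table missing cells: ",
         paste(missing_cells, collapse = "; "))
  if (anyDuplicated(key))
    stop("configuration error: duplicated decision_table cells: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!all(dt$color %in% colors3()))
    stop("configuration error: colors must be green/orange/red")
  structure(list(ptsd_cutoffs = as.integer(ptsd_cutoffs),
                 functioning_cutoffs = as.integer(functioning_cutoffs),
                 resilience_cutoff = as.integer(resilience_cutoff),
                 decision_table = dt[c("ptsd_level", "functioning_level",
                                       "phase", "color")]),
            class = "triage_config")
}

# verbal-rule default: red iff functioning low, or complaints (>= moderate)
# with moderate functioning past 4 weeks / recurring; green iff low complaints
# with at least moderate functioning, or high functioning with at most
# moderate complaints; orange otherwise.
default_decision_cell <- function(ptsd_level, functioning_level, phase) {
  p <- match(ptsd_level, level3())
  f <- match(functioning_level, level3())
  late <- phase %in% c("over_4_weeks", "recurring")
  if (f == 1L) return("red")
  if (p >= 2L && f == 2L && late) return("red")
  if ((p == 1L && f >= 2L) || (f == 3L && p <= 2L)) return("green")
  "orange"
}

#' @rdname triage_config
#' @export
default_triage_config <- function() {
  full <- expand.grid(ptsd_level = level3(), functioning_level = level3(),
                      phase = time_phase_levels(), stringsAsFactors = FALSE)
  full$color <- mapply(default_decision_cell, full$ptsd_level,
                       full$functioning_level, full$phase)
  triage_config(ptsd_cutoffs = c(9L, 14L),
                functioning_cutoffs = c(4L, 6L),
                resilience_cutoff = 9L,
                decision_table = full)
}

#' Read / write a triage configuration as JSON
#'
#' @param path Path to a JSON document with fields \code{ptsd_cutoffs},
#'   \code{functioning_cutoffs}, \code{resilience_cutoff},
#'   \code{decision_table}.
#' @return \code{read_triage_config}: a \code{triage_config};
#'   \code{write_triage_config}: \code{path}, invisibly.
#' @export
read_triage_config <- function(path) {
  doc <- jsonlite::fromJSON(path)
  triage_config(doc$ptsd_cutoffs, doc$functioning_cutoffs,
                doc$resilience_cutoff, doc$decision_table)
}

#' @rdname read_triage_config
#' @param cfg A \code{triage_config}.
#' @export
write_triage_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "triage_config"))
  jsonlite::write_json(
    list(schema = "mirrorscreen/triage-config/v1",
         ptsd_cutoffs = cfg$ptsd_cutoffs,
         functioning_cutoffs = cfg$functioning_cutoffs,
         resilience_cutoff = cfg$resilience_cutoff,
         decision_table = cfg$decision_table),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

band3 <- function(total, cutoffs) {
  factor(ifelse(total <= cutoffs[1], "low",
         ifelse(total <= cutoffs[2], "moderate", "high")),
         levels = level3())
}

#' Classify MIRROR scale scores into algorithm levels
#'
#' @param scores A \code{mirror_scores} object or a data frame with columns
#'   \code{ptsd_total}, \code{functioning}, \code{resilience_total}.
#' @param cfg A \code{triage_config}; defaults to
#'   \code{\link{default_triage_config}()}.
#' @return Data frame with factors \code{ptsd_level}, \code{functioning_level}
#'   (low/moderate/high) and \code{resilience_level} (low/high).
#' @export
classify_levels <- function(scores, cfg = default_triage_config()) {
  if (!inherits(cfg, "triage_config"))
    stop("configuration error: cfg must be a triage_config")
  s <- if (is.data.frame(scores)) scores else
    data.frame(ptsd_total = scores$ptsd_total, functioning = scores$functioning,
               resilience_total = scores$resilience_total)
  data.frame(
    ptsd_level = band3(s$ptsd_total, cfg$ptsd_cutoffs),
    functioning_level = band3(s$functioning, cfg$functioning_cutoffs),
    resilience_level = factor(
      ifelse(s$resilience_total <= cfg$resilience_cutoff, "low", "high"),
      levels = level2()))
}

#' Look up the triage color
#'
#' One deterministic decision-table lookup on (PTSD level, functioning level,
#' time phase). Resilience never enters the color outcome; it only shapes the
#' advice.
#'
#' @param ptsd_level,functioning_level Levels from \code{\link{classify_levels}}
#'   (character or factor; vectorised).
#' @param phase Time phase from \code{\link{time_phase}}.
#' @inheritParams classify_levels
#' @return Factor green/orange/red.
#' @export
triage_color <- function(ptsd_level, functioning_level, phase,
                         cfg = default_triage_config()) {
  dt <- cfg$decision_table
  key <- paste(as.character(ptsd_level), as.character(functioning_level),
               as.character(phase), sep = "|")
  lut <- stats::setNames(dt$color, paste(dt$ptsd_level, dt$functioning_level,
                                         dt$phase, sep = "|"))
  factor(unname(lut[key]), levels = colors3())
}

#' Compose the personal advice for a triage outcome
#'
#' Green advises that no further action is needed; orange normalizes the
#' complaints and promotes watchful waiting with a reminder to re-take MIRROR
#' in 2 weeks; red advises seeking consultation with a general practitioner or
#' victim support. A respondent scoring low on resilience is additionally
#' encouraged to seek support from those close to them, whatever the color.
#'
#' @param color Triage color (green/orange/red).
#' @param resilience_level low/high.
#' @param phase Optional time phase (carried through for reporting).
#' @return List of class \code{advice_bundle}: \code{components} (ordered
#'   character vector), \code{followup_options} (always the full set), and
#'   \code{highlight} (\code{"set_reminder"} for orange, else \code{NA}).
#' @export
compose_advice <- function(color, resilience_level, phase = NA) {
  color <- as.character(color)
  stopifnot(length(color) == 1, color %in% colors3())
  components <- switch(color,
    green = "no_action",
    orange = c("normalize_complaints", "watchful_waiting_reminder"),
    red = "seek_consultation")
  if (as.character(resilience_level) == "low")
    components <- c(components, "social_support_encouragement")
  structure(list(
    components = components,
    followup_options = c("peer_contact", "stress_information", "send_advice",
                         "set_reminder", "victim_support_contact"),
    highlight = if (color == "orange") "set_reminder" else NA_character_),
    class = "advice_bundle")
}

#' Enumerate the full decision table
#'
#' Expands a configuration into all 36 (PTSD level, functioning level, phase)
#' cells with their colors, for totality, determinism and monotonicity
#' checking.
#'
#' @inheritParams classify_levels
#' @return Data frame with 36 rows: \code{ptsd_level}, \code{functioning_level},
#'   \code{phase}, \code{color}.
#' @export
enumerate_decision_table <- function(cfg = default_triage_config()) {
  if (!inherits(cfg, "triage_config"))
    stop("configuration error: cfg must be a triage_config")
  full <- expand.grid(ptsd_level = level3(), functioning_level = level3(),
                      phase = time_phase_levels(), stringsAsFactors = FALSE)
  full$color <- as.character(
    triage_color(full$ptsd_level, full$functioning_level, full$phase, cfg))
  full
}

#' Triage a whole cohort
#'
#' Scores every respondent, classifies levels, derives the time phase and the
#' color, and appends advice components.
#'
#' @param data Data frame in the canonical respondent schema
#'   (\code{\link{mirror_columns}}).
#' @inheritParams classify_levels
#' @return The input with appended columns \code{ptsd_total},
#'   \code{functioning}, \code{resilience_total}, \code{phase},
#'   \code{ptsd_level}, \code{functioning_level}, \code{resilience_level},
#'   \code{color} and \code{advice} (components joined by \code{"+"}).
#' @export
triage_cohort <- function(data, cfg = default_triage_config()) {
  scores <- score_mirror_scales(data)
  lv <- classify_levels(scores, cfg)
  phase <- time_phase(data$weeks_since_event, data$recurring)
  color <- triage_color(lv$ptsd_level, lv$functioning_level, phase, cfg)
  advice <- vapply(seq_len(nrow(data)), function(i)
    paste(compose_advice(color[i], lv$resilience_level[i])$components,
          collapse = "+"), character(1))
  cbind(data, scores, phase = phase, lv, color = color, advice = advice)
}

#' @export
print.triage_config <- function(x, ...) {
  cat("MIRROR triage configuration\n")
  cat(sprintf("  PTSD bands (4-20):        low <= %d < moderate <= %d < high\n",
              x$ptsd_cutoffs[1], x$ptsd_cutoffs[2]))
  cat(sprintf("  functioning bands (1-10): low <= %d < moderate <= %d < high\n",
              x$functioning_cutoffs[1], x$functioning_cutoffs[2]))
  cat(sprintf("  resilience bands (3-15):  low <= %d < high\n", x$resilience_cutoff))
  tab <- table(x$decision_table$color)
  cat("  decision table: 36 cells —",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.advice_bundle <- function(x, ...) {
  cat("Advice:", paste(x$components, collapse = ", "), "\n")
  cat("Follow-up options:", paste(x$followup_options, collapse = ", "),
      if (!is.na(x$highlight)) sprintf("(highlighted: %s)", x$highlight), "\n")
  invisible(x)
}
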