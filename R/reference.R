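#' PCL-5 DSM-5 symptom-cluster map
#'
#' Item indices of the four DSM-5 symptom clusters in the standard published
#' PCL-5 ordering: intrusion (B, items 1-5), avoidance (C, 6-7), negative
#' alterations in cognitions and mood (D, 8-14), alterations in arousal and
#' reactivity (E, 15-20).
#'
#' @return Named list of integer index vectors B, C, D, E.
#' @export
pcl5_cluster_map <- function() {
  list(B = 1:5, C = 6:7, D = 8:14, E = 15:20)
}

as_item_matrix <- function(items, k, lo, hi, what) {
  m <- if (is.matrix(items) || is.data.frame(items)) as.matrix(items)
       else matrix(items, nrow = 1)
  if (ncol(m) != k)
    stop(sprintf("schema error: %s requires %d items, got %d", what, k, ncol(m)))
  if (any(!is_whole(m)) || any(m < lo) || any(m > hi))
    stop(sprintf("range violation: %s items must be integers in %d..%d",
                 what, lo, hi))
  m
}

#' Score the PCL-5
#'
#' Total score is the sum of all 20 items (0-80); cluster scores sum the items
#' of each DSM-5 cluster. Higher scores reflect more severe PTSD symptoms.
#'
#' @param items Integer vector of 20 item responses (0-4), or a matrix/data
#'   frame with one respondent per row.
#' @return Data frame with columns \code{pcl5_total}, \code{pcl5_B},
#'   \code{pcl5_C}, \code{pcl5_D}, \code{pcl5_E}.
#' @export
score_pcl5 <- function(items) {
  m <- as_item_matrix(items, 20L, 0L, 4L, "PCL-5")
  cl <- pcl5_cluster_map()
  data.frame(pcl5_total = as.integer(rowSums(m)),
             pcl5_B = as.integer(rowSums(m[, cl$B, drop = FALSE])),
             pcl5_C = as.integer(rowSums(m[, cl$C, drop = FALSE])),
             pcl5_D = as.integer(rowSums(m[, cl$D, drop = FALSE])),
             pcl5_E = as.integer(rowSums(m[, cl$E, drop = FALSE])))
}

#' PCL-5 provisional PTSD diagnosis
#'
#' DSM-5 symptom-count rule: an item scored at least 2 counts as an endorsed
#' symptom; a provisional diagnosis requires at least one endorsed B symptom,
#' one C, two D and two E symptoms.
#'
#' @inheritParams score_pcl5
#' @return Logical vector, one flag per respondent.
#' @export
pcl5_provisional_diagnosis <- function(items) {
  m <- as_item_matrix(items, 20L, 0L, 4L, "PCL-5")
  e <- m >= 2L
  cl <- pcl5_cluster_map()
  rowSums(e[, cl$B, drop = FALSE]) >= 1L &
    rowSums(e[, cl$C, drop = FALSE]) >= 1L &
    rowSums(e[, cl$D, drop = FALSE]) >= 2L &
    rowSums(e[, cl$E, drop = FALSE]) >= 2L
}

dass_scale_map <- function() {
  # standard DASS-21 item assignment
  list(depression = c(3L, 5L, 10L, 13L, 16L, 17L, 21L),
       anxiety    = c(2L, 4L, 7L, 9L, 15L, 19L, 20L),
       stress     = c(1L, 6L, 8L, 11L, 12L, 14L, 18L))
}

#' Classify a doubled DASS-21 scale score into a severity band
#'
#' Bands follow the DASS manual cutoffs for the doubled (full-scale
#' equivalent) scores. The printed cutoff lists leave small integer gaps
#' between adjacent bands; the closure used here keeps the partition total:
#' normal <=9/<=7/<=14, mild 10-13/8-9/15-18, moderate 14-20/10-14/19-25,
#' severe 21-27/15-19/26-33, extremely severe >=28/>=20/>=34 for
#' depression/anxiety/stress respectively. Normal and mild form the
#' subclinical group; moderate and above the clinical group.
#'
#' @param scale One of \code{"depression"}, \code{"anxiety"}, \code{"stress"}.
#' @param doubled_score Doubled scale score, 0-42 (vectorised).
#' @return Data frame with factor columns \code{band} (normal, mild, moderate,
#'   severe, extremely_severe) and \code{clinical_group}
#'   (subclinical/clinical).
#' @export
classify_dass_band <- function(scale, doubled_score) {
  bands <- c("normal", "mild", "moderate", "severe", "extremely_severe")
  # upper bound of the first four bands, per scale
  ub <- switch(match.arg(scale, c("depression", "anxiety", "stress")),
    depression = c(9, 13, 20, 27),
    anxiety    = c(7, 9, 14, 19),
    stress     = c(14, 18, 25, 33))
  if (any(doubled_score < 0 | doubled_score > 42))
    stop("range violation: doubled DASS score outside 0..42")
  idx <- findInterval(doubled_score, ub + 1L) + 1L
  band <- factor(bands[idx], levels = bands)
  data.frame(band = band,
             clinical_group = factor(
               ifelse(band %in% c("normal", "mild"), "subclinical", "clinical"),
               levels = c("subclinical", "clinical")))
}

#' Score the DASS-21
#'
#' Sums the 7 items of each scale (depression, anxiety, stress), doubles the
#' sums in accordance with the scale manual, and classifies each doubled score
#' into its severity band (\code{\link{classify_dass_band}}).
#'
#' @param items Integer vector of 21 item responses (0-3), or a matrix/data
#'   frame with one respondent per row, in the standard DASS-21 item order.
#' @return Data frame with raw sums (\code{dass_depression_raw}, ...),
#'   doubled scores (\code{dass_depression}, ...), \code{dass21_total}
#'   (doubled total), and band/clinical-group columns per scale.
#' @export
score_dass21 <- function(items) {
  m <- as_item_matrix(items, 21L, 0L, 3L, "DASS-21")
  sm <- dass_scale_map()
  out <- data.frame(row.names = seq_len(nrow(m)))
  for (sc in names(sm)) {
    raw <- as.integer(rowSums(m[, sm[[sc]], drop = FALSE]))
    dbl <- 2L * raw
    cls <- classify_dass_band(sc, dbl)
    out[[paste0("dass_", sc, "_raw")]] <- raw
    out[[paste0("dass_", sc)]] <- dbl
    out[[paste0("dass_", sc, "_band")]] <- cls$band
    out[[paste0("dass_", sc, "_clinical")]] <- cls$clinical_group
  }
  out$dass21_total <- out$dass_depression + out$dass_anxiety + out$dass_stress
  out
}

#' Score a summative reference scale (RES or MHC-SF)
#'
#' Both instruments are scored as the plain sum of their items: RES has 9
#' items on 0-4 (total 0-36, higher = more psychological resilience), MHC-SF
#' 14 items on 0-5 (total 0-70, higher = more positive mental health).
#'
#' @param name \code{"RES"} or \code{"MHC-SF"}.
#' @param items Item vector, or matrix/data frame with one respondent per row.
#' @return Integer vector of totals.
#' @export
score_summative_scale <- function(name, items) {
  name <- match.arg(name, c("RES", "MHC-SF"))
  m <- if (name == "RES") as_item_matrix(items, 9L, 0L, 4L, "RES")
       else as_item_matrix(items, 14L, 0L, 5L, "MHC-SF")
  as.integer(rowSums(m))
}

#' Fixed tertile classification of RES and MHC-SF totals
#'
#' Uses the published cutpoints (33rd/66th percentile of the validation
#' sample), not cutpoints recomputed from the data at hand: RES low <=17,
#' moderate 18-24, high >=25; MHC-SF low <=23, moderate 24-47, high >=48.
#'
#' @param scale_name \code{"RES"} or \code{"MHC-SF"}.
#' @param total Total score (vectorised).
#' @return Factor low/moderate/high.
#' @export
tertile_classify <- function(scale_name, total) {
  scale_name <- match.arg(scale_name, c("RES", "MHC-SF"))
  cuts <- if (scale_name == "RES") c(17, 24) else c(23, 47)
  hi <- if (scale_name == "RES") 36 else 70
  if (any(total < 0 | total > hi))
    stop("range violation: ", scale_name, " total outside 0..", hi)
  band3(total, cuts)
}

#' Score all reference batteries attached to a cohort table
#'
#' Convenience wrapper: applies \code{\link{score_pcl5}},
#' \code{\link{pcl5_provisional_diagnosis}}, \code{\link{score_dass21}},
#' and \code{\link{score_summative_scale}} to the battery columns
#' (\code{pcl5_q1..q20}, \code{dass_q1..q21}, \code{res_q1..q9},
#' \code{mhc_q1..q14}) and appends totals, bands, diagnosis flag and the
#' fixed tertile classes.
#'
#' @param data Cohort data frame carrying the battery columns.
#' @return \code{data} with scored columns appended.
#' @export
score_reference_battery <- function(data) {
  pcl <- as.matrix(data[paste0("pcl5_q", 1:20)])
  dss <- as.matrix(data[paste0("dass_q", 1:21)])
  res <- as.matrix(data[paste0("res_q", 1:9)])
  mhc <- as.matrix(data[paste0("mhc_q", 1:14)])
  out <- cbind(data, score_pcl5(pcl), score_dass21(dss))
  out$pcl5_diagnosis <- pcl5_provisional_diagnosis(pcl)
  out$res_total <- score_summative_scale("RES", res)
  out$mhc_total <- score_summative_scale("MHC-SF", mhc)
  out$res_tertile <- tertile_classify("RES", out$res_total)
  out$mhc_tertile <- tertile_classify("MHC-SF", out$mhc_total)
  out
}
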