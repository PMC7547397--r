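#' Cronbach alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} for a k-item scale with
#' item variances \eqn{s_i^2} and total-score variance \eqn{s_T^2}.
#'
#' @param items Matrix or data frame, one respondent per row, one item per
#'   column; complete cases required.
#' @return Numeric alpha (at most 1; can be negative for incoherent scales).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  k <- ncol(m)
  if (k < 2) stop("scale too short: Cronbach alpha needs at least 2 items")
  if (anyNA(m)) stop("incomplete record: complete cases required")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("degenerate-input error: total score has zero variance")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Scale reliability report
#'
#' Summarizes the internal consistency of a multi-item scale: the range and
#' mean of the interitem correlations, the corrected item-total correlation of
#' each item (item against the sum of the remaining items), and Cronbach
#' alpha. A single-item scale (such as the MIRROR functioning rating) cannot
#' be evaluated and raises a "scale too short" error.
#'
#' @inheritParams cronbach_alpha
#' @return Object of class \code{reliability_report}: \code{interitem} (min /
#'   mean / max), \code{item_total} (named vector), \code{alpha}, \code{k},
#'   \code{n}.
#' @export
reliability_report <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2) stop("scale too short: reliability needs at least 2 items")
  if (nrow(m) < 3) stop("degenerate-input error: need at least 3 respondents")
  if (anyNA(m)) stop("incomplete record: complete cases required")
  R <- stats::cor(m)
  off <- R[lower.tri(R)]
  item_total <- vapply(seq_len(ncol(m)), function(i)
    stats::cor(m[, i], rowSums(m[, -i, drop = FALSE])), numeric(1))
  names(item_total) <- colnames(m)
  structure(list(
    interitem = c(min = min(off), mean = mean(off), max = max(off)),
    item_total = item_total,
    alpha = cronbach_alpha(m),
    k = ncol(m), n = nrow(m)),
    class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, digits = 2, ...) {
  cat(sprintf("Reliability (%d items, n = %d)\n", x$k, x$n))
  cat(sprintf("  interitem r: min %.*f, mean %.*f, max %.*f\n",
              digits, x$interitem[["min"]], digits, x$interitem[["mean"]],
              digits, x$interitem[["max"]]))
  cat("  corrected item-total:",
      paste(sprintf("%.*f", digits, x$item_total), collapse = " "), "\n")
  cat(sprintf("  Cronbach alpha: %.*f\n", digits, x$alpha))
  invisible(x)
}
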