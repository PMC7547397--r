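group_summaries <- function(values = NULL, groups = NULL,
                            means = NULL, sds = NULL, ns = NULL) {
  if (!is.null(values)) {
    g <- split(values, groups)
    means <- vapply(g, mean, numeric(1))
    sds <- vapply(g, stats::sd, numeric(1))
    ns <- vapply(g, length, numeric(1))
  }
  stopifnot(length(means) == length(sds), length(means) == length(ns))
  if (length(means) < 2) stop("degenerate-group error: need at least 2 groups")
  if (any(ns < 2)) stop("degenerate-group error: every group needs n >= 2")
  if (is.null(names(means))) names(means) <- paste0("g", seq_along(means))
  list(means = means, sds = sds, ns = ns)
}

#' One-way between-groups ANOVA (classic or Welch)
#'
#' Computes the classic F statistic (equal-variance assumption) or the Welch
#' heteroscedasticity-robust F with Satterthwaite-type denominator degrees of
#' freedom. Both depend only on the group means, standard deviations and
#' sizes, so summary statistics and raw data give identical results.
#' Eta-squared (SSB / (SSB + SSW)) is reported as the effect size.
#'
#' @param values Numeric response vector (raw-data interface).
#' @param groups Grouping vector parallel to \code{values}.
#' @param means,sds,ns Alternatively, per-group summary statistics.
#' @param variant \code{"classic"} or \code{"welch"}.
#' @return Object of class \code{anova_result}: \code{variant}, \code{F},
#'   \code{df_between}, \code{df_within}, \code{p_value},
#'   \code{eta_squared}, and the group summaries.
#' @examples
#' # classic F from printed group summaries
#' oneway_anova(means = c(10.42, 17.60, 22.49), sds = c(7.32, 9.20, 9.37),
#'              ns = c(24, 200, 439), variant = "classic")
#' @export
oneway_anova <- function(values = NULL, groups = NULL, means = NULL,
                         sds = NULL, ns = NULL,
                         variant = c("classic", "welch")) {
  variant <- match.arg(variant)
  s <- group_summaries(values, groups, means, sds, ns)
  k <- length(s$means)
  N <- sum(s$ns)
  grand <- sum(s$ns * s$means) / N
  ssb <- sum(s$ns * (s$means - grand)^2)
  ssw <- sum((s$ns - 1) * s$sds^2)
  eta2 <- ssb / (ssb + ssw)
  if (variant == "classic") {
    f <- (ssb / (k - 1)) / (ssw / (N - k))
    df2 <- N - k
  } else {
    w <- s$ns / s$sds^2
    W <- sum(w)
    xw <- sum(w * s$means) / W
    a <- sum(w * (s$means - xw)^2) / (k - 1)
    u <- sum((1 - w / W)^2 / (s$ns - 1))
    f <- a / (1 + 2 * (k - 2) / (k^2 - 1) * u)
    df2 <- (k^2 - 1) / (3 * u)
  }
  structure(list(variant = variant, F = f, df_between = k - 1,
                 df_within = df2,
                 p_value = stats::pf(f, k - 1, df2, lower.tail = FALSE),
                 eta_squared = eta2,
                 means = s$means, sds = s$sds, ns = s$ns),
            class = "anova_result")
}

#' Games-Howell post hoc pairwise comparisons
#'
#' Heteroscedasticity-robust pairwise comparisons matching the Welch ANOVA:
#' each pair's standard error uses unpooled variances, degrees of freedom are
#' Welch-Satterthwaite, and the p-value comes from the studentized-range
#' distribution over all k groups.
#'
#' @inheritParams oneway_anova
#' @return Data frame with one row per pair: \code{group1}, \code{group2},
#'   \code{diff} (mean of group1 minus group2), \code{se}, \code{df},
#'   \code{t}, \code{p_value}.
#' @export
games_howell <- function(values = NULL, groups = NULL, means = NULL,
                         sds = NULL, ns = NULL) {
  s <- group_summaries(values, groups, means, sds, ns)
  k <- length(s$means)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    vi <- s$sds[i]^2 / s$ns[i]
    vj <- s$sds[j]^2 / s$ns[j]
    se <- sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (s$ns[i] - 1) + vj^2 / (s$ns[j] - 1))
    tt <- (s$means[i] - s$means[j]) / se
    data.frame(group1 = names(s$means)[i], group2 = names(s$means)[j],
               diff = s$means[i] - s$means[j], se = se, df = df, t = tt,
               p_value = stats::ptukey(abs(tt) * sqrt(2), k, df,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test of independence
#'
#' @param tab Matrix of non-negative integer counts with positive row and
#'   column margins.
#' @return List with \code{chi_square}, \code{df}, \code{p_value} and the
#'   \code{expected} counts.
#' @examples
#' chi_square_independence(matrix(c(409, 224, 230, 214, 24, 11),
#'                                nrow = 3, byrow = TRUE))
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate-table error: zero row or column margin")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Two-sample t test from raw data or summary statistics
#'
#' Pooled-variance (Student) or Welch statistic with the sign convention
#' mean(a) - mean(b). Both variants depend only on the two samples' means,
#' standard deviations and sizes.
#'
#' @param a,b Numeric samples (raw interface).
#' @param means,sds,ns Length-2 summary vectors (alternative interface).
#' @param variant \code{"pooled"} or \code{"welch"}.
#' @return List with \code{t}, \code{df}, \code{p_value} (two-sided).
#' @export
two_sample_t <- function(a = NULL, b = NULL, means = NULL, sds = NULL,
                         ns = NULL, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (!is.null(a)) {
    means <- c(mean(a), mean(b))
    sds <- c(stats::sd(a), stats::sd(b))
    ns <- c(length(a), length(b))
  }
  if (any(ns < 2)) stop("degenerate sample: each sample needs n >= 2")
  if (variant == "pooled") {
    sp2 <- ((ns[1] - 1) * sds[1]^2 + (ns[2] - 1) * sds[2]^2) / (sum(ns) - 2)
    se <- sqrt(sp2 * (1 / ns[1] + 1 / ns[2]))
    df <- sum(ns) - 2
  } else {
    v <- sds^2 / ns
    se <- sqrt(sum(v))
    df <- sum(v)^2 / (v[1]^2 / (ns[1] - 1) + v[2]^2 / (ns[2] - 1))
  }
  tt <- (means[1] - means[2]) / se
  list(t = tt, df = df, p_value = 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s one-way ANOVA: F(%d, %.2f) = %.2f, p %s, eta^2 = %.3f\n",
              x$variant, x$df_between, x$df_within, x$F,
              if (x$p_value < .001) "< .001" else sprintf("= %.3f", x$p_value),
              x$eta_squared))
  invisible(x)
}
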