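#' Convergent/divergent validity matrix
#'
#' Pearson correlations of the three MIRROR scores (PTSD scale, resilience
#' scale, functioning item) with the four reference-measure totals (PCL-5,
#' DASS-21 total, RES, MHC-SF), with per-cell p-values. Respondents lacking
#' any of the seven scores are excluded and counted.
#'
#' @param data Data frame with columns \code{ptsd_total},
#'   \code{resilience_total}, \code{functioning}, \code{pcl5_total},
#'   \code{dass21_total}, \code{res_total}, \code{mhc_total}.
#' @return Object of class \code{validity_report}: \code{r} (4 x 3 matrix,
#'   reference measures by MIRROR scales), \code{p_value} (same shape),
#'   \code{n}, \code{n_excluded}.
#' @export
validity_report <- function(data) {
  mirror_cols <- c(PTSD = "ptsd_total", resilience = "resilience_total",
                   functioning = "functioning")
  ref_cols <- c(`PCL-5` = "pcl5_total", `DASS-21` = "dass21_total",
                RES = "res_total", `MHC-SF` = "mhc_total")
  need <- c(mirror_cols, ref_cols)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing battery: columns absent: ", paste(missing_cols, collapse = ", "))
  d <- data[need]
  ok <- stats::complete.cases(d)
  d <- d[ok, ]
  r <- matrix(NA_real_, length(ref_cols), length(mirror_cols),
              dimnames = list(names(ref_cols), names(mirror_cols)))
  p <- r
  for (i in seq_along(ref_cols)) for (j in seq_along(mirror_cols)) {
    ct <- stats::cor.test(d[[ref_cols[i]]], d[[mirror_cols[j]]])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  structure(list(r = r, p_value = p, n = nrow(d), n_excluded = sum(!ok)),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, digits = 3, ...) {
  cat(sprintf("Validity correlations (n = %d, %d excluded)\n",
              x$n, x$n_excluded))
  print(round(x$r, digits))
  invisible(x)
}
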