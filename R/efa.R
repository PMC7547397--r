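# --- unweighted least squares (minres) factor extraction -------------------

# given uniquenesses, the best rank-m approximation of R with its diagonal
# replaced by the communalities comes from the eigendecomposition
uls_loadings <- function(R, psi, m) {
  R1 <- R
  diag(R1) <- 1 - psi
  e <- eigen(R1, symmetric = TRUE)
  L <- e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
  rownames(L) <- rownames(R)
  L
}

fa_uls <- function(R, m) {
  p <- ncol(R)
  if (m < 1 || m >= p) stop("n_factors must satisfy 1 <= n_factors < n_items")
  objective <- function(psi) {
    L <- uls_loadings(R, psi, m)
    resid <- R - L %*% t(L)
    diag(resid) <- 0
    sum(resid^2)
  }
  smc <- 1 - 1 / diag(solve(smooth_correlation(R)))
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = 0.005, upper = 0.995,
                      control = list(maxit = 500))
  psi <- opt$par
  L <- uls_loadings(R, psi, m)
  list(loadings = L, uniquenesses = stats::setNames(psi, rownames(R)),
      converged = opt$convergence == 0, objective = opt$value)
}

# --- oblique geomin rotation by gradient projection ------------------------

vgQ_geomin <- function(L, eps) {
  m <- ncol(L)
  L2 <- L^2 + eps
  pro <- exp(rowSums(log(L2)) / m)
  list(f = sum(pro), Gq = (2 / m) * (L / L2) * matrix(pro, nrow(L), m))
}

gpa_oblique <- function(A, Tmat, eps, maxit = 1000, tol = 1e-7) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- vgQ_geomin(L, eps)
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  f <- vg$f
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (i in 0:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vgt <- vgQ_geomin(L, eps)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, f = f, converged = converged,
       iterations = iter)
}

# deterministic pseudo-random rotation starts, independent of the caller's
# RNG state
rotation_starts <- function(m, n_starts) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(285714L)
  starts <- list(diag(m))
  for (i in seq_len(n_starts - 1)) {
    X <- matrix(stats::rnorm(m * m), m)
    starts[[i + 1]] <- X %*% diag(1 / sqrt(colSums(X^2)), m)
  }
  starts
}

rotate_geomin <- function(A, eps = 0.01, n_starts = 10) {
  m <- ncol(A)
  best <- NULL
  for (Tmat in rotation_starts(m, n_starts)) {
    fit <- tryCatch(gpa_oblique(A, Tmat, eps), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$f < best$f) best <- fit
  }
  if (is.null(best))
    stop("rotation error: geomin rotation failed to converge from any start")
  # canonical form: order factors by explained variance, sign so each
  # factor's dominant loading is positive
  L <- best$loadings
  Phi <- best$Phi
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  sgn <- vapply(seq_len(m), function(j) sign(L[which.max(abs(L[, j])), j]),
                numeric(1))
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2, sgn, `*`)
  Phi <- diag(sgn) %*% Phi %*% diag(sgn)
  colnames(L) <- paste0("F", seq_len(m))
  dimnames(Phi) <- list(colnames(L), colnames(L))
  list(loadings = L, Phi = Phi, criterion = best$f,
       converged = best$converged, iterations = best$iterations)
}

# --- normal-theory fit statistics ------------------------------------------

logdet <- function(M) {
  d <- determinant(M, logarithm = TRUE)
  if (d$sign <= 0) return(NA_real_)
  as.numeric(d$modulus)
}

ml_discrepancy <- function(S, Sigma) {
  p <- ncol(S)
  ld_S <- logdet(S)
  ld_Sig <- logdet(Sigma)
  if (is.na(ld_S) || is.na(ld_Sig)) return(NA_real_)
  max(ld_Sig - ld_S + sum(diag(S %*% solve(Sigma))) - p, 0)
}

#' Model fit indices for a fitted correlation structure
#'
#' Chi-square from the normal-theory maximum-likelihood discrepancy between
#' the sample matrix and the model-implied matrix, with the independence model
#' on the same matrix as baseline. CFI and TLI are clamped to [0, 1]; RMSEA is
#' 0 whenever the chi-square does not exceed its degrees of freedom.
#'
#' @param S Sample correlation matrix.
#' @param Sigma Model-implied matrix.
#' @param df Model degrees of freedom.
#' @param n Sample size.
#' @return Object of class \code{fit_indices}: \code{chi_square}, \code{df},
#'   \code{p_value}, \code{CFI}, \code{TLI}, \code{RMSEA}.
#' @export
fit_indices <- function(S, Sigma, df, n) {
  S <- cor_values(S)
  p <- ncol(S)
  chi2 <- (n - 1) * ml_discrepancy(S, Sigma)
  df_b <- p * (p - 1) / 2
  chi2_b <- (n - 1) * ml_discrepancy(S, diag(p))
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, .Machine$double.eps)
  tli_raw <- if (df > 0 && df_b > 0 && chi2_b / df_b > 1)
    ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1) else 1
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else 0
  structure(list(
    chi_square = chi2, df = df,
    p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
    CFI = min(max(cfi, 0), 1),
    TLI = min(max(tli_raw, 0), 1),
    RMSEA = rmsea,
    baseline_chi_square = chi2_b, baseline_df = df_b, n = n),
    class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.2f, p %s, CFI = %.3f, TLI = %.3f, RMSEA = %.3f\n",
              x$df, x$chi_square,
              if (is.na(x$p_value)) "= NA"
              else if (x$p_value < .001) "< .001"
              else sprintf("= %.3f", x$p_value),
              x$CFI, x$TLI, x$RMSEA))
  invisible(x)
}

#' Exploratory factor analysis with oblique geomin rotation
#'
#' Extracts factors from a correlation matrix by unweighted least squares
#' (minres) and applies an oblique geomin rotation (gradient projection with
#' multiple deterministic starts). Eigenvalues of the input matrix are
#' reported for the Kaiser criterion. When a sample size is supplied, model
#' fit is evaluated through the maximum-likelihood discrepancy at the
#' extracted solution (an approximation to the weighted least squares
#' estimation used for ordinal data by dedicated SEM software; see the
#' methods vignette).
#'
#' @param R A \code{\link{correlation_matrix}} or plain correlation matrix.
#' @param n_factors Number of factors, \code{1 <= n_factors < n_items}.
#' @param n_obs Sample size behind \code{R}; taken from a
#'   \code{correlation_matrix} object when available.
#' @param geomin_eps Geomin epsilon (default 0.01).
#' @return Object of class \code{factor_solution}: rotated \code{loadings},
#'   \code{factor_correlations}, \code{eigenvalues}, \code{uniquenesses},
#'   \code{rotation}, \code{n_factors} and \code{fit}
#'   (\code{\link{fit_indices}} or \code{NULL}).
#' @export
efa_geomin <- function(R, n_factors, n_obs = NULL, geomin_eps = 0.01) {
  if (inherits(R, "correlation_matrix") && is.null(n_obs)) n_obs <- R$n
  S <- smooth_correlation(cor_values(R))
  p <- ncol(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ex <- fa_uls(S, n_factors)
  if (n_factors >= 2) {
    rot <- rotate_geomin(ex$loadings, eps = geomin_eps)
    loadings <- rot$loadings
    Phi <- rot$Phi
    rotation <- "geomin"
  } else {
    loadings <- ex$loadings
    sgn <- sign(loadings[which.max(abs(loadings[, 1])), 1])
    if (sgn < 0) loadings <- -loadings
    colnames(loadings) <- "F1"
    Phi <- matrix(1, 1, 1, dimnames = list("F1", "F1"))
    rotation <- "none"
  }
  fit <- NULL
  if (!is.null(n_obs)) {
    df <- ((p - n_factors)^2 - (p + n_factors)) / 2
    Sigma <- ex$loadings %*% t(ex$loadings) + diag(ex$uniquenesses)
    fit <- fit_indices(S, Sigma, df, n_obs)
  }
  structure(list(n_factors = n_factors, loadings = loadings,
                 factor_correlations = Phi,
                 eigenvalues = ev, uniquenesses = ex$uniquenesses,
                 rotation = rotation, fit = fit),
            class = "factor_solution")
}

#' Kaiser criterion
#'
#' Number of factors with eigenvalue greater than 1.
#'
#' @param x A \code{factor_solution}, \code{correlation_matrix} or numeric
#'   eigenvalue vector.
#' @return Integer count.
#' @export
kaiser_criterion <- function(x) {
  ev <- if (inherits(x, "factor_solution")) x$eigenvalues
        else if (inherits(x, "correlation_matrix"))
          eigen(x$values, symmetric = TRUE, only.values = TRUE)$values
        else as.numeric(x)
  sum(ev > 1)
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat(sprintf("%d-factor solution (%s rotation)\n", x$n_factors, x$rotation))
  cat("Eigenvalues:", paste(round(x$eigenvalues, 3), collapse = " "), "\n")
  cat("Loadings:\n")
  print(round(x$loadings, digits))
  if (x$n_factors > 1) {
    cat("Factor correlations:\n")
    print(round(x$factor_correlations, digits))
  }
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
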