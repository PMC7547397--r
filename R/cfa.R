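#' Confirmatory factor analysis of a correlation structure
#'
#' Fits a congeneric CFA model (every item loads on exactly one factor,
#' latent variances fixed at 1, correlated factors, unit-diagonal implied
#' matrix) to a Pearson or polychoric correlation matrix by minimizing the
#' normal-theory maximum-likelihood discrepancy, and evaluates fit through
#' \code{\link{fit_indices}}.
#'
#' @param model Named list mapping factor names to character vectors of item
#'   names (or integer column indices). Every item must appear in exactly one
#'   factor, and every factor must carry at least 2 items.
#' @param R A \code{\link{correlation_matrix}} or plain correlation matrix
#'   covering all model items.
#' @param n_obs Sample size; taken from a \code{correlation_matrix} when
#'   available.
#' @return Object of class \code{cfa_fit}: \code{loadings} (named, per item),
#'   \code{factor_correlations}, \code{uniquenesses}, \code{fit}
#'   (\code{\link{fit_indices}}), \code{model}, \code{converged}.
#' @export
cfa_fit <- function(model, R, n_obs = NULL) {
  if (inherits(R, "correlation_matrix") && is.null(n_obs)) n_obs <- R$n
  if (is.null(n_obs)) stop("n_obs is required to evaluate fit")
  S <- cor_values(R)
  items <- unlist(model, use.names = FALSE)
  if (is.numeric(items)) {
    model <- lapply(model, function(ix) colnames(S)[ix])
    items <- unlist(model, use.names = FALSE)
  }
  if (anyDuplicated(items))
    stop("identification error: an item is assigned to more than one factor")
  if (!all(items %in% colnames(S)))
    stop("unknown items: ", paste(setdiff(items, colnames(S)), collapse = ", "))
  if (any(lengths(model) < 2))
    stop("identification error: every factor needs at least 2 items")
  S <- smooth_correlation(S[items, items])
  p <- length(items)
  m <- length(model)
  fac_of <- rep(seq_len(m), lengths(model))
  n_rho <- m * (m - 1) / 2
  lower_idx <- which(lower.tri(diag(m)))

  build <- function(par) {
    lambda <- par[seq_len(p)]
    Phi <- diag(m)
    if (n_rho > 0) Phi[lower_idx] <- tanh(par[p + seq_len(n_rho)])
    Phi <- Phi + t(Phi) - diag(m)
    Lambda <- matrix(0, p, m)
    Lambda[cbind(seq_len(p), fac_of)] <- lambda
    common <- Lambda %*% Phi %*% t(Lambda)
    theta <- 1 - diag(common)
    Sigma <- common
    diag(Sigma) <- 1
    list(Lambda = Lambda, Phi = Phi, theta = theta, Sigma = Sigma)
  }
  objective <- function(par) {
    mod <- build(par)
    if (any(mod$theta < 1e-3)) return(1e6 + sum(pmax(1e-3 - mod$theta, 0)) * 1e6)
    if (n_rho > 0 && min(eigen(mod$Phi, symmetric = TRUE,
                               only.values = TRUE)$values) < 1e-6)
      return(1e6)
    f <- ml_discrepancy(S, mod$Sigma)
    if (is.na(f)) 1e6 else f
  }
  # start loadings at the item's mean absolute within-factor correlation
  start_lambda <- vapply(seq_len(p), function(i) {
    mates <- setdiff(which(fac_of == fac_of[i]), i)
    sqrt(min(max(mean(abs(S[i, mates])), 0.1), 0.9))
  }, numeric(1))
  start <- c(start_lambda, rep(0, n_rho))
  opt <- stats::optim(start, objective, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  mod <- build(opt$par)
  # df as for the covariance structure: p(p+1)/2 minus loadings,
  # uniquenesses and factor correlations
  df <- p * (p + 1) / 2 - (2 * p + n_rho)
  fit <- fit_indices(S, mod$Sigma, df, n_obs)
  loadings <- stats::setNames(opt$par[seq_len(p)], items)
  dimnames(mod$Phi) <- list(names(model), names(model))
  structure(list(loadings = loadings, factor_correlations = mod$Phi,
                 uniquenesses = stats::setNames(mod$theta, items),
                 fit = fit, model = model, converged = opt$convergence == 0),
            class = "cfa_fit")
}

#' @rdname cfa_fit
#' @param data Respondent table; the polychoric (default) or Pearson matrix is
#'   computed over the model's items first.
#' @param method Correlation method handed to
#'   \code{\link{correlation_matrix}}.
#' @export
cfa_fit_indices <- function(model, data, method = "polychoric") {
  items <- unlist(model, use.names = FALSE)
  R <- correlation_matrix(data, items, method = method)
  cfa_fit(model, R)$fit
}

#' Compare two nested CFA models
#'
#' Reports the chi-square difference, its degrees of freedom and p-value, and
#' the CFI difference; following the practical decision rule, the simpler
#' model is preferred unless its CFI is worse by 0.01 or more.
#'
#' @param restricted,general \code{cfa_fit} objects, the restricted model
#'   nested in the general one (fewer parameters, larger df).
#' @return List with \code{delta_chi_square}, \code{delta_df}, \code{p_value},
#'   \code{delta_cfi} and \code{prefer} (name of the preferred model's role).
#' @export
cfa_compare <- function(restricted, general) {
  stopifnot(inherits(restricted, "cfa_fit"), inherits(general, "cfa_fit"))
  d_chi <- restricted$fit$chi_square - general$fit$chi_square
  d_df <- restricted$fit$df - general$fit$df
  if (d_df <= 0) stop("models are not nested in the stated order")
  d_cfi <- general$fit$CFI - restricted$fit$CFI
  list(delta_chi_square = d_chi, delta_df = d_df,
       p_value = stats::pchisq(max(d_chi, 0), d_df, lower.tail = FALSE),
       delta_cfi = d_cfi,
       prefer = if (d_cfi < 0.01) "restricted" else "general")
}

#' @export
print.cfa_fit <- function(x, digits = 3, ...) {
  cat(sprintf("CFA: %d factors, %d items%s\n", length(x$model),
              length(x$loadings), if (x$converged) "" else " (NOT converged)"))
  for (f in names(x$model)) {
    cat(sprintf("  %s: %s\n", f, paste(
      sprintf("%s=%.*f", x$model[[f]], digits, x$loadings[x$model[[f]]]),
      collapse = " ")))
  }
  if (length(x$model) > 1) {
    cat("Factor correlations:\n")
    print(round(x$factor_correlations, digits))
  }
  print(x$fit)
  invisible(x)
}
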