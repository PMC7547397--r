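# Gauss-Legendre nodes on [-1, 1] via the Golub-Welsch eigenvalue method;
# cached, since the rule is fixed.
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    rule <- list(nodes = rev(e$values),
                 weights = rev(2 * e$vectors[1, ]^2))
    cache[[key]] <<- rule
    rule
  }
})

#' Standard bivariate normal CDF
#'
#' P(X <= h, Y <= k) for standard normal X, Y with correlation \code{rho},
#' computed from the identity that the derivative of the CDF with respect to
#' the correlation is the bivariate normal density, integrated from
#' independence with Gauss-Legendre quadrature.
#'
#' @param h,k Upper integration limits (vectors of equal length; infinite
#'   values allowed).
#' @param rho Scalar correlation in (-1, 1).
#' @param nodes Number of quadrature nodes.
#' @return Vector of probabilities.
#' @export
pbinorm <- function(h, k, rho, nodes = 48L) {
  stopifnot(length(rho) == 1, abs(rho) < 1)
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  gl <- gauss_legendre(nodes)
  r <- rho / 2 * (gl$nodes + 1)       # map [-1,1] -> [0, rho]
  w <- rho / 2 * gl$weights
  # handle infinite limits: density term vanishes there
  fin <- is.finite(h) & is.finite(k)
  out <- base
  if (any(fin)) {
    hf <- h[fin]; kf <- k[fin]
    acc <- numeric(length(hf))
    for (j in seq_along(r)) {
      rj <- r[j]
      om <- 1 - rj^2
      acc <- acc + w[j] / (2 * pi * sqrt(om)) *
        exp(-(hf^2 - 2 * rj * hf * kf + kf^2) / (2 * om))
    }
    out[fin] <- base[fin] + acc
  }
  pmin(pmax(out, 0), 1)
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum likelihood under the latent bivariate-normal model:
#' thresholds are fixed at the normal quantiles of the marginal cumulative
#' proportions, then the latent correlation maximizes the multinomial
#' likelihood of the observed contingency table.
#'
#' @param x,y Ordinal observations (integer or factor), complete cases.
#' @return List with \code{rho}, \code{thresholds_x}, \code{thresholds_y} and
#'   the contingency \code{table}.
#' @export
polychoric_cor <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  tab <- table(factor(x), factor(y))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate-input error: a variable has fewer than 2 observed categories")
  n <- sum(tab)
  tx <- stats::qnorm(cumsum(rowSums(tab))[-nrow(tab)] / n)
  ty <- stats::qnorm(cumsum(colSums(tab))[-ncol(tab)] / n)
  ax <- c(-Inf, tx, Inf)
  ay <- c(-Inf, ty, Inf)
  negloglik <- function(rho) {
    # CDF at every grid point, then rectangle probabilities by differencing
    H <- outer(ax, rep(1, length(ay)))
    K <- outer(rep(1, length(ax)), ay)
    P <- matrix(pbinorm(as.vector(H), as.vector(K), rho), length(ax))
    cell <- P[-1, -1] - P[-nrow(P), -1] - P[-1, -ncol(P)] +
      P[-nrow(P), -ncol(P)]
    cell <- pmax(cell, 1e-12)
    -sum(tab * log(cell))
  }
  opt <- stats::optimize(negloglik, interval = c(-0.999, 0.999), tol = 1e-6)
  list(rho = opt$minimum, thresholds_x = tx, thresholds_y = ty, table = tab)
}

#' Correlation matrix of a respondent table
#'
#' Pearson product-moment or pairwise polychoric correlations over the
#' selected columns, returned with a unit diagonal.
#'
#' @param data Data frame of complete cases.
#' @param variables Column names to correlate; defaults to all columns.
#' @param method \code{"pearson"} or \code{"polychoric"}.
#' @return Object of class \code{correlation_matrix}: list with \code{values}
#'   (symmetric matrix, unit diagonal), \code{method}, \code{n}.
#' @export
correlation_matrix <- function(data, variables = colnames(data),
                               method = c("pearson", "polychoric")) {
  method <- match.arg(method)
  m <- as.data.frame(data)[variables]
  if (anyNA(m)) stop("incomplete record: correlation_matrix requires complete cases")
  sds <- vapply(m, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("degenerate-input error: zero variance in ",
         paste(variables[sds == 0], collapse = ", "))
  p <- length(variables)
  if (method == "pearson") {
    vals <- stats::cor(m)
  } else {
    vals <- diag(p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      r <- polychoric_cor(m[[i]], m[[j]])$rho
      vals[i, j] <- vals[j, i] <- r
    }
  }
  dimnames(vals) <- list(variables, variables)
  structure(list(values = vals, method = method, n = nrow(m)),
            class = "correlation_matrix")
}

# eigenvalue-floor smoothing back to a proper correlation matrix
smooth_correlation <- function(R, floor = 1e-4) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  v <- pmax(e$values, floor)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- 1 / sqrt(diag(S))
  S <- diag(d) %*% S %*% diag(d)
  dimnames(S) <- dimnames(R)
  S
}

cor_values <- function(R) {
  if (inherits(R, "correlation_matrix")) R$values else as.matrix(R)
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("%s correlation matrix (%d variables, n = %d)\n",
              x$method, ncol(x$values), x$n))
  print(round(x$values, digits))
  invisible(x)
}
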