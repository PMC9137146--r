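#' Mardia's multivariate skewness and kurtosis
#'
#' Computes Mardia's measures for a multivariate sample: with
#' \eqn{m_{ij} = (x_i-\bar x)^\top S^{-1} (x_j-\bar x)} (using the
#' maximum-likelihood covariance, divisor `n`), skewness is
#' \eqn{b_{1,p} = n^{-2}\sum_{ij} m_{ij}^3} and kurtosis
#' \eqn{b_{2,p} = n^{-1}\sum_i m_{ii}^2}.  For a bivariate Gaussian sample
#' the population values are 0 and 8.  Normality tests use the asymptotic
#' references: \eqn{n\,b_{1,p}/6 \sim \chi^2_{p(p+1)(p+2)/6}} and
#' \eqn{b_{2,p} \approx N(p(p+2),\, 8p(p+2)/n)}.
#'
#' @param x numeric matrix (rows = observations).  The study uses bivariate
#'   samples, but any dimension with a nonsingular covariance is accepted.
#' @return object of class `"mardia"`: list with `skewness`, `kurtosis`,
#'   `n`, `p`, `p_skew`, `p_kurt`.
#' @examples
#' set.seed(1)
#' x <- gaussian_margins(copula_sample(copula_spec("normal", tau = 0.4), 500))
#' mardia(x)
#' @export
mardia <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 3) stop("need at least 3 observations")
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / n
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("degenerate sample: singular covariance matrix"))
  if (!all(is.finite(Sinv)) || rcond(S) < 1e-12)
    stop("degenerate sample: singular covariance matrix")
  ## b1 = mean over all pairs of (z_i . z_j)^3 with z = xc %*% t(L),
  ## L'L = S^{-1}.  Expanding the cube multinomially gives
  ## b1 = sum_alpha (3!/alpha!) (mean_i prod_c z_ic^alpha_c)^2 over
  ## exponent vectors alpha of total degree 3 -- O(n) in memory and time,
  ## unlike the naive n x n double sum.
  z <- xc %*% t(chol(Sinv))
  alphas <- .compositions(3L, p)
  b1 <- sum(vapply(seq_len(nrow(alphas)), function(k) {
    a <- alphas[k, ]
    w <- factorial(3) / prod(factorial(a))
    term <- rep(1, n)
    for (c in seq_len(p)) if (a[c] > 0) term <- term * z[, c]^a[c]
    w * mean(term)^2
  }, numeric(1)))
  b2 <- mean(rowSums(z^2)^2)
  df <- p * (p + 1) * (p + 2) / 6
  z_kurt <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  structure(list(
    skewness = b1, kurtosis = b2, n = n, p = p,
    p_skew = stats::pchisq(n * b1 / 6, df = df, lower.tail = FALSE),
    p_kurt = 2 * stats::pnorm(abs(z_kurt), lower.tail = FALSE)),
    class = "mardia")
}

#' @export
print.mardia <- function(x, ...) {
  cat(sprintf("Mardia diagnostics (n = %d, p = %d)\n", x$n, x$p))
  cat(sprintf("  skewness: %.4f  (normality test p = %.3g)\n",
              x$skewness, x$p_skew))
  cat(sprintf("  kurtosis: %.4f  (normality test p = %.3g; Gaussian value %g)\n",
              x$kurtosis, x$p_kurt, x$p * (x$p + 2)))
  invisible(x)
}

## all non-negative integer vectors of length p summing to deg
.compositions <- function(deg, p) {
  if (p == 1L) return(matrix(deg, 1, 1))
  out <- NULL
  for (k in 0:deg) {
    rest <- .compositions(deg - k, p - 1L)
    out <- rbind(out, cbind(k, rest))
  }
  unname(out)
}

#' Rank-based normal scores
#'
#' Returns \eqn{\Phi^{-1}(r_i/(n+1))} where \eqn{r_i} is the rank of the
#' i-th value (ties averaged).  The result depends on the data only through
#' the ranks, so it is invariant under strictly increasing transformations;
#' scatter plots of normal scores of two phenotypes visualise their copula
#' free of marginal effects.
#'
#' @param x numeric vector.
#' @return numeric vector of normal scores.
#' @examples
#' normal_scores(c(10, 20, 30))   # standard normal quartiles
#' @export
normal_scores <- function(x) {
  n <- length(x)
  stopifnot(n >= 1)
  stats::qnorm(rank(x, ties.method = "average") / (n + 1))
}
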