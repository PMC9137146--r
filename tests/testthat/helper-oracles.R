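# Independent oracles used across the test files.  These deliberately use
# brute-force dense linear algebra and generic quadrature, not the
# package's sparse/canonical code paths.

## numerator relationship matrix by the tabular method (dense, O(n^2)).
## model = "constant" uses the constant Mendelian-sampling variance of the
## simulated scheme (diag = parent-average variance + 1/2), whose exact
## inverse is given by Henderson's non-inbred rules on any pedigree;
## model = "inbred" is the classical recursion diag = 1 + 0.5 A[s, d].
## The two coincide while no *parent* is inbred.
tabular_A <- function(ped, model = c("constant", "inbred")) {
  model <- match.arg(model)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    for (j in seq_len(i - 1L)) {
      val <- 0
      if (!is.na(s)) val <- val + 0.5 * A[j, s]
      if (!is.na(d)) val <- val + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- val
    }
    if (!is.na(s) && !is.na(d)) {
      A[i, i] <- if (model == "inbred") 1 + 0.5 * A[s, d]
        else 0.25 * (A[s, s] + A[d, d] + 2 * A[s, d]) + 0.5
    } else if (!is.na(s)) {
      A[i, i] <- if (model == "inbred") 1 else 0.25 * A[s, s] + 0.75
    } else if (!is.na(d)) {
      A[i, i] <- if (model == "inbred") 1 else 0.25 * A[d, d] + 0.75
    } else A[i, i] <- 1
  }
  A
}

## random non-inbred-rule pedigree: generations of fixed size, parents
## drawn from the previous generation
random_pedigree <- function(n_founders, n_gen, per_gen) {
  sire <- dam <- rep(NA_integer_, n_founders)
  gen <- rep(0L, n_founders)
  for (g in seq_len(n_gen)) {
    prev <- which(gen == g - 1L)
    males <- prev[seq_len(max(2L, length(prev) %/% 3))]
    fems <- setdiff(prev, males)
    sire <- c(sire, sample(males, per_gen, replace = TRUE))
    dam <- c(dam, sample(fems, per_gen, replace = TRUE))
    gen <- c(gen, rep(g, per_gen))
  }
  data.frame(id = seq_along(sire), sire = sire, dam = dam,
             generation = gen)
}

## dense GLS/BLUP for the bivariate animal model with an arbitrary
## missingness pattern on trait 2: builds V = Z G Z' + R explicitly
dense_gls_blup <- function(phen, ped, sigma_a, sigma_e,
                           fixed = ~ f1, traits = c("y1", "y2")) {
  A <- tabular_A(ped)
  n <- nrow(ped)
  X1 <- stats::model.matrix(fixed, phen)
  Y <- as.matrix(phen[, traits])
  obs <- c(rep(TRUE, n), !is.na(Y[, 2]))
  y <- c(Y[, 1], Y[, 2])[obs]
  Xfull <- rbind(cbind(X1, 0 * X1), cbind(0 * X1, X1))[obs, ]
  G <- kronecker(sigma_a, A)
  R <- kronecker(sigma_e, diag(n))
  V <- (G + R)[obs, obs]
  Vi <- solve(V)
  XtVi <- t(Xfull) %*% Vi
  beta <- solve(XtVi %*% Xfull, XtVi %*% y)
  resid <- y - Xfull %*% beta
  ebv <- G[, obs] %*% Vi %*% resid          # BLUP: Cov(a, y) V^{-1} (y - Xb)
  p <- ncol(X1)
  list(beta = cbind(beta[1:p], beta[p + 1:p]),
       ebv = cbind(ebv[1:n], ebv[n + 1:n]))
}

## dense restricted log-likelihood for the same model (up to the constant
## used in the package: -(nrec - 2p)/2 log 2pi is included)
dense_restricted_ll <- function(phen, ped, sigma_a, sigma_e,
                                fixed = ~ f1, traits = c("y1", "y2")) {
  A <- tabular_A(ped)
  n <- nrow(ped)
  X1 <- stats::model.matrix(fixed, phen)
  Y <- as.matrix(phen[, traits])
  obs <- c(!is.na(Y[, 1]), !is.na(Y[, 2]))
  y <- c(Y[, 1], Y[, 2])[obs]
  Xfull <- rbind(cbind(X1, 0 * X1), cbind(0 * X1, X1))[obs, ]
  V <- (kronecker(sigma_a, A) + kronecker(sigma_e, diag(n)))[obs, obs]
  Vi <- solve(V)
  XtViX <- t(Xfull) %*% Vi %*% Xfull
  P <- Vi - Vi %*% Xfull %*% solve(XtViX, t(Xfull) %*% Vi)
  as.numeric(
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(t(y) %*% P %*% y)) -
      0.5 * (sum(obs) - ncol(Xfull)) * log(2 * pi))
}

## univariate animal-model REML by dense profile likelihood: for a
## variance ratio gamma = s2a/s2e, V0 = gamma A + I; s2e-hat is closed
## form, and the profile is maximised by Brent to high precision.
univariate_reml_oracle <- function(y, X, A) {
  n <- length(y); p <- ncol(X)
  profile <- function(lgamma) {
    V0 <- exp(lgamma) * A + diag(n)
    Vi <- solve(V0)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    q <- drop(t(y) %*% P %*% y)
    s2e <- q / (n - p)
    ll <- -0.5 * (determinant(V0)$modulus + (n - p) * log(s2e) +
                  determinant(XtViX)$modulus + (n - p))
    list(ll = as.numeric(ll), s2e = s2e)
  }
  opt <- stats::optimize(function(lg) -profile(lg)$ll,
                         interval = c(-12, 6), tol = 1e-12)
  pr <- profile(opt$minimum)
  c(sigma2_a = exp(opt$minimum) * pr$s2e, sigma2_e = pr$s2e)
}

## Kendall's tau by generic 2-D quadrature using only the copula CDF:
## tau = 1 - 4 int int (dC/du)(dC/dv) du dv, partials by central
## differences on a Gauss-Legendre grid.
tau_cdf_oracle <- function(spec, m = 64L, h = 1e-5) {
  gauss <- function(n, a, b) {
    i <- seq_len(n - 1); be <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n); J[cbind(i, i + 1)] <- be; J[cbind(i + 1, i)] <- be
    e <- eigen(J, symmetric = TRUE)
    list(x = (a + b) / 2 + (b - a) / 2 * e$values,
         w = (b - a) / 2 * 2 * e$vectors[1, ]^2)
  }
  gl <- gauss(m, 0, 1)
  U <- rep(gl$x, times = m); V <- rep(gl$x, each = m)
  W <- as.vector(outer(gl$w, gl$w))
  cu <- (copula_cdf(spec, U + h, V) - copula_cdf(spec, U - h, V)) / (2 * h)
  cv <- (copula_cdf(spec, U, V + h) - copula_cdf(spec, U, V - h)) / (2 * h)
  1 - 4 * sum(W * cu * cv)
}

## small simulated bivariate instance for oracle comparisons
make_instance <- function(n_founders = 8, n_gen = 2, per_gen = 16,
                          miss_frac = 0, seed = 1,
                          sigma_a = matrix(c(0.4, 0.1, 0.1, 0.6), 2),
                          sigma_e = matrix(c(1, 0.5, 0.5, 1.2), 2)) {
  set.seed(seed)
  ped <- random_pedigree(n_founders, n_gen, per_gen)
  n <- nrow(ped)
  a <- copulaAM:::.sim_breeding_values(ped, sigma_a)
  e <- copulaAM:::.rmvnorm2(n, sigma_e)
  f1 <- factor(sample(1:2, n, replace = TRUE))
  b <- c(0, 0.8)
  phen <- data.frame(id = ped$id,
                     y1 = b[f1] + a[, 1] + e[, 1],
                     y2 = -b[f1] + a[, 2] + e[, 2],
                     f1 = f1)
  if (miss_frac > 0)
    phen$y2[sample(n, round(miss_frac * n))] <- NA
  list(ped = ped, phen = phen, sigma_a = sigma_a, sigma_e = sigma_e)
}
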