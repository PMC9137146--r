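#' Fit the bivariate animal model by REML
#'
#' Estimates the six variance components of the bivariate animal model
#' \deqn{y_j = X_j\beta_j + a_j + \varepsilon_j, \quad j = 1, 2,}
#' where the stacked breeding values have covariance
#' \eqn{\Sigma_a \otimes A} (pedigree numerator relationship matrix
#' \eqn{A}) and the residual pairs are i.i.d. with covariance
#' \eqn{\Sigma_e}, by direct maximisation of the exact restricted
#' log-likelihood.  Both traits share the fixed-effect design given by
#' `fixed`; records with a missing second trait contribute through their
#' observed sub-vector only (no imputation).
#'
#' The restricted likelihood is evaluated through sparse Cholesky
#' factorisations of the mixed-model equations.  With complete records the
#' fit uses a canonical decomposition: for a candidate
#' \eqn{(\Sigma_a, \Sigma_e)} the traits are linearly transformed so that
#' the transformed residual covariance is the identity and the transformed
#' genetic covariance is diagonal, which splits the bivariate restricted
#' likelihood into two univariate animal-model likelihoods plus a Jacobian
#' term.  Each univariate likelihood costs one numeric update of a cached
#' sparse factorisation, so an evaluation is cheap even for tens of
#' thousands of animals.  With missing records the full bivariate
#' mixed-model equations are factorised instead.  Positive definiteness is
#' enforced throughout by optimising log-Cholesky parameters, so every
#' iterate corresponds to valid covariance matrices.
#'
#' @param phen data frame of phenotypes with one row per pedigree animal,
#'   in pedigree order: trait columns (see `traits`; `NA` = missing) and
#'   the fixed-effect factors named in `fixed`.
#' @param ped pedigree data frame (see [check_pedigree()]), same animals
#'   in the same order.
#' @param fixed one-sided formula for the fixed effects, shared by the two
#'   traits (each trait gets its own coefficients).
#' @param traits names of the two trait columns in `phen`.
#' @param start optional starting values: list with 2x2 matrices
#'   `sigma_a`, `sigma_e`.  Default: variances 0.3 (genetic) and 0.7
#'   (residual), zero covariances.
#' @param method `"auto"` picks the canonical path when both traits are
#'   complete and falls back to the direct sparse path otherwise; the
#'   other values force a path (the direct path is mainly useful for
#'   cross-checks).
#' @param fix_zero_cov if `TRUE` the genetic and residual covariances are
#'   held at zero, so the two traits are estimated as independent
#'   univariate animal models (used for univariate cross-checks).
#' @param maxit maximum number of optimiser iterations.
#' @param reltol relative convergence tolerance on the restricted
#'   log-likelihood.
#' @return an object of class `"am_reml"`; see [coef.am_reml()],
#'   [summary.am_reml()], [predict.am_reml()].
#' @seealso [am_blup()] for BLUP at known variance components,
#'   [heritability()], [genetic_gain()].
#' @export
am_reml <- function(phen, ped, fixed = ~ f1 + f2 + f3,
                    traits = c("y1", "y2"), start = NULL,
                    method = c("auto", "canonical", "direct"),
                    fix_zero_cov = FALSE, maxit = 200L, reltol = 1e-8) {
  method <- match.arg(method)
  check_pedigree(ped)
  stopifnot(nrow(phen) == nrow(ped), all(traits %in% names(phen)))
  Y <- as.matrix(phen[, traits])
  obs2 <- !is.na(Y[, 2])
  if (anyNA(Y[, 1])) {
    if (method == "canonical") stop("canonical path requires complete records")
    method <- "direct"
  }
  complete <- all(obs2)
  if (method == "auto") method <- if (complete) "canonical" else "direct"
  if (method == "canonical" && !complete)
    stop("canonical path requires complete records on both traits")

  X <- stats::model.matrix(fixed, data = phen)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  Ainv <- a_inverse(ped)
  ldA <- .logdet_A(ped)

  if (is.null(start))
    start <- list(sigma_a = diag(0.3, 2), sigma_e = diag(0.7, 2))
  par0 <- c(.logchol(start$sigma_a), .logchol(start$sigma_e))
  free <- if (fix_zero_cov) c(1, 3, 4, 6) else 1:6

  env <- new.env(parent = emptyenv())
  env$evals <- 0L
  env$best <- -Inf
  env$trace <- numeric(0)

  if (method == "canonical") {
    ch <- Matrix::Cholesky(Ainv, LDL = FALSE, perm = TRUE, Imult = 1)
    ctx <- list(X = X, Y = Y, Ainv = Ainv, ch = ch, ldA = ldA,
                n = nrow(Y), p = ncol(X), XtX = crossprod(X))
    objective <- function(pfree) {
      par <- par0; par[free] <- pfree
      Ga <- .chol2cov(par[1:3]); Re <- .chol2cov(par[4:6])
      ll <- .loglik_canonical(Ga, Re, ctx)
      env$evals <- env$evals + 1L
      if (ll > env$best) { env$best <- ll; env$trace <- c(env$trace, ll) }
      -ll
    }
  } else {
    ctx <- .direct_context(X, Y, Ainv, ldA)
    objective <- function(pfree) {
      par <- par0; par[free] <- pfree
      Ga <- .chol2cov(par[1:3]); Re <- .chol2cov(par[4:6])
      ll <- .loglik_direct(Ga, Re, ctx)$loglik
      env$evals <- env$evals + 1L
      if (ll > env$best) { env$best <- ll; env$trace <- c(env$trace, ll) }
      -ll
    }
  }

  ## forward-difference gradient reusing the objective value at the
  ## expansion point (optim evaluates fn before gr at the same point)
  cache <- new.env(parent = emptyenv())
  fn <- function(p) {
    v <- objective(p)
    cache$p <- p; cache$v <- v
    v
  }
  gr <- function(p) {
    f0 <- if (!is.null(cache$p) && isTRUE(all.equal(cache$p, p))) cache$v
          else objective(p)
    h <- 1e-6
    vapply(seq_along(p), function(k) {
      pk <- p; pk[k] <- pk[k] + h
      (objective(pk) - f0) / h
    }, numeric(1))
  }
  opt <- stats::optim(par0[free], fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = reltol / 1e-16))
  par <- par0; par[free] <- opt$par
  Ga <- .chol2cov(par[1:3]); Re <- .chol2cov(par[4:6])

  ## solutions (fixed effects + EBV) at the optimum
  sol <- if (method == "canonical") .solve_canonical(Ga, Re, ctx)
         else .loglik_direct(Ga, Re, ctx, solutions = TRUE)

  h2 <- diag(Ga) / (diag(Ga) + diag(Re))
  out <- list(
    call = match.call(), method = method,
    sigma_a = Ga, sigma_e = Re,
    h2 = stats::setNames(h2, traits),
    r_g = Ga[1, 2] / sqrt(Ga[1, 1] * Ga[2, 2]),
    r_e = Re[1, 2] / sqrt(Re[1, 1] * Re[2, 2]),
    beta = sol$beta, ebv = sol$ebv,
    loglik = -opt$value, trace = env$trace,
    converged = opt$convergence == 0L, evals = env$evals,
    message = opt$message,
    n = nrow(Y), n_obs2 = sum(obs2), p = ncol(X),
    traits = traits, fixed = fixed,
    fitted = sol$fitted, Y = Y, generation = ped$generation)
  class(out) <- "am_reml"
  out
}

## ---- parameterisation -----------------------------------------------------

## log-Cholesky: (log l11, l21, log l22) <-> SPD 2x2
.logchol <- function(S) {
  L <- t(chol(S))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}
.chol2cov <- function(p) {
  L <- matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2, 2)
  L %*% t(L)
}

## ---- canonical path -------------------------------------------------------

## transform achieving T Re T' = I, T Ga T' = diag(lambda)
.canonical_transform <- function(Ga, Re) {
  LR <- t(chol(Re))
  W <- forwardsolve(LR, t(forwardsolve(LR, Ga)))
  W <- (W + t(W)) / 2
  e <- eigen(W, symmetric = TRUE)
  Tm <- t(e$vectors) %*% forwardsolve(LR, diag(2))
  list(Tm = Tm, lambda = e$values)
}

## univariate animal-model restricted log-likelihood, residual variance 1,
## genetic variance lambda; all animals recorded once (Z = I).
## Factorises K = Ainv + lambda I; M = Z'Z + Ainv/lambda = K/lambda.
.loglik_univariate <- function(lambda, y, ctx, solutions = FALSE) {
  n <- ctx$n; p <- ctx$p; X <- ctx$X
  chK <- Matrix::update(ctx$ch, ctx$Ainv, mult = lambda)
  S <- as.matrix(Matrix::solve(chK, cbind(X, y)))    # K^{-1} [X y]
  Minv_X <- lambda * S[, 1:p, drop = FALSE]
  Minv_y <- lambda * S[, p + 1]
  XtX <- if (is.null(ctx$XtX)) crossprod(X) else ctx$XtX
  Xty <- drop(crossprod(X, y))
  Schur <- XtX - crossprod(X, Minv_X)
  cy <- Xty - drop(crossprod(X, Minv_y))
  Rs <- chol(Schur)
  beta <- backsolve(Rs, backsolve(Rs, cy, transpose = TRUE))
  a <- Minv_y - drop(Minv_X %*% beta)
  yPy <- sum(y * y) - sum(beta * Xty) - sum(a * y)
  ldK <- 2 * as.numeric(Matrix::determinant(chK, sqrt = TRUE)$modulus)
  ldM <- ldK - n * log(lambda)
  ldC <- ldM + 2 * sum(log(diag(Rs)))
  ldG <- n * log(lambda) + ctx$ldA
  ll <- -0.5 * (ldG + ldC + yPy) - 0.5 * (n - p) * log(2 * pi)
  if (solutions) list(loglik = ll, beta = beta, a = a) else ll
}

.loglik_canonical <- function(Ga, Re, ctx) {
  ct <- .canonical_transform(Ga, Re)
  if (any(ct$lambda <= 0)) return(-Inf)
  Ys <- ctx$Y %*% t(ct$Tm)
  ll <- .loglik_univariate(ct$lambda[1], Ys[, 1], ctx) +
        .loglik_univariate(ct$lambda[2], Ys[, 2], ctx)
  ll - 0.5 * (ctx$n - ctx$p) * as.numeric(determinant(Re)$modulus)
}

.solve_canonical <- function(Ga, Re, ctx) {
  ct <- .canonical_transform(Ga, Re)
  Ys <- ctx$Y %*% t(ct$Tm)
  s1 <- .loglik_univariate(ct$lambda[1], Ys[, 1], ctx, solutions = TRUE)
  s2 <- .loglik_univariate(ct$lambda[2], Ys[, 2], ctx, solutions = TRUE)
  Tinv <- solve(ct$Tm)
  beta <- cbind(s1$beta, s2$beta) %*% t(Tinv)
  ebv <- cbind(s1$a, s2$a) %*% t(Tinv)
  dimnames(beta) <- list(colnames(ctx$X), NULL)
  list(beta = beta, ebv = ebv,
       fitted = ctx$X %*% beta + ebv)
}

## ---- direct sparse path ---------------------------------------------------

## Pre-computations for the stacked bivariate mixed-model equations with
## per-record residual patterns (both traits / trait 1 only / trait 2 only).
.direct_context <- function(X, Y, Ainv, ldA) {
  o1 <- !is.na(Y[, 1]); o2 <- !is.na(Y[, 2])
  db <- o1 & o2; d1 <- o1 & !o2; d2 <- o2 & !o1
  y1 <- ifelse(o1, Y[, 1], 0); y2 <- ifelse(o2, Y[, 2], 0)
  list(X = X, Ainv = Ainv, ldA = ldA, n = nrow(Y), p = ncol(X),
       db = db, d1 = d1, d2 = d2, y1 = y1, y2 = y2,
       nrec = sum(o1) + sum(o2))
}

.loglik_direct <- function(Ga, Re, ctx, solutions = FALSE) {
  n <- ctx$n; p <- ctx$p; X <- ctx$X
  E <- solve(Re); Gi <- solve(Ga)
  r11 <- 1 / Re[1, 1]; r22 <- 1 / Re[2, 2]
  w11 <- E[1, 1] * ctx$db + r11 * ctx$d1
  w12 <- E[1, 2] * ctx$db
  w22 <- E[2, 2] * ctx$db + r22 * ctx$d2
  ## fixed-effect blocks
  B11 <- crossprod(X, X * w11); B12 <- crossprod(X, X * w12)
  B22 <- crossprod(X, X * w22)
  TL <- rbind(cbind(B11, B12), cbind(B12, B22))
  ## fixed x animal blocks
  FA <- rbind(cbind(t(X * w11), t(X * w12)),
              cbind(t(X * w12), t(X * w22)))
  ## animal blocks
  D <- Matrix::Diagonal
  AA <- rbind(
    cbind(D(x = w11) + Gi[1, 1] * ctx$Ainv, D(x = w12) + Gi[1, 2] * ctx$Ainv),
    cbind(D(x = w12) + Gi[1, 2] * ctx$Ainv, D(x = w22) + Gi[2, 2] * ctx$Ainv))
  C <- rbind(cbind(Matrix::Matrix(TL, sparse = TRUE),
                   Matrix::Matrix(FA, sparse = TRUE)),
             cbind(Matrix::t(Matrix::Matrix(FA, sparse = TRUE)), AA))
  C <- Matrix::forceSymmetric(C)
  u1 <- w11 * ctx$y1 + w12 * ctx$y2
  u2 <- w12 * ctx$y1 + w22 * ctx$y2
  rhs <- c(drop(crossprod(X, u1)), drop(crossprod(X, u2)), u1, u2)
  ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(ch, rhs))
  yRy <- sum(ctx$y1 * u1) + sum(ctx$y2 * u2)
  yPy <- yRy - sum(sol * rhs)
  nb <- sum(ctx$db)
  ldR <- nb * as.numeric(determinant(Re)$modulus) +
    sum(ctx$d1) * log(Re[1, 1]) + sum(ctx$d2) * log(Re[2, 2])
  ldG <- n * as.numeric(determinant(Ga)$modulus) + 2 * ctx$ldA
  ldC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  ll <- -0.5 * (ldR + ldG + ldC + yPy) -
    0.5 * (ctx$nrec - 2 * p) * log(2 * pi)
  if (!solutions) return(list(loglik = ll))
  beta <- cbind(sol[1:p], sol[p + 1:p])
  ebv <- cbind(sol[2 * p + 1:n], sol[2 * p + n + 1:n])
  dimnames(beta) <- list(colnames(X), NULL)
  list(loglik = ll, beta = beta, ebv = ebv,
       fitted = X %*% beta + ebv)
}

#' BLUP of breeding values at known variance components
#'
#' Solves Henderson's mixed-model equations for the bivariate animal model
#' at the supplied genetic and residual covariance matrices, handling
#' records with a missing trait through their observed sub-vector.
#' Breeding values are predicted for every pedigree member, phenotyped or
#' not.
#'
#' @inheritParams am_reml
#' @param sigma_a,sigma_e 2x2 genetic and residual covariance matrices.
#' @return list with `beta` (fixed-effect solutions, one column per
#'   trait), `ebv` (n x 2 matrix of predicted breeding values) and
#'   `loglik` (restricted log-likelihood at the supplied components).
#' @export
am_blup <- function(phen, ped, sigma_a, sigma_e, fixed = ~ f1 + f2 + f3,
                    traits = c("y1", "y2")) {
  check_pedigree(ped)
  Y <- as.matrix(phen[, traits])
  X <- stats::model.matrix(fixed, data = phen)
  ctx <- .direct_context(X, Y, a_inverse(ped), .logdet_A(ped))
  res <- .loglik_direct(as.matrix(sigma_a), as.matrix(sigma_e), ctx,
                        solutions = TRUE)
  list(beta = res$beta, ebv = res$ebv, loglik = res$loglik)
}

## ---- methods --------------------------------------------------------------

#' @export
print.am_reml <- function(x, ...) {
  cat("Bivariate animal model fit by REML (", x$method, " path)\n", sep = "")
  cat(sprintf("  %d animals (%d with both traits), %d fixed-effect columns per trait\n",
              x$n, x$n_obs2, x$p))
  cat(sprintf("  restricted log-likelihood: %.4f (%s, %d evaluations)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$evals))
  cat("  genetic covariance:\n")
  print(round(x$sigma_a, 4))
  cat("  residual covariance:\n")
  print(round(x$sigma_e, 4))
  cat(sprintf("  h2 = (%.3f, %.3f), r_g = %.3f, r_e = %.3f\n",
              x$h2[1], x$h2[2], x$r_g, x$r_e))
  invisible(x)
}

#' Variance components of an `am_reml` fit
#'
#' @param object an [am_reml()] fit.
#' @param ... unused.
#' @return named numeric vector `(sigma2_a1, sigma_a12, sigma2_a2,
#'   sigma2_e1, sigma_e12, sigma2_e2)`.
#' @export
coef.am_reml <- function(object, ...) {
  c(sigma2_a1 = object$sigma_a[1, 1], sigma_a12 = object$sigma_a[1, 2],
    sigma2_a2 = object$sigma_a[2, 2], sigma2_e1 = object$sigma_e[1, 1],
    sigma_e12 = object$sigma_e[1, 2], sigma2_e2 = object$sigma_e[2, 2])
}

#' @export
logLik.am_reml <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- 6
  attr(val, "nobs") <- object$n + object$n_obs2
  class(val) <- "logLik"
  val
}

#' @export
summary.am_reml <- function(object, ...) {
  structure(list(fit = object), class = "summary.am_reml")
}

#' @export
print.summary.am_reml <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  fixed-effect solutions (per trait):\n")
  print(round(f$beta, 4))
  if (!is.null(f$generation)) {
    mg <- rowsum(f$ebv, f$generation) /
      as.vector(table(f$generation))
    cat("  mean EBV by generation:\n")
    print(round(mg, 4))
  }
  invisible(x)
}

#' Predicted breeding values
#'
#' @param object an [am_reml()] fit.
#' @param ... unused.
#' @return data frame with one row per pedigree animal: `id`,
#'   `generation` (when known) and the two predicted breeding values.
#' @export
predict.am_reml <- function(object, ...) {
  out <- data.frame(id = seq_len(object$n))
  if (!is.null(object$generation)) out$generation <- object$generation
  out$ebv1 <- object$ebv[, 1]
  out$ebv2 <- object$ebv[, 2]
  out
}

#' @export
fitted.am_reml <- function(object, ...) as.matrix(object$fitted)

#' @export
residuals.am_reml <- function(object, ...) {
  object$Y - as.matrix(object$fitted)
}

#' Simulate phenotypes from a fitted bivariate animal model
#'
#' Draws new phenotype pairs from the fitted Gaussian animal model:
#' breeding values by the Mendelian recursion down the pedigree with the
#' estimated \eqn{\Sigma_a}, residuals i.i.d. bivariate normal with the
#' estimated \eqn{\Sigma_e}, and the fitted fixed-effect means.  The
#' missing-data pattern of the original data is reproduced.
#'
#' @param object an [am_reml()] fit.
#' @param nsim number of simulated data sets.
#' @param seed optional seed passed to [set.seed()].
#' @param ped the pedigree the model was fitted to.
#' @param ... unused.
#' @return list of `nsim` matrices (n x 2).
#' @export
simulate.am_reml <- function(object, nsim = 1, seed = NULL, ped, ...) {
  if (!is.null(seed)) set.seed(seed)
  check_pedigree(ped)
  Xb <- as.matrix(object$fitted) - object$ebv
  miss2 <- is.na(object$Y[, 2])
  lapply(seq_len(nsim), function(k) {
    a <- .sim_breeding_values(ped, object$sigma_a)
    e <- .rmvnorm2(object$n, object$sigma_e)
    y <- Xb + a + e
    y[miss2, 2] <- NA
    colnames(y) <- object$traits
    y
  })
}

#' Narrow-sense heritability
#'
#' \eqn{h^2_j = \sigma^2_{a_j} / (\sigma^2_{a_j} + \sigma^2_{e_j})} per
#' trait.
#'
#' @param object an [am_reml()] fit, or a numeric vector of additive
#'   genetic variances.
#' @param sigma2_e residual variances (default method only).
#' @param ... unused.
#' @return numeric vector of heritabilities.
#' @examples
#' heritability(c(0.18, 0.67), c(1, 1))   # 0.153, 0.401
#' @export
heritability <- function(object, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.am_reml <- function(object, ...) object$h2

#' @rdname heritability
#' @export
heritability.default <- function(object, sigma2_e, ...) {
  object / (object + sigma2_e)
}

#' Genetic gain relative to the founder generation
#'
#' Mean predicted breeding value of generation `k` minus the founder mean,
#' divided by the true genetic standard deviation of each trait.
#'
#' @param ebv n x 2 matrix of predicted breeding values (e.g. from an
#'   [am_reml()] fit or [am_blup()]).
#' @param generation integer vector of generation numbers per animal.
#' @param k target generation.
#' @param sigma2_a true additive genetic variances used for scaling.
#' @return numeric vector of length 2.
#' @export
genetic_gain <- function(ebv, generation, k, sigma2_a) {
  gk <- generation == k
  g0 <- generation == 0
  if (!any(gk) || !any(g0)) stop("empty generation")
  (colMeans(ebv[gk, , drop = FALSE]) - colMeans(ebv[g0, , drop = FALSE])) /
    sqrt(sigma2_a)
}
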