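# Small instances with an explicit dense-covariance oracle: the sparse
# mixed-model-equation solutions must agree with GLS/BLUP computed from
# V = Z G Z' + R by direct inversion.  make_instance() lives in
# helper-oracles.R.

test_that("sparse MME BLUP equals dense GLS BLUP (complete and missing)", {
  for (mf in c(0, 0.4)) {
    inst <- make_instance(miss_frac = mf, seed = 10 + mf)
    got <- am_blup(inst$phen, inst$ped, inst$sigma_a, inst$sigma_e,
                   fixed = ~ f1)
    want <- dense_gls_blup(inst$phen, inst$ped, inst$sigma_a, inst$sigma_e,
                           fixed = ~ f1)
    expect_lt(max(abs(got$beta - want$beta)), 1e-8)
    expect_lt(max(abs(got$ebv - want$ebv)), 1e-8)
  }
})

test_that("restricted likelihood equals the dense formula on both paths", {
  inst <- make_instance(seed = 3)
  want <- dense_restricted_ll(inst$phen, inst$ped, inst$sigma_a,
                              inst$sigma_e, fixed = ~ f1)
  got <- am_blup(inst$phen, inst$ped, inst$sigma_a, inst$sigma_e,
                 fixed = ~ f1)$loglik
  expect_equal(got, want, tolerance = 1e-8)
  ## canonical evaluation agrees with the direct/dense value
  X <- stats::model.matrix(~ f1, inst$phen)
  ctx <- list(X = X, Y = as.matrix(inst$phen[, c("y1", "y2")]),
              Ainv = a_inverse(inst$ped),
              ch = Matrix::Cholesky(a_inverse(inst$ped), LDL = FALSE,
                                    perm = TRUE, Imult = 1),
              ldA = copulaAM:::.logdet_A(inst$ped),
              n = nrow(inst$ped), p = ncol(X))
  expect_equal(copulaAM:::.loglik_canonical(inst$sigma_a, inst$sigma_e, ctx),
               want, tolerance = 1e-8)
  ## and with missing records the direct path still matches the dense value
  inst2 <- make_instance(miss_frac = 0.3, seed = 4)
  want2 <- dense_restricted_ll(inst2$phen, inst2$ped, inst2$sigma_a,
                               inst2$sigma_e, fixed = ~ f1)
  got2 <- am_blup(inst2$phen, inst2$ped, inst2$sigma_a, inst2$sigma_e,
                  fixed = ~ f1)$loglik
  expect_equal(got2, want2, tolerance = 1e-8)
})

test_that("zero residual covariance decouples into two single-trait BLUPs", {
  inst <- make_instance(seed = 5,
                        sigma_a = diag(c(0.4, 0.6)),
                        sigma_e = diag(c(1, 1.2)))
  got <- am_blup(inst$phen, inst$ped, inst$sigma_a, inst$sigma_e,
                 fixed = ~ f1)
  A <- tabular_A(inst$ped)
  X <- stats::model.matrix(~ f1, inst$phen)
  for (j in 1:2) {
    ## univariate dense BLUP for trait j alone
    y <- inst$phen[[c("y1", "y2")[j]]]
    V <- inst$sigma_a[j, j] * A + inst$sigma_e[j, j] * diag(nrow(A))
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    ebv <- inst$sigma_a[j, j] * A %*% Vi %*% (y - X %*% beta)
    expect_lt(max(abs(got$ebv[, j] - ebv)), 1e-8)
  }
})

test_that("EBVs shrink to zero as genetic variance vanishes", {
  inst <- make_instance(seed = 6)
  got <- am_blup(inst$phen, inst$ped, diag(2) * 1e-8, inst$sigma_e,
                 fixed = ~ f1)
  expect_lt(max(abs(got$ebv)), 1e-5)
})

test_that("REML with pinned covariances matches a univariate dense oracle", {
  inst <- make_instance(n_founders = 10, n_gen = 2, per_gen = 30, seed = 8)
  fit <- am_reml(inst$phen, inst$ped, fixed = ~ f1, fix_zero_cov = TRUE,
                 method = "direct", reltol = 1e-12)
  A <- tabular_A(inst$ped)
  X <- stats::model.matrix(~ f1, inst$phen)
  for (j in 1:2) {
    want <- univariate_reml_oracle(inst$phen[[c("y1", "y2")[j]]], X, A)
    got <- c(fit$sigma_a[j, j], fit$sigma_e[j, j])
    expect_equal(got, unname(want), tolerance = 1e-5)
  }
  expect_equal(fit$sigma_a[1, 2], 0)
  expect_equal(fit$sigma_e[1, 2], 0)
})

test_that("canonical and direct REML fits coincide on complete data", {
  inst <- make_instance(n_founders = 10, n_gen = 2, per_gen = 25, seed = 9)
  f1 <- am_reml(inst$phen, inst$ped, fixed = ~ f1, method = "canonical")
  f2 <- am_reml(inst$phen, inst$ped, fixed = ~ f1, method = "direct")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
})

test_that("accepted restricted log-likelihoods increase monotonically", {
  inst <- make_instance(seed = 12)
  fit <- am_reml(inst$phen, inst$ped, fixed = ~ f1)
  expect_true(all(diff(fit$trace) > 0))
  expect_true(fit$converged)
  ## estimated covariance matrices are positive definite by construction
  expect_true(all(eigen(fit$sigma_a)$values > 0))
  expect_true(all(eigen(fit$sigma_e)$values > 0))
})

test_that("heritability and genetic gain formulas", {
  expect_equal(unname(heritability(c(0.18, 0.67), c(1, 1))),
               c(0.18 / 1.18, 0.67 / 1.67))
  expect_equal(round(unname(heritability(c(0.18, 0.67), c(1, 1))), 3),
               c(0.153, 0.401))
  expect_equal(unname(heritability(0, 1)), 0)
  ebv <- cbind(c(0, 0, 1, 3), c(0, 0, 2, 2))
  gen <- c(0, 0, 1, 1)
  expect_equal(genetic_gain(ebv, gen, 0, c(1, 1)), c(0, 0))
  expect_equal(genetic_gain(ebv, gen, 1, c(4, 1)), c(1, 2))
  expect_error(genetic_gain(ebv, gen, 2, c(1, 1)), "empty")
})

test_that("fit methods: coef, logLik, predict, residuals, simulate", {
  inst <- make_instance(seed = 14)
  fit <- am_reml(inst$phen, inst$ped, fixed = ~ f1)
  expect_named(coef(fit), c("sigma2_a1", "sigma_a12", "sigma2_a2",
                            "sigma2_e1", "sigma_e12", "sigma2_e2"))
  expect_s3_class(logLik(fit), "logLik")
  pr <- predict(fit)
  expect_equal(nrow(pr), nrow(inst$ped))
  expect_equal(unname(as.matrix(pr[, c("ebv1", "ebv2")])), unname(fit$ebv))
  r <- residuals(fit)
  expect_equal(dim(r), c(nrow(inst$ped), 2))
  expect_lt(abs(mean(r)), 0.2)
  sims <- simulate(fit, nsim = 2, seed = 1, ped = inst$ped)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(nrow(inst$ped), 2))
  expect_false(identical(sims[[1]], sims[[2]]))
})

test_that("REML recovers the simulation truth on mid-sized populations", {
  ## mean of a few replicates: within wide Monte-Carlo bands of the truth
  est <- do.call(rbind, lapply(1:5, function(r) {
    pop <- sim_population(design = "complete",
                          copula = copula_spec("normal", tau = 0.4),
                          tau_a = 0.4, sigma2_a = c(0.18, 0.67),
                          n_generations = 3, scale = 1/4, seed = 2020 + r,
                          reml_at = 3)
    pop$estimates
  }))
  expect_true(all(est$converged))
  expect_lt(abs(mean(est$h2_1) - 0.18 / 1.18), 0.05)
  expect_lt(abs(mean(est$h2_2) - 0.67 / 1.67), 0.06)
  expect_lt(abs(mean(est$r_e) - sin(pi * 0.2)), 0.03)
  expect_lt(abs(mean(est$r_g) - sin(pi * 0.2)), 0.17)
})
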