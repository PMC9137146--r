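specs_under_test <- list(
  copula_spec("normal", tau = 0.4),
  copula_spec("normal", tau = -0.7),
  copula_spec("frank", tau = 0.7),
  copula_spec("frank", tau = -0.4),
  copula_spec("clayton", tau = 0.4),
  copula_spec("clayton", tau = -0.7),
  copula_spec("joe", tau = 0.7),
  copula_spec("joe", tau = -0.4))

test_that("construction validates parameter domains and rotation", {
  expect_error(copula_spec("joe", theta = 0.5), "domain")
  expect_error(copula_spec("normal", theta = 1.2), "domain")
  expect_error(copula_spec("normal", tau = 1), "tau")
  expect_error(copula_spec("frank", tau = 0.4, theta = 2), "exactly one")
  for (f in c("clayton", "joe")) {
    expect_true(copula_spec(f, tau = -0.4)$rotated)
    expect_false(copula_spec(f, tau = 0.4)$rotated)
  }
  expect_false(copula_spec("frank", tau = -0.4)$rotated)
  expect_false(copula_spec("normal", tau = -0.4)$rotated)
})

test_that("copula CDF satisfies uniform-margin boundary conditions", {
  u <- seq(0, 1, by = 0.1)
  for (sp in specs_under_test) {
    expect_equal(copula_cdf(sp, u, rep(1, 11)), u, tolerance = 1e-9)
    expect_equal(copula_cdf(sp, rep(1, 11), u), u, tolerance = 1e-9)
    expect_equal(copula_cdf(sp, u, rep(0, 11)), rep(0, 11),
                 tolerance = 1e-12)
    expect_equal(copula_cdf(sp, rep(0, 11), u), rep(0, 11),
                 tolerance = 1e-12)
  }
})

test_that("closed-form CDF values are reproduced", {
  ## Clayton theta = 2 at (0.5, 0.5): (4 + 4 - 1)^(-1/2)
  expect_equal(copula_cdf(copula_spec("clayton", theta = 2), 0.5, 0.5),
               7^(-0.5), tolerance = 1e-10)
  ## independence copula
  expect_equal(copula_cdf(copula_spec("normal", theta = 0), 0.3, 0.5),
               0.15, tolerance = 1e-9)
  expect_equal(copula_cdf(copula_spec("frank", tau = 0), 0.3, 0.5),
               0.15, tolerance = 1e-9)
})

test_that("Frechet-Hoeffding bounds and 2-increasingness hold on a grid", {
  g <- seq(0, 1, length.out = 50)
  for (sp in specs_under_test) {
    C <- outer(g, g, function(u, v) copula_cdf(sp, u, v))
    lower <- outer(g, g, function(u, v) pmax(u + v - 1, 0))
    upper <- outer(g, g, pmin)
    expect_true(all(C >= lower - 1e-9))
    expect_true(all(C <= upper + 1e-9))
    vol <- C[-1, -1] - C[-1, -50] - C[-50, -1] + C[-50, -50]
    expect_true(all(vol >= -1e-9))
  }
})

test_that("tau_to_theta matches closed forms and round-trips", {
  expect_equal(tau_to_theta("normal", 0.7), sin(0.35 * pi), tolerance = 1e-12)
  expect_equal(tau_to_theta("normal", 0.7), 0.891, tolerance = 5e-4)
  expect_equal(tau_to_theta("clayton", 0.4), 4 / 3, tolerance = 1e-12)
  ## independence limits
  expect_equal(tau_to_theta("normal", 0), 0)
  expect_equal(tau_to_theta("frank", 0), 0)
  expect_equal(tau_to_theta("clayton", 0), 0)
  expect_equal(tau_to_theta("joe", 0), 1)
  for (tau in c(-0.7, -0.4, -0.2, 0.2, 0.4, 0.7)) {
    for (f in c("normal", "frank", "clayton", "joe")) {
      sp <- copula_spec(f, tau = tau)
      expect_equal(kendall_tau(sp), tau, tolerance = 1e-6,
                   label = sprintf("%s tau=%g", f, tau))
    }
  }
})

test_that("generator-integral tau agrees with a CDF-only quadrature oracle", {
  for (sp in list(copula_spec("joe", tau = 0.7),
                  copula_spec("frank", tau = 0.4),
                  copula_spec("clayton", tau = 0.4),
                  copula_spec("clayton", tau = -0.7))) {
    expect_equal(kendall_tau(sp), tau_cdf_oracle(sp), tolerance = 2e-3)
  }
})

test_that("sampling reproduces the target Kendall tau and uniform margins", {
  set.seed(101)
  uv <- copula_sample(copula_spec("frank", tau = 0.4), 1e5)
  expect_lt(abs(stats::cor(uv[, 1], uv[, 2], method = "kendall") - 0.4),
            0.005)
  expect_gt(suppressWarnings(stats::ks.test(uv[, 1], "punif")$p.value),
            0.01)
  expect_gt(suppressWarnings(stats::ks.test(uv[, 2], "punif")$p.value),
            0.01)
  uv <- copula_sample(copula_spec("clayton", tau = -0.7), 5e4)
  expect_lt(abs(stats::cor(uv[, 1], uv[, 2], method = "kendall") + 0.7),
            0.01)
  uv <- copula_sample(copula_spec("joe", tau = 0.7), 5e4)
  expect_lt(abs(stats::cor(uv[, 1], uv[, 2], method = "kendall") - 0.7),
            0.01)
})

test_that("empirical copula converges to the analytic CDF", {
  set.seed(202)
  for (sp in list(copula_spec("joe", tau = 0.4),
                  copula_spec("clayton", tau = -0.4))) {
    uv <- copula_sample(sp, 1e5)
    g <- seq(0.05, 0.95, by = 0.15)
    emp <- outer(g, g, Vectorize(function(u, v)
      mean(uv[, 1] <= u & uv[, 2] <= v)))
    thy <- outer(g, g, function(u, v) copula_cdf(sp, u, v))
    expect_lt(max(abs(emp - thy)), 0.01)
  }
})

test_that("gaussian margins give standard normal coordinates", {
  expect_equal(gaussian_margins(cbind(0.5, 0.5)), cbind(x = 0, y = 0))
  expect_error(gaussian_margins(cbind(0, 0.5)), "strictly inside")
  set.seed(7)
  xy <- gaussian_margins(copula_sample(copula_spec("normal", tau = 0.4), 1e5))
  expect_equal(apply(xy, 2, stats::var), c(x = 1, y = 1), tolerance = 0.02)
  expect_equal(stats::cor(xy[, 1], xy[, 2]), sin(0.2 * pi), tolerance = 0.01)
})

test_that("pearson correlation: normal closed form, independence, rotation", {
  for (tau in c(-0.7, -0.2, 0.3, 0.6))
    expect_equal(copula_pearson(copula_spec("normal", tau = tau)),
                 sin(pi * tau / 2), tolerance = 1e-9)
  expect_equal(copula_pearson(copula_spec("frank", theta = 1e-12)), 0,
               tolerance = 1e-6)
  expect_equal(copula_pearson(copula_spec("clayton", tau = -0.7)),
               -copula_pearson(copula_spec("clayton", tau = 0.7)),
               tolerance = 1e-12)
})

test_that("tail dependence matches closed forms and the diagonal limit", {
  td <- tail_dependence(copula_spec("clayton", tau = 0.7))
  expect_equal(unname(td), c(2^(-1 / tau_to_theta("clayton", 0.7)), 0))
  ## numeric limit C(q, q)/q as q -> 0
  sp <- copula_spec("clayton", tau = 0.7)
  q <- 1e-7
  expect_equal(copula_cdf(sp, q, q) / q, td[["lambda_L"]], tolerance = 1e-3)
  sp <- copula_spec("joe", tau = 0.7)
  tdj <- tail_dependence(sp)
  expect_equal(unname(tdj), c(0, 2 - 2^(1 / sp$theta)))
  ## upper limit: (1 - 2q + C(q', q'))/(1 - q') with q' -> 1
  qp <- 1 - 1e-7
  expect_equal((1 - 2 * qp + copula_cdf(sp, qp, qp)) / (1 - qp),
               tdj[["lambda_U"]], tolerance = 1e-3)
  expect_equal(unname(tail_dependence(copula_spec("frank", tau = 0.5))),
               c(0, 0))
  expect_equal(unname(tail_dependence(copula_spec("normal", tau = 0.5))),
               c(0, 0))
})
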