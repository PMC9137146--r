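#' Default fixed-effect values
#'
#' Three categorical fixed effects with three, two and two levels per
#' trait; the level values are small arbitrary contrasts, identical for
#' the two traits.
#'
#' @return list of numeric level-value vectors, one per factor.
#' @export
default_fixed_values <- function() {
  list(f1 = c(0, 1, -1), f2 = c(0.5, -0.5), f3 = c(0.3, -0.3))
}

#' Simulate a selected pig-type breeding scheme
#'
#' Generates the closed breeding scheme used throughout the package's
#' Monte-Carlo study.  At full scale the founder generation has 216
#' unrelated animals (12 males, 204 females); every sire is mated to 17
#' dams, each dam produces 12 offspring (2 males, 10 females) in the
#' complete design or 24 (4 males, 20 females, half of each sex missing
#' the second trait) in the missing design, so one generation has 2448
#' (complete) or 4896 (missing) animals.  Generations 1 to
#' `random_generations` are bred from randomly chosen reproducers; later
#' generations are bred by within-family truncation on a 50/50 EBV index
#' (one male and 17 females kept per paternal half-sib family, i.e.
#' selected fractions 1/34 and 17/170).  In the missing design only the
#' animals lacking the second trait are selection candidates.
#'
#' Breeding values follow the Mendelian recursion with genetic covariance
#' `Sigma_a` implied by `sigma2_a` and `tau_a`
#' (\eqn{\rho_a = \sin(\pi\tau_a/2)}); residual pairs are i.i.d. with
#' standard normal margins and the copula `copula`; three categorical
#' fixed effects (3, 2, 2 levels) are assigned uniformly at random.
#' Phenotypes follow \eqn{y_j = x^\top\beta_j + a_j + \varepsilon_j}.
#'
#' Genetic draws, residual draws and scheme randomness (mating, random
#' selection, tie-breaks) come from three separate streams derived from
#' `seed`, so replicates that differ only in the residual copula share
#' their genetic realisations.
#'
#' @param design `"complete"` (both traits on every animal) or
#'   `"missing"` (second trait missing on the selection candidates).
#' @param copula residual dependence structure, a [copula_spec()].
#' @param tau_a Kendall correlation of the genetic effects.
#' @param sigma2_a additive genetic variances of the two traits.
#' @param sigma2_e residual variances (the study keeps them at 1).
#' @param n_generations number of offspring generations (8 in the full
#'   study).
#' @param random_generations generations bred from random reproducers
#'   before truncation selection starts (3 in the full study).
#' @param scale population scale factor: the number of sires is
#'   `round(12 * scale)` with 17 dams per sire and unchanged litter
#'   sizes, preserving the within-family selected fractions.
#' @param seed integer seed for the replicate.
#' @param selection_vc variance components behind the selection-stage
#'   BLUP: `"reml"` re-fits REML on all data available at each selection
#'   round (the default), `"true"` uses the simulation values.
#' @param reml_at generations at which REML estimates (and EBV-based
#'   genetic gains) are recorded, e.g. `3:8`.
#' @param fixed_values list of per-factor level values, see
#'   [default_fixed_values()].
#' @param weights selection-index weights.
#' @return an object of class `"am_population"`: list with `ped`
#'   (pedigree incl. sex, generation, candidate and missing flags),
#'   `phen` (phenotypes and fixed-effect factors), `bv` and `resid`
#'   (true simulated effects), `config`, `fits` (REML or BLUP results by
#'   generation, when requested) and `estimates` (per-generation
#'   estimated components and genetic gains).
#' @examples
#' pop <- sim_population(scale = 1/6, n_generations = 2, seed = 1)
#' table(pop$ped$generation)
#' @export
sim_population <- function(design = c("complete", "missing"),
                           copula = copula_spec("normal", tau = 0.4),
                           tau_a = 0.2, sigma2_a = c(0.18, 0.18),
                           sigma2_e = c(1, 1),
                           n_generations = 8L, random_generations = 3L,
                           scale = 1, seed = 1L,
                           selection_vc = c("reml", "true"),
                           reml_at = integer(0),
                           fixed_values = default_fixed_values(),
                           weights = c(0.5, 0.5)) {
  design <- match.arg(design)
  selection_vc <- match.arg(selection_vc)
  ns <- max(1L, as.integer(round(12 * scale)))
  nd <- 17L * ns
  if (design == "complete") { noff <- 12L; nM <- 2L; nF <- 10L }
  else { noff <- 24L; nM <- 4L; nF <- 20L }
  rho_a <- sin(pi * tau_a / 2)
  Sigma_a <- sqrt(sigma2_a) %o% sqrt(sigma2_a) *
    matrix(c(1, rho_a, rho_a, 1), 2)
  streams <- .rng_streams(seed, c("genetic", "residual", "scheme"))

  ## founders
  n0 <- ns + nd
  ped <- data.frame(
    id = seq_len(n0),
    sire = NA_integer_, dam = NA_integer_,
    sex = c(rep("M", ns), rep("F", nd)),
    generation = 0L, candidate = FALSE, trait2_missing = FALSE)
  bv <- .with_stream(streams, "genetic", .rmvnorm2(n0, Sigma_a))
  lev <- .with_stream(streams, "residual", .draw_env(n0, copula, fixed_values))
  resid <- lev$eps
  fx <- lev$fx

  fits <- list()
  estimates <- NULL

  for (g in seq_len(n_generations)) {
    ## choose reproducers among generation g-1
    if (g == 1L) {
      sires <- which(ped$sex == "M" & ped$generation == 0L)
      dams <- which(ped$sex == "F" & ped$generation == 0L)
    } else {
      ebv <- NULL
      if (g > random_generations) {
        fit <- .fit_for_selection(g - 1L, ped, bv, resid, fx, fixed_values,
                                  sigma2_e, Sigma_a, selection_vc,
                                  design, fits)
        fits[[as.character(g - 1L)]] <- fit
        ebv <- fit$ebv
      }
      sel <- .with_stream(streams, "scheme",
        select_breeders(ped, g - 1L, ebv = ebv, n_females = nd %/% ns,
                        weights = weights))
      sires <- sel$sires; dams <- sel$dams
    }
    mat <- .with_stream(streams, "scheme", .assign_mates(sires, dams, ped))

    nnew <- nrow(mat) * noff
    base <- nrow(ped)
    sex <- rep(c(rep("M", nM), rep("F", nF)), nrow(mat))
    miss <- if (design == "missing")
      rep(c(rep(TRUE, nM / 2), rep(FALSE, nM / 2),
            rep(TRUE, nF / 2), rep(FALSE, nF / 2)), nrow(mat))
    else rep(FALSE, nnew)
    cand <- if (design == "missing") miss else rep(TRUE, nnew)
    newped <- data.frame(
      id = base + seq_len(nnew),
      sire = rep(mat$sire, each = noff),
      dam = rep(mat$dam, each = noff),
      sex = sex, generation = g, candidate = cand, trait2_missing = miss)
    M <- .with_stream(streams, "genetic", .rmvnorm2(nnew, Sigma_a / 2))
    newbv <- 0.5 * (bv[newped$sire, , drop = FALSE] +
                    bv[newped$dam, , drop = FALSE]) + M
    env <- .with_stream(streams, "residual",
                        .draw_env(nnew, copula, fixed_values))
    ped <- rbind(ped, newped)
    bv <- rbind(bv, newbv)
    resid <- rbind(resid, env$eps)
    fx <- rbind(fx, env$fx)
  }
  phen <- .make_phen(ped, bv, resid, fx, fixed_values, sigma2_e)

  config <- list(design = design, copula = copula, tau_a = tau_a,
                 rho_a = rho_a, sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 Sigma_a = Sigma_a, n_sires = ns, n_dams = nd,
                 offspring_per_dam = noff, scale = scale,
                 n_generations = n_generations,
                 random_generations = random_generations,
                 selection_vc = selection_vc, weights = weights,
                 fixed_values = fixed_values, seed = seed)

  ## REML estimates (and gains) at the requested generations
  for (k in sort(unique(as.integer(reml_at)))) {
    key <- as.character(k)
    if (is.null(fits[[key]]) || !identical(fits[[key]]$how, "reml")) {
      prev <- fits[[as.character(k - 1L)]]
      start <- if (!is.null(prev) && identical(prev$how, "reml"))
        list(sigma_a = prev$sigma_a, sigma_e = prev$sigma_e) else NULL
      fits[[key]] <- .fit_generation(k, ped, phen, "reml",
                                     Sigma_a, sigma2_e, start = start)
      fits[[key]]$how <- "reml"
    }
    fit <- fits[[key]]
    est <- data.frame(
      generation = k,
      h2_1 = fit$h2[1], h2_2 = fit$h2[2], r_g = fit$r_g, r_e = fit$r_e,
      sigma2_a1 = fit$sigma_a[1, 1], sigma_a12 = fit$sigma_a[1, 2],
      sigma2_a2 = fit$sigma_a[2, 2], sigma2_e1 = fit$sigma_e[1, 1],
      sigma_e12 = fit$sigma_e[1, 2], sigma2_e2 = fit$sigma_e[2, 2],
      converged = fit$converged,
      gain1 = NA_real_, gain2 = NA_real_)
    gg <- genetic_gain(fit$ebv, ped$generation[seq_len(nrow(fit$ebv))],
                       k, sigma2_a)
    est$gain1 <- gg[1]; est$gain2 <- gg[2]
    estimates <- rbind(estimates, est)
  }
  if (!is.null(estimates)) rownames(estimates) <- NULL

  structure(list(ped = ped, phen = phen, bv = bv, resid = resid,
                 config = config, fits = fits, estimates = estimates),
            class = "am_population")
}

#' @export
print.am_population <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated breeding scheme (%s design, %s copula, tau_e = %.2g)\n",
              cfg$design, cfg$copula$family, cfg$copula$tau))
  cat(sprintf("  %d animals over %d generations (%d sires x 17 dams, %d offspring/dam)\n",
              nrow(x$ped), cfg$n_generations, cfg$n_sires,
              cfg$offspring_per_dam))
  cat(sprintf("  h2 = (%.3f, %.3f), rho_a = %.3f\n",
              cfg$sigma2_a[1] / (cfg$sigma2_a[1] + cfg$sigma2_e[1]),
              cfg$sigma2_a[2] / (cfg$sigma2_a[2] + cfg$sigma2_e[2]),
              cfg$rho_a))
  if (!is.null(x$estimates)) {
    cat("  REML estimates by generation:\n")
    print(round(x$estimates[, c("generation", "h2_1", "h2_2", "r_g",
                                "r_e", "gain1", "gain2")], 4))
  }
  invisible(x)
}

## residuals (copula with standard normal margins) and fixed-effect levels
.draw_env <- function(n, copula, fixed_values) {
  eps <- gaussian_margins(copula_sample(copula, n))
  fx <- data.frame(lapply(fixed_values, function(v)
    sample.int(length(v), n, replace = TRUE)))
  list(eps = eps, fx = fx)
}

.make_phen <- function(ped, bv, resid, fx, fixed_values, sigma2_e) {
  lp <- rowSums(mapply(function(v, l) v[l], fixed_values, fx))
  se <- sqrt(sigma2_e)
  y1 <- lp + bv[, 1] + se[1] * resid[, 1]
  y2 <- lp + bv[, 2] + se[2] * resid[, 2]
  y2[ped$trait2_missing] <- NA_real_
  phen <- data.frame(id = ped$id, y1 = y1, y2 = y2)
  for (nm in names(fx)) phen[[nm]] <- factor(fx[[nm]])
  phen
}

## data visible at generation k (animals of generations 0..k)
.fit_generation <- function(k, ped, phen, how, Sigma_a, sigma2_e,
                            start = NULL) {
  keep <- ped$generation <= k
  pedk <- ped[keep, , drop = FALSE]
  phenk <- phen[keep, , drop = FALSE]
  if (how == "true") {
    bl <- am_blup(phenk, pedk, Sigma_a, diag(sigma2_e))
    list(ebv = bl$ebv, beta = bl$beta, h2 = diag(Sigma_a) /
           (diag(Sigma_a) + sigma2_e),
         sigma_a = Sigma_a, sigma_e = diag(sigma2_e),
         r_g = Sigma_a[1, 2] / sqrt(prod(diag(Sigma_a))), r_e = 0,
         converged = TRUE, how = "true")
  } else {
    fit <- am_reml(phenk, pedk, start = start)
    fit$how <- "reml"
    fit
  }
}

.fit_for_selection <- function(k, ped, bv, resid, fx, fixed_values,
                               sigma2_e, Sigma_a, selection_vc, design,
                               fits) {
  prev <- fits[[as.character(k - 1L)]]
  start <- if (!is.null(prev) && identical(prev$how, "reml"))
    list(sigma_a = prev$sigma_a, sigma_e = prev$sigma_e) else NULL
  keep <- ped$generation <= k
  phen <- .make_phen(ped, bv, resid, fx, fixed_values, sigma2_e)
  .fit_generation(k, ped, phen, selection_vc, Sigma_a, sigma2_e,
                  start = start)
}
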