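## Named random-number streams.
##
## The simulator draws genetic effects, residuals and scheme randomness
## (mating, random selection, tie-breaks) from separate streams derived
## from one seed, so that changing the residual copula family leaves the
## genetic draws of a replicate untouched and paired comparisons across
## copulas share their genetic realisations.

.rng_streams <- function(seed, names) {
  env <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    sub <- (as.numeric(seed) * 48271 + i * 1000003) %% 2147483563 + 1
    set.seed(as.integer(sub))
    env[[names[i]]] <- get(".Random.seed", envir = .GlobalEnv)
  }
  env
}

.with_stream <- function(streams, name, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  assign(".Random.seed", streams[[name]], envir = .GlobalEnv)
  on.exit({
    streams[[name]] <- get(".Random.seed", envir = .GlobalEnv)
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
  })
  expr
}

## bivariate normal draws, rows iid N(0, S)
.rmvnorm2 <- function(n, S) {
  if (all(S == 0)) return(matrix(0, n, 2))
  matrix(stats::rnorm(2 * n), n, 2) %*% chol(S)
}

## breeding values down a pedigree: animals with both parents unknown get
## N(0, Sigma), offspring get the parent average plus a Mendelian term
## N(0, Sigma/2) (non-inbred scheme: both parents known for non-founders).
.sim_breeding_values <- function(ped, Sigma) {
  n <- nrow(ped)
  a <- matrix(0, n, 2)
  founder <- is.na(ped$sire) & is.na(ped$dam)
  a[founder, ] <- .rmvnorm2(sum(founder), Sigma)
  idx <- which(!founder)
  if (length(idx)) {
    M <- .rmvnorm2(length(idx), Sigma / 2)
    for (j in seq_along(idx)) {
      i <- idx[j]
      a[i, ] <- 0.5 * (a[ped$sire[i], ] + a[ped$dam[i], ]) + M[j, ]
    }
  }
  a
}
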