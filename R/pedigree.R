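#' Validate a pedigree table
#'
#' A pedigree is a data frame with integer columns `id`, `sire`, `dam`
#' (`NA` for unknown parents) and, for simulated schemes, `sex`
#' (`"M"`/`"F"`), `generation`, `candidate` and `trait2_missing`.
#' Identifiers must be consecutive integers in birth order so parents
#' always precede their offspring; that ordering is what Henderson's
#' direct rules for the relationship inverse rely on.
#'
#' @param ped a pedigree data frame.
#' @return the pedigree, invisibly, after validation.
#' @export
check_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  if (!identical(as.integer(ped$id), seq_len(n)))
    stop("pedigree ids must be consecutive integers 1..n in birth order")
  for (col in c("sire", "dam")) {
    par <- ped[[col]]
    known <- !is.na(par)
    if (any(par[known] >= ped$id[known]))
      stop("each parent must precede its offspring (parent id < own id)")
  }
  invisible(ped)
}

#' Inverse of the numerator relationship matrix
#'
#' Builds \eqn{A^{-1}} directly from the pedigree by Henderson's rules for
#' non-inbred pedigrees.  For each animal the contribution
#' \eqn{\delta = 2} (both parents known), \eqn{4/3} (one known) or 1 (none)
#' is added at the diagonal, \eqn{-\delta/2} at (animal, parent) and
#' \eqn{\delta/4} at each parent pair.
#'
#' @param ped pedigree data frame (see [check_pedigree()]).
#' @return a sparse symmetric matrix (`Matrix::dsCMatrix`) of order
#'   `nrow(ped)`.
#' @examples
#' trio <- data.frame(id = 1:3, sire = c(NA, NA, 1), dam = c(NA, NA, 2))
#' as.matrix(a_inverse(trio))
#' @export
a_inverse <- function(ped) {
  check_pedigree(ped)
  n <- nrow(ped)
  id <- seq_len(n)
  s <- ped$sire; d <- ped$dam
  ks <- !is.na(s); kd <- !is.na(d)
  delta <- ifelse(ks & kd, 2, ifelse(ks | kd, 4 / 3, 1))
  ii <- id; jj <- id; xx <- delta
  ## animal-parent blocks
  ii <- c(ii, id[ks], s[ks], id[kd], d[kd])
  jj <- c(jj, s[ks], id[ks], d[kd], id[kd])
  xx <- c(xx, rep(-delta[ks] / 2, 2), rep(-delta[kd] / 2, 2))
  ## parent-parent blocks
  ii <- c(ii, s[ks], d[kd], s[ks & kd], d[ks & kd])
  jj <- c(jj, s[ks], d[kd], d[ks & kd], s[ks & kd])
  xx <- c(xx, delta[ks] / 4, delta[kd] / 4, rep(delta[ks & kd] / 4, 2))
  Matrix::forceSymmetric(
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)))
}

## log determinant of A for the non-inbred pedigree: A = T D T' with T unit
## triangular, so log|A| = sum(log d_i), d_i = 1/2, 3/4 or 1 by the number
## of known parents.
.logdet_A <- function(ped) {
  ks <- !is.na(ped$sire); kd <- !is.na(ped$dam)
  d <- ifelse(ks & kd, 0.5, ifelse(ks | kd, 0.75, 1))
  sum(log(d))
}
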