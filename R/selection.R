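#' Selection index from estimated breeding values
#'
#' Weighted sum of the per-trait EBVs, by default 50% on each trait.
#'
#' @param ebv numeric matrix (n x 2) or vector of length 2.
#' @param weights index weights, summing to one.
#' @return numeric vector of index values.
#' @export
selection_index <- function(ebv, weights = c(0.5, 0.5)) {
  stopifnot(abs(sum(weights) - 1) < 1e-12)
  if (is.null(dim(ebv))) ebv <- matrix(ebv, ncol = 2)
  drop(ebv %*% weights)
}

#' Select breeders within paternal half-sib families
#'
#' Selects the next round of reproducers from the candidates of one
#' generation, applying fixed within-family quotas: per sire family the
#' single best male and the best `n_females` females (truncation on the
#' [selection_index()]), or a uniform draw when `ebv` is `NULL` (the
#' random-selection phase).  Ties in the index are broken by a random
#' draw from the current RNG stream.
#'
#' @param ped pedigree data frame with `sex`, `generation`, `candidate`.
#' @param generation the generation whose candidates are ranked.
#' @param ebv n x 2 matrix of EBVs for all pedigree animals, or `NULL`
#'   for random selection.
#' @param n_females number of females kept per sire family (one male is
#'   always kept per family).
#' @param weights index weights passed to [selection_index()].
#' @return list with integer vectors `sires` and `dams` (selected ids).
#' @export
select_breeders <- function(ped, generation, ebv = NULL, n_females = 17L,
                            weights = c(0.5, 0.5)) {
  cand <- which(ped$generation == generation & ped$candidate)
  if (!length(cand)) stop("no candidates in generation ", generation)
  fam <- ped$sire[cand]
  if (anyNA(fam)) stop("candidates must have a known sire family")
  score <- if (is.null(ebv)) stats::runif(length(cand))
           else selection_index(ebv[cand, , drop = FALSE], weights)
  tie <- stats::runif(length(cand))
  sires <- integer(0); dams <- integer(0)
  for (f in unique(fam)) {
    in_f <- fam == f
    for (sex in c("M", "F")) {
      k <- if (sex == "M") 1L else as.integer(n_females)
      rows <- which(in_f & ped$sex[cand] == sex)
      if (length(rows) < k)
        stop(sprintf("family %d has %d %s candidates, %d required",
                     f, length(rows), sex, k))
      keep <- rows[order(-score[rows], tie[rows])[seq_len(k)]]
      if (sex == "M") sires <- c(sires, cand[keep])
      else dams <- c(dams, cand[keep])
    }
  }
  list(sires = sires, dams = dams)
}

## Assign `length(dams)` dams to sires in equal blocks such that no
## sire-dam pair shares a known parent (no full- or half-sib matings).
## Randomised assignment with swap repairs; errors out if no conflict-free
## assignment is found.
.assign_mates <- function(sires, dams, ped, max_sweeps = 1000L) {
  ns <- length(sires); nd <- length(dams)
  stopifnot(nd %% ns == 0)
  per <- nd %/% ns
  shares <- function(s, d) {
    (!is.na(ped$sire[s]) & !is.na(ped$sire[d]) & ped$sire[s] == ped$sire[d]) |
    (!is.na(ped$dam[s]) & !is.na(ped$dam[d]) & ped$dam[s] == ped$dam[d])
  }
  ord <- sample(nd)
  sire_of <- rep(sires, each = per)        # slot -> sire
  dam_in <- dams[ord]                      # slot -> dam
  for (sweep in seq_len(max_sweeps)) {
    bad <- which(shares(sire_of, dam_in))
    if (!length(bad)) {
      return(data.frame(sire = sire_of, dam = dam_in))
    }
    for (b in bad) {
      others <- sample(nd)
      swapped <- FALSE
      for (o in others) {
        if (o == b) next
        if (!shares(sire_of[b], dam_in[o]) && !shares(sire_of[o], dam_in[b])) {
          tmp <- dam_in[b]; dam_in[b] <- dam_in[o]; dam_in[o] <- tmp
          swapped <- TRUE
          break
        }
      }
      if (!swapped) break
    }
  }
  stop("could not find a mating assignment avoiding sib matings")
}
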