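#' Read and write pedigree and phenotype tables
#'
#' Plain-CSV interchange for simulated or user data.  The pedigree CSV
#' has columns `id, sire, dam, sex, generation, candidate,
#' trait2_missing` (empty sire/dam = unknown); the phenotype CSV has
#' `id`, the trait columns (empty = missing) and the fixed-effect
#' factors.
#'
#' @param x data frame to write.
#' @param file path of the CSV file.
#' @return `read_pedigree()` and `read_phenotypes()` return data frames
#'   ready for [am_reml()]; the writers return `file` invisibly.
#' @name am_io
NULL

#' @rdname am_io
#' @export
write_pedigree <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' @rdname am_io
#' @export
read_pedigree <- function(file) {
  ped <- utils::read.csv(file, na.strings = "")
  ped$id <- as.integer(ped$id)
  ped$sire <- as.integer(ped$sire)
  ped$dam <- as.integer(ped$dam)
  if (!is.null(ped$candidate)) ped$candidate <- as.logical(ped$candidate)
  if (!is.null(ped$trait2_missing))
    ped$trait2_missing <- as.logical(ped$trait2_missing)
  check_pedigree(ped)
  ped
}

#' @rdname am_io
#' @export
write_phenotypes <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' @rdname am_io
#' @param factors columns to convert to factors (default: every
#'   non-trait, non-id column).
#' @param traits trait column names.
#' @export
read_phenotypes <- function(file, traits = c("y1", "y2"), factors = NULL) {
  phen <- utils::read.csv(file, na.strings = "")
  if (is.null(factors)) factors <- setdiff(names(phen), c("id", traits))
  for (nm in factors) phen[[nm]] <- factor(phen[[nm]])
  phen
}

#' Write study summary tables
#'
#' Writes the component bias/SE table, the genetic-gain table and the
#' relative gain differences of a [summarize_study()] result as
#' tab-separated files (`components.tsv`, `gains.tsv`,
#' `gain_rel_diff.tsv`) in a directory.
#'
#' @param summary result of [summarize_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_tables <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("components", "gains", "gain_rel_diff")) {
    utils::write.table(summary[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
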