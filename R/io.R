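#' Write a simulated dataset to disk
#'
#' Emits the on-disk formats consumed by the downstream stages:
#' `cells.tsv` (per-cell metrics with the nuclear bin states comma-joined
#' into a `bin_states` column), `counts.tsv` (long-format strand-split
#' allele counts), `truth_cells.tsv` / `truth_variants.tsv`,
#' `reference.fa` (single circular contig `chrM`) and `manifest.json`
#' listing files with row counts. Integer fields round-trip exactly;
#' floats are written at full precision.
#'
#' @param sim result of [simulateDataset()].
#' @param outDir output directory (created if absent).
#' @return the manifest, invisibly, as a named list.
#' @seealso [readDataset()]
#' @export
writeDataset <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cells <- sim$cells
  cells$bin_states <- if (nrow(cells)) {
    apply(sim$binStates, 1L, paste, collapse = ",")
  } else character()
  writeTsv(cells, file.path(outDir, "cells.tsv"))
  writeTsv(sim$counts, file.path(outDir, "counts.tsv"))
  writeTsv(sim$truth$cells, file.path(outDir, "truth_cells.tsv"))
  writeTsv(sim$truth$variants, file.path(outDir, "truth_variants.tsv"))
  ref <- Biostrings::DNAStringSet(sim$reference)
  names(ref) <- "chrM"
  Biostrings::writeXStringSet(ref, file.path(outDir, "reference.fa"))
  manifest <- list(
    files = list(
      cells = list(path = "cells.tsv", rows = nrow(cells)),
      counts = list(path = "counts.tsv", rows = nrow(sim$counts)),
      truth_cells = list(path = "truth_cells.tsv",
                         rows = nrow(sim$truth$cells)),
      truth_variants = list(path = "truth_variants.tsv",
                            rows = nrow(sim$truth$variants)),
      reference = list(path = "reference.fa",
                       length = length(sim$reference))),
    seed = sim$config@seed)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir directory containing `cells.tsv`, `counts.tsv`, truth tables
#'   and `reference.fa`.
#' @return a list shaped like the output of [simulateDataset()] (without
#'   the `config` element).
#' @export
readDataset <- function(dir) {
  cells <- readTsv(file.path(dir, "cells.tsv"))
  binStates <- if (nrow(cells)) {
    m <- do.call(rbind, lapply(strsplit(cells$bin_states, ","), as.integer))
    rownames(m) <- cells$cell_id
    m
  } else matrix(integer(), 0L, 0L)
  cells$bin_states <- NULL
  counts <- readTsv(file.path(dir, "counts.tsv"))
  truthCellsPath <- file.path(dir, "truth_cells.tsv")
  truth <- if (file.exists(truthCellsPath)) {
    list(cells = readTsv(truthCellsPath),
         variants = readTsv(file.path(dir, "truth_variants.tsv")))
  } else NULL
  refPath <- file.path(dir, "reference.fa")
  reference <- if (file.exists(refPath)) {
    Biostrings::readDNAStringSet(refPath)[[1L]]
  } else NULL
  list(cells = cells, binStates = binStates, counts = counts,
       reference = reference, truth = truth)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = NA, check.names = FALSE)
}
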