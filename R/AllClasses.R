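#' Simulation configuration for synthetic scWGS datasets
#'
#' Holds every knob of the synthetic-data generator. Defaults describe a
#' typical amplification-free scWGS experiment: a lymphoblastoid-like
#' population with roughly 750 mtDNA copies per diploid cell (MNR around
#' 378 at ploidy 2), a per-cell mtDNA copy-number coefficient of variation
#' of 0.65, whole-genome doubling in 13% of cells, about 500 cells per
#' library, and ~79 reads per mtDNA site per cell.
#'
#' @slot nLibraries number of sequencing libraries.
#' @slot cellsPerLibrary cells per library.
#' @slot nClones number of clones K.
#' @slot cloneFractions length-K simplex of clone prevalences.
#' @slot cloneMnr length-K expected mtDNA copies per haploid genome.
#' @slot wgdFraction per-clone probability of whole-genome doubling
#'   (recycled to length K).
#' @slot cnCV target per-cell coefficient of variation of true mtDNA copy
#'   number within a clone/ploidy stratum.
#' @slot nVariants number of heteroplasmic variant sites V.
#' @slot cloneHeteroplasmy K x V matrix of clone-level heteroplasmies.
#' @slot meanSiteCoverage expected reads per mtDNA site per cell for a cell
#'   of library-average copy number.
#' @slot nuDepthMean mean nuclear per-base depth.
#' @slot diameterSlope mtDNA copies per micron of cell diameter (0 disables
#'   diameters).
#' @slot genomeBins number of 500-kb-equivalent nuclear bins.
#' @slot blacklistInsertion plant a subset of variants inside the
#'   homopolymer blacklist regions (513-525, 3105-3109).
#' @slot nStrandArtifacts number of extra forward-strand-only artifact
#'   variants to inject (negative controls for the strand filters).
#' @slot seed integer RNG seed.
#'
#' @seealso [simConfig()], [simulateDataset()]
#' @export
setClass("SimConfig",
  representation(
    nLibraries = "integer", cellsPerLibrary = "integer",
    nClones = "integer", cloneFractions = "numeric", cloneMnr = "numeric",
    wgdFraction = "numeric", cnCV = "numeric", nVariants = "integer",
    cloneHeteroplasmy = "matrix", meanSiteCoverage = "numeric",
    nuDepthMean = "numeric", diameterSlope = "numeric",
    genomeBins = "integer", blacklistInsertion = "logical",
    nStrandArtifacts = "integer", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  chkCount <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 1L)
      msg <<- c(msg, sprintf("'%s' must be a count >= 1", nm))
  }
  chkCount(object@nLibraries, "nLibraries")
  chkCount(object@cellsPerLibrary, "cellsPerLibrary")
  chkCount(object@nClones, "nClones")
  chkCount(object@nVariants, "nVariants")
  chkCount(object@genomeBins, "genomeBins")
  K <- object@nClones
  if (length(object@cloneFractions) != K ||
      abs(sum(object@cloneFractions) - 1) > 1e-9 ||
      any(object@cloneFractions < 0))
    msg <- c(msg, "'cloneFractions' must be a length-K probability vector summing to 1 (tol 1e-9)")
  if (length(object@cloneMnr) != K || any(object@cloneMnr <= 0))
    msg <- c(msg, "'cloneMnr' must be K positive reals")
  if (any(object@wgdFraction < 0 | object@wgdFraction > 1))
    msg <- c(msg, "'wgdFraction' must be probabilities in [0,1]")
  if (length(object@cnCV) != 1L || object@cnCV < 0)
    msg <- c(msg, "'cnCV' must be a nonnegative real")
  ch <- object@cloneHeteroplasmy
  if (!is.numeric(ch) || nrow(ch) != K || ncol(ch) != object@nVariants ||
      any(ch < 0 | ch > 1))
    msg <- c(msg, "'cloneHeteroplasmy' must be a K x nVariants matrix in [0,1]")
  if (object@meanSiteCoverage <= 0)
    msg <- c(msg, "'meanSiteCoverage' must be positive")
  if (object@nuDepthMean <= 0)
    msg <- c(msg, "'nuDepthMean' must be positive")
  if (object@nStrandArtifacts < 0L)
    msg <- c(msg, "'nStrandArtifacts' must be a nonnegative count")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Fitted MityBayes clone model
#'
#' The result of [fitMityBayes()]: a K-clone binomial mixture over mtDNA
#' variant read counts. Alternate reads of variant v in cell c are modelled
#' as Binomial(total_cv, P_kv) given clone k, with clone fractions pi and
#' per-cell posterior assignment probabilities gamma.
#'
#' @slot K clone count.
#' @slot pi length-K clone-fraction simplex.
#' @slot P K x V clone-by-variant heteroplasmy matrix in (0,1).
#' @slot gamma cells x K posterior assignment probabilities (rows simplex).
#' @slot contribution per-variant informativeness weight in [0,1].
#' @slot elboTrace objective values per iteration of the selected restart.
#' @slot converged logical convergence flag.
#' @slot backend "em" or "gradient".
#' @slot seed master RNG seed used for restarts.
#' @slot alt,total the cells x V count matrices the model was fit to.
#'
#' @seealso [fitMityBayes()], [assignClones()], [variantContribution()]
#' @export
setClass("CloneModel",
  representation(
    K = "integer", pi = "numeric", P = "matrix", gamma = "matrix",
    contribution = "numeric", elboTrace = "numeric", converged = "logical",
    backend = "character", seed = "integer", alt = "matrix", total = "matrix"
  )
)

setValidity("CloneModel", function(object) {
  msg <- character()
  if (length(object@pi) != object@K || abs(sum(object@pi) - 1) > 1e-6)
    msg <- c(msg, "pi must be a length-K simplex (tol 1e-6)")
  if (nrow(object@gamma) > 0 &&
      max(abs(rowSums(object@gamma) - 1)) > 1e-6)
    msg <- c(msg, "gamma rows must sum to 1 (tol 1e-6)")
  if (nrow(object@P) != object@K)
    msg <- c(msg, "P must have K rows")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "CloneModel", function(object) {
  cat(sprintf(
    "CloneModel: K=%d clones, %d cells, %d variants [%s backend]\n",
    object@K, nrow(object@gamma), ncol(object@P), object@backend))
  cat("  pi:", paste(sprintf("%.3f", object@pi), collapse = " "), "\n")
  cat(sprintf("  objective: %.4f after %d iterations (%sconverged)\n",
              tail2(object@elboTrace), length(object@elboTrace),
              if (object@converged) "" else "NOT "))
})

tail2 <- function(x) if (length(x)) x[length(x)] else NA_real_

#' Stratified weighted concordance result
#'
#' Association between one variant's heteroplasmy and per-cell mtDNA copy
#' number, combined over library strata. `c` is the unscaled concordance in
#' [0,1]; `cScaled = 2c - 1` lives in [-1,1] like Kendall's tau or Somers'
#' D, with values near -1/1 indicating strong discordance/concordance;
#' `z = (c - 0.5)/sqrt(variance)` with a two-tailed normal p value.
#'
#' @slot c,cScaled,variance,z,p scalar statistics (NA when undefined).
#' @slot nObs,nStrata observation and contributing-stratum counts.
#' @slot perStratum per-stratum data.frame (stratum, n, pairs, c_s, weight).
#' @slot reason character; non-empty when the statistic is undefined.
#' @export
setClass("ConcordanceResult",
  representation(
    c = "numeric", cScaled = "numeric", variance = "numeric",
    z = "numeric", p = "numeric", nObs = "integer", nStrata = "integer",
    perStratum = "data.frame", reason = "character"
  )
)

setMethod("show", "ConcordanceResult", function(object) {
  if (nzchar(object@reason)) {
    cat("ConcordanceResult: undefined (", object@reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "ConcordanceResult: c=%.4f (scaled %.4f), z=%.3f, p=%.3g [%d obs, %d strata]\n",
      object@c, object@cScaled, object@z, object@p, object@nObs,
      object@nStrata))
  }
})
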