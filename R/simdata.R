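#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig-class]. Defaults emulate the statistical
#' structure of an amplification-free scWGS experiment on a near-diploid
#' population: one clone at MNR 378 (about 756 mtDNA copies per diploid
#' cell), a whole-genome-doubled subpopulation of 13%, a per-cell
#' copy-number coefficient of variation of 0.65, about 500 cells per
#' library, 79 reads per mtDNA site per cell and a cell-size coupling of
#' 24 mtDNA copies per micron.
#'
#' @param nLibraries,cellsPerLibrary library layout.
#' @param nClones,cloneFractions,cloneMnr clone structure; `cloneMnr` is
#'   expected mtDNA copies per haploid genome for each clone.
#' @param wgdFraction per-clone probability that a cell is whole-genome
#'   doubled (recycled to `nClones`).
#' @param cnCV target within-stratum coefficient of variation of true
#'   mtDNA copy number (lognormal dispersion, sigma = sqrt(log(1+CV^2))).
#' @param nVariants,cloneHeteroplasmy heteroplasmic variant sites and the
#'   K x V clone-level heteroplasmy matrix; by default a block pattern in
#'   which each clone carries its own subset of variants at 0.9 and the
#'   rest at 0.05 (0.5 everywhere when `nClones == 1`).
#' @param meanSiteCoverage expected reads per mtDNA site for a cell of
#'   library-average copy number.
#' @param nuDepthMean mean nuclear per-base depth.
#' @param diameterSlope mtDNA copies per micron (0 disables diameters).
#' @param genomeBins number of 500-kb-equivalent nuclear bins.
#' @param blacklistInsertion plant ~20% of variants inside the homopolymer
#'   blacklist regions.
#' @param nStrandArtifacts forward-only artifact variants to inject.
#' @param seed integer RNG seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nClones = 2, cloneFractions = c(0.6, 0.4),
#'                  cloneMnr = c(300, 450), cellsPerLibrary = 100)
#' @export
simConfig <- function(nLibraries = 2, cellsPerLibrary = 507,
                      nClones = 1, cloneFractions = rep(1 / nClones, nClones),
                      cloneMnr = rep(378, nClones), wgdFraction = 0.13,
                      cnCV = 0.65, nVariants = 10,
                      cloneHeteroplasmy = defaultCloneHeteroplasmy(nClones, nVariants),
                      meanSiteCoverage = 79, nuDepthMean = 0.1,
                      diameterSlope = 24, genomeBins = 500,
                      blacklistInsertion = FALSE, nStrandArtifacts = 0,
                      seed = 1L) {
  new("SimConfig",
    nLibraries = as.integer(nLibraries),
    cellsPerLibrary = as.integer(cellsPerLibrary),
    nClones = as.integer(nClones),
    cloneFractions = as.numeric(cloneFractions),
    cloneMnr = as.numeric(cloneMnr),
    wgdFraction = as.numeric(wgdFraction),
    cnCV = as.numeric(cnCV),
    nVariants = as.integer(nVariants),
    cloneHeteroplasmy = cloneHeteroplasmy,
    meanSiteCoverage = as.numeric(meanSiteCoverage),
    nuDepthMean = as.numeric(nuDepthMean),
    diameterSlope = as.numeric(diameterSlope),
    genomeBins = as.integer(genomeBins),
    blacklistInsertion = isTRUE(blacklistInsertion),
    nStrandArtifacts = as.integer(nStrandArtifacts),
    seed = as.integer(seed))
}

#' Default clone-by-variant heteroplasmy pattern
#'
#' Each clone carries its own block of variants at heteroplasmy 0.9,
#' all others at 0.05; a single clone gets 0.5 everywhere.
#' @param K,V clone and variant counts.
#' @return a K x V matrix in [0,1].
#' @export
defaultCloneHeteroplasmy <- function(K, V) {
  if (K == 1L) return(matrix(0.5, 1L, V))
  owner <- ((seq_len(V) - 1L) %% K) + 1L
  m <- matrix(0.05, K, V)
  m[cbind(owner, seq_len(V))] <- 0.9
  m
}

MT_GENOME_LENGTH <- 16569L

#' Simulate a synthetic single-cell mtDNA/nuDNA dataset
#'
#' Generates, deterministically for a given seed, per-cell metrics and
#' per-(cell, variant) strand-split allele counts with the structure the
#' downstream analysis assumes:
#' \itemize{
#'   \item each clone has a diploid baseline nuclear bin-state profile
#'     (clones beyond the first differ in ~30% of bins by one state);
#'     whole-genome-doubled cells carry the exactly doubled profile;
#'   \item true mtDNA copy number = clone MNR x average ploidy x lognormal
#'     noise with sigma = sqrt(log(1 + cnCV^2)) (mean 1), so WGD doubles
#'     copy number but leaves the MNR distribution unchanged;
#'   \item mtDNA and nuclear depths are consistent with the copy-number
#'     identity mnr = mt_depth / nu_depth;
#'   \item per-variant total reads ~ Poisson(meanSiteCoverage x CN /
#'     library mean CN), alternate reads ~ Binomial(total, clone
#'     heteroplasmy), strands split ~ Binomial(., 0.5);
#'   \item diameter = 10 + CN / diameterSlope + N(0, 1) microns.
#' }
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return a list with elements `cells` (data.frame: cell_id, library_id,
#'   sample_id, quality, mt_depth, nu_depth, diameter_um), `binStates`
#'   (cells x bins integer matrix), `counts` (long data.frame: cell_id,
#'   position, ref, alt, fwd_alt, rev_alt, fwd_total, rev_total; rows with
#'   zero total depth omitted), `reference` (circular mtDNA
#'   [Biostrings::DNAString]), `truth` (list of `cells`, `variants`,
#'   `cloneHeteroplasmy`) and `config`.
#' @examples
#' sim <- simulateDataset(simConfig(cellsPerLibrary = 30, nVariants = 4))
#' head(sim$cells)
#' @export
simulateDataset <- function(config) {
  if (!is(config, "SimConfig"))
    stop("'config' must be a SimConfig object")
  validObject(config)
  set.seed(config@seed)
  K <- config@nClones
  V <- config@nVariants
  L <- config@nLibraries
  nCells <- L * config@cellsPerLibrary

  libraryId <- rep(sprintf("LIB%02d", seq_len(L)),
                   each = config@cellsPerLibrary)
  cellId <- sprintf("cell_%05d", seq_len(nCells))
  clone <- sample.int(K, nCells, replace = TRUE,
                      prob = config@cloneFractions)
  wgdFrac <- rep_len(config@wgdFraction, K)
  isTetra <- rbinom(nCells, 1L, wgdFrac[clone]) == 1L

  # clone baseline diploid bin-state profiles; WGD = exact doubling.
  # With several clones, every clone (including the first) carries its own
  # set of altered bins so that profiles are non-constant and
  # clone-distinct; a single clone keeps the flat diploid baseline.
  B <- config@genomeBins
  baseline <- matrix(2L, K, B)
  if (K > 1L) {
    for (k in seq_len(K)) {
      nAlt <- max(1L, round(0.3 * B))
      idx <- sample.int(B, nAlt)
      baseline[k, idx] <- pmax(1L, baseline[k, idx] +
                                 sample(c(-1L, 1L), nAlt, replace = TRUE))
    }
  }
  binStates <- baseline[clone, , drop = FALSE]
  binStates[isTetra, ] <- 2L * binStates[isTetra, , drop = FALSE]
  storage.mode(binStates) <- "integer"
  rownames(binStates) <- cellId
  avgPloidy <- rowMeans(binStates)

  # true mtDNA copy number, lognormal dispersion calibrated to cnCV
  sigma <- sqrt(log(1 + config@cnCV^2))
  cnNoise <- if (sigma > 0) rlnorm(nCells, -sigma^2 / 2, sigma) else rep(1, nCells)
  cnTrue <- config@cloneMnr[clone] * avgPloidy * cnNoise
  mnrTrue <- cnTrue / avgPloidy

  nuDepth <- config@nuDepthMean * rlnorm(nCells, -0.02, 0.2)
  mtDepth <- mnrTrue * nuDepth

  diameter <- if (config@diameterSlope > 0) {
    10 + cnTrue / config@diameterSlope + rnorm(nCells, 0, 1)
  } else rep(NA_real_, nCells)
  quality <- round(rbeta(nCells, 14, 2), 3)

  # variant sites on the circular mtDNA reference
  reference <- Biostrings::DNAString(paste(
    sample(c("A", "C", "G", "T"), MT_GENOME_LENGTH, replace = TRUE,
           prob = c(0.31, 0.31, 0.13, 0.25)), collapse = ""))
  blRegions <- defaultBlacklist()
  blPositions <- unlist(lapply(seq_len(nrow(blRegions)), function(i)
    seq(blRegions$start[i], blRegions$end[i])))
  nBlack <- if (config@blacklistInsertion) max(1L, ceiling(0.2 * V)) else 0L
  cleanPool <- setdiff(seq_len(MT_GENOME_LENGTH), blPositions)
  cleanDraw <- sample(cleanPool, (V - nBlack) + config@nStrandArtifacts)
  positions <- c(
    sort(c(if (nBlack > 0L) sample(blPositions, nBlack) else integer(),
           cleanDraw[seq_len(V - nBlack)])),          # genuine, sorted
    sort(cleanDraw[seq_len(config@nStrandArtifacts) + (V - nBlack)]))
  nTot <- V + config@nStrandArtifacts
  isArtifact <- rep(c(FALSE, TRUE), c(V, config@nStrandArtifacts))
  refAllele <- vapply(positions, function(p)
    as.character(Biostrings::subseq(reference, p, p)), "")
  altAllele <- vapply(refAllele, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "",
    USE.NAMES = FALSE)
  variants <- data.frame(
    variant = seq_len(nTot), position = positions,
    ref = refAllele, alt = altAllele,
    class = sample(c("truncating", "silent", "missense", "noncoding"),
                   nTot, replace = TRUE, prob = c(0.2, 0.2, 0.3, 0.3)),
    in_blacklist = positions %in% blPositions,
    artifact = isArtifact, stringsAsFactors = FALSE)

  # strand-split read counts; genuine variant j uses heteroplasmy column j
  hMat <- config@cloneHeteroplasmy[clone, , drop = FALSE]
  libMeanCn <- stats::ave(cnTrue, libraryId)
  covScale <- config@meanSiteCoverage * cnTrue / libMeanCn
  countsList <- vector("list", nTot)
  for (j in seq_len(nTot)) {
    total <- rpois(nCells, covScale)
    if (variants$artifact[j]) {
      alt <- rbinom(nCells, total, 0.3)
      fwdAlt <- alt
      fwdTotal <- total       # all reads forward: strand-exclusive evidence
    } else {
      alt <- rbinom(nCells, total, hMat[, j])
      fwdAlt <- rbinom(nCells, alt, 0.5)
      fwdTotal <- fwdAlt + rbinom(nCells, total - alt, 0.5)
    }
    keep <- total > 0L
    countsList[[j]] <- data.frame(
      cell_id = cellId[keep], position = variants$position[j],
      ref = variants$ref[j], alt = variants$alt[j],
      fwd_alt = fwdAlt[keep], rev_alt = (alt - fwdAlt)[keep],
      fwd_total = fwdTotal[keep], rev_total = (total - fwdTotal)[keep],
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, countsList)
  counts <- counts[order(counts$position, counts$cell_id), , drop = FALSE]
  rownames(counts) <- NULL

  cells <- data.frame(
    cell_id = cellId, library_id = libraryId, sample_id = "SIM01",
    quality = quality, mt_depth = mtDepth, nu_depth = nuDepth,
    diameter_um = diameter, stringsAsFactors = FALSE)

  truthCells <- data.frame(
    cell_id = cellId, library_id = libraryId, clone = clone,
    ploidy_label = ifelse(isTetra, "tetraploid", "diploid"),
    cn_true = cnTrue, mnr_true = mnrTrue, stringsAsFactors = FALSE)

  list(cells = cells, binStates = binStates, counts = counts,
       reference = reference,
       truth = list(cells = truthCells, variants = variants,
                    cloneHeteroplasmy = config@cloneHeteroplasmy),
       config = config)
}
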