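#' Quality gate on per-cell quality scores
#'
#' Keeps live, well-sequenced cells: quality score >= `minQuality`
#' (boundary inclusive).
#'
#' @param cells data.frame with a `quality` column in [0,1].
#' @param minQuality minimum quality score (default 0.75).
#' @return list(cells = kept data.frame, nKept, nDropped).
#' @export
qualityGate <- function(cells, minQuality = 0.75) {
  if (nrow(cells) && any(cells$quality < 0 | cells$quality > 1))
    stop("quality scores must be in [0,1]")
  keep <- cells$quality >= minQuality
  list(cells = cells[keep, , drop = FALSE],
       nKept = sum(keep), nDropped = sum(!keep))
}

#' Average and baseline nuclear ploidy from bin states
#'
#' Average ploidy is the arithmetic mean of the per-bin integer
#' copy-number states; baseline ploidy is the modal state (ties broken
#' toward the smallest tied state, conservative against over-calling
#' whole-genome doubling). The baseline maps to a label: 2 = diploid,
#' 3 = triploid, 4 = tetraploid, anything else = other.
#'
#' @param binStates integer vector for one cell, or a cells x bins matrix.
#' @return for a vector: data.frame(average_ploidy, baseline_ploidy,
#'   wgd_label); for a matrix: one row per cell (cell ids from rownames).
#' @examples
#' ploidySummary(c(2L, 2L, 2L, 4L))   # average 2.5, baseline 2, diploid
#' @export
ploidySummary <- function(binStates) {
  if (is.matrix(binStates)) {
    if (ncol(binStates) == 0L) stop("bin states must be nonempty")
    out <- data.frame(
      average_ploidy = rowMeans(binStates),
      baseline_ploidy = apply(binStates, 1L, modalState))
    out$wgd_label <- ploidyLabel(out$baseline_ploidy)
    if (!is.null(rownames(binStates)))
      out <- cbind(cell_id = rownames(binStates), out,
                   stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  if (!length(binStates)) stop("bin states must be nonempty")
  baseline <- modalState(binStates)
  data.frame(average_ploidy = mean(binStates),
             baseline_ploidy = baseline,
             wgd_label = ploidyLabel(baseline))
}

ploidyLabel <- function(baseline) {
  lab <- rep("other", length(baseline))
  lab[baseline == 2L] <- "diploid"
  lab[baseline == 3L] <- "triploid"
  lab[baseline == 4L] <- "tetraploid"
  lab
}

#' Per-cell mtDNA copy number and MNR
#'
#' mtDNA copy number = (mtDNA depth / nuDNA depth) x average ploidy;
#' the mtDNA-to-nuDNA ratio (MNR, copies per average haploid genome) is
#' the depth ratio itself. Depths are mean per-base coverages, making the
#' ratio independent of read length. Cells with nonpositive nuclear depth
#' get NA and are flagged.
#'
#' @param mtDepth,nuDepth mean per-base mtDNA and nuDNA read depths.
#' @param averagePloidy average nuclear ploidy (from [ploidySummary()]).
#' @return data.frame(mnr, cn, flagged).
#' @examples
#' mitoCopyNumber(50, 0.1, 2)   # mnr 500, cn 1000
#' @export
mitoCopyNumber <- function(mtDepth, nuDepth, averagePloidy) {
  bad <- !(nuDepth > 0) | !(averagePloidy > 0)
  mnr <- ifelse(bad, NA_real_, mtDepth / nuDepth)
  data.frame(mnr = mnr, cn = mnr * averagePloidy, flagged = bad)
}

#' Percent change in MNR from diploid to tetraploid cells
#'
#' 100 x (median(tetraploid MNR) - median(diploid MNR)) / median(diploid
#' MNR). Under mtDNA/nuDNA dosage homeostasis this is near zero: doubling
#' the nuclear genome doubles the mtDNA copy number but leaves the ratio
#' unchanged.
#'
#' @param mnrDiploid,mnrTetraploid MNR values of the two ploidy groups.
#' @return percent change (scalar); NA with a warning when the diploid
#'   median is zero.
#' @examples
#' mnrPercentChange(c(1, 2, 3), c(2, 4, 6))   # +100
#' @export
mnrPercentChange <- function(mnrDiploid, mnrTetraploid) {
  if (!length(mnrDiploid) || !length(mnrTetraploid))
    stop("both ploidy groups must be nonempty")
  md <- median(mnrDiploid)
  if (md == 0) {
    warning("diploid median MNR is zero; percent change undefined")
    return(NA_real_)
  }
  100 * (median(mnrTetraploid) - md) / md
}

#' Diploid-versus-tetraploid copy-number and MNR contrasts
#'
#' For each sample (or library), compares diploid and tetraploid cells:
#' median CN and MNR per group, log2 CN fold change, percent MNR change,
#' and Wilcoxon rank-sum tests (two-sided for CN, one-sided
#' tetraploid > diploid for MNR by default, following the usual
#' homeostasis question). Groups with fewer than `minGroup` cells in
#' either ploidy class are skipped with a reason.
#'
#' @param cells data.frame with columns `cn`, `mnr`, `wgd_label` and the
#'   grouping column.
#' @param groupBy grouping column name (default "sample_id"; use
#'   "library_id" to stratify by library).
#' @param minGroup minimum cells per ploidy class (default 20).
#' @param cnAlternative,mnrAlternative `wilcox.test` alternatives for the
#'   CN and MNR contrasts ("two.sided" and "greater" by default, the MNR
#'   alternative being tetraploid > diploid).
#' @return data.frame with one row per group.
#' @export
ploidyContrast <- function(cells, groupBy = "sample_id", minGroup = 20L,
                           cnAlternative = "two.sided",
                           mnrAlternative = "greater") {
  groups <- split(cells, cells[[groupBy]])
  rows <- lapply(names(groups), function(g) {
    cc <- groups[[g]]
    dip <- cc[cc$wgd_label == "diploid", , drop = FALSE]
    tet <- cc[cc$wgd_label == "tetraploid", , drop = FALSE]
    base <- data.frame(group = g, n_diploid = nrow(dip),
                       n_tetraploid = nrow(tet), stringsAsFactors = FALSE)
    if (nrow(dip) < minGroup || nrow(tet) < minGroup) {
      return(cbind(base, median_cn_diploid = NA_real_,
                   median_cn_tetraploid = NA_real_,
                   cn_log2_fc = NA_real_, mnr_pct_change = NA_real_,
                   p_cn = NA_real_, p_mnr = NA_real_,
                   skipped = "insufficient_cells"))
    }
    pCn <- suppressWarnings(
      wilcox.test(tet$cn, dip$cn, alternative = cnAlternative))$p.value
    pMnr <- suppressWarnings(
      wilcox.test(tet$mnr, dip$mnr, alternative = mnrAlternative))$p.value
    cbind(base,
          median_cn_diploid = median(dip$cn),
          median_cn_tetraploid = median(tet$cn),
          cn_log2_fc = log2(median(tet$cn) / median(dip$cn)),
          mnr_pct_change = mnrPercentChange(dip$mnr, tet$mnr),
          p_cn = pCn, p_mnr = pMnr, skipped = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binomial thinning of counts or depths
#'
#' Models in silico downsampling of sequencing depth: integer counts are
#' thinned as Binomial(n, f); non-integer depths are scaled by f.
#'
#' @param x nonnegative counts or depths.
#' @param f retained fraction in [0,1].
#' @param seed optional integer seed (thinning is deterministic given it).
#' @return thinned vector of the same length.
#' @export
downsampleCounts <- function(x, f, seed = NULL) {
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("'f' must be a single value in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  if (all(x == round(x))) {
    out <- rbinom(length(x), as.integer(round(x)), f)
    if (f == 1) out <- as.integer(round(x))   # identity, no sampling noise
    out
  } else {
    x * f
  }
}

#' Stability of estimates under downsampling
#'
#' Compares per-cell estimates (typically mtDNA copy number) from full
#' and thinned data: Pearson r, median relative error, and optionally the
#' fraction of PASS variants retained after thinning.
#'
#' @param full,thinned paired per-cell estimates.
#' @param fullPass,thinnedPass optional PASS variant identifier vectors
#'   before/after thinning.
#' @return list(r, medianRelError, passRetained, flagged); `r` is NA and
#'   `flagged` TRUE when fewer than 3 pairs or either vector is constant.
#' @export
stabilityReport <- function(full, thinned, fullPass = NULL,
                            thinnedPass = NULL) {
  stopifnot(length(full) == length(thinned))
  ok <- is.finite(full) & is.finite(thinned)
  r <- NA_real_
  flagged <- FALSE
  if (sum(ok) < 3L || sd(full[ok]) == 0 || sd(thinned[ok]) == 0) {
    flagged <- TRUE
  } else {
    r <- cor(full[ok], thinned[ok])
  }
  relErr <- abs(thinned[ok] - full[ok]) / ifelse(full[ok] != 0,
                                                 abs(full[ok]), NA)
  passRetained <- if (!is.null(fullPass)) {
    if (length(fullPass)) length(intersect(fullPass, thinnedPass)) /
      length(fullPass) else NA_real_
  } else NA_real_
  list(r = r, medianRelError = median(relErr, na.rm = TRUE),
       passRetained = passRetained, flagged = flagged)
}
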