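#' Pipeline parameter set
#'
#' All stage parameters with their standard defaults: quality gate 0.75,
#' pooled strand support 2+2, strand concordance R >= 0.2 over >= 3
#' informative cells, homopolymer blacklist 513-525/3105-3109, MityBayes
#' learning rate 0.1 and relative ELBO tolerance 1e-5, concordance
#' filters (>= 10 alternate reads, heteroplasmy window (0.05, 0.95),
#' range >= 0.15).
#'
#' @param minQuality,minStrandReads,minR,minCells,minAlt,hetLo,hetHi,minRange
#'   filter thresholds (see the stage functions).
#' @param K clone count for MityBayes; NULL = choose via [selectK()] over
#'   `Kgrid`.
#' @param Kgrid candidate K values when `K` is NULL.
#' @param lr,relTol,nRestarts MityBayes optimizer settings.
#' @param minProb minimum assignment probability for clone labels.
#' @param groupBy grouping for the diploid/tetraploid contrast.
#' @return named list of parameters.
#' @export
pipelineParams <- function(minQuality = 0.75, minStrandReads = 2L,
                           minR = 0.2, minCells = 3L, minAlt = 10L,
                           hetLo = 0.05, hetHi = 0.95, minRange = 0.15,
                           K = NULL, Kgrid = 1:4, lr = 0.1, relTol = 1e-5,
                           nRestarts = 4L, minProb = 0.9,
                           groupBy = "sample_id") {
  p <- list(minQuality = minQuality, minStrandReads = minStrandReads,
            minR = minR, minCells = minCells, minAlt = minAlt,
            hetLo = hetLo, hetHi = hetHi, minRange = minRange, K = K,
            Kgrid = Kgrid, lr = lr, relTol = relTol,
            nRestarts = nRestarts, minProb = minProb, groupBy = groupBy)
  if (p$minQuality < 0 || p$minQuality > 1)
    stop("'minQuality' must be in [0,1]")
  if (p$hetLo < 0 || p$hetHi > 1 || p$hetLo >= p$hetHi)
    stop("heteroplasmy window must satisfy 0 <= hetLo < hetHi <= 1")
  if (p$minR < -1 || p$minR > 1) stop("'minR' must be in [-1,1]")
  p
}

#' Run the full synthetic-to-association pipeline
#'
#' Orchestrates simulate -> quality gate -> variant filtering and
#' genotyping -> per-cell copy number -> MityBayes clonal inference ->
#' nuclear-profile clustering and cross-check -> concordance and
#' cell-size association, writing every stage's table under `outDir`
#' together with `report.md`. All randomness flows from the
#' configuration's master seed via named substreams, so a rerun with the
#' same configuration reproduces every output byte for byte.
#'
#' @param config a [SimConfig-class]; the dataset is simulated from it.
#'   (To analyze data on disk, read it with [readDataset()] and call the
#'   stage functions directly.)
#' @param outDir output directory.
#' @param params stage parameters from [pipelineParams()].
#' @return invisibly, a list with the stage results and a `summary` list
#'   of headline numbers (also written to `report.md`).
#' @export
runPipeline <- function(config, outDir, params = pipelineParams()) {
  stopifnot(is(config, "SimConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulateDataset(config)
  writeDataset(sim, file.path(outDir, "data"))

  qg <- qualityGate(sim$cells, params$minQuality)
  cells <- qg$cells

  vt <- filterVariants(sim$counts, cellIds = cells$cell_id,
                       minStrandReads = params$minStrandReads,
                       minR = params$minR, minCells = params$minCells)
  writeTsv(vt, file.path(outDir, "variants.tsv"))
  writeVariantsVcf(vt, file.path(outDir, "variants.vcf"))
  passVt <- vt[vt$filter == "PASS", , drop = FALSE]
  se <- genotypeCells(sim$counts, variants = passVt,
                      cellIds = cells$cell_id)
  hetOut <- as.data.frame(t(SummarizedExperiment::assay(se, "heteroplasmy")))
  hetOut <- cbind(cell_id = rownames(hetOut), hetOut)
  writeTsv(hetOut, file.path(outDir, "heteroplasmy.tsv"))
  depthOut <- as.data.frame(t(SummarizedExperiment::assay(se, "depth")))
  depthOut <- cbind(cell_id = rownames(depthOut), depthOut)
  writeTsv(depthOut, file.path(outDir, "depth.tsv"))

  ps <- ploidySummary(sim$binStates[cells$cell_id, , drop = FALSE])
  mcn <- mitoCopyNumber(cells$mt_depth, cells$nu_depth, ps$average_ploidy)
  perCell <- data.frame(
    cell_id = cells$cell_id, library_id = cells$library_id,
    sample_id = cells$sample_id,
    average_ploidy = signif(ps$average_ploidy, 6),
    baseline_ploidy = ps$baseline_ploidy, wgd_label = ps$wgd_label,
    mnr = signif(mcn$mnr, 6), cn = signif(mcn$cn, 6),
    stringsAsFactors = FALSE)
  writeTsv(perCell, file.path(outDir, "percell_cn.tsv"))
  contrast <- ploidyContrast(
    cbind(perCell, diameter_um = cells$diameter_um),
    groupBy = params$groupBy)
  writeTsv(contrast, file.path(outDir, "ploidy_contrast.tsv"))

  # MityBayes on the PASS variants
  altM <- t(SummarizedExperiment::assay(se, "alt"))
  totalM <- t(SummarizedExperiment::assay(se, "depth"))
  model <- NULL
  clones <- NULL
  if (ncol(altM) >= 1L && nrow(altM) >= 2L) {
    mbSeed <- deriveSeed(config@seed, "pipeline-mitybayes")
    K <- params$K
    if (is.null(K))
      K <- selectK(altM, totalM, Kgrid = params$Kgrid,
                   nRestarts = params$nRestarts, seed = mbSeed)$K
    model <- fitMityBayes(altM, totalM, K, lr = params$lr,
                          relTol = params$relTol,
                          nRestarts = params$nRestarts, seed = mbSeed)
    labels <- assignClones(model, params$minProb)
    clones <- data.frame(
      cell_id = rownames(altM), clone = labels,
      max_prob = signif(apply(model@gamma, 1L, max), 6),
      stringsAsFactors = FALSE)
    writeTsv(clones, file.path(outDir, "clones.tsv"))
    jsonlite::write_json(
      list(K = model@K, pi = model@pi, P = model@P,
           contribution = model@contribution,
           elbo_trace = model@elboTrace, converged = model@converged,
           seed = model@seed),
      file.path(outDir, "model.json"), auto_unbox = TRUE, digits = NA)
  }

  nuClones <- clusterCellsNu(
    sim$binStates[cells$cell_id, , drop = FALSE],
    seed = deriveSeed(config@seed, "pipeline-nuclones"))
  writeTsv(nuClones, file.path(outDir, "nuclones.tsv"))
  cross <- if (!is.null(clones)) {
    assigned <- clones[clones$clone != "unassigned", , drop = FALSE]
    if (nrow(assigned)) crosscheckClones(nuClones, assigned) else NULL
  } else NULL

  filt <- concordanceFilters(se, minAlt = params$minAlt,
                             lo = params$hetLo, hi = params$hetHi,
                             minRange = params$minRange)
  assocTab <- NULL
  if (nrow(filt)) {
    obs <- merge(filt, perCell[, c("cell_id", "library_id", "cn")],
                 by = "cell_id")
    libSize <- table(perCell$library_id)
    obs$stratum <- obs$library_id
    obs$weight <- as.numeric(libSize[obs$library_id])
    obs$y <- obs$cn
    obs <- obs[order(obs$variant, obs$cell_id), , drop = FALSE]
    assocTab <- concordanceTable(obs)
    writeTsv(assocTab, file.path(outDir, "assoc.tsv"))
  }
  sizeTab <- sizeRegression(cbind(perCell,
                                  diameter_um = cells$diameter_um))
  writeTsv(sizeTab, file.path(outDir, "regression.tsv"))

  summary <- list(
    n_cells = nrow(sim$cells), n_cells_pass_quality = qg$nKept,
    n_variants = nrow(vt), n_variants_pass = nrow(passVt),
    median_cn = median(perCell$cn), median_mnr = median(perCell$mnr),
    wgd_fraction = mean(perCell$wgd_label == "tetraploid"),
    K = if (!is.null(model)) model@K else NA_integer_,
    crosscheck_ari = if (!is.null(cross)) cross$ari else NA_real_,
    n_assoc_variants = if (!is.null(assocTab)) nrow(assocTab) else 0L)
  writeReport(summary, contrast, file.path(outDir, "report.md"))

  invisible(list(sim = sim, cells = cells, variants = vt, genotypes = se,
                 perCell = perCell, contrast = contrast, model = model,
                 clones = clones, nuClones = nuClones, crosscheck = cross,
                 assoc = assocTab, sizeRegression = sizeTab,
                 summary = summary))
}

writeReport <- function(summary, contrast, path) {
  lines <- c(
    "# Pipeline report", "",
    sprintf("- cells simulated: %d (quality-passing: %d)",
            summary$n_cells, summary$n_cells_pass_quality),
    sprintf("- variants called: %d (PASS: %d)", summary$n_variants,
            summary$n_variants_pass),
    sprintf("- median mtDNA copy number: %.1f (median MNR %.1f)",
            summary$median_cn, summary$median_mnr),
    sprintf("- WGD fraction: %.3f", summary$wgd_fraction),
    sprintf("- MityBayes clones: %s", summary$K),
    sprintf("- nuclear/mtDNA clone agreement (ARI): %s",
            ifelse(is.na(summary$crosscheck_ari), "NA",
                   sprintf("%.3f", summary$crosscheck_ari))),
    sprintf("- variants entering the concordance analysis: %d",
            summary$n_assoc_variants),
    "", "## Diploid vs tetraploid contrast", "")
  for (i in seq_len(nrow(contrast))) {
    r <- contrast[i, ]
    lines <- c(lines, sprintf(
      "- %s: n=%d/%d, CN log2 FC %s, MNR change %s%%, p(CN) %s, p(MNR) %s %s",
      r$group, r$n_diploid, r$n_tetraploid,
      fmtOrNa(r$cn_log2_fc), fmtOrNa(r$mnr_pct_change),
      fmtOrNa(r$p_cn, "%.2g"), fmtOrNa(r$p_mnr, "%.2g"),
      if (nzchar(r$skipped)) paste0("[", r$skipped, "]") else ""))
  }
  writeLines(lines, path)
}

fmtOrNa <- function(x, fmt = "%.3f") if (is.na(x)) "NA" else sprintf(fmt, x)
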