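#' Homopolymer blacklist regions of the mitochondrial genome
#'
#' The homopolymer repeat regions 513-525 and 3105-3109 (1-based,
#' inclusive at both ends) on the circular mtDNA contig, which are
#' excluded from variant calling.
#'
#' @return data.frame with columns `start`, `end`.
#' @export
defaultBlacklist <- function() {
  data.frame(start = c(513L, 3105L), end = c(525L, 3109L))
}

#' Pooled strand-support filter
#'
#' A variant passes when the pseudo-bulk (pooled over all quality-passing
#' cells) alternate counts have at least `minReads` supporting reads on
#' the forward AND the reverse strand. Strand-exclusive evidence fails.
#'
#' @param fwdAlt,revAlt pooled alternate read counts per strand
#'   (vectorized over variants).
#' @param minReads minimum per-strand alternate reads (default 2).
#' @return logical vector, TRUE = pass.
#' @examples
#' strandSupportFilter(c(2, 3, 0), c(2, 1, 10))  # TRUE FALSE FALSE
#' @export
strandSupportFilter <- function(fwdAlt, revAlt, minReads = 2L) {
  if (any(fwdAlt < 0 | revAlt < 0, na.rm = TRUE))
    stop("negative read counts are invalid")
  fwdAlt >= minReads & revAlt >= minReads
}

#' Per-cell strand-concordance filter
#'
#' False positive calls tend to show disagreeing heteroplasmy between the
#' two strands. For one variant, per-cell forward heteroplasmy
#' (fwd_alt/fwd_total) and reverse heteroplasmy (rev_alt/rev_total) are
#' computed over informative cells (both strand totals > 0) and their
#' Pearson correlation must reach `minR` over at least `minCells` cells.
#' An undefined correlation (zero variance on either strand, or too few
#' informative cells) fails conservatively with a reason code.
#'
#' @param counts data.frame with columns fwd_alt, rev_alt, fwd_total,
#'   rev_total (one row per cell for one variant).
#' @param minR minimum Pearson correlation (default 0.2).
#' @param minCells minimum informative cells (default 3).
#' @return list(pass, r, nInformative, reason).
#' @export
strandConcordanceFilter <- function(counts, minR = 0.2, minCells = 3L) {
  inf <- counts$fwd_total > 0 & counts$rev_total > 0
  n <- sum(inf)
  if (n == 0L)
    return(list(pass = FALSE, r = NA_real_, nInformative = 0L,
                reason = "no_informative_cells"))
  fh <- counts$fwd_alt[inf] / counts$fwd_total[inf]
  rh <- counts$rev_alt[inf] / counts$rev_total[inf]
  if (n < minCells)
    return(list(pass = FALSE, r = NA_real_, nInformative = n,
                reason = "too_few_informative_cells"))
  if (sd(fh) == 0 || sd(rh) == 0)
    return(list(pass = FALSE, r = NA_real_, nInformative = n,
                reason = "zero_variance"))
  r <- cor(fh, rh)
  list(pass = isTRUE(r >= minR), r = r, nInformative = n,
       reason = if (isTRUE(r >= minR)) "" else "low_strand_correlation")
}

#' Blacklist position filter
#'
#' @param position 1-based position(s) on the circular mtDNA contig.
#' @param refLength reference length (default 16,569, the human mtDNA).
#' @param regions data.frame of inclusive blacklist ranges
#'   (default [defaultBlacklist()]).
#' @return logical vector, TRUE = pass (outside every blacklist region).
#' @examples
#' blacklistFilter(c(512, 513, 525, 526, 3105, 3109, 3110))
#' @export
blacklistFilter <- function(position, refLength = MT_GENOME_LENGTH,
                            regions = defaultBlacklist()) {
  if (any(position < 1L | position > refLength))
    stop("position outside the reference coordinates [1, ", refLength, "]")
  inBl <- rep(FALSE, length(position))
  for (i in seq_len(nrow(regions)))
    inBl <- inBl | (position >= regions$start[i] & position <= regions$end[i])
  !inBl
}

#' Apply the full mtDNA variant filter stack
#'
#' Pools strand counts over quality-passing cells and applies, in an
#' order-invariant fashion, the three filters: pooled strand support
#' (>= 2 alternate reads on each strand), per-cell strand concordance
#' (Pearson R >= 0.2 over >= `minCells` informative cells) and the
#' homopolymer blacklist. A variant is PASS iff it passes all three.
#'
#' @param counts long-format strand-split allele counts (as produced by
#'   [simulateDataset()]: cell_id, position, ref, alt, fwd_alt, rev_alt,
#'   fwd_total, rev_total).
#' @param cellIds optional character vector restricting which cells
#'   contribute (e.g. the quality-gated set); default all cells present.
#' @param minStrandReads,minR,minCells,refLength,regions filter
#'   parameters, see the individual filters.
#' @return data.frame, one row per variant: position, ref, alt, n_cells,
#'   pooled_het, strand_r, strand_support, strand_concordance, blacklist
#'   (logicals), filter (character: "PASS" or semicolon-joined failing
#'   filter names).
#' @export
filterVariants <- function(counts, cellIds = NULL, minStrandReads = 2L,
                           minR = 0.2, minCells = 3L,
                           refLength = MT_GENOME_LENGTH,
                           regions = defaultBlacklist()) {
  if (!is.null(cellIds))
    counts <- counts[counts$cell_id %in% cellIds, , drop = FALSE]
  key <- paste(counts$position, counts$ref, counts$alt, sep = ":")
  split_ <- split(counts, key)
  rows <- lapply(split_, function(cc) {
    fwdAltSum <- sum(cc$fwd_alt)
    revAltSum <- sum(cc$rev_alt)
    totalSum <- sum(cc$fwd_total) + sum(cc$rev_total)
    sc <- strandConcordanceFilter(cc, minR = minR, minCells = minCells)
    data.frame(
      position = cc$position[1L], ref = cc$ref[1L], alt = cc$alt[1L],
      n_cells = nrow(cc),
      pooled_het = if (totalSum > 0) (fwdAltSum + revAltSum) / totalSum
                   else NA_real_,
      strand_r = sc$r,
      strand_support = strandSupportFilter(fwdAltSum, revAltSum,
                                           minStrandReads),
      strand_concordance = sc$pass,
      blacklist = blacklistFilter(cc$position[1L], refLength, regions),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  failNames <- c("strand_support", "strand_concordance", "blacklist")
  out$filter <- vapply(seq_len(nrow(out)), function(i) {
    fails <- failNames[!unlist(out[i, failNames])]
    if (length(fails)) paste(fails, collapse = ";") else "PASS"
  }, "")
  out
}

#' Per-cell heteroplasmy genotyping
#'
#' For each (variant, cell), heteroplasmy = (fwd_alt + rev_alt) /
#' (fwd_total + rev_total) where the denominator is positive, missing
#' (NA) otherwise.
#'
#' @param counts long-format strand-split allele counts.
#' @param variants optional data.frame (position, ref, alt) restricting
#'   the variant set (typically the PASS rows of [filterVariants()]);
#'   default: every variant present in `counts`.
#' @param cellIds optional character vector fixing the cell universe
#'   (cells without counts get all-missing columns); default: cells
#'   present in `counts`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with rows =
#'   variants, columns = cells and assays `heteroplasmy` (NA where depth
#'   is 0), `depth` (total reads) and `alt` (alternate reads). Row
#'   metadata carries position/ref/alt.
#' @examples
#' cnt <- data.frame(cell_id = "c1", position = 100L, ref = "A",
#'                   alt = "G", fwd_alt = 3L, rev_alt = 1L,
#'                   fwd_total = 5L, rev_total = 5L)
#' se <- genotypeCells(cnt)
#' SummarizedExperiment::assay(se, "heteroplasmy")  # 4/10 = 0.4
#' @export
genotypeCells <- function(counts, variants = NULL, cellIds = NULL) {
  key <- paste(counts$position, counts$ref, counts$alt, sep = ":")
  if (is.null(variants)) {
    uk <- !duplicated(key)
    variants <- data.frame(position = counts$position[uk],
                           ref = counts$ref[uk], alt = counts$alt[uk],
                           stringsAsFactors = FALSE)
    variants <- variants[order(variants$position, variants$ref,
                               variants$alt), , drop = FALSE]
  }
  vKey <- paste(variants$position, variants$ref, variants$alt, sep = ":")
  if (is.null(cellIds)) cellIds <- sort(unique(counts$cell_id))
  keep <- key %in% vKey & counts$cell_id %in% cellIds
  counts <- counts[keep, , drop = FALSE]
  key <- key[keep]
  ri <- match(key, vKey)
  ci <- match(counts$cell_id, cellIds)
  V <- length(vKey); C <- length(cellIds)
  depth <- matrix(0, V, C, dimnames = list(vKey, cellIds))
  altM <- matrix(0, V, C, dimnames = list(vKey, cellIds))
  idx <- cbind(ri, ci)
  depth[idx] <- counts$fwd_total + counts$rev_total
  altM[idx] <- counts$fwd_alt + counts$rev_alt
  het <- ifelse(depth > 0, altM / depth, NA_real_)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(heteroplasmy = het, depth = depth, alt = altM),
    rowData = S4Vectors::DataFrame(position = variants$position,
                                   ref = variants$ref, alt = variants$alt,
                                   row.names = vKey))
}

#' Classify variants as homoplasmic or heteroplasmic
#'
#' A variant is called homoplasmic when the median of its defined per-cell
#' heteroplasmies exceeds `threshold`. This operationalizes the
#' homoplasmic/heteroplasmic split without an external haplogroup
#' database.
#'
#' @param se heteroplasmy container from [genotypeCells()] (or a plain
#'   variants x cells numeric matrix with NAs for missing entries).
#' @param threshold median heteroplasmy above which a variant is
#'   homoplasmic (default 0.95).
#' @return character vector per variant in `c("homoplasmic",
#'   "heteroplasmic")`.
#' @export
classifyHomoplasmy <- function(se, threshold = 0.95) {
  het <- if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "heteroplasmy") else se
  med <- apply(het, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) stop("variant with no defined heteroplasmy entries")
    median(x)
  })
  ifelse(med > threshold, "homoplasmic", "heteroplasmic")
}

#' Strand-resolved trinucleotide substitution spectrum
#'
#' For each single-base substitution, the immediate 5' and 3' bases are
#' extracted (with circular wrap-around) and substitution rates are
#' computed per trinucleotide context, normalized by the frequency of
#' that context in the reference, separately for the reference (L) strand
#' and its reverse complement (H strand, where the context and the
#' substitution are complemented). De-normalizing (rate x context
#' frequency) and summing over contexts recovers the substitution total
#' on each strand.
#'
#' @param variants data.frame with columns position, ref, alt. Indels are
#'   skipped (their count is reported in the `skipped` attribute).
#' @param reference circular reference sequence
#'   ([Biostrings::DNAString] or character).
#' @return data.frame (strand, context, substitution, count,
#'   context_freq, rate) covering every observed (strand, context,
#'   substitution); attribute `skipped` counts non-SNV inputs.
#' @export
trinucleotideSpectrum <- function(variants, reference) {
  refStr <- as.character(reference)
  n <- nchar(refStr)
  if (n < 3L) stop("reference must be at least 3 bases long")
  bases <- c("A", "C", "G", "T")
  isSnv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% bases & variants$alt %in% bases
  skipped <- sum(!isSnv)
  if (skipped > 0L)
    warning(skipped, " non-SNV variant(s) skipped")
  variants <- variants[isSnv, , drop = FALSE]

  # circularly padded sequence: position p context = circ[p..p+2]
  circ <- paste0(substr(refStr, n, n), refStr, substr(refStr, 1L, 1L))
  allCtx <- substring(circ, seq_len(n), seq_len(n) + 2L)
  freqL <- table(allCtx)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revComp <- function(s) {
    vapply(strsplit(s, ""), function(ch)
      paste(rev(unname(comp[ch])), collapse = ""), "")
  }

  mkRows <- function(ctx, ref, alt, strand, freqTab) {
    if (!length(ctx)) return(NULL)
    sub <- paste0(ref, ">", alt)
    agg <- as.data.frame(table(context = ctx, substitution = sub),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0, , drop = FALSE]
    agg$context_freq <- as.integer(freqTab[agg$context])
    data.frame(strand = strand, context = agg$context,
               substitution = agg$substitution, count = agg$Freq,
               context_freq = agg$context_freq,
               rate = agg$Freq / agg$context_freq,
               stringsAsFactors = FALSE)
  }

  ctxL <- if (nrow(variants)) {
    substring(circ, variants$position, variants$position + 2L)
  } else character()
  out <- rbind(
    mkRows(ctxL, variants$ref, variants$alt, "L", freqL),
    mkRows(revComp(ctxL), unname(comp[variants$ref]),
           unname(comp[variants$alt]), "H",
           # H-strand context frequency = frequency of its L reverse
           # complement
           setNames(as.integer(freqL), revComp(names(freqL)))))
  if (is.null(out))
    out <- data.frame(strand = character(), context = character(),
                      substitution = character(), count = integer(),
                      context_freq = integer(), rate = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Homopolymer length heteroplasmy at an anchor position
#'
#' For variable-length insertion alleles at a homopolymer anchor (the
#' m.302 poly-C block being the canonical case), computes each cell's
#' reference-allele heteroplasmy (reference reads / total reads) and
#' major allele, restricted to cells with at least `minCoverage` reads at
#' the anchor.
#'
#' @param alleleCounts data.frame with columns cell_id, allele, count.
#' @param refAllele the reference (uninserted) allele; defaults to the
#'   shortest observed allele.
#' @param minCoverage minimum per-cell total reads (default 10).
#' @return data.frame (cell_id, total, ref_het, major_allele) for
#'   included cells; zero rows with attribute `reason =
#'   "all_below_coverage"` when no cell qualifies.
#' @examples
#' ac <- data.frame(cell_id = "c1", allele = c("A", "AC", "ACC"),
#'                  count = c(5, 3, 2))
#' lengthHeteroplasmy(ac)  # ref_het 0.5, major allele "A"
#' @export
lengthHeteroplasmy <- function(alleleCounts, refAllele = NULL,
                               minCoverage = 10L) {
  if (is.null(refAllele))
    refAllele <- alleleCounts$allele[which.min(nchar(alleleCounts$allele))]
  res <- lapply(split(alleleCounts, alleleCounts$cell_id), function(cc) {
    total <- sum(cc$count)
    if (total < minCoverage) return(NULL)
    refCount <- sum(cc$count[cc$allele == refAllele])
    data.frame(cell_id = cc$cell_id[1L], total = total,
               ref_het = refCount / total,
               major_allele = cc$allele[which.max(cc$count)],
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    out <- data.frame(cell_id = character(), total = numeric(),
                      ref_het = numeric(), major_allele = character())
    attr(out, "reason") <- "all_below_coverage"
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a variant filter table as VCF 4.2
#'
#' @param variantTable output of [filterVariants()].
#' @param path output file path.
#' @param contig contig name (default "chrM").
#' @param refLength contig length for the header.
#' @return `path`, invisibly.
#' @export
writeVariantsVcf <- function(variantTable, path, contig = "chrM",
                             refLength = MT_GENOME_LENGTH) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, refLength),
    "##FILTER=<ID=strand_support,Description=\"Fewer than 2 alternate reads on one strand in the pooled pseudo-bulk\">",
    "##FILTER=<ID=strand_concordance,Description=\"Pearson correlation of forward and reverse per-cell heteroplasmy below 0.2 or undefined\">",
    "##FILTER=<ID=blacklist,Description=\"Position inside homopolymer blacklist regions 513-525 or 3105-3109\">",
    "##INFO=<ID=NCELLS,Number=1,Type=Integer,Description=\"Cells with coverage at the site\">",
    "##INFO=<ID=HET,Number=1,Type=Float,Description=\"Pooled pseudo-bulk heteroplasmy\">",
    "##INFO=<ID=STRANDR,Number=1,Type=Float,Description=\"Forward/reverse heteroplasmy Pearson correlation\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmtNum <- function(x) ifelse(is.na(x), ".", sprintf("%.6g", x))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tNCELLS=%d;HET=%s;STRANDR=%s",
                  contig, variantTable$position, variantTable$ref,
                  variantTable$alt, variantTable$filter,
                  variantTable$n_cells, fmtNum(variantTable$pooled_het),
                  fmtNum(variantTable$strand_r))
  writeLines(c(hdr, body), path)
  invisible(path)
}
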