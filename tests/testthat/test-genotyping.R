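test_that("pooled strand support requires two reads on each strand", {
  expect_true(strandSupportFilter(2, 2))
  expect_false(strandSupportFilter(3, 1))
  expect_false(strandSupportFilter(0, 10))
  expect_equal(strandSupportFilter(c(2, 3, 0), c(2, 1, 10)),
               c(TRUE, FALSE, FALSE))
  expect_error(strandSupportFilter(-1, 2), "negative")
})

test_that("strand concordance passes on agreement and fails on anticorrelation", {
  mk <- function(fa, ra, ft = 10L, rt = 10L)
    data.frame(fwd_alt = fa, rev_alt = ra,
               fwd_total = rep_len(ft, length(fa)),
               rev_total = rep_len(rt, length(fa)))
  identical_ <- strandConcordanceFilter(mk(c(1, 5, 9), c(1, 5, 9)))
  expect_true(identical_$pass)
  expect_equal(identical_$r, 1)
  anti <- strandConcordanceFilter(mk(c(1, 5, 9), c(9, 5, 1)))
  expect_false(anti$pass)
  expect_equal(anti$r, -1)
  # hand-evaluated Pearson on 4 points (direct formula as the oracle)
  fh <- c(0.2, 0.4, 0.6, 0.8); rh <- c(0.25, 0.35, 0.65, 0.75)
  rHand <- sum((fh - mean(fh)) * (rh - mean(rh))) /
    sqrt(sum((fh - mean(fh))^2) * sum((rh - mean(rh))^2))
  four <- strandConcordanceFilter(mk(as.integer(round(fh * 10)),
                                     as.integer(round(rh * 20)),
                                     10L, 20L))
  expect_equal(four$r, rHand, tolerance = 1e-12)
  expect_true(four$pass)
  # degenerate cases fail with a reason, not an exception
  none <- strandConcordanceFilter(mk(integer(), integer()))
  expect_false(none$pass)
  expect_equal(none$reason, "no_informative_cells")
  const <- strandConcordanceFilter(mk(c(2, 2, 2), c(1, 2, 3)))
  expect_false(const$pass)
  expect_equal(const$reason, "zero_variance")
  few <- strandConcordanceFilter(mk(c(1, 5), c(1, 5)))
  expect_equal(few$reason, "too_few_informative_cells")
})

test_that("blacklist boundaries are inclusive on both ends", {
  expect_equal(blacklistFilter(c(512, 513, 514, 525, 526,
                                 3104, 3105, 3109, 3110)),
               c(TRUE, FALSE, FALSE, FALSE, TRUE,
                 TRUE, FALSE, FALSE, TRUE))
  expect_error(blacklistFilter(0), "coordinates")
  expect_error(blacklistFilter(16570), "coordinates")
})

test_that("the filter stack reproduces the hand-derived PASS set and is order-invariant", {
  toy <- makeFilterToy()
  vt <- filterVariants(toy$counts)
  expect_setequal(vt$position[vt$filter == "PASS"], toy$expectedPass)
  # order invariance: sequential application in every order of the three
  # per-variant filters yields the same surviving set
  passSets <- lapply(combinat_orders <- list(
    c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
  ), function(ord) {
    surviving <- unique(toy$counts$position)
    for (f in ord) {
      surviving <- Filter(function(pos) {
        cc <- toy$counts[toy$counts$position == pos, ]
        switch(f,
               strandSupportFilter(sum(cc$fwd_alt), sum(cc$rev_alt)),
               strandConcordanceFilter(cc)$pass,
               blacklistFilter(pos))
      }, surviving)
    }
    sort(unlist(surviving))
  })
  for (s in passSets) expect_equal(s, sort(toy$expectedPass))
})

test_that("per-cell heteroplasmy pools strands and marks zero-depth cells missing", {
  cnt <- data.frame(
    cell_id = c("c1", "c2", "c3"), position = 100L, ref = "A", alt = "G",
    fwd_alt = c(5L, 3L, 0L), rev_alt = c(0L, 1L, 0L),
    fwd_total = c(10L, 5L, 0L), rev_total = c(0L, 5L, 0L))
  se <- genotypeCells(cnt, cellIds = c("c1", "c2", "c3", "c4"))
  het <- SummarizedExperiment::assay(se, "heteroplasmy")
  expect_equal(unname(het[1, "c1"]), 0.5)
  expect_equal(unname(het[1, "c2"]), 0.4)      # (3+1)/(5+5)
  expect_true(is.na(het[1, "c3"]))             # depth 0 -> missing
  expect_true(is.na(het[1, "c4"]))             # cell absent from counts
  depth <- SummarizedExperiment::assay(se, "depth")
  expect_equal(unname(depth[1, ]), c(10, 10, 0, 0))
})

test_that("homoplasmy classification uses the median with threshold 0.95", {
  het <- rbind(v1 = c(1, 1, 1), v2 = c(0.3, 0.3, 0.3),
               v3 = c(0.96, 0.97, 0.95), v4 = c(0.95, 0.95, NA))
  expect_equal(unname(classifyHomoplasmy(het)),
               c("homoplasmic", "heteroplasmic", "homoplasmic",
                 "heteroplasmic"))
  expect_error(classifyHomoplasmy(rbind(v = c(NA, NA))), "no defined")
})

test_that("trinucleotide spectrum matches a brute-force scan of a circular toy genome", {
  ref <- "AACGT"
  vars <- data.frame(position = 3L, ref = "C", alt = "T")
  sp <- trinucleotideSpectrum(vars, ref)
  L <- sp[sp$strand == "L", ]
  expect_equal(L$context, "ACG")
  expect_equal(L$substitution, "C>T")
  # brute-force context frequency on the circular 5-mer
  circ <- paste0(substr(ref, 5, 5), ref, substr(ref, 1, 1))
  freqACG <- sum(substring(circ, 1:5, 3:7) == "ACG")
  expect_equal(L$context_freq, freqACG)
  expect_equal(L$rate, 1 / freqACG)
  H <- sp[sp$strand == "H", ]
  expect_equal(H$context, "CGT")               # revcomp of ACG
  expect_equal(H$substitution, "G>A")
  # de-normalization recovers the substitution total on each strand
  expect_equal(sum(L$rate * L$context_freq), 1)
  expect_equal(sum(H$rate * H$context_freq), 1)
})

test_that("L and H spectra coincide for a strand-symmetric variant set on a palindromic genome", {
  ref <- "ACGT"  # its own circular reverse complement
  vars <- data.frame(position = c(2L, 3L), ref = c("C", "G"),
                     alt = c("T", "A"))
  sp <- trinucleotideSpectrum(vars, ref)
  key <- function(d) {
    d <- d[order(d$context, d$substitution), ]
    d[, c("context", "substitution", "count", "context_freq", "rate")]
  }
  expect_equal(key(sp[sp$strand == "L", ]), key(sp[sp$strand == "H", ]),
               ignore_attr = TRUE)
})

test_that("indels are skipped with a warning and empty input yields empty rates", {
  vars <- data.frame(position = c(2L, 3L), ref = c("C", "A"),
                     alt = c("T", "AC"))
  expect_warning(sp <- trinucleotideSpectrum(vars, "AACGT"), "skipped")
  expect_equal(attr(sp, "skipped"), 1)
  empty <- trinucleotideSpectrum(
    data.frame(position = integer(), ref = character(),
               alt = character()), "AACGT")
  expect_equal(nrow(empty), 0)
})

test_that("length heteroplasmy reports reference fraction and major allele", {
  ac <- data.frame(cell_id = rep(c("c1", "c2", "c3"), each = 3),
                   allele = rep(c("A", "AC", "ACC"), 3),
                   count = c(8, 2, 0,  0, 10, 0,  5, 3, 2))
  lh <- lengthHeteroplasmy(ac, refAllele = "A", minCoverage = 10)
  expect_equal(lh$ref_het[lh$cell_id == "c1"], 0.8)
  expect_equal(lh$major_allele[lh$cell_id == "c1"], "A")
  expect_equal(lh$ref_het[lh$cell_id == "c2"], 0)
  expect_equal(lh$major_allele[lh$cell_id == "c2"], "AC")
  expect_equal(lh$ref_het[lh$cell_id == "c3"], 0.5)
  expect_equal(lh$major_allele[lh$cell_id == "c3"], "A")
  # coverage rule drops cells below 10 reads; all-below yields a reason
  ac$count <- c(4, 2, 0, 0, 5, 0, 2, 1, 1)
  lh2 <- lengthHeteroplasmy(ac, refAllele = "A", minCoverage = 10)
  expect_equal(nrow(lh2), 0)
  expect_equal(attr(lh2, "reason"), "all_below_coverage")
})

test_that("simulated clean variants pass the stack and artifacts never do", {
  cfg <- simConfig(nLibraries = 1, cellsPerLibrary = 150, nClones = 2,
                   cloneFractions = c(0.5, 0.5), cloneMnr = c(350, 350),
                   nVariants = 20, genomeBins = 40, nStrandArtifacts = 3,
                   seed = 42)
  sim <- simulateDataset(cfg)
  vt <- filterVariants(sim$counts)
  tr <- sim$truth$variants
  genuine <- vt[vt$position %in% tr$position[!tr$artifact], ]
  # every genuine variant here has pooled expected alt reads far above 4
  # per strand (coverage 79, heteroplasmy >= 0.05 over 150 cells)
  expect_gte(mean(genuine$filter == "PASS"), 0.95)
  artifacts <- vt[vt$position %in% tr$position[tr$artifact], ]
  expect_true(all(!artifacts$strand_support))
  expect_true(all(artifacts$filter != "PASS"))
  # VCF output is well-formed
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantsVcf(vt, vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(vt))
  expect_true(all(grepl("^chrM\t", body)))
})
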