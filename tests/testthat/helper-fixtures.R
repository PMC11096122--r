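# Shared fixtures, all built in code.

# Toy 12-variant strand-count table exercising every filter rule:
# pooled strand-support boundary (2+2), strand-exclusive evidence,
# perfect strand anticorrelation, and all four blacklist boundaries.
makeFilterToy <- function() {
  rows <- list()
  addVariant <- function(position, fwdAlt, revAlt, fwdTotal = 10L,
                         revTotal = 10L) {
    n <- length(fwdAlt)
    rows[[length(rows) + 1L]] <<- data.frame(
      cell_id = sprintf("c%02d", seq_len(n)), position = position,
      ref = "A", alt = "G", fwd_alt = fwdAlt, rev_alt = revAlt,
      fwd_total = rep_len(fwdTotal, n), rev_total = rep_len(revTotal, n),
      stringsAsFactors = FALSE)
  }
  concordant <- c(1L, 2L, 3L, 4L, 5L)          # r = 1, pooled 15+15
  addVariant(100L, concordant, concordant)          # PASS
  addVariant(200L, c(0L, 1L, 1L, 0L, 0L),
             c(0L, 1L, 1L, 0L, 0L))                 # pooled exactly 2+2: PASS
  addVariant(300L, c(1L, 1L, 1L, 0L, 0L),
             c(1L, 0L, 0L, 0L, 0L))                 # pooled 3+1: strand_support fail
  addVariant(400L, c(5L, 5L, 5L, 0L, 0L),
             rep(0L, 5))                            # forward-only: fail
  addVariant(513L, concordant, concordant)          # blacklist start: fail
  addVariant(525L, concordant, concordant)          # blacklist end: fail
  addVariant(526L, concordant, concordant)          # just outside: PASS
  addVariant(512L, concordant, concordant)          # just outside: PASS
  addVariant(3105L, concordant, concordant)         # blacklist: fail
  addVariant(3109L, concordant, concordant)         # blacklist: fail
  addVariant(3110L, concordant, concordant)         # just outside: PASS
  addVariant(600L, c(1L, 5L, 9L), c(9L, 5L, 1L))    # r = -1: concordance fail
  list(counts = do.call(rbind, rows),
       expectedPass = c(100L, 200L, 512L, 526L, 3110L))
}

# Binomial-mixture scenario generator used for MityBayes recovery tests:
# K well-separated clones (ownership-block heteroplasmy 0.9 vs 0.05),
# Poisson site coverage.
simMbScenario <- function(nCells, nVariants, K, coverage, seed) {
  set.seed(seed)
  P <- defaultCloneHeteroplasmy(K, nVariants)
  z <- sample.int(K, nCells, replace = TRUE)
  total <- matrix(rpois(nCells * nVariants, coverage), nCells, nVariants)
  alt <- matrix(rbinom(nCells * nVariants, total, P[z, ]),
                nCells, nVariants)
  list(alt = alt, total = total, z = z, P = P)
}

# align the columns of a fitted gamma to a reference gamma by the best
# clone-label permutation (K <= 3), returning the aligned matrix
alignGamma <- function(gamma, ref) {
  K <- ncol(gamma)
  perms <- if (K == 1L) list(1L) else if (K == 2L) {
    list(c(1L, 2L), c(2L, 1L))
  } else {
    list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
         c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
  }
  errs <- vapply(perms, function(p) max(abs(gamma[, p] - ref)), 0)
  gamma[, perms[[which.min(errs)]], drop = FALSE]
}

# TRUE when two labelings induce the same partition of the items
samePartition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# exact rank-sum one-sided p by enumeration of group assignments
# (independent oracle for wilcox.test on small untied samples)
exactRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combs <- utils::combn(length(pooled), n)
  obs <- sum(rank(pooled)[seq_len(n)])
  stats <- apply(combs, 2L, function(idx) sum(rank(pooled)[idx]))
  mean(stats >= obs)
}
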