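#' Exact enumeration oracle for the MityBayes objective
#'
#' Brute-force reference for [fitMityBayes()] on tiny instances:
#' enumerates every assignment of cells to clones (K^cells of them) and,
#' for each assignment, profiles out the parameters — each P_kv is
#' maximized over a fixed probability grid (with its Beta prior) and pi
#' at its MAP given the assignment counts (or held at `priors$fixedPi`).
#' The global MAP assignment and the exact assignment marginals under the
#' resulting complete-data score are returned. Refuses instances above
#' the combinatorial caps.
#'
#' @param alt,total cells x variants count matrices.
#' @param K number of clones.
#' @param priors hyperparameters from [mbPriors()].
#' @param gridStep spacing of the P grid in (0,1) (default 0.01; the grid
#'   is `seq(gridStep, 1 - gridStep, by = gridStep)`).
#' @param maxCells,maxVariants,maxK size caps (defaults 8, 4, 3).
#' @param canonical when FALSE (default) all K^cells labelled assignments
#'   are enumerated, so the marginals are label-symmetric (a symmetric
#'   instance yields uniform marginals); when TRUE only canonically
#'   labelled assignments (each partition once, clones indexed by first
#'   appearance) are enumerated, which breaks label symmetry and makes
#'   the marginals directly comparable to a fitted model after aligning
#'   clone labels.
#' @return list(mapAssignment = integer per cell, gamma = cells x K exact
#'   marginals, logScores = per-assignment log scores, assignments =
#'   matrix of enumerated assignments).
#' @export
exactPosterior <- function(alt, total, K, priors = mbPriors(),
                           gridStep = 0.01, maxCells = 8L,
                           maxVariants = 4L, maxK = 3L,
                           canonical = FALSE) {
  alt <- as.matrix(alt); total <- as.matrix(total)
  C <- nrow(alt); V <- ncol(alt)
  if (C > maxCells || V > maxVariants || K > maxK)
    stop(sprintf(
      "instance exceeds exact enumeration caps (cells<=%d, variants<=%d, K<=%d)",
      maxCells, maxVariants, maxK))
  if (any(alt > total)) stop("alt counts exceed total counts")

  grid <- seq(gridStep, 1 - gridStep, by = gridStep)
  G <- length(grid)
  # llg[c, v, g] = log Binom(alt_cv | total_cv, grid[g])
  llg <- array(NA_real_, c(C, V, G))
  for (g in seq_len(G))
    llg[, , g] <- dbinom(alt, total, grid[g], log = TRUE)
  betaPrior <- (priors$a - 1) * log(grid) + (priors$b - 1) * log1p(-grid)

  assignments <- as.matrix(expand.grid(
    rep(list(seq_len(K)), C), KEEP.OUT.ATTRS = FALSE))
  colnames(assignments) <- NULL
  if (canonical) {
    isCanon <- apply(assignments, 1L, function(z) {
      all(z <= cummax(c(0L, z[-length(z)])) + 1L)
    })
    assignments <- assignments[isCanon, , drop = FALSE]
  }
  nA <- nrow(assignments)
  logScores <- numeric(nA)
  for (i in seq_len(nA)) {
    z <- assignments[i, ]
    nk <- tabulate(z, K)
    if (is.null(priors$fixedPi)) {
      piHat <- nk + priors$alpha - 1
      piHat <- pmax(piHat, 0)
      piHat <- piHat / sum(piHat)
      lp <- ifelse(nk > 0, log(piHat), 0)     # 0 * log(0) := 0
      score <- sum(nk * lp) +
        (priors$alpha - 1) * sum(ifelse(piHat > 0, log(piHat), 0))
    } else {
      score <- sum(nk * log(priors$fixedPi))
    }
    for (k in seq_len(K)) {
      cells <- which(z == k)
      if (!length(cells)) next
      # per-variant grid profile: V x G matrix of summed log-likelihoods
      m <- apply(llg[cells, , , drop = FALSE], c(2L, 3L), sum)
      m <- sweep(m, 2L, betaPrior, "+")
      score <- score + sum(apply(m, 1L, max))
    }
    logScores[i] <- score
  }
  w <- exp(logScores - logSumExp(logScores))
  gamma <- matrix(0, C, K)
  for (k in seq_len(K))
    for (cc in seq_len(C))
      gamma[cc, k] <- sum(w[assignments[, cc] == k])
  list(mapAssignment = assignments[which.max(logScores), ],
       gamma = gamma, logScores = logScores, assignments = assignments)
}
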