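#' Observation filters for the concordance analysis
#'
#' Builds, per variant, the set of (cell, heteroplasmy) observations
#' entering the heteroplasmy-to-copy-number concordance test:
#' \itemize{
#'   \item keep cell-variant observations with at least `minAlt` reads
#'     supporting the alternate allele;
#'   \item drop cells with heteroplasmy below `lo` or above `hi`
#'     (strictly: h < lo or h > hi are dropped, the endpoints are kept),
#'     preventing clusters of cells pinned at 0 or 1 from skewing the
#'     rank statistic;
#'   \item retain a variant only if the surviving heteroplasmies span a
#'     range (max - min) of at least `minRange`.
#' }
#'
#' @param se genotyping container from [genotypeCells()] (assays
#'   `heteroplasmy` and `alt`), or a list with elements `heteroplasmy`
#'   and `alt` (variants x cells matrices).
#' @param minAlt minimum alternate reads per observation (default 10).
#' @param lo,hi heteroplasmy window (default 0.05, 0.95).
#' @param minRange minimum heteroplasmy range per variant (default 0.15).
#' @return long data.frame (variant, cell_id, h) of surviving
#'   observations; attribute `dropped` is a data.frame (variant, reason)
#'   for variants removed wholesale.
#' @export
concordanceFilters <- function(se, minAlt = 10L, lo = 0.05, hi = 0.95,
                               minRange = 0.15) {
  if (is(se, "SummarizedExperiment")) {
    het <- SummarizedExperiment::assay(se, "heteroplasmy")
    altM <- SummarizedExperiment::assay(se, "alt")
  } else {
    het <- se$heteroplasmy; altM <- se$alt
  }
  vnames <- rownames(het) %||% as.character(seq_len(nrow(het)))
  cnames <- colnames(het) %||% as.character(seq_len(ncol(het)))
  out <- vector("list", nrow(het))
  dropped <- list()
  for (v in seq_len(nrow(het))) {
    h <- het[v, ]
    ok <- !is.na(h) & altM[v, ] >= minAlt & h >= lo & h <= hi
    if (!any(ok)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(variant = vnames[v], reason = "no_observations")
      next
    }
    if (max(h[ok]) - min(h[ok]) < minRange) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(variant = vnames[v], reason = "range_below_minimum")
      next
    }
    out[[v]] <- data.frame(variant = vnames[v], cell_id = cnames[ok],
                           h = unname(h[ok]), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(variant = character(), cell_id = character(),
                      h = numeric())
  rownames(res) <- NULL
  attr(res, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
    else data.frame(variant = character(), reason = character())
  res
}

# per-stratum concordance from pair counting:
# concordant if (h_i - h_j)(y_i - y_j) > 0, discordant if < 0, ties 0.5
strataConcordance <- function(h, y) {
  n <- length(h)
  sh <- sign(outer(h, h, "-"))
  sy <- sign(outer(y, y, "-"))
  prod_ <- sh * sy
  up <- upper.tri(prod_)
  nPairs <- sum(up)
  nConc <- sum(prod_[up] > 0)
  nTie <- sum(prod_[up] == 0)
  list(c = (nConc + 0.5 * nTie) / nPairs, n = n, pairs = nPairs)
}

#' Stratified, weighted concordance between heteroplasmy and copy number
#'
#' Within each stratum (sequencing library), all observation pairs are
#' classified as concordant, discordant, or tied; the per-stratum
#' concordance c_s = (concordant + 0.5 x ties) / pairs is combined across
#' strata with weights w_s (the number of cells in the library):
#' c = sum(w_s c_s) / sum(w_s). The variance under the null combines the
#' Kendall null variance mapped to the concordance scale,
#' Var0(c_s) = 2(2n_s + 5) / (9 n_s (n_s - 1)) / 4, as
#' sum(w_s^2 Var0(c_s)) / sum(w_s)^2. The z score is
#' (c - 0.5) / sqrt(variance) with a two-tailed normal p value; with one
#' stratum and no ties, 2c - 1 equals Kendall's tau-a.
#'
#' @param h heteroplasmy values.
#' @param y response (per-cell mtDNA copy number).
#' @param stratum stratum labels (default: one stratum).
#' @param weight per-observation stratum weights (constant within
#'   stratum; default: the stratum's observation count).
#' @return a [ConcordanceResult-class]. Strata with fewer than 2
#'   observations are excluded; if none remain the result is undefined
#'   with a reason.
#' @examples
#' stratifiedConcordance(1:4, c(1, 3, 2, 4))  # c = 5/6, scaled 2/3
#' @export
stratifiedConcordance <- function(h, y, stratum = NULL, weight = NULL) {
  n <- length(h)
  stopifnot(length(y) == n)
  if (is.null(stratum)) stratum <- rep("all", n)
  strata <- split(seq_len(n), stratum)
  rows <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    if (length(idx) < 2L) next
    sc <- strataConcordance(h[idx], y[idx])
    w <- if (is.null(weight)) sc$n else weight[idx][1L]
    var0 <- 2 * (2 * sc$n + 5) / (9 * sc$n * (sc$n - 1)) / 4
    rows[[s]] <- data.frame(stratum = s, n = sc$n, pairs = sc$pairs,
                            c_s = sc$c, weight = w, var0 = var0,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(new("ConcordanceResult", c = NA_real_, cScaled = NA_real_,
               variance = NA_real_, z = NA_real_, p = NA_real_,
               nObs = as.integer(n), nStrata = 0L,
               perStratum = data.frame(), reason = "all_strata_degenerate"))
  }
  ps <- do.call(rbind, rows)
  rownames(ps) <- NULL
  W <- sum(ps$weight)
  cHat <- sum(ps$weight * ps$c_s) / W
  variance <- sum(ps$weight^2 * ps$var0) / W^2
  z <- (cHat - 0.5) / sqrt(variance)
  new("ConcordanceResult",
      c = cHat, cScaled = 2 * cHat - 1, variance = variance, z = z,
      p = 2 * pnorm(-abs(z)), nObs = as.integer(sum(ps$n)),
      nStrata = nrow(ps), perStratum = ps, reason = "")
}

#' Permutation null for the stratified concordance
#'
#' Permutes the response within each stratum and recomputes the weighted
#' concordance; the empirical two-tailed p value is
#' (1 + #\{|c* - 0.5| >= |c - 0.5|\}) / (nPerm + 1). Serves as the
#' calibration oracle for the analytic normal p value.
#'
#' @param h,y,stratum,weight as in [stratifiedConcordance()].
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed (the permutation stream is deterministic
#'   given it).
#' @return list(p, observed = the observed [ConcordanceResult-class],
#'   cPerm = permuted concordances).
#' @export
permutationNull <- function(h, y, stratum = NULL, weight = NULL,
                            nPerm = 999L, seed = 1L) {
  if (nPerm < 100L) stop("'nPerm' must be at least 100")
  obs <- stratifiedConcordance(h, y, stratum, weight)
  if (nzchar(obs@reason)) stop("observed statistic undefined: ", obs@reason)
  n <- length(h)
  if (is.null(stratum)) stratum <- rep("all", n)
  strata <- split(seq_len(n), stratum)
  set.seed(seed)
  cPerm <- vapply(seq_len(nPerm), function(i) {
    yp <- y
    for (idx in strata) yp[idx] <- y[idx][sample.int(length(idx))]
    stratifiedConcordance(h, yp, stratum, weight)@c
  }, 0)
  p <- (1 + sum(abs(cPerm - 0.5) >= abs(obs@c - 0.5))) / (nPerm + 1)
  list(p = p, observed = obs, cPerm = cPerm)
}

#' Concordance tests for many variants with BH correction
#'
#' Runs [stratifiedConcordance()] per variant on a long observation table
#' and adjusts the p values with Benjamini-Hochberg.
#'
#' @param obs data.frame with columns variant, h, y, and optionally
#'   stratum and weight.
#' @return data.frame (variant, n_obs, n_strata, c, c_scaled, z, p, q,
#'   reason), input variant order preserved.
#' @export
concordanceTable <- function(obs) {
  stopifnot(all(c("variant", "h", "y") %in% names(obs)))
  vs <- unique(obs$variant)
  rows <- lapply(vs, function(v) {
    oo <- obs[obs$variant == v, , drop = FALSE]
    res <- stratifiedConcordance(oo$h, oo$y, oo$stratum, oo$weight)
    data.frame(variant = v, n_obs = res@nObs, n_strata = res@nStrata,
               c = res@c, c_scaled = res@cScaled, z = res@z, p = res@p,
               reason = res@reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bhAdjust(out$p[ok])
  rownames(out) <- NULL
  out[, c("variant", "n_obs", "n_strata", "c", "c_scaled", "z", "p", "q",
          "reason")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement;
#' output preserves input order.
#'
#' @param p p values in [0,1].
#' @return q values in [0,1].
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must be in [0,1]")
  p.adjust(p, method = "BH")
}

#' Per-library cell-size regressions
#'
#' For each sequencing library with at least `minCells` cells carrying a
#' diameter, fits ordinary least squares of mtDNA copy number on cell
#' diameter (and, as a second model, on diameter plus average ploidy) and
#' reports the Pearson correlation with a two-sided p value; q values are
#' BH-adjusted across libraries.
#'
#' @param cells data.frame with columns cn, diameter_um, average_ploidy,
#'   library_id.
#' @param minCells minimum cells per library (default 3).
#' @return data.frame, one row per library: n, slope, intercept,
#'   slope_multi (diameter coefficient with ploidy in the model), r,
#'   r_ci_lo, r_ci_hi, p, q, flagged.
#' @export
sizeRegression <- function(cells, minCells = 3L) {
  libs <- split(cells, cells$library_id)
  rows <- lapply(names(libs), function(l) {
    cc <- libs[[l]]
    cc <- cc[is.finite(cc$diameter_um) & is.finite(cc$cn), , drop = FALSE]
    base <- data.frame(library_id = l, n = nrow(cc),
                       stringsAsFactors = FALSE)
    if (nrow(cc) < minCells || sd(cc$diameter_um) == 0) {
      return(cbind(base, slope = NA_real_, intercept = NA_real_,
                   slope_multi = NA_real_, r = NA_real_,
                   r_ci_lo = NA_real_, r_ci_hi = NA_real_, p = NA_real_,
                   flagged = TRUE))
    }
    fit <- lm(cn ~ diameter_um, data = cc)
    fitMulti <- if (sd(cc$average_ploidy) > 0) {
      lm(cn ~ diameter_um + average_ploidy, data = cc)
    } else fit
    ct <- suppressWarnings(cor.test(cc$diameter_um, cc$cn))
    ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
    cbind(base, slope = unname(coef(fit)[2L]),
          intercept = unname(coef(fit)[1L]),
          slope_multi = unname(coef(fitMulti)["diameter_um"]),
          r = unname(ct$estimate), r_ci_lo = ci[1L], r_ci_hi = ci[2L],
          p = max(ct$p.value, .Machine$double.xmin), flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bhAdjust(out$p[ok])
  rownames(out) <- NULL
  out
}
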