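#' Clone assignment from nuclear copy-number profiles
#'
#' Clusters cells on their nuclear bin-state profiles. Two backends:
#' \describe{
#'   \item{"hclust" (default, dependency-free)}{average-linkage
#'     hierarchical clustering on correlation distance (1 - Pearson
#'     correlation between cell profiles); the number of clusters is
#'     either given (`k`) or chosen by maximum average silhouette width
#'     over 2..`kMax`. Cells with zero-variance profiles are attached to
#'     the cluster of the nearest cell by Euclidean distance; if all
#'     profiles are identical a single cluster is returned.}
#'   \item{"umap_hdbscan"}{the embedding/density-clustering adapter
#'     (UMAP with min_dist = 0 and correlation metric, HDBSCAN with
#'     cluster_selection_epsilon = 0.2, approx_min_span_tree = FALSE,
#'     gen_min_span_tree = TRUE). Requires the optional `uwot` and
#'     `dbscan` packages; errors when they are unavailable and
#'     `fallback = FALSE`, otherwise falls back to "hclust".}
#' }
#' Both backends are deterministic given `seed`.
#'
#' @param binStates cells x bins numeric matrix (rownames = cell ids).
#' @param method backend name.
#' @param k fixed number of clusters (NULL = choose by silhouette).
#' @param kMax maximum clusters scanned when `k` is NULL (default 8).
#' @param params adapter parameters; defaults mirror
#'   `list(umap = list(min_dist = 0, metric = "correlation"), hdbscan =
#'   list(cluster_selection_epsilon = 0.2, approx_min_span_tree = FALSE,
#'   gen_min_span_tree = TRUE))`.
#' @param fallback fall back to "hclust" when the adapter backend is
#'   missing (default TRUE).
#' @param seed integer seed.
#' @return data.frame (cell_id, clone, method); clone labels are letters
#'   ("A", "B", ...) in order of first appearance, or "noise" for
#'   density-backend outliers.
#' @export
clusterCellsNu <- function(binStates, method = c("hclust", "umap_hdbscan"),
                           k = NULL, kMax = 8L, params = nuCloneParams(),
                           fallback = TRUE, seed = 1L) {
  method <- match.arg(method)
  if (nrow(binStates) < 10L)
    stop("need at least 10 cells to cluster")
  cellIds <- rownames(binStates) %||% as.character(seq_len(nrow(binStates)))

  if (method == "umap_hdbscan") {
    haveBackend <- requireNamespace("uwot", quietly = TRUE) &&
      requireNamespace("dbscan", quietly = TRUE)
    if (!haveBackend) {
      if (!fallback)
        stop("umap_hdbscan backend unavailable (needs 'uwot' and 'dbscan')")
      method <- "hclust"
    } else {
      set.seed(seed)
      emb <- uwot::umap(binStates, min_dist = params$umap$min_dist,
                        metric = params$umap$metric, n_threads = 1)
      hd <- dbscan::hdbscan(
        emb, minPts = params$hdbscan$minPts %||% 10L,
        cluster_selection_epsilon =
          params$hdbscan$cluster_selection_epsilon,
        gen_simplified_tree = FALSE)
      lab <- ifelse(hd$cluster == 0L, "noise", letterLabels(hd$cluster))
      return(data.frame(cell_id = cellIds, clone = lab,
                        method = "umap_hdbscan", stringsAsFactors = FALSE))
    }
  }

  set.seed(seed)
  X <- as.matrix(binStates)
  varOk <- apply(X, 1L, sd) > 0
  if (!any(varOk) || nrow(unique(X)) == 1L) {
    return(data.frame(cell_id = cellIds, clone = "A", method = "hclust",
                      stringsAsFactors = FALSE))
  }
  cl <- integer(nrow(X))
  Xv <- X[varOk, , drop = FALSE]
  if (nrow(unique(Xv)) == 1L) {
    cl[varOk] <- 1L
  } else {
    d <- as.dist(1 - cor(t(Xv)))
    d[!is.finite(d)] <- 2   # defensive: max correlation distance
    hc <- hclust(d, method = "average")
    if (!is.null(k)) {
      cl[varOk] <- cutree(hc, k = min(k, nrow(Xv)))
    } else {
      kGrid <- 2:min(kMax, nrow(Xv) - 1L)
      sil <- vapply(kGrid, function(kk) {
        ct <- cutree(hc, k = kk)
        if (length(unique(ct)) < 2L) return(-Inf)
        mean(cluster::silhouette(ct, d)[, "sil_width"])
      }, 0)
      cl[varOk] <- cutree(hc, k = kGrid[which.max(sil)])
    }
  }
  if (any(!varOk)) {
    # attach flat-profile cells to the nearest clustered cell
    for (i in which(!varOk)) {
      dEuc <- colSums((t(Xv) - X[i, ])^2)
      cl[i] <- cl[varOk][which.min(dEuc)]
    }
  }
  data.frame(cell_id = cellIds, clone = letterLabels(cl),
             method = "hclust", stringsAsFactors = FALSE)
}

#' Default adapter parameters for nuclear-profile clustering
#' @return nested list of UMAP/HDBSCAN parameters.
#' @export
nuCloneParams <- function() {
  list(umap = list(min_dist = 0.0, metric = "correlation"),
       hdbscan = list(cluster_selection_epsilon = 0.2,
                      approx_min_span_tree = FALSE,
                      gen_min_span_tree = TRUE))
}

# relabel integer clusters as letters in order of first appearance
letterLabels <- function(cl) {
  first <- unique(cl)
  LETTERS[match(cl, first)]
}

#' Cross-check nuclear and mitochondrial clone assignments
#'
#' Compares a nuclear-profile partition with an mtDNA-based one on the
#' overlapping cells: contingency counts, adjusted Rand index (ARI,
#' symmetric in its arguments) and the modal mtDNA clone per nuclear
#' clone.
#'
#' @param nuLabels data.frame (cell_id, clone) from [clusterCellsNu()].
#' @param mtLabels data.frame (cell_id, clone), e.g. built from
#'   [assignClones()]; or a [CloneModel-class] plus `cellIds`.
#' @param cellIds cell ids for `mtLabels` when it is a CloneModel.
#' @param minProb passed to [assignClones()] in that case.
#' @return list(contingency = table, ari, modal = data.frame(nu_clone,
#'   mt_clone)).
#' @export
crosscheckClones <- function(nuLabels, mtLabels, cellIds = NULL,
                             minProb = 0.9) {
  if (is(mtLabels, "CloneModel")) {
    if (is.null(cellIds))
      stop("'cellIds' required when 'mtLabels' is a CloneModel")
    mtLabels <- data.frame(cell_id = cellIds,
                           clone = assignClones(mtLabels, minProb),
                           stringsAsFactors = FALSE)
  }
  common <- intersect(nuLabels$cell_id, mtLabels$cell_id)
  if (!length(common))
    stop("nuclear and mtDNA labelings share no cells")
  nu <- nuLabels$clone[match(common, nuLabels$cell_id)]
  mt <- mtLabels$clone[match(common, mtLabels$cell_id)]
  tab <- table(nu_clone = nu, mt_clone = mt)
  modal <- data.frame(
    nu_clone = rownames(tab),
    mt_clone = colnames(tab)[apply(tab, 1L, which.max)],
    stringsAsFactors = FALSE)
  list(contingency = tab, ari = mclust::adjustedRandIndex(nu, mt),
       modal = modal)
}
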