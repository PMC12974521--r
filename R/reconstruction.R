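## Connectome reconstruction from PI gradients: squared PI distance, ROC/AUC,
## and the physical-distance baseline.

#' Squared PI distance for every directed region pair
#'
#' `values[i, j] = sum_k (Ps[i, k] - Pt[j, k])^2` over the first `kUsed`
#' components: the dissimilarity between region i acting as a source and
#' region j acting as a target. Low values predict a connection.
#'
#' @param maps a [PIMaps-class].
#' @param kUsed number of leading components to use (default: all).
#' @return A [DPIMatrix-class] over all R x R directed pairs (eligibility is
#'   applied downstream).
#' @export
computeDPI <- function(maps, kUsed = ncol(sourceMaps(maps))) {
  K <- ncol(sourceMaps(maps))
  .stopIfNot(kUsed >= 1L && kUsed <= K, "kUsed must lie in [1, %d]", K)
  Ps <- sourceMaps(maps)
  Pt <- targetMaps(maps)
  R <- nrow(Ps)
  vals <- matrix(0, R, R, dimnames = list(rownames(Ps), rownames(Pt)))
  for (k in seq_len(kUsed)) {
    vals <- vals + outer(Ps[, k], Pt[, k], "-")^2
  }
  new("DPIMatrix", values = vals, kUsed = as.integer(kUsed))
}

#' ROC curve and AUC for connectome reconstruction
#'
#' Sweeps a threshold over all distinct score values on the evaluated cells
#' (with infinite endpoints) and computes the true/false positive rates of
#' predicting "connected". Positives are the connected eligible cells. The AUC
#' is the tie-corrected rank statistic: the probability that a random
#' connected cell scores better (for `"lower"` orientation: lower) than a
#' random unconnected cell, with ties credited 0.5.
#'
#' @param score numeric R x R matrix (e.g. a dPI matrix or distances), or a
#'   [DPIMatrix-class].
#' @param conn a [Connectome-class].
#' @param orientation `"lower"` if small scores predict a connection (the
#'   convention for dPI and physical distance), `"higher"` otherwise.
#' @param cellSubset optional linear cell indices (subset of eligible cells) to
#'   evaluate on, e.g. held-out cells; defaults to all eligible cells.
#' @return list with `thresholds`, `fpr`, `tpr`, `auc`, `nPos`, `nNeg`.
#' @export
rocAUC <- function(score, conn, orientation = c("lower", "higher"),
                   cellSubset = NULL) {
  orientation <- match.arg(orientation)
  if (is(score, "DPIMatrix")) score <- score@values
  mask <- eligibleMask(conn)
  cells <- if (is.null(cellSubset)) which(mask) else {
    .stopIfNot(all(cellSubset %in% which(mask)),
               "cellSubset contains ineligible cells")
    cellSubset
  }
  s <- score[cells]
  y <- adjacency(conn)[cells] == 1
  nPos <- sum(y); nNeg <- sum(!y)
  .stopIfNot(nPos > 0L && nNeg > 0L,
             "both connected and unconnected cells are required (pos = %d, neg = %d)",
             nPos, nNeg)
  # orient so that HIGHER oriented score predicts connection
  so <- if (orientation == "lower") -s else s
  r <- rank(so)
  auc <- (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  # threshold sweep on the original scale
  ord <- order(so, decreasing = TRUE)
  yo <- y[ord]
  uniq <- !duplicated(so[ord], fromLast = TRUE) # last index of each tie block
  tp <- cumsum(yo)[uniq]
  fp <- cumsum(!yo)[uniq]
  thr <- s[ord][uniq]
  list(thresholds = c(if (orientation == "lower") -Inf else Inf, thr),
       fpr = c(0, fp / nNeg),
       tpr = c(0, tp / nPos),
       auc = auc, nPos = nPos, nNeg = nNeg)
}

#' Pairwise physical distances between region centroids
#'
#' @param atlas a [RegionAtlas-class].
#' @return symmetric R x R matrix of Euclidean centroid distances, zero
#'   diagonal.
#' @export
physicalDistances <- function(atlas) {
  d <- as.matrix(stats::dist(centroids(atlas)))
  dimnames(d) <- list(regionIds(atlas), regionIds(atlas))
  d
}

#' Correlation of dPI with physical distance, by connection status
#'
#' Pearson correlation of the squared PI distance against interregional
#' physical distance over the eligible cells: across all cells, across
#' connected cells only, and across unconnected cells only. A stratum with
#' fewer than 3 cells or zero variance is reported as `NA`.
#'
#' @param dpi a [DPIMatrix-class] (or plain R x R matrix).
#' @param dist R x R physical-distance matrix.
#' @param conn a [Connectome-class].
#' @return named numeric vector `c(all, connected, unconnected)`.
#' @export
dpiDistanceRelation <- function(dpi, dist, conn) {
  if (is(dpi, "DPIMatrix")) dpi <- dpi@values
  mask <- eligibleMask(conn)
  con <- adjacency(conn) == 1 & mask
  unc <- adjacency(conn) == 0 & mask
  strat <- list(all = mask, connected = con, unconnected = unc)
  out <- vapply(strat, function(m) {
    if (sum(m) < 3L) return(NA_real_)
    .safeCor(dpi[m], dist[m])
  }, numeric(1))
  out
}
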