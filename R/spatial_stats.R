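## Spatial statistics: weight matrices, Moran's I, variograms, and
## variogram-matched surrogate maps (spatially-constrained permutation nulls).

#' Build a spatial weights matrix
#'
#' Two schemes: `"knn"` assigns weight 1 to each region's `k` nearest
#' centroids and symmetrizes by the elementwise maximum; `"invdist"` uses
#' inverse distance `d^-p`. Optionally row-standardized so each nonzero row
#' sums to 1.
#'
#' @param atlas a [RegionAtlas-class] (R >= 3).
#' @param scheme `"knn"` or `"invdist"`.
#' @param k neighbourhood size for `"knn"` (default 6).
#' @param p exponent for `"invdist"` (default 2).
#' @param rowStandardize logical (default `TRUE`).
#' @return A [SpatialWeights-class].
#' @export
spatialWeights <- function(atlas, scheme = c("knn", "invdist"), k = 6L, p = 2,
                           rowStandardize = TRUE) {
  scheme <- match.arg(scheme)
  R <- nRegions(atlas)
  .stopIfNot(R >= 3L, "at least 3 regions are required")
  d <- physicalDistances(atlas)
  if (scheme == "knn") {
    .stopIfNot(k >= 1L && k < R, "k must lie in [1, R - 1]")
    W <- matrix(0, R, R)
    for (i in seq_len(R)) {
      nn <- order(d[i, -i])[seq_len(k)]
      idx <- seq_len(R)[-i][nn]
      W[i, idx] <- 1
    }
    W <- pmax(W, t(W))
    label <- sprintf("knn:%d", as.integer(k))
  } else {
    off <- d[upper.tri(d)]
    .stopIfNot(all(off > 0), "coincident centroids: inverse-distance weights undefined")
    W <- d
    W[W > 0] <- W[W > 0]^(-p)
    diag(W) <- 0
    label <- sprintf("invdist:%g", p)
  }
  if (rowStandardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  dimnames(W) <- list(regionIds(atlas), regionIds(atlas))
  new("SpatialWeights", W = W, scheme = label, rowStandardized = rowStandardize)
}

#' Moran's I spatial autocorrelation
#'
#' `I = (R / S0) * (sum_ij W_ij z_i z_j) / (sum_i z_i^2)` with `z` the centered
#' map and `S0` the total weight. Positive for spatially smooth maps; the
#' expectation under random permutation is `-1 / (R - 1)`.
#'
#' @param map numeric vector of R region values with nonzero variance.
#' @param w a [SpatialWeights-class] or plain R x R weight matrix.
#' @return scalar Moran's I.
#' @export
moransI <- function(map, w) {
  W <- if (is(w, "SpatialWeights")) w@W else w
  R <- length(map)
  .stopIfNot(nrow(W) == R, "map length and weight dimension disagree")
  z <- map - mean(map)
  ss <- sum(z^2)
  .stopIfNot(ss > 0, "Moran's I is undefined for a constant map")
  (R / sum(W)) * drop(crossprod(z, W %*% z)) / ss
}

# Quantile bin assignment for pair distances; shared by the variogram and the
# surrogate fit so their bins always agree.
.variogramBins <- function(d, nBins) {
  br <- unique(stats::quantile(d, probs = seq(0, 1, length.out = nBins + 1L)))
  bin <- cut(d, breaks = br, include.lowest = TRUE, labels = FALSE)
  list(breaks = br, bin = bin, nBins = length(br) - 1L)
}

#' Empirical variogram of a regional map
#'
#' Semivariance `gamma(h) = mean over pairs in the bin of (z_i - z_j)^2 / 2`,
#' with distance bins at quantiles of the pairwise distances (upper-triangle
#' pairs). An empty bin is reported as `NA`.
#'
#' @param map numeric vector of R region values.
#' @param dist R x R symmetric distance matrix.
#' @param nBins number of quantile bins (>= 2; default 15).
#' @return data.frame with `bin`, `lower`, `upper`, `n_pairs`, `gamma`.
#' @export
spatialVariogram <- function(map, dist, nBins = 15L) {
  .stopIfNot(nBins >= 2L, "nBins must be >= 2")
  R <- length(map)
  ut <- upper.tri(dist)
  d <- dist[ut]
  bi <- .variogramBins(d, nBins)
  ii <- row(dist)[ut]
  jj <- col(dist)[ut]
  sq <- 0.5 * (map[ii] - map[jj])^2
  nb <- bi$nBins
  gamma <- rep(NA_real_, nb)
  np <- integer(nb)
  agg <- tapply(sq, bi$bin, mean)
  cnt <- table(bi$bin)
  gamma[as.integer(names(agg))] <- agg
  np[as.integer(names(cnt))] <- as.integer(cnt)
  data.frame(bin = seq_len(nb),
             lower = bi$breaks[-length(bi$breaks)],
             upper = bi$breaks[-1L],
             n_pairs = np,
             gamma = gamma)
}

#' Precompute the machinery for variogram-matched surrogates
#'
#' Builds, once per distance matrix, everything [makeSurrogates()] needs:
#' upper-triangle pair indices and their variogram bin assignment, and one
#' row-normalized Gaussian smoothing kernel per candidate bandwidth. Reuse the
#' context across many maps (e.g. across genes in [screenGenes()]) — kernel
#' construction dominates the cost otherwise.
#'
#' @param dist R x R symmetric distance matrix.
#' @param nBins variogram quantile bins (default 15).
#' @param bandwidths optional explicit bandwidth grid (0 means "no
#'   smoothing"); default: 10 log-spaced values spanning the 5th-95th
#'   percentile of pairwise distances.
#' @param nBandwidths grid size when `bandwidths` is `NULL`.
#' @param nuggets admixture weights for the unsmoothed permutation: every
#'   candidate kernel is `(1 - a) * K_bandwidth + a * I`, so partially smooth
#'   maps (a nugget in the variogram) are representable. Default
#'   `c(0, 0.25, 0.5)`.
#' @return an opaque list used by [makeSurrogates()].
#' @export
surrogateContext <- function(dist, nBins = 15L, bandwidths = NULL,
                             nBandwidths = 10L, nuggets = c(0, 0.25, 0.5)) {
  R <- nrow(dist)
  ut <- upper.tri(dist)
  d <- dist[ut]
  if (is.null(bandwidths)) {
    rng <- stats::quantile(d[d > 0], c(0.05, 0.95))
    # always offer "no smoothing": a spatially unstructured map must be able
    # to select the pure permutation
    bandwidths <- c(0, exp(seq(log(rng[1]), log(rng[2]),
                               length.out = nBandwidths)))
  }
  .stopIfNot(length(bandwidths) >= 1L && all(bandwidths >= 0),
             "bandwidths must be nonnegative")
  .stopIfNot(all(nuggets >= 0 & nuggets <= 1), "nuggets must lie in [0, 1]")
  grid <- expand.grid(bandwidth = as.numeric(bandwidths),
                      nugget = as.numeric(nuggets))
  # a zero bandwidth is pure permutation whatever the nugget: keep one copy
  grid <- grid[!(grid$bandwidth == 0 & grid$nugget > 0), , drop = FALSE]
  kernels <- lapply(seq_len(nrow(grid)), function(i) {
    b <- grid$bandwidth[i]; a <- grid$nugget[i]
    if (b == 0) return(diag(R))
    Kb <- exp(-dist^2 / (2 * b^2))
    (1 - a) * Kb / rowSums(Kb) + a * diag(R)
  })
  bi <- .variogramBins(d, nBins)
  cnt <- tabulate(bi$bin, nbins = bi$nBins)
  list(R = R,
       ii = row(dist)[ut], jj = col(dist)[ut],
       bin = bi$bin, nBins = bi$nBins, binCounts = cnt,
       breaks = bi$breaks,
       grid = grid,
       bandwidths = grid$bandwidth,
       nuggets = grid$nugget,
       kernels = kernels)
}

# Variograms of many maps at once: columns of Z are maps; returns nBins x M.
.variogramMany <- function(Z, ctx) {
  D2 <- 0.5 * (Z[ctx$ii, , drop = FALSE] - Z[ctx$jj, , drop = FALSE])^2
  G <- rowsum(D2, ctx$bin)
  out <- matrix(NA_real_, ctx$nBins, ncol(Z))
  present <- as.integer(rownames(G))
  out[present, ] <- G / ctx$binCounts[present]
  out
}

#' Spatially-constrained surrogate maps by variogram matching
#'
#' Each surrogate is built by (1) randomly permuting the map, (2) smoothing
#' the permutation with a family of distance-decaying Gaussian kernels
#' (bandwidth grid x permutation-admixture "nugget" weights, including pure
#' permutation), (3) keeping the kernel whose rescaled variogram best matches
#' the original map's (squared error over bins), and (4) rescaling to the
#' original mean and variance. The result randomizes the map while
#' approximately preserving its spatial autocorrelation, giving a permutation
#' null that respects spatial smoothness.
#'
#' With `fit = "ensemble"` (default) one kernel is chosen per map by
#' minimizing the mean variogram error across all M permutations; this avoids
#' the selection bias of fitting each surrogate separately, which overfits
#' variogram noise and injects spurious smoothness into surrogates of
#' unstructured maps. `fit = "per-surrogate"` selects independently for each
#' permutation.
#'
#' @param map numeric vector of R region values (nonconstant).
#' @param dist R x R symmetric distance matrix (ignored when `context` is
#'   supplied).
#' @param M number of surrogates (>= 1).
#' @param seed integer seed.
#' @param nBins,bandwidths forwarded to [surrogateContext()] when no context
#'   is given.
#' @param context a precomputed [surrogateContext()].
#' @param fit `"ensemble"` or `"per-surrogate"` kernel selection.
#' @return list of class `"SurrogateEnsemble"`: `surrogates` (R x M matrix),
#'   `bandwidth` and `nugget` (chosen per surrogate), `relSSE`
#'   (variogram-fit diagnostic, SSE relative to the squared norm of the
#'   target variogram), and `bandwidthGrid`.
#' @export
makeSurrogates <- function(map, dist = NULL, M, seed, nBins = 15L,
                           bandwidths = NULL, context = NULL,
                           fit = c("ensemble", "per-surrogate")) {
  fit <- match.arg(fit)
  .stopIfNot(M >= 1L, "M must be >= 1")
  .stopIfNot(stats::sd(map) > 0, "surrogates of a constant map are undefined")
  if (is.null(context)) {
    .stopIfNot(!is.null(dist), "either dist or context must be supplied")
    context <- surrogateContext(dist, nBins = nBins, bandwidths = bandwidths)
  }
  R <- context$R
  .stopIfNot(length(map) == R, "map length and context disagree")
  gamma0 <- .variogramMany(matrix(map, ncol = 1L), context)[, 1L]
  ok <- which(!is.na(gamma0))
  .stopIfNot(length(ok) >= 2L, "too few populated variogram bins")
  Z <- .withSeed(as.integer(seed),
                 vapply(seq_len(M), function(m) sample(map), numeric(R)))
  nb <- length(context$bandwidths)
  mu0 <- mean(map); sd0 <- stats::sd(map)
  i0 <- which(context$bandwidths == 0 & context$nuggets == 0)[1]
  bestSSE <- rep(Inf, M)
  bestIdx <- rep(1L, M)
  bestMaps <- Z
  sse0 <- rep(Inf, M)
  meanSSE <- rep(Inf, nb)
  smoothed <- if (fit == "ensemble") vector("list", nb) else NULL
  for (b in seq_len(nb)) {
    S <- context$kernels[[b]] %*% Z
    sdS <- apply(S, 2L, stats::sd)
    keep <- sdS > 0
    if (!any(keep)) next  # bandwidth so wide it flattens every map
    # rescale to the original mean/variance BEFORE comparing variograms:
    # smoothing shrinks the variance, and the fit must judge shape, not scale
    S <- sweep(sweep(S, 2L, colMeans(S), "-"), 2L,
               ifelse(keep, sdS / sd0, 1), "/") + mu0
    G <- .variogramMany(S, context)
    sse <- colSums((G[ok, , drop = FALSE] - gamma0[ok])^2)
    sse[!keep] <- Inf
    if (fit == "ensemble") {
      if (all(keep)) meanSSE[b] <- mean(sse)
      smoothed[[b]] <- S
    } else {
      if (!is.na(i0) && b == i0) sse0 <- sse
      upd <- which(sse < bestSSE)
      if (length(upd)) {
        bestSSE[upd] <- sse[upd]
        bestIdx[upd] <- b
        bestMaps[, upd] <- S[, upd]
      }
    }
  }
  # Parsimony: adopt a structured kernel only when it beats the pure
  # permutation's variogram error by > 5%; chance fluctuations in an
  # unstructured map's variogram rarely reach that, so surrogates of
  # unstructured maps stay exact permutations (exactly calibrated p-values).
  if (fit == "ensemble") {
    .stopIfNot(any(is.finite(meanSSE)), "all candidate bandwidths degenerate")
    b <- which.min(meanSSE)
    if (!is.na(i0) && is.finite(meanSSE[i0]) &&
        meanSSE[b] > 0.95 * meanSSE[i0]) b <- i0
    bestIdx <- rep(b, M)
    bestMaps <- smoothed[[b]]
    bestSSE <- rep(meanSSE[b], M)
  } else if (!is.na(i0)) {
    back <- which(is.finite(sse0) & bestSSE > 0.95 * sse0)
    if (length(back)) {
      bestSSE[back] <- sse0[back]
      bestIdx[back] <- i0
      bestMaps[, back] <- Z[, back] # b = 0: surrogate is the raw permutation
    }
  }
  .stopIfNot(all(is.finite(bestSSE)), "all candidate bandwidths degenerate")
  # exact rescale of the selected surrogates to the original mean/variance
  mu <- colMeans(bestMaps)
  sds <- apply(bestMaps, 2L, stats::sd)
  out <- sweep(sweep(bestMaps, 2L, mu, "-"), 2L, sds / sd0, "/") + mu0
  structure(list(surrogates = out,
                 bandwidth = context$bandwidths[bestIdx],
                 nugget = context$nuggets[bestIdx],
                 relSSE = bestSSE / sum(gamma0[ok]^2),
                 bandwidthGrid = context$grid),
            class = "SurrogateEnsemble")
}

#' @export
print.SurrogateEnsemble <- function(x, ...) {
  cat(sprintf("SurrogateEnsemble: %d surrogates of a %d-region map; median rel. SSE %.3g\n",
              ncol(x$surrogates), nrow(x$surrogates), stats::median(x$relSSE)))
  invisible(x)
}

#' Spatial correlation of a source/target PI gradient pair
#'
#' Pearson correlation across regions between the source and target map of one
#' component: high values mean the paired gradients share a spatial pattern.
#'
#' @param maps a [PIMaps-class].
#' @param component component index (<= K).
#' @return scalar correlation (`NA` if a side has zero variance).
#' @export
piPairSpatialCorrelation <- function(maps, component = 1L) {
  K <- ncol(sourceMaps(maps))
  .stopIfNot(component >= 1L && component <= K, "component must lie in [1, %d]", K)
  .safeCor(sourceMaps(maps)[, component], targetMaps(maps)[, component])
}
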