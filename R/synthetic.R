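## Synthetic chemoaffinity data generator: an MR-partitioned atlas with
## spatially clustered centroids, smooth planted gradient pairs, gene
## expression as noisy linear mixtures of the gradients, and a connectome
## whose edges preferentially join regions with similar source/target PI.

#' Simulate a region atlas
#'
#' Major regions are spatially separated clusters: `nMR` cluster centres are
#' drawn uniformly in a cube of side 10 (atlas length units) and each region's
#' centroid is its cluster centre plus isotropic Gaussian scatter. Region
#' counts are split as evenly as possible across MRs. Defaults mirror the
#' mouse mesoscale data: 213 regions in 13 major regions.
#'
#' @param R number of regions (default 213).
#' @param nMR number of major regions (default 13; `R >= 2 * nMR`).
#' @param spread within-cluster centroid SD (default 0.8).
#' @param seed integer seed.
#' @return A [RegionAtlas-class].
#' @export
simulateAtlas <- function(R = 213L, nMR = 13L, spread = 0.8, seed = 1L) {
  .stopIfNot(nMR >= 2L, "nMR must be >= 2")
  .stopIfNot(R >= 2L * nMR, "R must be at least 2 * nMR")
  .withSeed(as.integer(seed), {
    centres <- matrix(stats::runif(nMR * 3L, 0, 10), nMR, 3L)
    sizes <- rep(R %/% nMR, nMR)
    extra <- R %% nMR
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    mr <- rep(seq_len(nMR), sizes)
    ctr <- centres[mr, , drop = FALSE] +
      matrix(stats::rnorm(R * 3L, sd = spread), R, 3L)
    RegionAtlas(sprintf("R%03d", seq_len(R)),
                sprintf("MR%02d", mr),
                ctr)
  })
}

# Draw one standardized map from a squared-exponential Gaussian process over
# the given coordinates.
.gpDraw <- function(coords, lengthScale, n = 1L) {
  R <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  K <- exp(-d^2 / (2 * lengthScale^2)) + diag(1e-8, R)
  L <- t(chol(K))
  Z <- L %*% matrix(stats::rnorm(R * n), R, n)
  apply(Z, 2L, function(z) (z - mean(z)) / stats::sd(z))
}

# Center x, remove its projection onto the (centered) columns of B, and
# restandardize to unit sample variance.
.orthogonalizeAgainst <- function(x, B) {
  x <- x - mean(x)
  if (!is.null(B) && ncol(B) > 0) {
    for (j in seq_len(ncol(B))) {
      b <- B[, j] - mean(B[, j])
      x <- x - b * sum(x * b) / sum(b * b)
    }
  }
  (x - mean(x)) / stats::sd(x)
}

#' Simulate planted gradient map pairs
#'
#' Each of the `kStar` components gets a source map and a target map drawn
#' from a squared-exponential Gaussian process over region coordinates and
#' standardized (mean 0, sample variance 1). Source and target draws of a
#' component share a configurable cross-correlation, emulating gradient pairs
#' that range from near-identical to dissimilar spatial patterns. With
#' `basis = "spatial"` the process runs over the true centroids (maps are
#' spatially smooth); with `basis = "latent"` it runs over random latent
#' coordinates, decoupling the gradients from brain geometry — useful to test
#' that PI-based reconstruction beats a physical-distance baseline.
#'
#' @param atlas a [RegionAtlas-class].
#' @param kStar number of gradient pairs (default 3).
#' @param lengthScale kernel length-scale(s) in atlas units; a vector is
#'   recycled across components (default `c(8, 4, 2)` truncated/recycled to
#'   `kStar`: the leading component varies at the whole-brain scale, later
#'   ones at finer scales).
#' @param pairCorrelation correlation between the source and target draw of a
#'   component (default 0.5).
#' @param basis `"spatial"` (default) or `"latent"`.
#' @param seed integer seed.
#' @return list with matrices `source` and `target` (R x kStar).
#' @export
simulateGradients <- function(atlas, kStar = 3L,
                              lengthScale = c(8, 4, 2),
                              pairCorrelation = 0.5,
                              basis = c("spatial", "latent"),
                              seed = 1L) {
  basis <- match.arg(basis)
  .stopIfNot(kStar >= 1L, "kStar must be >= 1")
  .stopIfNot(all(lengthScale > 0), "lengthScale must be positive")
  .stopIfNot(abs(pairCorrelation) <= 1, "pairCorrelation must lie in [-1, 1]")
  ls <- rep_len(lengthScale, kStar)
  R <- nRegions(atlas)
  .withSeed(as.integer(seed), {
    coords <- switch(basis,
      spatial = centroids(atlas),
      latent = matrix(stats::runif(R * 3L, 0, 10), R, 3L))
    src <- matrix(0, R, kStar)
    tgt <- matrix(0, R, kStar)
    for (k in seq_len(kStar)) {
      draws <- .gpDraw(coords, ls[k], n = 2L)
      # successive source maps are orthogonalized: planted components are
      # distinct positional axes, which keeps them identifiable downstream
      src[, k] <- .orthogonalizeAgainst(draws[, 1L],
                                        src[, seq_len(k - 1L), drop = FALSE])
      # the target companion shares correlation pairCorrelation with its
      # source map; its innovation is orthogonal to all source maps and to
      # earlier targets, so target maps are mutually orthogonal too
      e <- .orthogonalizeAgainst(draws[, 2L],
                                 cbind(src[, seq_len(k), drop = FALSE],
                                       tgt[, seq_len(k - 1L), drop = FALSE]))
      t0 <- pairCorrelation * src[, k] +
        sqrt(1 - pairCorrelation^2) * e
      tgt[, k] <- (t0 - mean(t0)) / stats::sd(t0)
    }
    rownames(src) <- rownames(tgt) <- regionIds(atlas)
    colnames(src) <- colnames(tgt) <- paste0("G", seq_len(kStar))
    list(source = src, target = tgt)
  })
}

#' Simulate gene expression as noisy mixtures of planted gradients
#'
#' Every gene is a random linear mixture of all planted maps (both source and
#' target gradients, stacked) plus independent Gaussian noise: gene g =
#' `maps %*% w_g + noise`, with mixing weights `w_g ~ N(0, 1)`. The mixing
#' matrix is returned so ground truth is recoverable. Default G = 763 mirrors
#' the mouse gene panel.
#'
#' @param gradients a [simulateGradients()] result (or any R x K map matrix).
#' @param G number of genes (default 763; must be >= number of maps).
#' @param noiseSd additive noise SD per region per gene (default 0.3; planted
#'   maps have unit variance).
#' @param seed integer seed.
#' @return list: `expression` (raw [ExpressionMatrix-class]), `mixing`
#'   (maps x G weight matrix).
#' @export
simulateExpression <- function(gradients, G = 763L, noiseSd = 0.3, seed = 1L) {
  maps <- if (is.list(gradients)) cbind(gradients$source, gradients$target)
          else as.matrix(gradients)
  Kall <- ncol(maps)
  .stopIfNot(G >= Kall, "G must be >= the number of planted maps")
  .stopIfNot(noiseSd >= 0, "noiseSd must be nonnegative")
  R <- nrow(maps)
  .withSeed(as.integer(seed), {
    W <- matrix(stats::rnorm(Kall * G), Kall, G)
    E <- maps %*% W + matrix(stats::rnorm(R * G, sd = noiseSd), R, G)
    colnames(E) <- sprintf("gene%04d", seq_len(G))
    rownames(E) <- rownames(maps)
    list(expression = ExpressionMatrix(E, "raw"), mixing = W)
  })
}

#' Simulate a connectome from planted gradient pairs
#'
#' For every eligible directed cell (i, j) the squared PI distance
#' `dpi = sum_k w_k (source[i, k] - target[j, k])^2` is computed (optionally
#' with per-component weights) and an edge is drawn with probability
#' `1 / (1 + exp(beta * (dpi - tau)))`: a logistic chemoaffinity rule in which
#' similar source/target PI favours a projection. The intercept `tau` is
#' calibrated by bisection so the expected density matches `targetDensity`;
#' `beta = Inf` gives the hard-threshold limit (exactly the
#' `round(density * n)` smallest-dPI cells connected, deterministically).
#'
#' @param atlas a [RegionAtlas-class].
#' @param gradients a [simulateGradients()] result.
#' @param targetDensity desired fraction of eligible cells connected, in
#'   (0, 1) (default 0.05).
#' @param beta logistic steepness (default 20; `Inf` = hard threshold).
#' @param componentWeights optional per-component weights in the dPI sum
#'   (default: equal). Decreasing weights give the planted components distinct
#'   association strengths.
#' @param seed integer seed.
#' @return A [Connectome-class] (inter-MR eligibility mask from the atlas).
#' @export
simulateConnectome <- function(atlas, gradients, targetDensity = 0.05,
                               beta = 20, componentWeights = NULL, seed = 1L) {
  .stopIfNot(targetDensity > 0 && targetDensity < 1,
             "targetDensity must lie in (0, 1)")
  src <- gradients$source
  tgt <- gradients$target
  K <- ncol(src)
  w <- if (is.null(componentWeights)) rep(1, K) else rep_len(componentWeights, K)
  R <- nRegions(atlas)
  dpi <- matrix(0, R, R)
  for (k in seq_len(K)) dpi <- dpi + w[k] * outer(src[, k], tgt[, k], "-")^2
  conn0 <- Connectome(matrix(0, R, R), atlas)
  mask <- eligibleMask(conn0)
  elig <- which(mask)
  d <- dpi[elig]
  n <- length(d)
  A <- matrix(0, R, R, dimnames = list(regionIds(atlas), regionIds(atlas)))
  if (is.infinite(beta)) {
    nOnes <- round(targetDensity * n)
    .stopIfNot(nOnes >= 1L, "targetDensity too small: no connections")
    A[elig[order(d)[seq_len(nOnes)]]] <- 1
  } else {
    dens <- function(tau) mean(stats::plogis(-beta * (d - tau)))
    lo <- min(d) - 10 / beta; hi <- max(d) + 10 / beta
    .stopIfNot(dens(lo) <= targetDensity && dens(hi) >= targetDensity,
               "target density unreachable under this rule")
    for (it in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (dens(mid) < targetDensity) lo <- mid else hi <- mid
    }
    pConn <- stats::plogis(-beta * (d - (lo + hi) / 2))
    ones <- .withSeed(as.integer(seed), stats::runif(n) < pConn)
    A[elig[ones]] <- 1
  }
  Connectome(A, atlas)
}

#' Simulate a complete chemoaffinity dataset
#'
#' Bundles [simulateAtlas()], [simulateGradients()], [simulateExpression()]
#' and [simulateConnectome()] with internally derived sub-seeds. Defaults are
#' the package's reference study conditions: 213 regions in 13 major regions,
#' 763 genes, 3 planted gradient pairs with decreasing length-scales and
#' decreasing connection-rule weights (so the components have distinct
#' association strengths and are identifiable), noise SD 0.3, edge density
#' 0.05 under a logistic rule with beta = 20.
#'
#' @param R,nMR,G,kStar,noiseSd,density,lengthScale,pairCorrelation,basis,beta
#'   forwarded to the stage generators (see their pages).
#' @param componentWeights connection-rule weights per component (default
#'   `seq(1, 0.5, length.out = kStar)`).
#' @param seed master seed; stage seeds are derived via [deriveSeeds()].
#' @return list of class `"ChemoaffinityData"`: `atlas`, `expression` (raw),
#'   `connectome`, and `truth` (planted maps, mixing weights, parameters).
#' @export
simulateChemoaffinityData <- function(R = 213L, nMR = 13L, G = 763L,
                                      kStar = 3L, noiseSd = 0.3,
                                      density = 0.05,
                                      lengthScale = c(8, 4, 2),
                                      pairCorrelation = 0.5,
                                      basis = "spatial",
                                      beta = 20,
                                      componentWeights =
                                        seq(1, 0.5, length.out = kStar),
                                      seed = 1L) {
  seeds <- deriveSeeds(seed, 4L)
  atlas <- simulateAtlas(R, nMR, seed = seeds[1L])
  grads <- simulateGradients(atlas, kStar, lengthScale = lengthScale,
                             pairCorrelation = pairCorrelation,
                             basis = basis, seed = seeds[2L])
  exprSim <- simulateExpression(grads, G = G, noiseSd = noiseSd,
                                seed = seeds[3L])
  conn <- simulateConnectome(atlas, grads, targetDensity = density,
                             beta = beta, componentWeights = componentWeights,
                             seed = seeds[4L])
  structure(list(atlas = atlas,
                 expression = exprSim$expression,
                 connectome = conn,
                 truth = list(sourceGradients = grads$source,
                              targetGradients = grads$target,
                              mixing = exprSim$mixing,
                              noiseSd = noiseSd,
                              density = density,
                              componentWeights = componentWeights,
                              lengthScale = rep_len(lengthScale, kStar),
                              pairCorrelation = pairCorrelation,
                              basis = basis, beta = beta,
                              seed = as.integer(seed))),
            class = "ChemoaffinityData")
}

#' @export
print.ChemoaffinityData <- function(x, ...) {
  cat(sprintf(
    "ChemoaffinityData: %d regions, %d genes, %d planted gradient pairs, %d connections\n",
    nRegions(x$atlas), ncol(exprValues(x$expression)),
    ncol(x$truth$sourceGradients), connectionCount(x$connectome)))
  invisible(x)
}
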