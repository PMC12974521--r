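## Connectome null ensembles: global, within-block (local), distance-
## constrained and degree-constrained randomization, plus the machinery to
## re-run the whole gradient-extraction pipeline on each replicate.

# Replace the eligible ones of `conn` with `ones` new linear cell positions.
.rebuildFromCells <- function(conn, cells) {
  A <- matrix(0, nRegions(conn), nRegions(conn),
              dimnames = dimnames(adjacency(conn)))
  A[cells] <- 1
  new("Connectome", adjacency = A, eligibleMask = eligibleMask(conn),
      regionIds = regionIds(conn))
}

#' Globally randomized connectome
#'
#' Places the original number of eligible connections uniformly at random on
#' the eligible cells, destroying all structure except the total edge count.
#'
#' @param conn a [Connectome-class].
#' @param seed integer seed.
#' @return A randomized [Connectome-class].
#' @export
globallyRandomize <- function(conn, seed) {
  mask <- eligibleMask(conn)
  nOnes <- sum(adjacency(conn)[mask])
  .stopIfNot(nOnes >= 1L, "connectome has no eligible connections")
  cells <- .withSeed(as.integer(seed), sample(which(mask), nOnes))
  .rebuildFromCells(conn, cells)
}

#' Locally randomized connectome (within MR-pair blocks)
#'
#' For every ordered pair of distinct major regions (A -> B), the connections
#' inside that block are re-placed uniformly at random within the block,
#' preserving each block's connection count exactly. Macroscale (block-level)
#' connectivity is untouched; only the local placement within blocks is
#' disrupted.
#'
#' @param conn a [Connectome-class].
#' @param atlas a [RegionAtlas-class] supplying MR labels.
#' @param seed integer seed.
#' @return A randomized [Connectome-class].
#' @export
locallyRandomize <- function(conn, atlas, seed) {
  mask <- eligibleMask(conn)
  A <- adjacency(conn)
  mr <- as.integer(majorRegion(atlas))
  blockId <- outer(mr, mr, function(a, b) a * (max(mr) + 1L) + b)
  elig <- which(mask)
  .withSeed(as.integer(seed), {
    newCells <- integer(0)
    for (b in unique(blockId[elig])) {
      cellsB <- elig[blockId[elig] == b]
      nB <- sum(A[cellsB])
      if (nB > 0) {
        pick <- if (length(cellsB) == 1L) cellsB else sample(cellsB, nB)
        newCells <- c(newCells, pick)
      }
    }
    .rebuildFromCells(conn, newCells)
  })
}

#' Distance-constrained randomized connectome
#'
#' Eligible cells are stratified into `nBins` quantile bins of interregional
#' distance; within each bin the connections are re-placed uniformly at
#' random, preserving the per-bin connection counts exactly and hence the
#' (binned) connection-distance histogram.
#'
#' @param conn a [Connectome-class].
#' @param dist R x R physical-distance matrix.
#' @param nBins number of quantile bins (default 10).
#' @param seed integer seed.
#' @return A randomized [Connectome-class].
#' @export
distanceConstrainedRandomize <- function(conn, dist, nBins = 10L, seed) {
  .stopIfNot(nBins >= 1L, "nBins must be >= 1")
  mask <- eligibleMask(conn)
  A <- adjacency(conn)
  elig <- which(mask)
  d <- dist[elig]
  br <- unique(stats::quantile(d, probs = seq(0, 1, length.out = nBins + 1L)))
  bin <- cut(d, breaks = br, include.lowest = TRUE, labels = FALSE)
  .withSeed(as.integer(seed), {
    newCells <- integer(0)
    for (b in unique(bin)) {
      cellsB <- elig[bin == b]
      nB <- sum(A[cellsB])
      if (nB > 0) {
        pick <- if (length(cellsB) == 1L) cellsB else sample(cellsB, nB)
        newCells <- c(newCells, pick)
      }
    }
    .rebuildFromCells(conn, newCells)
  })
}

#' Degree-constrained randomized connectome
#'
#' Directed double-edge swaps restricted to the eligible cell universe: two
#' edges (a -> b, c -> d) are rewired to (a -> d, c -> b) when both new cells
#' are eligible, empty, and off-diagonal. Every region's in-degree and
#' out-degree (and the edge count) are preserved exactly. Failed proposals are
#' skipped; by default 10 swap attempts are made per edge.
#'
#' @param conn a [Connectome-class].
#' @param nSwapsPerEdge attempted swaps per edge (default 10).
#' @param seed integer seed.
#' @return A randomized [Connectome-class].
#' @export
degreeConstrainedRandomize <- function(conn, nSwapsPerEdge = 10L, seed) {
  mask <- eligibleMask(conn)
  A <- adjacency(conn) == 1 & mask
  edges <- which(A)
  nE <- length(edges)
  .stopIfNot(nE >= 2L, "at least 2 eligible connections are required")
  R <- nRegions(conn)
  src <- (edges - 1L) %% R + 1L
  tgt <- (edges - 1L) %/% R + 1L
  .withSeed(as.integer(seed), {
    nAttempts <- nSwapsPerEdge * nE
    for (t in seq_len(nAttempts)) {
      ij <- sample.int(nE, 2L)
      a <- src[ij[1L]]; b <- tgt[ij[1L]]
      c_ <- src[ij[2L]]; d <- tgt[ij[2L]]
      if (a == c_ || b == d || a == d || c_ == b) next
      if (A[a, d] || A[c_, b]) next
      if (!mask[a, d] || !mask[c_, b]) next
      A[a, b] <- FALSE; A[c_, d] <- FALSE
      A[a, d] <- TRUE; A[c_, b] <- TRUE
      tgt[ij[1L]] <- d; tgt[ij[2L]] <- b
    }
    .rebuildFromCells(conn, which(A))
  })
}

#' PI-map similarity between a null fit and the reference
#'
#' Absolute cosine similarity between corresponding component maps (component
#' i vs i, separately for source and target side) after centering each map.
#' A zero-variance map yields `NA`.
#'
#' @param mapsNull,mapsRef [PIMaps-class] objects over the same regions with
#'   the same K.
#' @return data.frame with columns `component`, `side`, `similarity`.
#' @export
piSimilarity <- function(mapsNull, mapsRef) {
  .stopIfNot(all(dim(sourceMaps(mapsNull)) == dim(sourceMaps(mapsRef))),
             "PI map dimensions differ")
  K <- ncol(sourceMaps(mapsNull))
  out <- expand.grid(component = seq_len(K), side = c("source", "target"),
                     stringsAsFactors = FALSE)
  out$similarity <- vapply(seq_len(nrow(out)), function(r) {
    k <- out$component[r]
    mN <- if (out$side[r] == "source") sourceMaps(mapsNull)[, k] else targetMaps(mapsNull)[, k]
    mR <- if (out$side[r] == "source") sourceMaps(mapsRef)[, k] else targetMaps(mapsRef)[, k]
    cs <- .centeredCosine(mN, mR)
    if (is.na(cs)) NA_real_ else abs(cs)
  }, numeric(1))
  out
}

# One full fit on a given connectome: split, fit CCA on training connections,
# held-out correlations, held-out reconstruction AUC, projected maps.
.fitPipelineOnce <- function(conn, red, nComponentsCca, kUsed, testFraction,
                             ridge, seed) {
  split <- holdoutSplit(conn, testFraction, seed)
  trainPairs <- buildConnectionPairs(conn, red, cellSubset = split@trainCells)
  wpi <- fitCCA(trainPairs, nComponentsCca, ridge = ridge)
  testPairs <- buildConnectionPairs(conn, red, cellSubset = split@testCells)
  rhoTest <- heldoutCorrelations(wpi, testPairs)
  maps <- projectPI(red, wpi)
  dpi <- computeDPI(maps, kUsed = min(kUsed, nComponentsCca))
  roc <- rocAUC(dpi, conn, orientation = "lower", cellSubset = split@testCells)
  list(wpi = wpi, maps = maps, dpi = dpi, rhoTest = rhoTest,
       auc = roc$auc, split = split)
}

#' Run a null-model ensemble through the full pipeline
#'
#' For each of `M` replicates: randomize the connectome under the chosen null
#' model, rebuild connection pairs, refit CCA with the same configuration,
#' and record the held-out canonical correlations, held-out reconstruction
#' AUC, and PI-map similarity to the reference maps. Replicate seeds are
#' derived deterministically from the master seed (see [deriveSeeds()]).
#' Replicate-level failures are recorded (with `NA` metrics and the error
#' message in the `error` column), never silently dropped.
#'
#' @param conn the original [Connectome-class].
#' @param atlas a [RegionAtlas-class].
#' @param red the [ReducedExpression-class] used by the original fit.
#' @param model one of `"global"`, `"local"`, `"distance"`, `"degree"`.
#' @param M ensemble size (>= 1).
#' @param refMaps reference [PIMaps-class] from the original fit (for the
#'   similarity score); if `NULL`, similarity columns are `NA`.
#' @param nComponentsCca,kUsed,testFraction,ridge pipeline configuration
#'   (identical to the original fit by construction).
#' @param nBins quantile bins for the distance-constrained model.
#' @param nSwapsPerEdge swap attempts per edge for the degree-constrained
#'   model.
#' @param seed master seed.
#' @return data.frame with one row per replicate x component: `replicate`,
#'   `component`, `rho_holdout`, `auc`, `pi_similarity_source`,
#'   `pi_similarity_target`, `error`.
#' @export
runNullEnsemble <- function(conn, atlas, red,
                            model = c("global", "local", "distance", "degree"),
                            M, refMaps = NULL,
                            nComponentsCca = 5L, kUsed = 5L,
                            testFraction = 0.2, ridge = 0,
                            nBins = 10L, nSwapsPerEdge = 10L, seed = 1L) {
  model <- match.arg(model)
  .stopIfNot(M >= 1L, "M must be >= 1")
  dist <- if (model == "distance") physicalDistances(atlas) else NULL
  seeds <- deriveSeeds(seed, 2L * M)
  randSeeds <- seeds[seq_len(M)]
  fitSeeds <- seeds[M + seq_len(M)]
  rows <- vector("list", M)
  for (m in seq_len(M)) {
    rec <- tryCatch({
      connNull <- switch(model,
        global = globallyRandomize(conn, randSeeds[m]),
        local = locallyRandomize(conn, atlas, randSeeds[m]),
        distance = distanceConstrainedRandomize(conn, dist, nBins, randSeeds[m]),
        degree = degreeConstrainedRandomize(conn, nSwapsPerEdge, randSeeds[m]))
      fit <- .fitPipelineOnce(connNull, red, nComponentsCca, kUsed,
                              testFraction, ridge, fitSeeds[m])
      sim <- if (!is.null(refMaps)) piSimilarity(fit$maps, refMaps) else NULL
      K <- length(fit$rhoTest)
      data.frame(
        replicate = m,
        component = seq_len(K),
        rho_holdout = fit$rhoTest,
        auc = fit$auc,
        pi_similarity_source = if (is.null(sim)) NA_real_ else
          sim$similarity[sim$side == "source"],
        pi_similarity_target = if (is.null(sim)) NA_real_ else
          sim$similarity[sim$side == "target"],
        error = NA_character_)
    }, error = function(e) {
      data.frame(replicate = m, component = NA_integer_,
                 rho_holdout = NA_real_, auc = NA_real_,
                 pi_similarity_source = NA_real_,
                 pi_similarity_target = NA_real_,
                 error = conditionMessage(e))
    })
    rows[[m]] <- rec
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  attr(out, "seed") <- as.integer(seed)
  attr(out, "replicate_seeds") <- randSeeds
  out
}
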