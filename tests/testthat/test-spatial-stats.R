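test_that("spatial weights follow their schemes", {
  # 3 collinear points, k = 1: the middle region links to both ends after
  # max-symmetrization
  atlas <- RegionAtlas(c("a", "b", "c"), c("m1", "m1", "m2"),
                       matrix(c(0, 0, 0, 1, 0, 0, 3, 0, 0), 3, 3, byrow = TRUE))
  w <- spatialWeights(atlas, "knn", k = 1L, rowStandardize = FALSE)
  expect_equal(unname(w@W["b", ]), c(1, 0, 1))
  expect_equal(w@W, t(w@W))  # knn-max weights are symmetric
  # row-standardized rows sum to 1
  ws <- spatialWeights(atlas, "knn", k = 1L, rowStandardize = TRUE)
  expect_equal(unname(rowSums(ws@W)), rep(1, 3))
  # inverse-distance weights and the coincident-centroid error
  wd <- spatialWeights(atlas, "invdist", p = 2, rowStandardize = FALSE)
  expect_equal(wd@W["a", "c"], 1 / 9)
  bad <- RegionAtlas(c("a", "b", "c"), c("m", "m", "n"),
                     matrix(0, 3, 3))
  expect_error(spatialWeights(bad, "invdist"), "coincident")
  expect_error(spatialWeights(atlas, "knn", k = 3L), "k must lie")
})

test_that("Moran's I matches its formula and sign expectations", {
  # 6-node path, binary adjacency weights: direct formula oracle
  W <- matrix(0, 6, 6)
  for (i in 1:5) { W[i, i + 1] <- 1; W[i + 1, i] <- 1 }
  alternating <- c(1, -1, 1, -1, 1, -1)
  z <- alternating - mean(alternating)
  oracle <- (6 / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
  expect_equal(moransI(alternating, W), oracle)
  expect_lt(moransI(alternating, W), 0)
  # smooth linear gradient on a 10-node line with knn weights is positive
  atlas <- RegionAtlas(sprintf("r%d", 1:10), rep(c("m1", "m2"), 5),
                       cbind(1:10, 0, 0))
  wk <- spatialWeights(atlas, "knn", k = 2L)
  expect_gt(moransI(1:10, wk), 0.5)
  expect_error(moransI(rep(2, 10), wk), "constant")
  # invariance to adding a constant
  set.seed(31)
  m <- rnorm(10)
  expect_equal(moransI(m, wk), moransI(m + 100, wk), tolerance = 1e-12)
})

test_that("Moran's I permutation mean is -1/(R-1)", {
  set.seed(32)
  atlas <- simulateAtlas(R = 40L, nMR = 4L, seed = 32L)
  w <- spatialWeights(atlas, "knn", k = 6L)
  m <- rnorm(40)
  perms <- replicate(10000, moransI(sample(m), w))
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / 39)), 5 * se)
})

test_that("variogram agrees with an exhaustive pair loop", {
  set.seed(33)
  atlas <- simulateAtlas(R = 30L, nMR = 3L, seed = 33L)
  d <- physicalDistances(atlas)
  m <- rnorm(30)
  vg <- spatialVariogram(m, d, nBins = 6L)
  # brute force: loop over all pairs, assign to the same quantile bins
  ut <- upper.tri(d)
  dv <- d[ut]
  br <- vg$lower
  for (b in seq_len(nrow(vg))) {
    lo <- vg$lower[b]; hi <- vg$upper[b]
    inBin <- if (b == 1) dv >= lo & dv <= hi else dv > lo & dv <= hi
    ii <- row(d)[ut][inBin]; jj <- col(d)[ut][inBin]
    g <- 0
    for (q in seq_along(ii)) g <- g + 0.5 * (m[ii[q]] - m[jj[q]])^2
    expect_equal(vg$gamma[b], g / length(ii), tolerance = 1e-12)
    expect_equal(vg$n_pairs[b], length(ii))
  }
  # constant map has zero semivariance everywhere
  expect_equal(spatialVariogram(rep(1, 30), d, 6L)$gamma, rep(0, 6))
  # invariance to adding a constant
  expect_equal(spatialVariogram(m + 7, d, 6L)$gamma, vg$gamma,
               tolerance = 1e-12)
})

test_that("a pure-noise variogram is flat near the sample variance", {
  set.seed(34)
  atlas <- simulateAtlas(R = 400L, nMR = 8L, seed = 34L)
  d <- physicalDistances(atlas)
  m <- rnorm(400)
  vg <- spatialVariogram(m, d, nBins = 10L)
  expect_true(all(abs(vg$gamma - var(m)) < 0.15 * var(m)))
})

test_that("surrogates preserve mean and variance and honour a degenerate grid", {
  set.seed(35)
  atlas <- simulateAtlas(R = 50L, nMR = 4L, seed = 35L)
  d <- physicalDistances(atlas)
  m <- simulateGradients(atlas, 1L, lengthScale = 3, seed = 36L)$source[, 1]
  su <- makeSurrogates(m, d, M = 25L, seed = 37L)
  expect_equal(colMeans(su$surrogates), rep(mean(m), 25), tolerance = 1e-8)
  expect_equal(apply(su$surrogates, 2, sd), rep(sd(m), 25), tolerance = 1e-8)
  expect_true(all(is.finite(su$relSSE)))
  # determinism
  su2 <- makeSurrogates(m, d, M = 25L, seed = 37L)
  expect_equal(su$surrogates, su2$surrogates)
  # grid with only "no smoothing": surrogates are exact permutations
  su0 <- makeSurrogates(m, d, M = 10L, seed = 38L, bandwidths = 0)
  for (j in 1:10)
    expect_equal(sort(su0$surrogates[, j]), unname(sort(m)), tolerance = 1e-10)
  expect_error(makeSurrogates(rep(1, 50), d, M = 2L, seed = 1L), "constant")
})

test_that("variogram matching preserves smoothness better than permutation", {
  atlas <- simulateAtlas(R = 60L, nMR = 4L, seed = 39L)
  d <- physicalDistances(atlas)
  w <- spatialWeights(atlas, "knn", k = 6L)
  ctx <- surrogateContext(d)
  closer <- vapply(1:8, function(s) {
    m <- simulateGradients(atlas, 1L, lengthScale = 4, seed = 40L + s)$source[, 1]
    i0 <- moransI(m, w)
    su <- makeSurrogates(m, M = 20L, seed = s, context = ctx)
    permCtx <- surrogateContext(d, bandwidths = 0)
    perm <- makeSurrogates(m, M = 20L, seed = s, context = permCtx)
    miSu <- median(apply(su$surrogates, 2, moransI, w = w))
    miPerm <- median(apply(perm$surrogates, 2, moransI, w = w))
    abs(miSu - i0) < abs(miPerm - i0)
  }, logical(1))
  expect_gt(mean(closer), 0.7)
  # surrogate variogram fit at least as good as permutation-only (median)
  m <- simulateGradients(atlas, 1L, lengthScale = 4, seed = 60L)$source[, 1]
  su <- makeSurrogates(m, M = 30L, seed = 3L, context = ctx)
  permCtx <- surrogateContext(d, bandwidths = 0)
  pu <- makeSurrogates(m, M = 30L, seed = 3L, context = permCtx)
  expect_lte(median(su$relSSE), median(pu$relSSE))
})

test_that("PI pair spatial correlation behaves on known inputs", {
  set.seed(41)
  Ps <- matrix(rnorm(200), 100, 2)
  mapsSame <- new("PIMaps", Ps = Ps, Pt = Ps)
  expect_equal(piPairSpatialCorrelation(mapsSame, 1L), 1)
  mapsNeg <- new("PIMaps", Ps = Ps, Pt = -Ps)
  expect_equal(piPairSpatialCorrelation(mapsNeg, 2L), -1)
  mapsInd <- new("PIMaps", Ps = matrix(rnorm(1000), 1000, 1),
                 Pt = matrix(rnorm(1000), 1000, 1))
  expect_lt(abs(piPairSpatialCorrelation(mapsInd, 1L)), 0.1)
  expect_error(piPairSpatialCorrelation(mapsSame, 3L), "component")
})
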