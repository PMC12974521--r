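test_that("all randomizers return valid, mask-respecting connectomes", {
  rc <- randomConnectome(R = 26L, nMR = 3L, density = 0.2, seed = 21L)
  conn <- rc$conn
  d <- physicalDistances(rc$atlas)
  nulls <- list(globallyRandomize(conn, 1L),
                locallyRandomize(conn, rc$atlas, 2L),
                distanceConstrainedRandomize(conn, d, 10L, 3L),
                degreeConstrainedRandomize(conn, 10L, 4L))
  for (cn in nulls) {
    expect_true(validObject(cn))
    expect_true(all(adjacency(cn) %in% c(0, 1)))
    expect_equal(diag(adjacency(cn)), diag(adjacency(conn)))
    expect_equal(sum(adjacency(cn)[!eligibleMask(cn)]), 0)  # mask respected
    expect_equal(connectionCount(cn), connectionCount(conn)) # edges conserved
  }
})

test_that("local randomization conserves every MR-block count exactly", {
  rc <- randomConnectome(R = 30L, nMR = 4L, density = 0.25, seed = 22L)
  conn <- rc$conn
  cn <- locallyRandomize(conn, rc$atlas, 5L)
  mr <- as.integer(majorRegion(rc$atlas))
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    blk <- outer(mr == a, mr == b)
    expect_equal(sum(adjacency(cn)[blk]), sum(adjacency(conn)[blk]))
  }
  # a full block is returned unchanged
  atlas <- toyAtlas()
  A <- matrix(0, 4, 4); A[1, 3] <- 1; A[1, 4] <- 1; A[2, 3] <- 1; A[2, 4] <- 1
  full <- Connectome(A, atlas)
  expect_equal(adjacency(locallyRandomize(full, atlas, 6L)), adjacency(full))
  # an empty connectome block stays empty (zero connections overall errors in
  # global, but local handles empty blocks silently)
  A2 <- matrix(0, 4, 4); A2[1, 3] <- 1
  one <- Connectome(A2, atlas)
  cn2 <- locallyRandomize(one, atlas, 7L)
  expect_equal(connectionCount(cn2), 1)
  expect_equal(sum(adjacency(cn2)[3:4, 1:2]), 0)
})

test_that("local randomization actually relocates edges within blocks", {
  # 2 MRs x 10 regions; one 10x10 block with 5 ones: repeat probability
  # 1 / choose(100, 5) ~ 1.3e-8, so arrangements should differ across seeds
  atlas <- RegionAtlas(sprintf("r%02d", 1:20), rep(c("m1", "m2"), each = 10),
                       matrix(rnorm(60), 20, 3))
  A <- matrix(0, 20, 20)
  set.seed(23); A[cbind(sample(1:10, 5, TRUE), sample(11:20, 5))] <- 1
  conn <- Connectome(A, atlas)
  reps <- vapply(1:50, function(s)
    paste(which(adjacency(locallyRandomize(conn, atlas, s)) == 1),
          collapse = ","), character(1))
  expect_gt(length(unique(reps)), 45)
})

test_that("global randomization is uniform over eligible cells", {
  rc <- randomConnectome(R = 12L, nMR = 2L, density = 0.3, seed = 24L)
  conn <- rc$conn
  elig <- eligibleCells(conn)
  nOnes <- connectionCount(conn)
  M <- 500L
  occ <- numeric(length(elig))
  for (s in seq_len(M)) {
    cn <- globallyRandomize(conn, s)
    occ <- occ + adjacency(cn)[elig]
  }
  p <- nOnes / length(elig)
  # binomial tolerance: 4.5 sd over 500 replicates
  tol <- 4.5 * sqrt(p * (1 - p) / M)
  expect_true(all(abs(occ / M - p) < tol))
})

test_that("distance-constrained nulls conserve per-bin counts and histograms", {
  rc <- randomConnectome(R = 28L, nMR = 3L, density = 0.2, seed = 25L)
  conn <- rc$conn
  d <- physicalDistances(rc$atlas)
  cn <- distanceConstrainedRandomize(conn, d, nBins = 8L, seed = 9L)
  elig <- which(eligibleMask(conn))
  br <- unique(quantile(d[elig], probs = seq(0, 1, length.out = 9)))
  bin <- cut(d[elig], br, include.lowest = TRUE, labels = FALSE)
  for (b in unique(bin)) {
    cellsB <- elig[bin == b]
    expect_equal(sum(adjacency(cn)[cellsB]), sum(adjacency(conn)[cellsB]))
  }
  # binned connection-distance histogram identical before/after
  hBefore <- table(bin[adjacency(conn)[elig] == 1])
  hAfter <- table(bin[adjacency(cn)[elig] == 1])
  expect_equal(hBefore, hAfter)
})

test_that("degree-constrained swaps preserve degree sequences and move edges", {
  rc <- randomConnectome(R = 40L, nMR = 4L, density = 0.15, seed = 26L)
  conn <- rc$conn
  stopifnot(connectionCount(conn) >= 150)
  cn <- degreeConstrainedRandomize(conn, 10L, seed = 10L)
  expect_equal(rowSums(adjacency(cn)), rowSums(adjacency(conn)))  # out-degree
  expect_equal(colSums(adjacency(cn)), colSums(adjacency(conn)))  # in-degree
  expect_equal(connectionCount(cn), connectionCount(conn))
  relocated <- 1 - sum(adjacency(cn) * adjacency(conn)) / connectionCount(conn)
  expect_gt(relocated, 0.5)
})

test_that("PI-map similarity is absolute cosine with index matching", {
  set.seed(27)
  Ps <- matrix(rnorm(40), 20, 2); Pt <- matrix(rnorm(40), 20, 2)
  maps <- new("PIMaps", Ps = Ps, Pt = Pt)
  # identity
  simId <- piSimilarity(maps, maps)
  expect_equal(simId$similarity, rep(1, 4), tolerance = 1e-12)
  # sign flip still gives 1
  flipped <- new("PIMaps", Ps = -Ps, Pt = -Pt)
  expect_equal(piSimilarity(flipped, maps)$similarity, rep(1, 4),
               tolerance = 1e-12)
  # orthogonal centered maps give 0
  v1 <- c(1, -1, 0, 0); v2 <- c(0, 0, 1, -1)
  m1 <- new("PIMaps", Ps = cbind(v1), Pt = cbind(v1))
  m2 <- new("PIMaps", Ps = cbind(v2), Pt = cbind(v2))
  expect_equal(piSimilarity(m1, m2)$similarity, c(0, 0), tolerance = 1e-12)
})

test_that("null ensembles record one row per replicate and component", {
  sim <- simulateChemoaffinityData(R = 60L, nMR = 4L, G = 80L, kStar = 2L,
                                   seed = 28L)
  red <- pcaReduce(zscoreExpression(sim$expression), 20L)
  wpi <- fitCCA(buildConnectionPairs(sim$connectome, red), 3L)
  maps <- projectPI(red, wpi)
  ns <- runNullEnsemble(sim$connectome, sim$atlas, red, "global", M = 3L,
                        refMaps = maps, nComponentsCca = 3L, kUsed = 3L,
                        seed = 29L)
  expect_equal(length(unique(ns$replicate)), 3L)
  expect_equal(nrow(ns), 9L)
  expect_true(all(is.na(ns$error)))
  expect_true(all(ns$auc >= 0 & ns$auc <= 1))
  expect_true(all(ns$pi_similarity_source >= 0 &
                  ns$pi_similarity_source <= 1))
  # determinism under the master seed
  ns2 <- runNullEnsemble(sim$connectome, sim$atlas, red, "global", M = 3L,
                         refMaps = maps, nComponentsCca = 3L, kUsed = 3L,
                         seed = 29L)
  expect_equal(ns$rho_holdout, ns2$rho_holdout)
})

test_that("global randomization collapses planted structure; local spares it", {
  topOrig <- c(); topGlob <- c(); topLoc <- c()
  for (s in 1:5) {
    sim <- simulateChemoaffinityData(R = 100L, nMR = 5L, G = 150L, kStar = 3L,
                                     seed = s + 300L)
    red <- pcaReduce(zscoreExpression(sim$expression), 30L)
    fit <- fitSynthetic(sim, seed = s, nPca = 30L, K = 3L, kUsed = 3L)
    topOrig <- c(topOrig, fit$rhoTest[1])
    g <- runNullEnsemble(sim$connectome, sim$atlas, red, "global", M = 2L,
                         nComponentsCca = 3L, kUsed = 3L, seed = s)
    topGlob <- c(topGlob, g$rho_holdout[g$component == 1])
    l <- runNullEnsemble(sim$connectome, sim$atlas, red, "local", M = 2L,
                         nComponentsCca = 3L, kUsed = 3L, seed = s)
    topLoc <- c(topLoc, l$rho_holdout[l$component == 1])
  }
  expect_lt(median(topGlob), median(topOrig))
  # block-level structure survives local randomization
  expect_gt(median(topLoc), median(topGlob))
})
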