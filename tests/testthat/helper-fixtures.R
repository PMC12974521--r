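# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

# 4-region, 2-MR toy atlas. Distances: A1-(0,0,0), A2-(1,0,0), B1-(0,1,0),
# B2-(3,4,0).
toyAtlas <- function() {
  RegionAtlas(c("A1", "A2", "B1", "B2"),
              c("MRa", "MRa", "MRb", "MRb"),
              matrix(c(0, 0, 0,
                       1, 0, 0,
                       0, 1, 0,
                       3, 4, 0), 4, 3, byrow = TRUE))
}

# Toy connectome on toyAtlas with ones at (1,3), (2,4), (1,2); (1,2) is
# within-MR, so 2 eligible connections.
toyConnectome <- function(atlas = toyAtlas()) {
  A <- matrix(0, 4, 4)
  A[1, 3] <- 1; A[2, 4] <- 1; A[1, 2] <- 1
  Connectome(A, atlas)
}

# Random raw ExpressionMatrix over an atlas.
randomExpression <- function(atlas, G = 6L, seed = 1L) {
  set.seed(seed)
  R <- nRegions(atlas)
  v <- matrix(rnorm(R * G, mean = 5, sd = 2), R, G,
              dimnames = list(regionIds(atlas), sprintf("gene%02d", seq_len(G))))
  ExpressionMatrix(v)
}

# A larger random atlas + connectome for statistical checks.
randomConnectome <- function(R = 30L, nMR = 3L, density = 0.15, seed = 1L) {
  atlas <- simulateAtlas(R = R, nMR = nMR, seed = seed)
  conn0 <- Connectome(matrix(0, R, R), atlas)
  set.seed(seed + 1L)
  elig <- which(eligibleMask(conn0))
  ones <- sample(elig, max(2L, round(density * length(elig))))
  A <- matrix(0, R, R)
  A[ones] <- 1
  list(atlas = atlas, conn = Connectome(A, atlas))
}

# --- independent oracles -------------------------------------------------

# CCA by direct solution of the generalized eigenproblem
# Sss^{-1} Sst Stt^{-1} Sts a = rho^2 a (no whitening, no SVD).
ccaOracle <- function(Xs, Xt, K) {
  n <- nrow(Xs)
  Xsc <- scale(Xs, scale = FALSE)
  Xtc <- scale(Xt, scale = FALSE)
  Sss <- crossprod(Xsc) / (n - 1)
  Stt <- crossprod(Xtc) / (n - 1)
  Sst <- crossprod(Xsc, Xtc) / (n - 1)
  M <- solve(Sss, Sst %*% solve(Stt, t(Sst)))
  eg <- eigen(M)
  ord <- order(Re(eg$values), decreasing = TRUE)
  rho <- sqrt(pmax(Re(eg$values[ord]), 0))[seq_len(K)]
  A <- Re(eg$vectors[, ord[seq_len(K)], drop = FALSE])
  # normalize each vector to unit variance of the source variate
  for (k in seq_len(K)) {
    a <- A[, k]
    A[, k] <- a / sqrt(drop(crossprod(a, Sss %*% a)))
  }
  list(rho = rho, A = A)
}

# AUC by exhaustive enumeration of positive-negative pairs, tie credit 0.5.
aucOracle <- function(scorePos, scoreNeg, lowerIsConnected = TRUE) {
  tot <- 0
  for (p in scorePos) for (q in scoreNeg) {
    better <- if (lowerIsConnected) p < q else p > q
    tot <- tot + better + 0.5 * (p == q)
  }
  tot / (length(scorePos) * length(scoreNeg))
}

# Mean |cosine| (centered) under the best one-to-one component matching,
# by exhaustive search over permutations (K is small).
bestMatchCosine <- function(A, B) {
  K <- ncol(A)
  C <- abs(stats::cor(A, B))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  max(vapply(perms(seq_len(K)),
             function(p) mean(C[cbind(seq_len(K), p)]), numeric(1)))
}

# One full synthetic fit, shared by several statistical tests.
fitSynthetic <- function(sim, seed, nPca = 50L, K = 5L, kUsed = 5L,
                         testFraction = 0.2) {
  exprZ <- zscoreExpression(sim$expression)
  red <- pcaReduce(exprZ, min(nPca, nRegions(sim$atlas) - 1L,
                              ncol(exprValues(exprZ))))
  split <- holdoutSplit(sim$connectome, testFraction, seed = seed)
  wpi <- fitCCA(buildConnectionPairs(sim$connectome, red, split@trainCells), K)
  testPairs <- buildConnectionPairs(sim$connectome, red, split@testCells)
  maps <- projectPI(red, wpi)
  dpi <- computeDPI(maps, kUsed = min(kUsed, K))
  list(red = red, split = split, wpi = wpi, maps = maps, dpi = dpi,
       rhoTest = heldoutCorrelations(wpi, testPairs),
       auc = rocAUC(dpi, sim$connectome, "lower", split@testCells)$auc)
}
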