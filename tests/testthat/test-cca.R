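makePairs <- function(Xs, Xt) {
  new("ConnectionPairs",
      sourceIdx = seq_len(nrow(Xs)), targetIdx = seq_len(nrow(Xs)),
      Xs = Xs, Xt = Xt)
}

test_that("identical full-rank inputs give canonical correlations of 1", {
  set.seed(1)
  X <- matrix(rnorm(60 * 4), 60, 4)
  wpi <- fitCCA(makePairs(X, X), 4L)
  expect_equal(canonicalCorrelations(wpi), rep(1, 4), tolerance = 1e-10)
})

test_that("CCA matches the generalized-eigenproblem oracle on random instances", {
  set.seed(99)
  for (i in 1:12) {
    D <- sample(2:6, 1)
    N <- 50L
    Xs <- matrix(rnorm(N * D), N, D)
    Xt <- 0.5 * Xs[, sample(D)] + matrix(rnorm(N * D), N, D)
    wpi <- fitCCA(makePairs(Xs, Xt), D)
    orc <- ccaOracle(Xs, Xt, D)
    expect_equal(canonicalCorrelations(wpi), orc$rho, tolerance = 1e-8)
    # weights match up to sign after unit-variance normalization
    for (k in seq_len(D)) {
      a <- sourceWeights(wpi)[, k]
      ao <- orc$A[, k]
      expect_lt(min(max(abs(a - ao)), max(abs(a + ao))), 1e-6)
    }
  }
})

test_that("training variates are standardized and mutually orthogonal", {
  set.seed(3)
  N <- 200L; D <- 6L
  Xs <- matrix(rnorm(N * D), N, D)
  Xt <- 0.4 * Xs + matrix(rnorm(N * D), N, D)
  wpi <- fitCCA(makePairs(Xs, Xt), 4L)
  Us <- sweep(Xs, 2, wpi@meanS, "-") %*% sourceWeights(wpi)
  Ut <- sweep(Xt, 2, wpi@meanT, "-") %*% targetWeights(wpi)
  expect_equal(unname(diag(cov(Us))), rep(1, 4), tolerance = 1e-6)
  expect_equal(unname(diag(cov(Ut))), rep(1, 4), tolerance = 1e-6)
  expect_lt(max(abs(cov(Us)[upper.tri(diag(4))])), 1e-6)
  expect_lt(max(abs(cov(Ut)[upper.tri(diag(4))])), 1e-6)
  # training rho equals the variate correlation
  expect_equal(unname(diag(cor(Us, Ut))), canonicalCorrelations(wpi),
               tolerance = 1e-10)
})

test_that("canonical correlations are invariant to invertible remixing", {
  set.seed(4)
  N <- 150L; D <- 5L
  Xs <- matrix(rnorm(N * D), N, D)
  Xt <- 0.6 * Xs + matrix(rnorm(N * D), N, D)
  rho1 <- canonicalCorrelations(fitCCA(makePairs(Xs, Xt), D))
  Tm <- matrix(rnorm(D * D), D, D) + diag(D)  # invertible a.s.
  rho2 <- canonicalCorrelations(fitCCA(makePairs(Xs %*% Tm, Xt), D))
  expect_equal(rho1, rho2, tolerance = 1e-8)
})

test_that("independent inputs stay below the shuffled-pairing null", {
  set.seed(5)
  N <- 2000L; D <- 5L
  Xs <- matrix(rnorm(N * D), N, D)
  Xt <- matrix(rnorm(N * D), N, D)
  rhoTop <- canonicalCorrelations(fitCCA(makePairs(Xs, Xt), 1L))[1]
  nullTop <- replicate(200, {
    canonicalCorrelations(fitCCA(makePairs(Xs, Xt[sample(N), ]), 1L))[1]
  })
  # the observed draw is itself a sample from the null: it must not exceed
  # the upper null quantile
  expect_lt(rhoTop, quantile(nullTop, 0.99) + 0.05)
  expect_lt(rhoTop, 0.2)
})

test_that("degenerate and small-N inputs are rejected helpfully", {
  set.seed(6)
  X <- matrix(rnorm(10 * 4), 10, 4)
  Xdef <- cbind(X, X[, 1])  # rank-deficient
  expect_error(fitCCA(makePairs(Xdef, cbind(X, rnorm(10))), 2L), "ridge")
  expect_warning(fitCCA(makePairs(X[1:3, ], X[1:3, ]), 1L, ridge = 0.1),
                 "degenerate")
  expect_error(suppressWarnings(fitCCA(makePairs(X[1:3, ], X[1:3, ]), 1L)),
               "ridge")
})

test_that("PI projection respects centering, consistency and homogeneity", {
  set.seed(7)
  N <- 80L; D <- 4L
  Xs <- matrix(rnorm(N * D), N, D)
  Xt <- 0.7 * Xs + matrix(rnorm(N * D), N, D)
  pairs <- makePairs(Xs, Xt)
  wpi <- fitCCA(pairs, 3L)
  sc <- rbind(wpi@meanS, Xs)
  rownames(sc) <- c("atMean", sprintf("r%03d", seq_len(N)))
  colnames(sc) <- paste0("PC", 1:D)
  red <- new("ReducedExpression", scores = sc,
             loadings = qr.Q(qr(matrix(rnorm(D * D), D))),
             explainedVarianceRatio = rep(1 / D, D),
             geneMeans = numeric(), geneSds = numeric())
  maps <- projectPI(red, wpi)
  # region at the training mean has zero source PI
  expect_equal(unname(sourceMaps(maps)["atMean", ]), rep(0, 3),
               tolerance = 1e-12)
  # projected source PI of training source regions equals the training variate
  Us <- sweep(Xs, 2, wpi@meanS, "-") %*% sourceWeights(wpi)
  expect_equal(unname(sourceMaps(maps)[-1, ]), unname(Us), tolerance = 1e-12)
  # doubling A doubles Ps
  wpi2 <- wpi; wpi2@A <- 2 * wpi@A
  expect_equal(sourceMaps(projectPI(red, wpi2)), 2 * sourceMaps(maps),
               tolerance = 1e-12)
  # dimension mismatch is an error
  redBad <- new("ReducedExpression", scores = sc[, 1:3],
                loadings = qr.Q(qr(matrix(rnorm(D * D), D)))[, 1:3],
                explainedVarianceRatio = rep(1 / 3, 3),
                geneMeans = numeric(), geneSds = numeric())
  expect_error(projectPI(redBad, wpi), "D = ")
})

test_that("held-out correlations reuse frozen training weights", {
  set.seed(8)
  N <- 120L; D <- 5L
  Xs <- matrix(rnorm(N * D), N, D)
  Xt <- 0.8 * Xs + matrix(rnorm(N * D), N, D)
  pairs <- makePairs(Xs, Xt)
  wpi <- fitCCA(pairs, 3L)
  # degenerate reuse: test set = training set reproduces training rho
  expect_equal(heldoutCorrelations(wpi, pairs), canonicalCorrelations(wpi),
               tolerance = 1e-10)
  # 3 test pairs accepted, 2 rejected
  expect_silent(heldoutCorrelations(wpi, makePairs(Xs[1:3, ], Xt[1:3, ])))
  expect_error(heldoutCorrelations(wpi, makePairs(Xs[1:2, ], Xt[1:2, ])),
               "3 test pairs")
  # zero-variance variate reported as NA, not 0
  XsC <- matrix(1, 5, D); XtC <- matrix(rnorm(5 * D), 5, D)
  expect_true(all(is.na(heldoutCorrelations(wpi, makePairs(XsC, XtC)))))
})

test_that("planted gradient pairs beat unplanted components out of sample", {
  hi <- c(); lo <- c()
  for (s in 1:5) {
    sim <- simulateChemoaffinityData(R = 100L, nMR = 5L, G = 150L,
                                     kStar = 3L, seed = s)
    fit <- fitSynthetic(sim, seed = s + 50L, nPca = 30L, K = 4L)
    hi <- c(hi, fit$rhoTest[1:3])
    lo <- c(lo, fit$rhoTest[4])
  }
  expect_gt(min(hi), max(lo))
})
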