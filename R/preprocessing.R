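## Expression normalization, PCA reduction, paired-vector construction and
## hold-out splitting of the connectome cells.

#' Z-score expression per gene
#'
#' Centers and scales each gene column to mean 0 and unit sample standard
#' deviation (denominator n - 1) across regions. Constant genes are an error:
#' they carry no spatial pattern and would produce undefined scores — drop them
#' before normalizing.
#'
#' @param expr a raw [ExpressionMatrix-class].
#' @return A z-scored [ExpressionMatrix-class] carrying the per-gene means and
#'   standard deviations used.
#' @export
zscoreExpression <- function(expr) {
  .stopIfNot(normalizationState(expr) == "raw",
             "expression is already normalized (state '%s')", normalizationState(expr))
  v <- exprValues(expr)
  mu <- colMeans(v)
  sd <- apply(v, 2L, stats::sd)
  const <- sd == 0 | !is.finite(sd)
  .stopIfNot(!any(const), "constant gene column(s): %s",
             paste(colnames(v)[const], collapse = ", "))
  z <- sweep(sweep(v, 2L, mu, "-"), 2L, sd, "/")
  ExpressionMatrix(z, "zscored", geneMeans = mu, geneSds = sd)
}

#' Reduce expression to D principal components
#'
#' Singular value decomposition of the column-centered, z-scored expression
#' matrix. Scores are the projections of regions onto the top `nComponents`
#' right singular directions; the explained-variance ratio is relative to the
#' total variance of all components. Each component's sign is fixed so that
#' its largest-magnitude gene loading is positive, making results reproducible
#' across platforms.
#'
#' @param expr a z-scored [ExpressionMatrix-class].
#' @param nComponents number of components, `1 <= D <= min(R - 1, G)`.
#' @return A [ReducedExpression-class].
#' @export
pcaReduce <- function(expr, nComponents) {
  .stopIfNot(normalizationState(expr) == "zscored",
             "expression must be z-scored before PCA")
  v <- exprValues(expr)
  R <- nrow(v); G <- ncol(v)
  dmax <- min(R - 1L, G)
  .stopIfNot(nComponents >= 1L && nComponents <= dmax,
             "nComponents must lie in [1, %d] (got %s)", dmax, nComponents)
  nComponents <- as.integer(nComponents)
  vc <- sweep(v, 2L, colMeans(v), "-")
  sv <- svd(vc)
  total <- sum(sv$d^2)
  ratio <- (sv$d^2 / total)[seq_len(nComponents)]
  load <- sv$v[, seq_len(nComponents), drop = FALSE]
  sc <- sv$u[, seq_len(nComponents), drop = FALSE] %*%
    diag(sv$d[seq_len(nComponents)], nComponents)
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(nComponents)) {
    i0 <- which.max(abs(load[, j]))
    if (load[i0, j] < 0) {
      load[, j] <- -load[, j]
      sc[, j] <- -sc[, j]
    }
  }
  rownames(sc) <- rownames(v)
  rownames(load) <- colnames(v)
  colnames(sc) <- colnames(load) <- paste0("PC", seq_len(nComponents))
  new("ReducedExpression", scores = sc, loadings = load,
      explainedVarianceRatio = ratio,
      geneMeans = expr@geneMeans, geneSds = expr@geneSds)
}

#' Build paired source/target vectors per connection
#'
#' One row per eligible connected cell (optionally restricted to a cell
#' subset), enumerated row-major (by source region, then target region). Row n
#' of `Xs` is a copy of the reduced-expression score row of the n-th
#' connection's source region; `Xt` likewise for its target.
#'
#' @param conn a [Connectome-class].
#' @param red a [ReducedExpression-class] sharing the atlas region order.
#' @param cellSubset optional integer vector of linear cell indices (must be a
#'   subset of the eligible cells); defaults to all eligible cells.
#' @return A [ConnectionPairs-class].
#' @export
buildConnectionPairs <- function(conn, red, cellSubset = NULL) {
  sc <- scores(red)
  .stopIfNot(nrow(sc) == nRegions(conn),
             "connectome and reduced expression disagree on region count")
  mask <- eligibleMask(conn)
  if (!is.null(cellSubset)) {
    .stopIfNot(all(cellSubset %in% which(mask)),
               "cellSubset contains ineligible cells")
    keep <- array(FALSE, dim(mask))
    keep[cellSubset] <- TRUE
    mask <- mask & keep
  }
  cells <- .cellsRowMajor(mask & adjacency(conn) == 1)
  .stopIfNot(length(cells) >= 1L, "no eligible connections after filtering")
  ai <- arrayInd(cells, dim(mask))
  new("ConnectionPairs",
      sourceIdx = as.integer(ai[, 1L]),
      targetIdx = as.integer(ai[, 2L]),
      Xs = sc[ai[, 1L], , drop = FALSE],
      Xt = sc[ai[, 2L], , drop = FALSE])
}

#' Split eligible cells into training and test sets
#'
#' Partitions the eligible directed cells (connected and unconnected alike)
#' uniformly at random: `floor(testFraction * n)` cells go to the test side,
#' the rest to training. Reproducible under `seed`.
#'
#' @param conn a [Connectome-class].
#' @param testFraction proportion in (0, 1) assigned to the test side.
#' @param seed integer seed.
#' @return A [HoldoutSplit-class].
#' @export
holdoutSplit <- function(conn, testFraction, seed) {
  .stopIfNot(testFraction > 0 && testFraction < 1,
             "testFraction must lie strictly between 0 and 1")
  cells <- eligibleCells(conn)
  n <- length(cells)
  nTest <- floor(testFraction * n)
  .stopIfNot(nTest >= 1L && nTest < n,
             "testFraction %g yields an empty train or test side (n = %d)",
             testFraction, n)
  test <- .withSeed(as.integer(seed), sort(sample(cells, nTest)))
  new("HoldoutSplit",
      trainCells = setdiff(cells, test),
      testCells = as.integer(test),
      seed = as.integer(seed),
      testFraction = testFraction)
}
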