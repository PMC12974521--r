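## Canonical correlation analysis on paired source/target reduced-expression
## vectors: the core estimator of wiring positional information.

#' Fit CCA on connection pairs
#'
#' Finds successive weight-vector pairs (a, b) maximizing the Pearson
#' correlation of the source variate `Xs %*% a` with the target variate
#' `Xt %*% b` over the observed connections, subject to unit variance and
#' orthogonality to earlier variates of the same side. Implemented by whitening
#' both within-set covariances (optionally ridge-regularized) and taking the
#' singular value decomposition of the whitened cross-covariance.
#'
#' Signs are fixed deterministically: each pair (a, b) is jointly flipped so
#' that the source variate correlates positively with the first reduced
#' dimension (ties broken toward a positive first source weight).
#'
#' @param pairs a [ConnectionPairs-class] (training pairs).
#' @param nComponents number of canonical pairs K, `1 <= K <= D`.
#' @param ridge nonnegative ridge added to both within-set covariance
#'   diagonals before whitening; default 0 (plain CCA, appropriate when
#'   N >> D).
#' @return A [WiringPI-class].
#' @export
fitCCA <- function(pairs, nComponents, ridge = 0) {
  Xs <- pairs@Xs
  Xt <- pairs@Xt
  N <- nrow(Xs); D <- ncol(Xs)
  .stopIfNot(N >= 2L, "at least 2 connection pairs are required")
  .stopIfNot(nComponents >= 1L && nComponents <= D,
             "nComponents must lie in [1, %d]", D)
  .stopIfNot(ridge >= 0, "ridge must be nonnegative")
  if (N <= D) {
    warning(sprintf("N = %d pairs <= D = %d dimensions; CCA is degenerate", N, D))
    .stopIfNot(ridge > 0, "with N <= D a positive ridge is required")
  }
  K <- as.integer(nComponents)
  meanS <- colMeans(Xs)
  meanT <- colMeans(Xt)
  Xsc <- sweep(Xs, 2L, meanS, "-")
  Xtc <- sweep(Xt, 2L, meanT, "-")
  Sss <- crossprod(Xsc) / (N - 1) + diag(ridge, D)
  Stt <- crossprod(Xtc) / (N - 1) + diag(ridge, D)
  Sst <- crossprod(Xsc, Xtc) / (N - 1)
  Ws <- .invSqrtm(Sss, "source", ridge)
  Wt <- .invSqrtm(Stt, "target", ridge)
  sv <- svd(Ws %*% Sst %*% Wt)
  rho <- pmin(pmax(sv$d[seq_len(K)], 0), 1)
  A <- Ws %*% sv$u[, seq_len(K), drop = FALSE]
  B <- Wt %*% sv$v[, seq_len(K), drop = FALSE]
  # joint sign convention per component
  for (k in seq_len(K)) {
    us <- Xsc %*% A[, k]
    anchor <- sum(us * Xsc[, 1L])
    s <- if (abs(anchor) > 1e-12) sign(anchor) else if (A[1L, k] < 0) -1 else 1
    if (s < 0) {
      A[, k] <- -A[, k]
      B[, k] <- -B[, k]
    }
  }
  colnames(A) <- colnames(B) <- paste0("CC", seq_len(K))
  new("WiringPI", A = A, B = B, rho = rho,
      meanS = meanS, meanT = meanT, ridge = ridge)
}

#' Project all regions onto wiring-PI gradient maps
#'
#' Every region — connected or not — receives K source-PI and K target-PI
#' values: its reduced-expression score row, centered with the training-pair
#' means frozen in the fit, projected through the weight columns.
#'
#' @param red a [ReducedExpression-class] with the same dimensionality D.
#' @param wpi a [WiringPI-class].
#' @return A [PIMaps-class] with R x K matrices `Ps` and `Pt`.
#' @export
projectPI <- function(red, wpi) {
  sc <- scores(red)
  .stopIfNot(ncol(sc) == nrow(wpi@A),
             "reduced expression has D = %d but weights expect D = %d",
             ncol(sc), nrow(wpi@A))
  Ps <- sweep(sc, 2L, wpi@meanS, "-") %*% wpi@A
  Pt <- sweep(sc, 2L, wpi@meanT, "-") %*% wpi@B
  rownames(Ps) <- rownames(Pt) <- rownames(sc)
  new("PIMaps", Ps = Ps, Pt = Pt)
}

#' Held-out canonical correlations
#'
#' Pearson correlation, per component, of the source and target variates of
#' test pairs computed with training weights and training centering constants.
#' A component whose variate is constant on the test pairs is reported as
#' `NA` (undefined), never as 0.
#'
#' @param wpi a [WiringPI-class] fitted on training pairs.
#' @param testPairs a [ConnectionPairs-class] disjoint from training.
#' @return numeric vector of K correlations (possibly `NA`).
#' @export
heldoutCorrelations <- function(wpi, testPairs) {
  .stopIfNot(length(testPairs@sourceIdx) >= 3L,
             "at least 3 test pairs are required")
  Us <- sweep(testPairs@Xs, 2L, wpi@meanS, "-") %*% wpi@A
  Ut <- sweep(testPairs@Xt, 2L, wpi@meanT, "-") %*% wpi@B
  vapply(seq_along(wpi@rho),
         function(k) .safeCor(Us[, k], Ut[, k]), numeric(1))
}
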