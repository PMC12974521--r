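## Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never clobber user randomness.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive per-replicate seeds from a master seed
#'
#' Deterministic counter-based derivation: the master seed initializes a
#' stream from which `n` distinct 31-bit seeds are drawn. Recorded in run
#' manifests so any replicate can be re-run in isolation.
#'
#' @param seed master integer seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
deriveSeeds <- function(seed, n) {
  .withSeed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Linear (column-major) indices of TRUE cells in `mask`, ordered row-major
# (by source region, then target region) for deterministic enumeration.
.cellsRowMajor <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(integer())
  ai <- arrayInd(idx, dim(mask))
  idx[order(ai[, 1L], ai[, 2L])]
}

#' Eligible cells of a connectome
#'
#' Linear indices (column-major, as returned by [which()]) of the eligible
#' directed region pairs, enumerated row-major (source, then target).
#'
#' @param conn a [Connectome-class].
#' @return integer vector of linear cell indices.
#' @export
eligibleCells <- function(conn) {
  .cellsRowMajor(eligibleMask(conn))
}

#' Number of eligible connections
#'
#' @param conn a [Connectome-class].
#' @return count of ones on eligible cells.
#' @export
connectionCount <- function(conn) {
  sum(adjacency(conn)[eligibleMask(conn)])
}

# Pearson correlation returning NA (undefined marker) instead of erroring on
# zero-variance input.
.safeCor <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

# Cosine similarity of two centered vectors; NA if either has zero norm.
.centeredCosine <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

# Symmetric inverse square root of a positive definite matrix.
.invSqrtm <- function(S, label, ridge) {
  eg <- eigen(S, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  if (any(eg$values < tol)) {
    stop(sprintf(paste0(
      "%s within-set covariance is rank-deficient; ",
      "refit with ridge > 0 (current ridge = %g)"), label, ridge))
  }
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

.stopIfNot <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
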