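## Gene screening: cosine similarity of spatial expression patterns to the
## wiring-PI gradient maps, with surrogate-based significance.

#' Cosine similarity between two regional maps
#'
#' Both maps are centered first, so the score equals the Pearson correlation
#' and is invariant to affine rescaling of either map; the sign is retained
#' (genes may mirror a gradient with inverted sign).
#'
#' @param geneMap,piMap numeric vectors of R region values.
#' @return scalar in `[-1, 1]`, or `NA` if either map is constant.
#' @export
cosineSimilarityMap <- function(geneMap, piMap) {
  .stopIfNot(length(geneMap) == length(piMap), "map lengths differ")
  .centeredCosine(geneMap, piMap)
}

# Centered, unit-norm columns; zero-norm columns become NA.
.unitColumns <- function(M) {
  M <- sweep(M, 2L, colMeans(M), "-")
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- NA_real_
  sweep(M, 2L, nrm, "/")
}

#' Screen genes against wiring-PI gradient maps
#'
#' For every gene, component and side (source/target): the observed centered
#' cosine similarity between the gene's spatial expression pattern and the PI
#' gradient map, and a two-sided p-value from `M` spatially-constrained
#' surrogates of the gene map (variogram-matched, see [makeSurrogates()]):
#' `p = (1 + #{|sim_surrogate| >= |sim_observed|}) / (1 + M)`, so the smallest
#' attainable p is `1 / (M + 1)`. Surrogates randomize the gene map; the PI
#' maps are held fixed. Constant gene maps are skipped with a warning.
#'
#' A Benjamini-Hochberg adjusted column (`p_bh`, per side x component across
#' genes) is appended as a convenience; the primary `p` column is the raw
#' surrogate p-value.
#'
#' @param expr a z-scored [ExpressionMatrix-class].
#' @param maps a [PIMaps-class].
#' @param dist R x R distance matrix (ignored when `context` is given).
#' @param M surrogates per gene (>= 99; default 999, giving a p floor of
#'   0.001).
#' @param seed master seed; per-gene seeds are derived deterministically.
#' @param context optional precomputed [surrogateContext()].
#' @return data.frame of class `"GeneScreenResult"` with columns `gene`,
#'   `side`, `component`, `similarity`, `p`, `p_bh`, sorted by
#'   `|similarity|` descending within each side x component.
#' @export
screenGenes <- function(expr, maps, dist = NULL, M = 999L, seed = 1L,
                        context = NULL) {
  .stopIfNot(M >= 99L, "M must be >= 99 for usable p-value resolution")
  .stopIfNot(normalizationState(expr) == "zscored",
             "expression must be z-scored before screening")
  v <- exprValues(expr)
  if (is.null(context)) {
    .stopIfNot(!is.null(dist), "either dist or context must be supplied")
    context <- surrogateContext(dist)
  }
  K <- ncol(sourceMaps(maps))
  P <- cbind(sourceMaps(maps), targetMaps(maps))     # R x 2K
  Pu <- .unitColumns(P)
  genes <- colnames(v)
  sds <- apply(v, 2L, stats::sd)
  usable <- sds > 0
  if (any(!usable))
    warning(sprintf("skipping constant gene map(s): %s",
                    paste(genes[!usable], collapse = ", ")))
  geneSeeds <- deriveSeeds(seed, ncol(v))
  recs <- vector("list", sum(usable))
  r <- 0L
  for (g in which(usable)) {
    gu <- .unitColumns(v[, g, drop = FALSE])[, 1L]
    simObs <- drop(crossprod(gu, Pu))                 # length 2K
    surr <- makeSurrogates(v[, g], M = M, seed = geneSeeds[g],
                           context = context)
    Su <- .unitColumns(surr$surrogates)
    simSurr <- abs(crossprod(Su, Pu))                 # M x 2K
    exceed <- colSums(sweep(simSurr, 2L, abs(simObs), ">="))
    p <- (1 + exceed) / (1 + M)
    r <- r + 1L
    recs[[r]] <- data.frame(
      gene = genes[g],
      side = rep(c("source", "target"), each = K),
      component = rep(seq_len(K), 2L),
      similarity = simObs,
      p = p)
  }
  out <- do.call(rbind, recs)
  out$p_bh <- NA_real_
  for (sd_ in c("source", "target")) for (k in seq_len(K)) {
    sel <- out$side == sd_ & out$component == k
    out$p_bh[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out <- out[order(out$side, out$component, -abs(out$similarity)), ]
  rownames(out) <- NULL
  class(out) <- c("GeneScreenResult", "data.frame")
  out
}

#' Top-ranked genes per component and side
#'
#' @param result a [screenGenes()] result.
#' @param n number of genes per side x component (default 10).
#' @return data.frame with an added `rank` column, at most `n` rows per
#'   side x component.
#' @export
topGenes <- function(result, n = 10L) {
  sp <- split(seq_len(nrow(result)),
              list(result$side, result$component), drop = TRUE)
  keep <- unlist(lapply(sp, function(ix) {
    ix <- ix[order(-abs(result$similarity[ix]))]
    utils::head(ix, n)
  }), use.names = FALSE)
  out <- result[sort(keep), , drop = FALSE]
  out <- out[order(out$component, out$side, -abs(out$similarity)), ]
  out$rank <- stats::ave(seq_len(nrow(out)),
                         out$side, out$component, FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Dependence of similarity on spatial autocorrelation
#'
#' Diagnostic for the concern that genes resembling a PI gradient are selected
#' merely for being spatially smooth: the Pearson correlation, across genes,
#' between each gene's Moran's I and its maximum absolute similarity over all
#' components and sides. Near-zero values indicate no such dependency.
#'
#' @param expr a z-scored [ExpressionMatrix-class] (>= 10 genes).
#' @param maps a [PIMaps-class].
#' @param w a [SpatialWeights-class].
#' @return scalar correlation (`NA` if degenerate).
#' @export
autocorrelationDependency <- function(expr, maps, w) {
  v <- exprValues(expr)
  .stopIfNot(ncol(v) >= 10L, "at least 10 genes are required")
  Pu <- .unitColumns(cbind(sourceMaps(maps), targetMaps(maps)))
  Vu <- .unitColumns(v)
  maxSim <- apply(abs(crossprod(Vu, Pu)), 1L, max)
  mor <- apply(v, 2L, function(g) {
    if (stats::sd(g) == 0) NA_real_ else moransI(g, w)
  })
  keep <- is.finite(maxSim) & is.finite(mor)
  .safeCor(mor[keep], maxSim[keep])
}
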