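## Expression-randomization control: randomize every gene map while preserving
## its spatial autocorrelation, then re-run the full pipeline on the unchanged
## connectome.

#' Randomize expression preserving spatial autocorrelation
#'
#' Replaces each gene column with one variogram-matched surrogate of itself
#' (see [makeSurrogates()]); per-gene mean and variance are preserved by the
#' surrogate rescaling. Genes are randomized independently, so cross-gene
#' covariance is intentionally destroyed. Constant genes are passed through
#' unchanged with a warning.
#'
#' @param expr a z-scored [ExpressionMatrix-class].
#' @param dist R x R distance matrix (ignored when `context` is given).
#' @param seed integer master seed.
#' @param context optional precomputed [surrogateContext()].
#' @return An [ExpressionMatrix-class] of the same shape, state `"zscored"`.
#' @export
randomizeExpression <- function(expr, dist = NULL, seed = 1L, context = NULL) {
  .stopIfNot(normalizationState(expr) == "zscored",
             "expression must be z-scored before spatial randomization")
  v <- exprValues(expr)
  if (is.null(context)) {
    .stopIfNot(!is.null(dist), "either dist or context must be supplied")
    context <- surrogateContext(dist)
  }
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    warning(sprintf("constant gene(s) passed through unchanged: %s",
                    paste(colnames(v)[sds == 0], collapse = ", ")))
  geneSeeds <- deriveSeeds(seed, ncol(v))
  out <- v
  for (g in which(sds > 0)) {
    out[, g] <- makeSurrogates(v[, g], M = 1L, seed = geneSeeds[g],
                               context = context)$surrogates[, 1L]
  }
  ExpressionMatrix(out, "zscored",
                   geneMeans = expr@geneMeans, geneSds = expr@geneSds)
}

#' Run the expression-randomization null ensemble
#'
#' For each replicate: randomize all gene maps (spatial-autocorrelation
#' preserving), redo PCA, pairing, CCA and reconstruction with the unchanged
#' connectome, and record held-out canonical correlations and held-out AUC.
#' The connectome is bit-identical across replicates; only expression varies.
#'
#' @param conn a [Connectome-class].
#' @param atlas a [RegionAtlas-class].
#' @param expr a z-scored [ExpressionMatrix-class].
#' @param M number of replicates (>= 1).
#' @param nComponentsPca,nComponentsCca,kUsed,testFraction,ridge pipeline
#'   configuration.
#' @param seed master seed.
#' @param context optional precomputed [surrogateContext()]; built from the
#'   atlas centroid distances when `NULL`.
#' @return data.frame with one row per replicate x component: `replicate`,
#'   `component`, `rho_holdout`, `auc`, `error`.
#' @export
runExpressionNull <- function(conn, atlas, expr, M,
                              nComponentsPca = 50L, nComponentsCca = 5L,
                              kUsed = 5L, testFraction = 0.2, ridge = 0,
                              seed = 1L, context = NULL) {
  .stopIfNot(M >= 1L, "M must be >= 1")
  if (is.null(context)) context <- surrogateContext(physicalDistances(atlas))
  seeds <- deriveSeeds(seed, 2L * M)
  rows <- vector("list", M)
  for (m in seq_len(M)) {
    rows[[m]] <- tryCatch({
      exprNull <- randomizeExpression(expr, seed = seeds[m], context = context)
      red <- pcaReduce(exprNull,
                       min(nComponentsPca,
                           nrow(exprValues(exprNull)) - 1L,
                           ncol(exprValues(exprNull))))
      fit <- .fitPipelineOnce(conn, red, nComponentsCca, kUsed, testFraction,
                              ridge, seeds[M + m])
      data.frame(replicate = m,
                 component = seq_along(fit$rhoTest),
                 rho_holdout = fit$rhoTest,
                 auc = fit$auc,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(replicate = m, component = NA_integer_,
                 rho_holdout = NA_real_, auc = NA_real_,
                 error = conditionMessage(e))
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- as.integer(seed)
  out
}
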