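#' @import methods
NULL

## Central S4 containers. All region-indexed objects use the atlas region order;
## readers reindex on the way in, so downstream code never re-sorts.

#' RegionAtlas: regions, major-region partition, spatial centroids
#'
#' An ordered set of brain regions, each assigned to exactly one major region
#' (MR, a coarse anatomical division) and carrying a 3-D centroid in atlas
#' length units. The region order of a `RegionAtlas` fixes the row/column
#' order of every other object in an analysis.
#'
#' @slot regionIds character vector of unique region identifiers (length R).
#' @slot regionNames character vector of display names (may equal `regionIds`).
#' @slot majorRegion factor of MR labels, one per region.
#' @slot centroids numeric R x 3 matrix of centroid coordinates.
#'
#' @seealso [readAtlas()], [simulateAtlas()]
#' @export
setClass("RegionAtlas",
  slots = c(
    regionIds = "character",
    regionNames = "character",
    majorRegion = "factor",
    centroids = "matrix"
  )
)

setValidity("RegionAtlas", function(object) {
  R <- length(object@regionIds)
  msg <- character()
  if (anyDuplicated(object@regionIds))
    msg <- c(msg, sprintf(
      "duplicated region_id: %s",
      paste(unique(object@regionIds[duplicated(object@regionIds)]), collapse = ", ")))
  if (length(object@regionNames) != R)
    msg <- c(msg, "regionNames length differs from regionIds")
  if (length(object@majorRegion) != R)
    msg <- c(msg, "majorRegion length differs from regionIds")
  if (anyNA(object@majorRegion))
    msg <- c(msg, "every region must have a major_region label")
  if (!is.numeric(object@centroids) || nrow(object@centroids) != R ||
      ncol(object@centroids) != 3L)
    msg <- c(msg, "centroids must be a numeric R x 3 matrix")
  else if (!all(is.finite(object@centroids)))
    msg <- c(msg, "centroids must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionAtlas
#'
#' @param regionIds character vector of unique region identifiers.
#' @param majorRegion character or factor of major-region labels, one per region.
#' @param centroids numeric R x 3 matrix (columns x, y, z).
#' @param regionNames optional display names; defaults to `regionIds`.
#' @return A [RegionAtlas-class] object.
#' @export
RegionAtlas <- function(regionIds, majorRegion, centroids, regionNames = regionIds) {
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  rownames(centroids) <- regionIds
  colnames(centroids) <- c("x", "y", "z")
  new("RegionAtlas",
      regionIds = as.character(regionIds),
      regionNames = as.character(regionNames),
      majorRegion = factor(majorRegion),
      centroids = centroids)
}

#' Connectome: binary directed adjacency with an eligibility mask
#'
#' The adjacency matrix holds directed projections: `adjacency[i, j] == 1` iff
#' region i (source) projects to region j (target). The eligibility mask marks
#' the analyzable cell universe; by default a cell is eligible iff source and
#' target lie in different major regions (long-range connections only). Entries
#' outside the mask may be recorded from the input file but are ignored by all
#' analyses, which intersect adjacency with the mask.
#'
#' @slot adjacency numeric R x R matrix with entries in {0, 1}, zero diagonal.
#' @slot eligibleMask logical R x R matrix.
#' @slot regionIds character vector giving the row/column order.
#'
#' @seealso [readConnectome()], [eligibleCells()], [connectionCount()]
#' @export
setClass("Connectome",
  slots = c(
    adjacency = "matrix",
    eligibleMask = "matrix",
    regionIds = "character"
  )
)

setValidity("Connectome", function(object) {
  A <- object@adjacency
  M <- object@eligibleMask
  R <- length(object@regionIds)
  msg <- character()
  if (nrow(A) != R || ncol(A) != R)
    msg <- c(msg, "adjacency must be R x R")
  if (nrow(M) != R || ncol(M) != R || !is.logical(M))
    msg <- c(msg, "eligibleMask must be a logical R x R matrix")
  if (!all(A %in% c(0, 1)))
    msg <- c(msg, "adjacency entries must be 0 or 1")
  if (nrow(A) == R && any(diag(A) != 0))
    msg <- c(msg, "adjacency diagonal must be zero")
  if (is.logical(M) && nrow(M) == R && any(diag(M)))
    msg <- c(msg, "diagonal cells cannot be eligible")
  if (length(msg)) msg else TRUE
})

#' Construct a Connectome
#'
#' @param adjacency numeric R x R binary matrix (rows = sources, cols = targets).
#' @param atlas a [RegionAtlas-class]; supplies region order and MR labels for
#'   the default eligibility mask (inter-MR, off-diagonal cells).
#' @param eligibleMask optional logical R x R matrix overriding the default.
#' @return A [Connectome-class] object.
#' @export
Connectome <- function(adjacency, atlas, eligibleMask = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  ids <- regionIds(atlas)
  dimnames(adjacency) <- list(ids, ids)
  if (is.null(eligibleMask)) {
    mr <- majorRegion(atlas)
    if (nlevels(droplevels(mr)) < 2L)
      stop("at least 2 distinct major_region labels are required for inter-MR analysis")
    eligibleMask <- outer(as.integer(mr), as.integer(mr), "!=")
  }
  eligibleMask <- as.matrix(eligibleMask)
  diag(eligibleMask) <- FALSE
  dimnames(eligibleMask) <- dimnames(adjacency)
  new("Connectome", adjacency = adjacency, eligibleMask = eligibleMask,
      regionIds = ids)
}

#' ExpressionMatrix: region x gene expression levels
#'
#' @slot values numeric R x G matrix, rows in atlas region order.
#' @slot normalizationState `"raw"` or `"zscored"`.
#' @slot geneMeans,geneSds per-gene constants recorded by [zscoreExpression()]
#'   (empty while raw).
#'
#' @seealso [readExpression()], [zscoreExpression()]
#' @export
setClass("ExpressionMatrix",
  slots = c(
    values = "matrix",
    normalizationState = "character",
    geneMeans = "numeric",
    geneSds = "numeric"
  )
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  else if (!all(is.finite(v))) msg <- c(msg, "expression values must be finite")
  g <- colnames(v)
  if (is.null(g)) msg <- c(msg, "values must carry gene symbols as colnames")
  else if (anyDuplicated(g))
    msg <- c(msg, sprintf("duplicated gene symbol: %s",
                          paste(unique(g[duplicated(g)]), collapse = ", ")))
  if (!object@normalizationState %in% c("raw", "zscored"))
    msg <- c(msg, "normalizationState must be 'raw' or 'zscored'")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric R x G matrix with gene symbols as column names and
#'   region ids as row names.
#' @param normalizationState `"raw"` (default) or `"zscored"`.
#' @param geneMeans,geneSds z-scoring constants (used internally).
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, normalizationState = "raw",
                             geneMeans = numeric(), geneSds = numeric()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values,
      normalizationState = normalizationState,
      geneMeans = geneMeans, geneSds = geneSds)
}

#' ReducedExpression: PCA-reduced region scores
#'
#' @slot scores numeric R x D matrix of component scores.
#' @slot loadings numeric G x D matrix of orthonormal gene loadings.
#' @slot explainedVarianceRatio numeric D vector, nonincreasing.
#' @slot geneMeans,geneSds z-scoring constants inherited from the input.
#' @seealso [pcaReduce()]
#' @export
setClass("ReducedExpression",
  slots = c(
    scores = "matrix",
    loadings = "matrix",
    explainedVarianceRatio = "numeric",
    geneMeans = "numeric",
    geneSds = "numeric"
  )
)

setValidity("ReducedExpression", function(object) {
  D <- ncol(object@scores)
  msg <- character()
  if (ncol(object@loadings) != D)
    msg <- c(msg, "loadings and scores disagree on D")
  if (length(object@explainedVarianceRatio) != D)
    msg <- c(msg, "explainedVarianceRatio length must equal D")
  else {
    r <- object@explainedVarianceRatio
    if (any(r < -1e-12) || sum(r) > 1 + 1e-8)
      msg <- c(msg, "explained variance ratios must be >= 0 and sum <= 1")
    if (is.unsorted(rev(r), strictly = FALSE) && any(diff(r) > 1e-12))
      msg <- c(msg, "explained variance ratios must be nonincreasing")
  }
  if (length(msg)) msg else TRUE
})

#' ConnectionPairs: paired source/target reduced-expression rows
#'
#' One row per directed connection: `Xs[n, ]` is the reduced expression of the
#' source region of connection n, `Xt[n, ]` that of its target.
#'
#' @slot sourceIdx,targetIdx integer region indices (atlas order) per connection.
#' @slot Xs,Xt numeric N x D matrices.
#' @seealso [buildConnectionPairs()]
#' @export
setClass("ConnectionPairs",
  slots = c(
    sourceIdx = "integer",
    targetIdx = "integer",
    Xs = "matrix",
    Xt = "matrix"
  )
)

setValidity("ConnectionPairs", function(object) {
  N <- length(object@sourceIdx)
  msg <- character()
  if (N < 1L) msg <- c(msg, "at least one connection is required")
  if (length(object@targetIdx) != N)
    msg <- c(msg, "sourceIdx and targetIdx lengths differ")
  if (nrow(object@Xs) != N || nrow(object@Xt) != N)
    msg <- c(msg, "Xs/Xt must have one row per connection")
  if (ncol(object@Xs) != ncol(object@Xt))
    msg <- c(msg, "Xs and Xt must share D")
  if (length(msg)) msg else TRUE
})

#' HoldoutSplit: partition of eligible cells into train/test
#'
#' Cells are linear (column-major) indices into the R x R connectome matrix;
#' connected and unconnected eligible cells alike are partitioned, so held-out
#' evaluation sees both classes.
#'
#' @slot trainCells,testCells integer vectors of linear cell indices.
#' @slot seed integer seed used for the draw.
#' @slot testFraction proportion assigned to the test side.
#' @seealso [holdoutSplit()]
#' @export
setClass("HoldoutSplit",
  slots = c(
    trainCells = "integer",
    testCells = "integer",
    seed = "integer",
    testFraction = "numeric"
  )
)

setValidity("HoldoutSplit", function(object) {
  if (length(intersect(object@trainCells, object@testCells)))
    "train and test cells must be disjoint"
  else TRUE
})

#' WiringPI: canonical weight pairs and correlations
#'
#' Columns of `A` and `B` are the paired weight vectors a^(i), b^(i) mapping
#' reduced expression to the i-th source/target wiring-PI variate; `rho` holds
#' the training canonical correlations in nonincreasing order. `meanS`/`meanT`
#' are the training-pair column means used for centering, frozen at fit time.
#'
#' @slot A,B numeric D x K weight matrices (source, target side).
#' @slot rho numeric K vector of canonical correlations.
#' @slot meanS,meanT numeric D centering vectors.
#' @slot ridge ridge added to the within-set covariances at fit time.
#' @seealso [fitCCA()], [projectPI()]
#' @export
setClass("WiringPI",
  slots = c(
    A = "matrix",
    B = "matrix",
    rho = "numeric",
    meanS = "numeric",
    meanT = "numeric",
    ridge = "numeric"
  )
)

setValidity("WiringPI", function(object) {
  K <- length(object@rho)
  msg <- character()
  if (ncol(object@A) != K || ncol(object@B) != K)
    msg <- c(msg, "A/B must have K columns")
  if (any(object@rho < -1e-10) || any(object@rho > 1 + 1e-10))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (K > 1 && any(diff(object@rho) > 1e-10))
    msg <- c(msg, "canonical correlations must be nonincreasing")
  if (length(object@meanS) != nrow(object@A) ||
      length(object@meanT) != nrow(object@B))
    msg <- c(msg, "centering vectors must have length D")
  if (length(msg)) msg else TRUE
})

#' PIMaps: region-level wiring-PI gradient maps
#'
#' @slot Ps,Pt numeric R x K matrices of source/target PI values per region.
#' @seealso [projectPI()]
#' @export
setClass("PIMaps",
  slots = c(Ps = "matrix", Pt = "matrix")
)

setValidity("PIMaps", function(object) {
  msg <- character()
  if (!all(dim(object@Ps) == dim(object@Pt)))
    msg <- c(msg, "Ps and Pt must have identical dimensions")
  if (!all(is.finite(object@Ps)) || !all(is.finite(object@Pt)))
    msg <- c(msg, "PI values must be finite")
  if (length(msg)) msg else TRUE
})

#' DPIMatrix: squared PI distance per directed region pair
#'
#' `values[i, j]` is the squared Euclidean distance between the source-PI
#' vector of region i and the target-PI vector of region j over the first
#' `kUsed` components; low values predict a connection i -> j.
#'
#' @slot values numeric R x R nonnegative matrix.
#' @slot kUsed integer number of components used.
#' @seealso [computeDPI()]
#' @export
setClass("DPIMatrix",
  slots = c(values = "matrix", kUsed = "integer")
)

setValidity("DPIMatrix", function(object) {
  if (any(object@values < -1e-12)) "dPI values must be nonnegative" else TRUE
})

#' SpatialWeights: spatial weight matrix for autocorrelation statistics
#'
#' @slot W numeric R x R nonnegative matrix with zero diagonal.
#' @slot scheme character descriptor, e.g. `"knn:6"` or `"invdist:2"`.
#' @slot rowStandardized logical.
#' @seealso [spatialWeights()], [moransI()]
#' @export
setClass("SpatialWeights",
  slots = c(W = "matrix", scheme = "character", rowStandardized = "logical")
)

setValidity("SpatialWeights", function(object) {
  msg <- character()
  if (any(object@W < 0)) msg <- c(msg, "weights must be nonnegative")
  if (any(diag(object@W) != 0)) msg <- c(msg, "weight diagonal must be zero")
  if (object@rowStandardized) {
    rs <- rowSums(object@W)
    if (any(abs(rs[rs > 0] - 1) > 1e-8))
      msg <- c(msg, "row-standardized rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})
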