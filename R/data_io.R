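## Readers and writers for the three standard input tables and result objects.
## All readers reindex to atlas region order so downstream code can rely on it.

# Guess the field separator from the file extension (tab for .tsv/.txt,
# comma otherwise).
.sepFor <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a region atlas table
#'
#' Expects a delimited text file (TSV or CSV, by extension) with a header and
#' columns `region_id`, `major_region`, `x`, `y`, `z`; an optional `name`
#' column supplies display names. File row order is preserved as the atlas
#' region order.
#'
#' @param path path to the atlas file.
#' @return A [RegionAtlas-class].
#' @export
readAtlas <- function(path) {
  df <- utils::read.table(path, sep = .sepFor(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("region_id", "major_region", "x", "y", "z")
  missing <- setdiff(need, names(df))
  .stopIfNot(length(missing) == 0L,
             "atlas file is missing required column(s): %s",
             paste(missing, collapse = ", "))
  dup <- unique(df$region_id[duplicated(df$region_id)])
  .stopIfNot(length(dup) == 0L, "duplicated region_id in atlas file: %s",
             paste(dup, collapse = ", "))
  xyz <- suppressWarnings(vapply(df[c("x", "y", "z")], as.numeric,
                                 numeric(nrow(df))))
  xyz <- matrix(xyz, nrow = nrow(df))
  .stopIfNot(all(is.finite(xyz)), "non-numeric centroid coordinate in atlas file")
  nm <- if ("name" %in% names(df)) df$name else df$region_id
  RegionAtlas(df$region_id, df$major_region, xyz, regionNames = nm)
}

#' Write a region atlas table
#'
#' Tab-separated, with columns `region_id`, `name`, `major_region`, `x`, `y`,
#' `z`; the inverse of [readAtlas()].
#'
#' @param atlas a [RegionAtlas-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAtlas <- function(atlas, path) {
  ctr <- centroids(atlas)
  df <- data.frame(region_id = regionIds(atlas),
                   name = atlas@regionNames,
                   major_region = as.character(majorRegion(atlas)),
                   x = ctr[, 1], y = ctr[, 2], z = ctr[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a square labeled numeric matrix (region-ID header row and column) and
# reindex it to atlas order, checking the ID sets agree.
.readSquareMatrix <- function(path, atlas, what) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  ids <- regionIds(atlas)
  bad <- setdiff(c(rownames(m), colnames(m)), ids)
  .stopIfNot(length(bad) == 0L, "%s file has region ids absent from atlas: %s",
             what, paste(utils::head(bad, 5), collapse = ", "))
  miss <- setdiff(ids, rownames(m))
  .stopIfNot(length(miss) == 0L && !length(setdiff(ids, colnames(m))),
             "%s file is missing atlas region(s): %s",
             what, paste(utils::head(miss, 5), collapse = ", "))
  m[ids, ids, drop = FALSE]
}

#' Read a binary directed connectome
#'
#' CSV with region IDs as header row and first column; entry `(i, j)` is 1 iff
#' region i projects to region j. The matrix is reindexed to atlas order and an
#' eligibility mask is built from the atlas major-region labels: cells joining
#' regions of different MRs are eligible; within-MR and diagonal cells are
#' recorded but marked ineligible (all analyses ignore them).
#'
#' @param path path to the connectome CSV.
#' @param atlas a [RegionAtlas-class].
#' @return A [Connectome-class].
#' @export
readConnectome <- function(path, atlas) {
  m <- .readSquareMatrix(path, atlas, "connectome")
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    ai <- arrayInd(bad[1L], dim(m))
    stop(sprintf(
      "connectome entries must be 0 or 1; first offending cell at row %s, column %s (value %g)",
      rownames(m)[ai[1]], colnames(m)[ai[2]], m[bad[1L]]))
  }
  diag(m) <- 0
  Connectome(m, atlas)
}

#' Write a connectome adjacency matrix
#'
#' @param conn a [Connectome-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeConnectome <- function(conn, path) {
  utils::write.csv(adjacency(conn), path, quote = FALSE)
  invisible(path)
}

#' Read a region x gene expression table
#'
#' CSV with one row per region (first column = region ID) and one column per
#' gene. Rows are reordered to atlas order; missing regions or duplicated gene
#' columns are errors, and missing values are rejected rather than imputed.
#'
#' @param path path to the expression CSV.
#' @param atlas a [RegionAtlas-class].
#' @return An [ExpressionMatrix-class] with `normalizationState = "raw"`.
#' @export
readExpression <- function(path, atlas) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  ids <- df[[1L]]
  genes <- names(df)[-1L]
  dup <- unique(genes[duplicated(genes)])
  .stopIfNot(length(dup) == 0L, "duplicated gene column in expression file: %s",
             paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  .stopIfNot(!anyNA(m), "expression file contains missing values; no imputation is performed")
  miss <- setdiff(regionIds(atlas), ids)
  .stopIfNot(length(miss) == 0L, "expression file is missing region(s): %s",
             paste(utils::head(miss, 5), collapse = ", "))
  extra <- setdiff(ids, regionIds(atlas))
  .stopIfNot(length(extra) == 0L, "expression file has region ids absent from atlas: %s",
             paste(utils::head(extra, 5), collapse = ", "))
  ExpressionMatrix(m[regionIds(atlas), , drop = FALSE], "raw")
}

#' Write a region x gene expression table
#'
#' @param expr an [ExpressionMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path) {
  v <- exprValues(expr)
  df <- data.frame(region_id = rownames(v), v, check.names = FALSE)
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
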