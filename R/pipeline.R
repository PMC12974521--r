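## One-call orchestration: inputs -> normalization -> PCA -> CCA (with
## repeated hold-out) -> gradient maps -> reconstruction -> spatial stats ->
## optional screening and null ensembles, with all artifacts written as
## labeled CSV tables plus a JSON run manifest.

#' Default pipeline configuration
#'
#' Defaults follow the reference mouse-brain analysis where values are known:
#' 50 PCA dimensions, 5 canonical components retained, dPI over the top 5
#' components. Hold-out uses a 0.2 test fraction repeated over 10 splits.
#'
#' @return named list of configuration defaults.
#' @export
defaultConfig <- function() {
  list(
    atlas = NULL, connectome = NULL, expression = NULL,
    synthetic = NULL,              # list of simulateChemoaffinityData() args
    out = NULL,
    n_components_pca = 50L,
    n_components_cca = 5L,
    k_used = 5L,
    test_fraction = 0.2,
    n_splits = 10L,
    ridge = 0,
    knn = 6L,
    screening = list(enabled = FALSE, M = 999L),
    nulls = list(models = character(), M = 100L),
    expression_null = list(enabled = FALSE, M = 20L),
    seed = 1L
  )
}

#' Read a YAML pipeline configuration
#'
#' Unspecified keys fall back to [defaultConfig()].
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  .stopIfNot(file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(defaultConfig(), cfg)
  out
}

.loadInputs <- function(config) {
  if (!is.null(config$synthetic)) {
    sim <- do.call(simulateChemoaffinityData, config$synthetic)
    list(atlas = sim$atlas, conn = sim$connectome, expr = sim$expression,
         truth = sim$truth, files = character())
  } else {
    for (p in c(config$atlas, config$connectome, config$expression)) {
      .stopIfNot(file.exists(p), "input file not found: %s", p)
    }
    atlas <- readAtlas(config$atlas)
    list(atlas = atlas,
         conn = readConnectome(config$connectome, atlas),
         expr = readExpression(config$expression, atlas),
         truth = NULL,
         files = c(atlas = config$atlas, connectome = config$connectome,
                   expression = config$expression))
  }
}

#' Run the full analysis pipeline
#'
#' Executes prepare (normalize, PCA) -> fit (full-data CCA plus repeated
#' hold-out validation) -> reconstruct (dPI, ROC/AUC, distance baseline) ->
#' spatial statistics (Moran's I of every PI map, source/target spatial
#' correlation per component) -> optional gene screening and null-model
#' ensembles. When `config$out` is set, every result is written there as a
#' labeled CSV together with a `manifest.json` recording the configuration,
#' seed, derived stage seeds, input checksums and package version.
#'
#' @param config configuration list (see [defaultConfig()]), or a path to a
#'   YAML file.
#' @return (invisibly) a list with all in-memory results.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- utils::modifyList(defaultConfig(), config)
  inp <- .loadInputs(config)
  atlas <- inp$atlas; conn <- inp$conn
  seedStages <- deriveSeeds(config$seed, 3L + config$n_splits)

  exprZ <- zscoreExpression(inp$expr)
  D <- min(config$n_components_pca,
           nRegions(atlas) - 1L, ncol(exprValues(exprZ)))
  red <- pcaReduce(exprZ, D)

  # full-data fit
  pairsAll <- buildConnectionPairs(conn, red)
  K <- min(config$n_components_cca, D)
  wpi <- fitCCA(pairsAll, K, ridge = config$ridge)
  maps <- projectPI(red, wpi)
  dpi <- computeDPI(maps, kUsed = min(config$k_used, K))
  rocFull <- rocAUC(dpi, conn, orientation = "lower")
  dist <- physicalDistances(atlas)
  rocDist <- rocAUC(dist, conn, orientation = "lower")
  rel <- dpiDistanceRelation(dpi, dist, conn)

  # repeated hold-out validation
  splitSeeds <- seedStages[3L + seq_len(config$n_splits)]
  holdout <- lapply(splitSeeds, function(s) {
    .fitPipelineOnce(conn, red, K, min(config$k_used, K),
                     config$test_fraction, config$ridge, s)
  })
  rhoHoldout <- do.call(rbind, lapply(holdout, `[[`, "rhoTest"))
  aucHoldout <- vapply(holdout, `[[`, numeric(1), "auc")

  # spatial statistics of the PI maps
  w <- spatialWeights(atlas, "knn", k = min(config$knn, nRegions(atlas) - 1L))
  moran <- data.frame(
    component = rep(seq_len(K), 2L),
    side = rep(c("source", "target"), each = K),
    morans_i = c(vapply(seq_len(K), function(k)
                   moransI(sourceMaps(maps)[, k], w), numeric(1)),
                 vapply(seq_len(K), function(k)
                   moransI(targetMaps(maps)[, k], w), numeric(1))))
  pairCor <- vapply(seq_len(K), function(k)
    piPairSpatialCorrelation(maps, k), numeric(1))

  screen <- NULL
  if (isTRUE(config$screening$enabled)) {
    ctx <- surrogateContext(dist)
    screen <- screenGenes(exprZ, maps, M = config$screening$M,
                          seed = seedStages[1L], context = ctx)
  }

  nulls <- list()
  for (model in config$nulls$models) {
    nulls[[model]] <- runNullEnsemble(
      conn, atlas, red, model = model, M = config$nulls$M, refMaps = maps,
      nComponentsCca = K, kUsed = min(config$k_used, K),
      testFraction = config$test_fraction, ridge = config$ridge,
      seed = seedStages[2L])
  }

  exprNull <- NULL
  if (isTRUE(config$expression_null$enabled)) {
    exprNull <- runExpressionNull(
      conn, atlas, exprZ, M = config$expression_null$M,
      nComponentsPca = D, nComponentsCca = K, kUsed = min(config$k_used, K),
      testFraction = config$test_fraction, ridge = config$ridge,
      seed = seedStages[3L])
  }

  result <- list(
    atlas = atlas, connectome = conn, reduced = red, wpi = wpi, maps = maps,
    dpi = dpi,
    rho_full = canonicalCorrelations(wpi),
    rho_holdout = rhoHoldout,
    auc_full = rocFull$auc, auc_holdout = aucHoldout,
    auc_distance = rocDist$auc,
    roc = rocFull,
    dpi_distance_r = rel,
    morans_i = moran, pi_pair_correlation = pairCor,
    screen = screen, nulls = nulls, expression_null = exprNull,
    truth = inp$truth, config = config)

  if (!is.null(config$out)) .writeResults(result, config, inp$files)
  invisible(result)
}

.writeMatrixCSV <- function(m, path) utils::write.csv(m, path, quote = FALSE)

.writeResults <- function(res, config, files) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out, f)
  .writeMatrixCSV(scores(res$reduced), out("scores.csv"))
  .writeMatrixCSV(res$wpi@A, out("weights_source.csv"))
  .writeMatrixCSV(res$wpi@B, out("weights_target.csv"))
  K <- length(res$rho_full)
  piLong <- rbind(
    data.frame(region_id = rownames(sourceMaps(res$maps)),
               side = "source",
               as.data.frame(sourceMaps(res$maps))),
    data.frame(region_id = rownames(targetMaps(res$maps)),
               side = "target",
               as.data.frame(targetMaps(res$maps))))
  utils::write.csv(piLong, out("pimaps.csv"), quote = FALSE, row.names = FALSE)
  utils::write.csv(
    data.frame(component = seq_len(K),
               rho_full = res$rho_full,
               rho_holdout_mean = colMeans(res$rho_holdout),
               pi_pair_spatial_r = res$pi_pair_correlation),
    out("rho.csv"), quote = FALSE, row.names = FALSE)
  utils::write.csv(
    data.frame(threshold = res$roc$thresholds, fpr = res$roc$fpr,
               tpr = res$roc$tpr),
    out("roc.csv"), quote = FALSE, row.names = FALSE)
  utils::write.csv(res$morans_i, out("morans_i.csv"), quote = FALSE,
                   row.names = FALSE)
  if (!is.null(res$screen))
    utils::write.csv(res$screen, out("screen.csv"), quote = FALSE,
                     row.names = FALSE)
  for (model in names(res$nulls))
    utils::write.csv(res$nulls[[model]],
                     out(sprintf("nullsummary_%s.csv", model)),
                     quote = FALSE, row.names = FALSE)
  if (!is.null(res$expression_null))
    utils::write.csv(res$expression_null, out("expression_null.csv"),
                     quote = FALSE, row.names = FALSE)
  summary <- list(
    n_regions = nRegions(res$atlas),
    n_connections = connectionCount(res$connectome),
    auc_dpi_full = res$auc_full,
    auc_dpi_holdout_mean = mean(res$auc_holdout),
    auc_distance = res$auc_distance,
    r_all = unname(res$dpi_distance_r["all"]),
    r_connected = unname(res$dpi_distance_r["connected"]),
    r_unconnected = unname(res$dpi_distance_r["unconnected"]))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("wiringPI")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "synthetic")],
    synthetic = if (is.null(config$synthetic)) NULL else config$synthetic,
    input_md5 = if (length(files)) as.list(tools::md5sum(files)) else NULL,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(NULL)
}
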