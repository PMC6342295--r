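## End-to-end orchestration: simulate -> dtm -> ndsm -> segment ->
## metrics -> ndvi -> wsi -> validate, each stage writing files that are
## independently consumable. Outputs are a function of (inputs, config,
## seed) only.

#' Default pipeline configuration
#'
#' Returns the nested configuration list understood by
#' \code{\link{runPipeline}}; every entry can be overridden via a YAML
#' file (\code{\link{readRunConfig}}). The \code{simulate} block mirrors
#' \code{\link{sceneConfig}}.
#'
#' @return named list of stage parameter blocks.
#' @export
defaultRunConfig <- function() {
  list(
    simulate = list(enabled = TRUE, treeRows = 3L, treeCols = 5L,
                    spacingX = 5, spacingY = 5, gsd = 0.02,
                    hollowCoreFraction = 0, noiseAmplitude = 0.10),
    inputs = list(dsm = NULL, dtm = NULL, nir = NULL, red = NULL,
                  trees = NULL, swp = NULL),
    dtm = list(gridStep = 2.5, heightThreshold = 0.5, blockSize = 5),
    segment = list(method = "sauvola", window = NA, k = NA, r = NA,
                   heightThreshold = 0.5, minArea = 0.5),
    metrics = list(d = 0.7, dMode = "per_tree", ringWidth = 2,
                   maxMatchDist = 2.5),
    wsi = list(startDoy = 182L, endDoy = 273L),
    validate = list(mode = "origin")
  )
}

.mergeConfig <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", sub("^\\.", "", paste0(path, ".", nm)))
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]],
                                 paste0(path, ".", nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML file; its entries override
#'   \code{\link{defaultRunConfig}}.
#' @return merged configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  .mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full per-tree canopy analytics pipeline
#'
#' Either simulates an orchard scene or reads DSM/NIR/RED rasters,
#' derives the DTM and nDSM, segments crowns, computes per-tree metrics
#' (with per-tree NDVI when reflectance bands are present), the water
#' stress integral for any stem water potential series provided, and a
#' measured-vs-estimated validation fit when a truth table is available.
#' All outputs land in \code{outdir} together with an echo of the
#' resolved configuration; identical config + seed reproduce identical
#' outputs.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @param seed integer seed for the simulation stage.
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the main in-memory results
#'   (\code{metrics}, \code{segments}, \code{validation}, \code{wsi},
#'   \code{trees}).
#' @export
runPipeline <- function(config = defaultRunConfig(), seed = 1L,
                        outdir = tempfile("canopy3d-run-")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config <- .mergeConfig(defaultRunConfig(), config)
  yaml::write_yaml(c(config, list(seed = as.integer(seed))),
                   file.path(outdir, "config_echo.yaml"))

  trees <- NULL; swpTab <- NULL; nir <- NULL; red <- NULL; dtm <- NULL
  if (isTRUE(config$simulate$enabled)) {
    .stage("simulate", {
      sim <- config$simulate
      sim$enabled <- NULL
      cfg <- do.call(sceneConfig, sim)
      scene <- generateScene(cfg, seed = seed)
      writeRaster(scene$dsm, file.path(outdir, "dsm.tif"))
      writeRaster(scene$dtm_true, file.path(outdir, "dtm_true.tif"))
      writeRaster(scene$nir, file.path(outdir, "nir.tif"))
      writeRaster(scene$red, file.path(outdir, "red.tif"))
      utils::write.csv(scene$trees, file.path(outdir, "trees.csv"),
                       row.names = FALSE)
      seeds <- .subSeeds(seed + 1L, 2L)
      swpTab <- rbind(
        .swpToDf(generateSwpSeries("irrigated", seed = seeds[1])),
        .swpToDf(generateSwpSeries("rainfed", seed = seeds[2])))
      utils::write.csv(swpTab, file.path(outdir, "swp.csv"),
                       row.names = FALSE)
      # the stage expression is evaluated in this function's frame, so
      # plain assignments are visible to the later stages
      dsm <- scene$dsm; trees <- scene$trees
      nir <- scene$nir; red <- scene$red
    })
  } else {
    if (is.null(config$inputs$dsm))
      stop("no DSM: provide inputs$dsm or enable the simulate stage")
    dsm <- .stage("read", readRaster(config$inputs$dsm))
    if (!is.null(config$inputs$dtm))
      dtm <- .stage("read", readRaster(config$inputs$dtm))
    if (!is.null(config$inputs$nir))
      nir <- .stage("read", readRaster(config$inputs$nir))
    if (!is.null(config$inputs$red))
      red <- .stage("read", readRaster(config$inputs$red))
    if (!is.null(config$inputs$trees))
      trees <- utils::read.csv(config$inputs$trees)
    if (!is.null(config$inputs$swp))
      swpTab <- utils::read.csv(config$inputs$swp)
  }

  if (is.null(dtm)) {
    dtm <- .stage("dtm", deriveDtm(
      dsm, gridStep = config$dtm$gridStep,
      heightThreshold = config$dtm$heightThreshold,
      blockSize = config$dtm$blockSize))
    writeRaster(dtm, file.path(outdir, "dtm.tif"))
  }
  ndsm <- .stage("ndsm", computeNdsm(dsm, dtm))
  writeRaster(ndsm, file.path(outdir, "ndsm.tif"))

  segments <- .stage("segment", {
    sp <- config$segment
    params <- segmentationParams(method = sp$method, window = sp$window,
                                 k = sp$k, r = sp$r,
                                 heightThreshold = sp$heightThreshold,
                                 minArea = sp$minArea)
    mask <- localThreshold(ndsm, params)
    labelCrowns(mask, ndsm, minArea = sp$minArea)
  })
  utils::write.csv(segmentTable(segments), file.path(outdir, "crowns.csv"),
                   row.names = FALSE)

  matching <- NULL
  if (!is.null(trees))
    matching <- matchSegmentsToTruth(segments, trees,
                                     maxDist = config$metrics$maxMatchDist)

  metrics <- .stage("metrics", {
    dTable <- NULL
    if (identical(config$metrics$dMode, "per_tree") && !is.null(trees) &&
        "d" %in% names(trees) && !is.null(matching))
      dTable <- trees[, c("tree_id", "d")]
    treeMetrics(ndsm, dsm, dtm, segments, d = config$metrics$d,
                dTable = dTable, matching = matching,
                ringWidth = config$metrics$ringWidth)
  })

  if (!is.null(nir) && !is.null(red)) {
    nd <- .stage("ndvi", ndvi(nir, red))
    writeRaster(nd, file.path(outdir, "ndvi.tif"))
    metrics$mean_ndvi <- vapply(metrics$label, function(l)
      perTreeNdvi(nd, segments, l), numeric(1))
  }
  utils::write.csv(metrics, file.path(outdir, "metrics.csv"),
                   row.names = FALSE)

  wsiTab <- NULL
  if (!is.null(swpTab)) {
    wsiTab <- .stage("wsi", {
      do.call(rbind, lapply(split(swpTab, swpTab$tree_id), function(df) {
        res <- waterStressIntegral(
          swpSeries(df$tree_id[1], df$doy, df$swp),
          window = c(config$wsi$startDoy, config$wsi$endDoy))
        data.frame(tree_id = df$tree_id[1], wsi_mpa_d = res@wsi,
                   daily_wsi_mpa = res@dailyWsi, n_days = res@nDays,
                   c_ref_mpa = res@cRef)
      }))
    })
    utils::write.csv(wsiTab, file.path(outdir, "wsi.csv"), row.names = FALSE)
  }

  validation <- NULL
  if (!is.null(trees) && !is.null(matching) && nrow(matching$pairs) >= 3L &&
      "surface_integral_volume" %in% names(trees)) {
    validation <- .stage("validate", {
      m <- merge(matching$pairs, metrics, by = "label")
      m <- merge(m, trees, by.x = "tree_id.x", by.y = "tree_id")
      fits <- list(
        net_volume = if (identical(config$validate$mode, "ordinary"))
          fitOrdinary(m$surface_integral_volume, m$net_volume_m3)
        else fitOriginForced(m$surface_integral_volume, m$net_volume_m3),
        height = fitOrdinary(m$ht, m$height_m)
      )
      do.call(rbind, lapply(names(fits), function(nm) {
        f <- fits[[nm]]
        co <- coef(f)
        data.frame(parameter = nm, model = f@model,
                   slope = unname(co[length(co)]),
                   intercept = if ("intercept" %in% names(co))
                     unname(co["intercept"]) else 0,
                   r2 = f@r2, rmse = f@rmse, n = f@n)
      }))
    })
    utils::write.csv(validation, file.path(outdir, "validation.csv"),
                     row.names = FALSE)
  }

  invisible(list(metrics = metrics, segments = segments, trees = trees,
                 matching = matching, wsi = wsiTab,
                 validation = validation, outdir = outdir))
}

.swpToDf <- function(series) {
  data.frame(tree_id = series@treeId, doy = series@doy, swp = series@swp)
}
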