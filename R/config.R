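#' Default run configuration for a pipeline stage
#'
#' Central defaults mirroring the analysis constants: bottom/top 25%
#' masking, 3 lattice levels with alpha = (1, 0.25, 0.01), 0.1-radian /
#' 25-pixel evaluation restrictions, 500 spins, 200 surrogates.
#'
#' @param stage one of "simulate", "fit-predict", "pairwise", "networks",
#'   "null-spin", "null-eigenstrap", "calcium".
#' @param ... overrides.
#' @return named configuration list.
#' @export
defaultConfig <- function(stage, ...) {
  common <- list(stage = stage, seed = 1, out = NULL,
                 quantile = 0.25, tail = "low",
                 nLevels = 3, baseSubdivision = 2, rangeMultiplier = 2.5,
                 alpha = c(1, 0.25, 0.01), kappa2 = 0.01, lambda = "auto",
                 lambdaGrid = 10^seq(-4, 1, length.out = 12),
                 fixed = "intercept", minDistance = 0.1,
                 nSpins = 500, nSurrogates = 200, nModesBasis = 200,
                 minNetworkSize = 50,
                 subdivisions = 3,
                 map = NULL, maps = NULL, meshPath = NULL, labels = NULL,
                 series = NULL, synthetic = NULL)
  if (identical(stage, "calcium"))
    common <- utils::modifyList(common, list(tail = "high",
                                             minDistance = 25,
                                             lambda = 1e-3))
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  utils::modifyList(common, over)
}

.stages <- c("simulate", "fit-predict", "pairwise", "networks",
             "null-spin", "null-eigenstrap", "calcium")

.validateConfig <- function(cfg) {
  problems <- character()
  if (is.null(cfg$stage) || !cfg$stage %in% .stages)
    problems <- c(problems, paste0("stage must be one of: ",
                                   paste(.stages, collapse = ", ")))
  if (!is.null(cfg$quantile) &&
      (cfg$quantile <= 0 || cfg$quantile > 1))
    problems <- c(problems, "quantile must lie in (0, 1]")
  if (!is.null(cfg$tail) && !cfg$tail %in% c("low", "high"))
    problems <- c(problems, "tail must be 'low' or 'high'")
  if (!is.null(cfg$alpha) && !is.null(cfg$nLevels) &&
      length(cfg$alpha) != cfg$nLevels)
    problems <- c(problems, "alpha length must equal nLevels")
  if (is.null(cfg$out)) problems <- c(problems, "out directory is required")
  if (length(problems))
    stop(structure(class = c("geokrig_config_error", "error", "condition"),
                   list(message = paste0("invalid configuration:\n  - ",
                                         paste(problems, collapse = "\n  - ")),
                        call = NULL)))
  invisible(cfg)
}

# Resolve the mesh for a stage: from file paths or a built icosphere.
.stageMesh <- function(cfg) {
  if (!is.null(cfg$meshPath)) readMesh(cfg$meshPath)
  else buildIcosphere(cfg$subdivisions)
}

# Resolve the input map(s): paths on the given mesh, or the synthetic
# generator driven by cfg$synthetic (fields of synthSpec, plus nTasks /
# sharedWeight for families).
.stageMaps <- function(cfg, mesh, several = FALSE) {
  if (!is.null(cfg$maps) && several) {
    return(lapply(cfg$maps, readSurfaceMap, mesh = mesh))
  }
  if (!is.null(cfg$map) && !several)
    return(readSurfaceMap(cfg$map, mesh))
  syn <- cfg$synthetic
  if (is.null(syn)) syn <- list()
  spec <- synthSpec(gamma = syn$gamma %||% 3,
                    nModes = syn$nModes %||% cfg$nModesBasis,
                    noiseSd = syn$noiseSd %||% 0.1,
                    seed = syn$seed %||% cfg$seed)
  if (several)
    synthTaskFamily(mesh, nTasks = syn$nTasks %||% 7,
                    sharedWeight = syn$sharedWeight %||% 0.5, spec = spec)
  else synthMap(mesh, spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeMetricsCsv <- function(df, path) {
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

.latticeCfgOf <- function(cfg)
  latticeConfig(nLevels = cfg$nLevels, baseSubdivision = cfg$baseSubdivision,
                rangeMultiplier = cfg$rangeMultiplier, alpha = cfg$alpha,
                kappa2 = cfg$kappa2, lambda = cfg$lambda,
                lambdaGrid = cfg$lambdaGrid, fixed = cfg$fixed,
                minDistance = cfg$minDistance)

#' Run a pipeline stage from a configuration
#'
#' Dispatches one analysis stage, writes its metric outputs and a resolved
#' configuration echo (`config_echo.yaml`) to the output directory, and
#' returns the written paths. Re-running from the echo reproduces the
#' outputs byte-identically; this function (called from `Rscript`) is the
#' command-line entry point of the package.
#'
#' @param config a configuration list (see [defaultConfig()]) or the path
#'   of a YAML file holding one.
#' @return invisibly, list(status = 0, outputs = <paths>).
#' @export
runStage <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- defaultConfig(config$stage %||% "", config)
  .validateConfig(cfg)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  outputs <- switch(cfg$stage,
    "simulate" = .runSimulate(cfg),
    "fit-predict" = .runFitPredict(cfg),
    "pairwise" = .runPairwise(cfg),
    "networks" = .runNetworks(cfg),
    "null-spin" = .runSpin(cfg),
    "null-eigenstrap" = .runEigenstrap(cfg),
    "calcium" = .runCalcium(cfg))
  # JSON echo: full floating-point precision, so a re-run from the echo
  # reproduces every output byte for byte
  echo <- cfg[!vapply(cfg, is.null, logical(1))]
  echoPath <- file.path(cfg$out, "config_echo.json")
  # I(17) significant digits: doubles survive the write/read round trip
  # exactly, which the byte-identical re-run contract depends on
  jsonlite::write_json(echo, echoPath, auto_unbox = TRUE, digits = I(17))
  invisible(list(status = 0L, outputs = c(outputs, echoPath)))
}

.runSimulate <- function(cfg) {
  mesh <- .stageMesh(cfg)
  syn <- cfg$synthetic %||% list()
  kind <- syn$kind %||% "map"
  out <- character()
  if (kind == "map") {
    map <- .stageMaps(cfg, mesh)
    out <- file.path(cfg$out, "map.tsv")
    writeSurfaceMap(map, out)
  } else if (kind == "family") {
    maps <- .stageMaps(cfg, mesh, several = TRUE)
    out <- vapply(seq_along(maps), function(i) {
      p <- file.path(cfg$out, sprintf("map_%02d.tsv", i))
      writeSurfaceMap(maps[[i]], p)
      p
    }, character(1))
  } else if (kind == "networks") {
    labs <- synthNetworks(mesh, nNetworks = syn$nNetworks %||% 7,
                          patchesPerNetwork = syn$patchesPerNetwork %||% 1,
                          seed = syn$seed %||% cfg$seed)
    out <- file.path(cfg$out, "networks.tsv")
    writeLabels(labs, out)
  } else if (kind == "movie") {
    mov <- synthMovie(gridShape = syn$gridShape %||% c(48, 48),
                      T = syn$T %||% 40, gamma = syn$gamma %||% 3,
                      temporalPhi = syn$temporalPhi %||% 0.8,
                      seed = syn$seed %||% cfg$seed)
    out <- file.path(cfg$out, "movie")
    writeSeries(mov, out)
  } else stop("unknown simulate kind: ", kind)
  out
}

.runFitPredict <- function(cfg) {
  mesh <- .stageMesh(cfg)
  map <- .stageMaps(cfg, mesh)
  res <- krigeFromMask(map, thresholdMask(map, cfg$quantile, cfg$tail),
                       .latticeCfgOf(cfg))
  mp <- .writeMetricsCsv(resultMetrics(res),
                         file.path(cfg$out, "metrics.csv"))
  pp <- file.path(cfg$out, "predicted.tsv")
  write.table(data.frame(predicted = res@predicted, observed = res@observed,
                         in_mask = as.integer(res@maskFlags)),
              pp, sep = "\t", row.names = FALSE, quote = FALSE)
  c(mp, pp)
}

.runPairwise <- function(cfg) {
  mesh <- .stageMesh(cfg)
  maps <- .stageMaps(cfg, mesh, several = TRUE)
  df <- pairwiseSpecificityAll(maps, quantile = cfg$quantile,
                               config = .latticeCfgOf(cfg),
                               minDistance = cfg$minDistance)
  .writeMetricsCsv(df, file.path(cfg$out, "pairs.csv"))
}

.runNetworks <- function(cfg) {
  mesh <- .stageMesh(cfg)
  maps <- .stageMaps(cfg, mesh, several = TRUE)
  labs <- if (!is.null(cfg$labels)) readLabels(cfg$labels, mesh)
    else synthNetworks(mesh, seed = cfg$seed)
  M <- networkPrediction(maps, labs, .latticeCfgOf(cfg),
                         minNetworkSize = cfg$minNetworkSize)
  df <- data.frame(network = rownames(M), as.data.frame(M),
                   check.names = FALSE)
  .writeMetricsCsv(df, file.path(cfg$out, "nets.csv"))
}

.runSpin <- function(cfg) {
  mesh <- .stageMesh(cfg)
  map <- .stageMaps(cfg, mesh)
  labs <- if (!is.null(cfg$labels)) readLabels(cfg$labels, mesh)
    else synthNetworks(mesh, seed = cfg$seed)
  sn <- spinNull(map, labs, n = cfg$nSpins, seed = cfg$seed,
                 config = .latticeCfgOf(cfg),
                 minNetworkSize = cfg$minNetworkSize)
  .writeMetricsCsv(sn$pvalues, file.path(cfg$out, "spin_pvalues.csv"))
}

.runEigenstrap <- function(cfg) {
  mesh <- .stageMesh(cfg)
  map <- .stageMaps(cfg, mesh)
  basis <- meshEigenmodes(mesh, cfg$nModesBasis)
  ens <- eigenstrap(map, basis, n = cfg$nSurrogates, seed = cfg$seed)
  lc <- .latticeCfgOf(cfg)
  des <- .resolveSphereDesign(lc, mesh)
  lc$lattice <- des$lattice
  lc$basisFull <- des$basisFull
  acc <- function(m)
    resultMetrics(krigeFromMask(m, thresholdMask(m, cfg$quantile,
                                                 cfg$tail), lc))$spearman_rho[1]
  obs <- acc(map)
  nulls <- vapply(seq_len(cfg$nSurrogates), function(s)
    acc(new("SurfaceMap", values = ens@maps[, s], mesh = mesh,
            name = sprintf("surrogate%03d", s))), numeric(1))
  df <- data.frame(task = mapName(map), observed_rho = obs,
                   null_mean = mean(nulls), null_sd = sd(nulls),
                   p_greater = surrogatePvalue(obs, nulls),
                   p_two_sided = surrogatePvalue(obs, nulls, "two.sided"))
  .writeMetricsCsv(df, file.path(cfg$out, "eigenstrap_pvalues.csv"))
}

.runCalcium <- function(cfg) {
  series <- if (!is.null(cfg$series)) readSeries(cfg$series)
    else {
      syn <- cfg$synthetic %||% list()
      synthMovie(gridShape = syn$gridShape %||% c(48, 48),
                 T = syn$T %||% 40, gamma = syn$gamma %||% 3,
                 temporalPhi = syn$temporalPhi %||% 0.8,
                 seed = syn$seed %||% cfg$seed)
    }
  d <- dim(seriesFrames(series))
  pc <- planarConfig(d[2:3], nLevels = cfg$nLevels,
                     rangeMultiplier = cfg$rangeMultiplier,
                     alpha = cfg$alpha, kappa2 = cfg$kappa2,
                     lambda = cfg$lambda, quantile = cfg$quantile,
                     tail = cfg$tail, minDistance = cfg$minDistance)
  rep <- seriesAnalyze(series, pc)
  fp <- .writeMetricsCsv(resultMetrics(rep),
                         file.path(cfg$out, "frames.csv"))
  inf <- rep@inference
  sm <- do.call(rbind, lapply(names(inf), function(nm)
    cbind(restriction = nm, as.data.frame(inf[[nm]]))))
  sp <- .writeMetricsCsv(sm, file.path(cfg$out, "summary.csv"))
  c(fp, sp)
}
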