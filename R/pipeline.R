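#' Default lattice kriging configuration for surface pipelines
#'
#' Central place for the analysis defaults: a 3-level spherical lattice
#' with relative level weights alpha = (1, 0.25, 0.01), bottom/top-quantile
#' masking at 0.25, an evaluation distance restriction of 0.1 radians, and
#' a fixed small noise-to-process ratio.
#'
#' @param ... overrides of the defaults.
#' @return named list of configuration values.
#' @export
latticeConfig <- function(...) {
  cfg <- list(nLevels = 3, baseSubdivision = 2, rangeMultiplier = 2.5,
              alpha = c(1, 0.25, 0.01), kappa2 = 0.01, lambda = "auto",
              lambdaGrid = 10^seq(-4, 1, length.out = 12),
              fixed = "intercept", normalize = FALSE, minDistance = 0.1,
              lattice = NULL, basisFull = NULL)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  utils::modifyList(cfg, over)
}

# Resolve a (possibly partial) config into a lattice + full-domain basis
# for the given mesh, honouring precomputed entries for reuse.
.resolveSphereDesign <- function(cfg, mesh) {
  lattice <- cfg$lattice
  if (is.null(lattice))
    lattice <- buildSphereLattice(cfg$nLevels, cfg$baseSubdivision,
                                  cfg$rangeMultiplier, cfg$alpha)
  basisFull <- cfg$basisFull
  if (is.null(basisFull))
    basisFull <- basisMatrix(lattice, mesh@coords)
  if (isTRUE(cfg$normalize) && !isTRUE(attr(basisFull, "normalized"))) {
    basisFull <- .normalizeBasis(basisFull, lattice, cfg$kappa2)
    attr(basisFull, "normalized") <- TRUE
  }
  Qalpha <- .latticePrecision(lattice, cfg$kappa2)
  list(lattice = lattice, basisFull = basisFull, Qalpha = Qalpha)
}

# Spearman rank correlation with average-rank ties; NA when undefined
# (fewer than 3 points or zero variance in either argument).
.spearman <- function(x, y) {
  if (length(x) < 3) return(NA_real_)
  # numerically constant inputs (e.g. an intercept-only prediction) have
  # meaningless ranks: report the correlation as undefined
  if (diff(range(x)) <= 1e-10 * max(1, max(abs(x))) ||
      diff(range(y)) <= 1e-10 * max(1, max(abs(y)))) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Threshold a surface map to its extreme tail
#'
#' Selects the `quantile` fraction of valid vertices with the smallest
#' (tail = "low") or largest (tail = "high") values. The member count is
#' `round(quantile * n_valid)`; ties at the cut boundary are broken by
#' ascending vertex index. Medial-wall (invalid) vertices are never
#' included.
#'
#' @param map a [SurfaceMap-class].
#' @param quantile fraction in (0, 1] (default 0.25, the bottom quarter).
#' @param tail "low" (default) or "high".
#' @return a [VertexMask-class].
#' @export
thresholdMask <- function(map, quantile = 0.25, tail = c("low", "high")) {
  stopifnot(is(map, "SurfaceMap"))
  tail <- match.arg(tail)
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile > 1)
    stop("quantile must lie in (0, 1]")
  vidx <- which(map@mesh@valid)
  if (length(vidx) < 20) stop("map must have at least 20 valid vertices")
  vals <- map@values[vidx]
  m <- round(quantile * length(vidx))
  m <- max(1L, min(length(vidx), m))
  ord <- if (tail == "low") order(vals, seq_along(vals))
         else order(-vals, seq_along(vals))
  members <- logical(nVertices(map))
  members[vidx[ord[seq_len(m)]]] <- TRUE
  new("VertexMask", members = members, tail = tail, quantile = quantile,
      mesh = map@mesh)
}

# Internal constructor shared by the spherical and planar pipelines.
.makePredictionResult <- function(domain, maskFlags, validFlags, predicted,
                                  observed, distToMask, mesh, meta,
                                  restrictions, minDistance) {
  res <- new("PredictionResult", domain = domain, maskFlags = maskFlags,
             validFlags = validFlags, predicted = predicted,
             observed = observed, distToMask = distToMask,
             metrics = data.frame(), mesh = mesh, meta = meta)
  res@metrics <- evaluatePrediction(res, restrictions, minDistance)
  res
}

#' Krige a whole surface from a masked extreme
#'
#' Fits a lattice kriging model using only the masked vertices (their
#' locations and observed values) and predicts every valid vertex of the
#' mesh. No information from out-of-mask observations enters the fit; the
#' observed map is stored solely for evaluation.
#'
#' @param map a [SurfaceMap-class].
#' @param mask a [VertexMask-class] on the same mesh (see
#'   [thresholdMask()]).
#' @param config list of lattice/fit settings, see [latticeConfig()].
#' @return a [PredictionResult-class] with metrics for the unrestricted,
#'   observed-positive and distance-restricted out-of-mask evaluations.
#' @export
krigeFromMask <- function(map, mask, config = list()) {
  stopifnot(is(map, "SurfaceMap"), is(mask, "VertexMask"))
  if (!identical(.meshFingerprint(map@mesh), .meshFingerprint(mask@mesh)))
    stop("map and mask live on different meshes")
  cfg <- latticeConfig(config)
  if (!any(mask@members)) stop("mask must be nonempty")
  if (any(!is.finite(map@values[mask@members])))
    stop("mask values must be finite")
  des <- .resolveSphereDesign(cfg, map@mesh)
  idx <- which(mask@members)
  fit <- krigFit(map@values[idx], map@mesh@coords[idx, , drop = FALSE],
                 des$lattice, lambda = cfg$lambda, fixed = cfg$fixed,
                 kappa2 = cfg$kappa2, normalize = FALSE,
                 basis = des$basisFull[idx, , drop = FALSE],
                 Qalpha = des$Qalpha, grid = cfg$lambdaGrid)
  predAll <- as.numeric(des$basisFull %*% fit@coefficients)
  X <- .fixedDesign(map@mesh@coords, cfg$fixed)
  if (ncol(X)) predAll <- predAll + as.numeric(X %*% fit@fixedCoef)
  predAll[!map@mesh@valid] <- NA_real_
  obs <- map@values
  obs[!map@mesh@valid] <- NA_real_
  d <- geodesicToSet(map@mesh, mask@members)
  meta <- list(task = map@name, meshFingerprint = .meshFingerprint(map@mesh),
               config = cfg[c("nLevels", "baseSubdivision", "rangeMultiplier",
                              "alpha", "kappa2", "lambda", "fixed",
                              "normalize", "minDistance")],
               quantile = mask@quantile, tail = mask@tail,
               model = fit)
  .makePredictionResult("sphere", mask@members, map@mesh@valid, predAll,
                        obs, d, map@mesh, meta,
                        list("none", "observed_positive", "min_distance"),
                        cfg$minDistance)
}

#' Evaluate out-of-mask prediction accuracy under restrictions
#'
#' Spearman rank correlation (average-rank ties) and mean absolute error
#' between predicted and observed values over the out-of-mask valid domain,
#' optionally restricted to points with observed values > 0
#' ("observed_positive") or farther than a minimum distance from the
#' predictor mask ("min_distance"). Restrictions leaving fewer than 10
#' points yield an NA (flagged-undefined) metric rather than an error.
#'
#' @param result a [PredictionResult-class].
#' @param restrictions character/list drawn from "none",
#'   "observed_positive", "min_distance" (a bare number is shorthand for a
#'   min-distance restriction at that radius).
#' @param minDistance radius (radians or pixels) for "min_distance".
#' @return data.frame with columns task, restriction, n, spearman_rho, mae.
#' @export
evaluatePrediction <- function(result,
                               restrictions = list("none",
                                                   "observed_positive",
                                                   "min_distance"),
                               minDistance = 0.1) {
  stopifnot(is(result, "PredictionResult"))
  out <- !result@maskFlags & result@validFlags
  task <- if (!is.null(result@meta$task)) result@meta$task else ""
  rows <- lapply(restrictions, function(r) {
    if (is.numeric(r)) {
      minDistance <- r
      r <- "min_distance"
    }
    sel <- switch(r,
      none = out,
      observed_positive = out & !is.na(result@observed) & result@observed > 0,
      min_distance = out & result@distToMask > minDistance,
      stop("unknown restriction: ", r))
    label <- if (r == "min_distance")
      sprintf("min_distance_%g", minDistance) else r
    n <- sum(sel)
    if (n < 10)
      return(data.frame(task = task, restriction = label, n = n,
                        spearman_rho = NA_real_, mae = NA_real_))
    p <- result@predicted[sel]; o <- result@observed[sel]
    data.frame(task = task, restriction = label, n = n,
               spearman_rho = .spearman(p, o), mae = mean(abs(p - o)))
  })
  do.call(rbind, rows)
}

#' Prediction accuracy as a function of distance from the mask
#'
#' Bins out-of-mask points by their distance to the predictor mask and
#' reports per-bin count, Spearman correlation and mean absolute error.
#' Bins with fewer than 10 points are flagged, not errors.
#'
#' @param result a [PredictionResult-class].
#' @param binEdges increasing distance bin edges covering the observed
#'   range (default: 8 equal-width bins over it).
#' @param nBins number of default bins when `binEdges` is NULL.
#' @return data.frame: bin_lo, bin_hi, bin_mid, n, spearman_rho, mae,
#'   flagged.
#' @export
distanceProfile <- function(result, binEdges = NULL, nBins = 8) {
  stopifnot(is(result, "PredictionResult"))
  out <- which(!result@maskFlags & result@validFlags)
  d <- result@distToMask[out]
  if (!length(d)) stop("mask covers the whole domain: empty profile")
  if (is.null(binEdges))
    binEdges <- seq(min(d), max(d) + 1e-12, length.out = nBins + 1)
  if (min(d) < min(binEdges) || max(d) >= max(binEdges) + 1e-9)
    stop("binEdges must cover the observed distance range")
  nb <- length(binEdges) - 1L
  bin <- pmin(nb, pmax(1L, findInterval(d, binEdges, rightmost.closed = TRUE)))
  rows <- lapply(seq_len(nb), function(b) {
    sel <- out[bin == b]
    n <- length(sel)
    rho <- mae <- NA_real_
    if (n >= 10) {
      rho <- .spearman(result@predicted[sel], result@observed[sel])
      mae <- mean(abs(result@predicted[sel] - result@observed[sel]))
    }
    data.frame(bin_lo = binEdges[b], bin_hi = binEdges[b + 1],
               bin_mid = (binEdges[b] + binEdges[b + 1]) / 2,
               n = n, spearman_rho = rho, mae = mae, flagged = n < 10)
  })
  do.call(rbind, rows)
}

#' Cross-task similarity of predictions
#'
#' Entry (i, j) is the Spearman correlation between task i's predicted map
#' and task j's observed map over the vertices out of task i's predictor
#' mask. The diagonal is each task's self-prediction accuracy; the matrix
#' is not symmetric.
#'
#' @param results list of [PredictionResult-class] on one common mesh.
#' @return numeric task x task matrix with task names.
#' @export
crossTaskSimilarity <- function(results) {
  if (length(results) < 2) stop("need at least 2 results")
  fps <- vapply(results, function(r) r@meta$meshFingerprint, character(1))
  if (length(unique(fps)) != 1L) stop("results live on different meshes")
  nt <- length(results)
  nms <- vapply(seq_len(nt), function(i) {
    nm <- results[[i]]@meta$task
    if (is.null(nm) || !nzchar(nm)) paste0("task", i) else nm
  }, character(1))
  M <- matrix(NA_real_, nt, nt, dimnames = list(predicted = nms,
                                                observed = nms))
  for (i in seq_len(nt)) {
    out <- !results[[i]]@maskFlags & results[[i]]@validFlags
    for (j in seq_len(nt))
      M[i, j] <- .spearman(results[[i]]@predicted[out],
                           results[[j]]@observed[out])
  }
  M
}

#' Per-vertex overlap of positive predictions across tasks
#'
#' Counts, at every vertex, how many tasks predict a positive value there,
#' and the same count for the observed maps.
#'
#' @param results list of [PredictionResult-class] on one common mesh.
#' @return list with integer vectors `predicted` and `observed` (NA at
#'   invalid vertices), each in `[0, n_tasks]`.
#' @export
overlapMap <- function(results) {
  fps <- vapply(results, function(r) r@meta$meshFingerprint, character(1))
  if (length(unique(fps)) != 1L) stop("results live on different meshes")
  valid <- results[[1]]@validFlags
  pc <- oc <- integer(length(valid))
  for (r in results) {
    pc <- pc + as.integer(!is.na(r@predicted) & r@predicted > 0)
    oc <- oc + as.integer(!is.na(r@observed) & r@observed > 0)
  }
  pc[!valid] <- NA_integer_
  oc[!valid] <- NA_integer_
  list(predicted = pc, observed = oc)
}

#' Run the masked-prediction pipeline over several threshold levels
#'
#' Repeats [thresholdMask()] + [krigeFromMask()] at each quantile (default
#' the 15%, 25% and 35% levels) and reports the metric sets side by side.
#'
#' @param map a [SurfaceMap-class].
#' @param quantiles numeric vector of mask quantiles.
#' @param tail "low" or "high".
#' @param config see [latticeConfig()].
#' @return data.frame of metrics with a `quantile` column.
#' @export
thresholdSweep <- function(map, quantiles = c(0.15, 0.25, 0.35),
                           tail = "low", config = list()) {
  cfg <- latticeConfig(config)
  # reuse one lattice/basis across quantiles
  des <- .resolveSphereDesign(cfg, map@mesh)
  cfg$lattice <- des$lattice
  cfg$basisFull <- des$basisFull
  rows <- lapply(quantiles, function(q) {
    res <- krigeFromMask(map, thresholdMask(map, q, tail), cfg)
    cbind(quantile = q, resultMetrics(res))
  })
  do.call(rbind, rows)
}
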