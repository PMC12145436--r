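#' SphericalMesh: a triangulated unit sphere with a validity mask
#'
#' The spatial domain for all spherical analyses. Vertices live on the unit
#' sphere; `valid` flags vertices that take part in fitting, evaluation and
#' eigenmode computation (FALSE marks the medial wall or other exclusions).
#'
#' @slot coords numeric matrix (V x 3) of unit vectors.
#' @slot triangles integer matrix (F x 3) of 1-based vertex indices.
#' @slot valid logical vector of length V.
#' @exportClass SphericalMesh
setClass("SphericalMesh",
  representation(coords = "matrix", triangles = "matrix", valid = "logical"))

setValidity("SphericalMesh", function(object) {
  v <- nrow(object@coords)
  msgs <- character()
  if (ncol(object@coords) != 3L) msgs <- c(msgs, "coords must be V x 3")
  nrm <- sqrt(rowSums(object@coords^2))
  if (any(abs(nrm - 1) > 1e-9))
    msgs <- c(msgs, "all vertices must have unit norm (tolerance 1e-9)")
  if (nrow(object@triangles) > 0) {
    if (ncol(object@triangles) != 3L) msgs <- c(msgs, "triangles must be F x 3")
    if (min(object@triangles) < 1L || max(object@triangles) > v)
      msgs <- c(msgs, "triangle indices out of range")
  }
  if (length(object@valid) != v)
    msgs <- c(msgs, "valid mask length must equal vertex count")
  if (length(msgs)) msgs else TRUE
})

#' SurfaceMap: one scalar value per vertex of a SphericalMesh
#'
#' Holds a per-vertex scalar field (typically a task-contrast z-score map)
#' bound to its mesh. Values on invalid (medial-wall) vertices may be NA.
#'
#' @slot values numeric vector, one value per vertex.
#' @slot mesh the [SphericalMesh-class] the values live on.
#' @slot name character label for the map.
#' @exportClass SurfaceMap
setClass("SurfaceMap",
  representation(values = "numeric", mesh = "SphericalMesh", name = "character"))

setValidity("SurfaceMap", function(object) {
  if (length(object@values) != nrow(object@mesh@coords))
    return("values length must equal mesh vertex count")
  if (any(!is.finite(object@values[object@mesh@valid])))
    return("values must be finite on valid vertices")
  TRUE
})

#' VertexMask: a subset of valid vertices from a quantile threshold
#'
#' @slot members logical per vertex; TRUE marks mask membership.
#' @slot tail "low" or "high": which extreme of the value distribution.
#' @slot quantile fraction in (0, 1] of valid vertices selected.
#' @slot mesh the mesh the mask refers to.
#' @exportClass VertexMask
setClass("VertexMask",
  representation(members = "logical", tail = "character",
                 quantile = "numeric", mesh = "SphericalMesh"))

setValidity("VertexMask", function(object) {
  if (length(object@members) != nrow(object@mesh@coords))
    return("members length must equal mesh vertex count")
  if (any(object@members & !object@mesh@valid))
    return("mask members must be valid vertices")
  if (!object@tail %in% c("low", "high")) return("tail must be 'low' or 'high'")
  if (object@quantile <= 0 || object@quantile > 1)
    return("quantile must lie in (0, 1]")
  TRUE
})

#' EigenBasis: Laplacian eigenmodes of a mesh
#'
#' Modes are orthonormal under the stored vertex weighting
#' (t(modes) %*% diag(weights) %*% modes = I on valid vertices). The first
#' mode is constant with eigenvalue 0. Rows at invalid vertices are zero.
#'
#' @slot modes numeric matrix (V x k).
#' @slot eigenvalues nonnegative, ascending, length k.
#' @slot weights per-vertex weights of the inner product (0 at invalid).
#' @exportClass EigenBasis
setClass("EigenBasis",
  representation(modes = "matrix", eigenvalues = "numeric", weights = "numeric"))

setValidity("EigenBasis", function(object) {
  k <- ncol(object@modes)
  if (length(object@eigenvalues) != k) return("one eigenvalue per mode")
  if (is.unsorted(object@eigenvalues, strictly = FALSE))
    return("eigenvalues must be ascending")
  if (object@eigenvalues[1] > 1e-8) return("first eigenvalue must be ~0")
  TRUE
})

#' MultiresLattice: the kriging design
#'
#' A list of basis-node levels (coarse to fine) on the sphere or the plane.
#' Each level carries node coordinates, a single basis range (radians on the
#' sphere, pixels on the plane) and its lattice neighbour edges, which define
#' the spatial-autoregressive coefficient prior.
#'
#' @slot domain "sphere" or "plane".
#' @slot levels list; each element has `nodes` (matrix), `range` (numeric),
#'   `edges` (2-column integer matrix of lattice neighbour pairs).
#' @slot alpha per-level nonnegative variance weights.
#' @slot config echo of the constructor arguments (for serialization).
#' @exportClass MultiresLattice
setClass("MultiresLattice",
  representation(domain = "character", levels = "list", alpha = "numeric",
                 config = "list"))

setValidity("MultiresLattice", function(object) {
  if (!object@domain %in% c("sphere", "plane"))
    return("domain must be 'sphere' or 'plane'")
  if (length(object@alpha) != length(object@levels))
    return("alpha must have one weight per level")
  if (any(object@alpha < 0)) return("alpha weights must be nonnegative")
  rng <- vapply(object@levels, function(l) l$range, numeric(1))
  if (length(rng) > 1 && any(diff(rng) >= 0))
    return("basis ranges must be strictly decreasing across levels")
  nn <- vapply(object@levels, function(l) nrow(l$nodes), numeric(1))
  if (length(nn) > 1 && any(diff(nn) <= 0))
    return("each level must be strictly denser than the previous")
  TRUE
})

#' KrigingModel: a fitted lattice kriging model
#'
#' @slot lattice the [MultiresLattice-class] design.
#' @slot coefficients one coefficient per basis node (all levels stacked).
#' @slot fixedCoef coefficients of the fixed part (intercept first).
#' @slot fixed "intercept" or "intercept+linear".
#' @slot lambda nonnegative noise-to-process variance ratio used in the fit.
#' @slot kappa2 SAR diagonal augmentation of the coefficient prior.
#' @slot normalize logical; basis variance normalization applied?
#' @slot trainingLocations,trainingValues retained for diagnostics.
#' @slot info solve metadata (criterion values, effective df when computed).
#' @exportClass KrigingModel
setClass("KrigingModel",
  representation(lattice = "MultiresLattice", coefficients = "numeric",
                 fixedCoef = "numeric", fixed = "character", lambda = "numeric",
                 kappa2 = "numeric", normalize = "logical",
                 trainingLocations = "matrix", trainingValues = "numeric",
                 info = "list"))

setValidity("KrigingModel", function(object) {
  p <- sum(vapply(object@lattice@levels, function(l) nrow(l$nodes), numeric(1)))
  if (length(object@coefficients) != p)
    return("coefficient count must equal total node count")
  if (object@lambda < 0) return("lambda must be nonnegative")
  TRUE
})

#' PredictionResult: whole-domain prediction from a masked extreme
#'
#' Stores the predictor mask, predicted and observed values over the whole
#' domain, the distance of every point to the predictor mask, and the
#' evaluation metrics. Spherical results carry their mesh; planar results
#' carry point coordinates and a validity mask instead.
#'
#' @slot domain "sphere" or "plane".
#' @slot maskFlags logical per point: predictor-mask membership.
#' @slot validFlags logical per point: analysis domain membership.
#' @slot predicted,observed numeric per point (NA outside validFlags).
#' @slot distToMask distance (radians / pixels) to the nearest mask point.
#' @slot metrics data.frame: restriction, n, spearman_rho, mae.
#' @slot mesh the SphericalMesh for spherical results (empty for planar).
#' @slot meta list: config echo, map name, timing.
#' @exportClass PredictionResult
setClass("PredictionResult",
  representation(domain = "character", maskFlags = "logical",
                 validFlags = "logical", predicted = "numeric",
                 observed = "numeric", distToMask = "numeric",
                 metrics = "data.frame", mesh = "ANY", meta = "list"))

setValidity("PredictionResult", function(object) {
  n <- length(object@predicted)
  if (length(object@observed) != n || length(object@maskFlags) != n ||
      length(object@validFlags) != n || length(object@distToMask) != n)
    return("per-point slots must have equal length")
  if (any(object@maskFlags & !object@validFlags))
    return("mask must be contained in the valid domain")
  TRUE
})

#' SurrogateEnsemble: eigenmode-rotation surrogate maps
#'
#' @slot maps numeric matrix (V x n): one surrogate per column (NA at
#'   invalid vertices).
#' @slot seed integer seed the ensemble is reproducible from.
#' @slot resample logical: were values rank-remapped onto the original
#'   value multiset?
#' @slot meta list (group structure, generator version).
#' @exportClass SurrogateEnsemble
setClass("SurrogateEnsemble",
  representation(maps = "matrix", seed = "numeric", resample = "logical",
                 meta = "list"))

#' SpinEnsemble: spin-rotation permutations of a label map
#'
#' @slot rotatedLabels integer matrix (V x n): one rotated labelling per
#'   column.
#' @slot seed integer seed.
#' @slot meta list (resampled-rotation count, generator version).
#' @exportClass SpinEnsemble
setClass("SpinEnsemble",
  representation(rotatedLabels = "matrix", seed = "numeric", meta = "list"))

#' ImageSeries: a planar image time series
#'
#' @slot frames numeric array (T x rows x cols), fluorescence a.u.
#' @slot pixelValid logical matrix (rows x cols): analysis support.
#' @slot pixelSize optional physical pixel scale (length 0 if unknown).
#' @exportClass ImageSeries
setClass("ImageSeries",
  representation(frames = "array", pixelValid = "matrix",
                 pixelSize = "numeric"))

setValidity("ImageSeries", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a T x rows x cols array")
  if (d[1] < 1L) return("at least one frame required")
  if (!identical(dim(object@pixelValid), d[2:3]))
    return("pixelValid must match frame dimensions")
  TRUE
})

#' PairwiseReport: task-specificity comparison for one ordered task pair
#'
#' @slot taskPair character(2): (true task A, alternative task B).
#' @slot conjunctionSize vertex count of the conjunction mask.
#' @slot table data.frame: restriction, n, rho_true, rho_alt, winner.
#' @exportClass PairwiseReport
setClass("PairwiseReport",
  representation(taskPair = "character", conjunctionSize = "numeric",
                 table = "data.frame"))

#' SeriesReport: per-frame kriging metrics and group inference for a series
#'
#' @slot frameMetrics data.frame with one row per frame: frame, n_all,
#'   rho_all, n_dist, rho_dist, fisher_z_all, fisher_z_dist.
#' @slot inference list of inference records (t-test and AR(1)-adjusted),
#'   one per restriction.
#' @slot config echo of the analysis configuration.
#' @exportClass SeriesReport
setClass("SeriesReport",
  representation(frameMetrics = "data.frame", inference = "list",
                 config = "list"))
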