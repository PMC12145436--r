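#' Wendland compactly supported radial kernel
#'
#' The C4-smooth Wendland polynomial used for all basis functions:
#' with r = d/range, value = (1-r)^6 (35 r^2 + 18 r + 3) / 3 for r < 1 and
#' exactly 0 beyond the range.
#'
#' @param d nonnegative distances (radians or pixels).
#' @param range positive support radius, same units as `d`.
#' @return kernel values in `[0, 1]`; `wendland(0, r)` is 1.
#' @examples
#' wendland(0, 1)          # 1
#' wendland(0.5, 1)        # 0.108072916...
#' @export
wendland <- function(d, range) {
  if (length(range) != 1L || !is.finite(range) || range <= 0)
    stop("range must be a single positive number")
  if (any(d < 0)) stop("distances must be nonnegative")
  r <- d / range
  out <- numeric(length(d))
  inside <- r < 1
  ri <- r[inside]
  out[inside] <- (1 - ri)^6 * (35 * ri^2 + 18 * ri + 3) / 3
  dim(out) <- dim(d)
  out
}

#' Build a multiresolution spherical lattice
#'
#' Basis-node levels are icosphere vertex sets of increasing subdivision:
#' level l uses `buildIcosphere(baseSubdivision + l - 1)`, so node counts
#' follow 10 * 4^n + 2 (e.g. 162, 642, 2562 for the defaults). Each level's
#' basis range is `rangeMultiplier` times the median nearest-node arc at
#' that level, and its lattice edges are the icosphere edges. Lattice nodes
#' tile the whole sphere regardless of any medial-wall masking of the data.
#'
#' @param nLevels number of resolution levels (default 3).
#' @param baseSubdivision icosphere subdivision of the coarsest level
#'   (default 2, giving node counts 162, 642, 2562).
#' @param rangeMultiplier basis range as a multiple of the median
#'   nearest-node arc (default 2.5, so neighbouring bases overlap).
#' @param alpha per-level relative variance weights
#'   (default `c(1, 0.25, 0.01)`).
#' @return a [MultiresLattice-class] with domain "sphere".
#' @export
buildSphereLattice <- function(nLevels = 3, baseSubdivision = 2,
                               rangeMultiplier = 2.5,
                               alpha = c(1, 0.25, 0.01)) {
  if (nLevels < 1 || nLevels != round(nLevels))
    stop("nLevels must be a positive integer")
  if (length(alpha) != nLevels)
    stop(sprintf("alpha must have length nLevels (%d), got %d",
                 as.integer(nLevels), length(alpha)))
  levels <- vector("list", nLevels)
  for (l in seq_len(nLevels)) {
    ms <- buildIcosphere(baseSubdivision + l - 1)
    edges <- .meshEdges(ms@triangles)
    arcs <- greatCircleDistance(ms@coords[edges[, 1], , drop = FALSE],
                                ms@coords[edges[, 2], , drop = FALSE])
    nearest <- rep(Inf, nrow(ms@coords))
    for (c2 in 1:2) {
      mn <- tapply(arcs, edges[, c2], min)
      idx <- as.integer(names(mn))
      nearest[idx] <- pmin(nearest[idx], mn)
    }
    levels[[l]] <- list(nodes = ms@coords,
                        range = rangeMultiplier * median(nearest),
                        edges = edges)
  }
  new("MultiresLattice", domain = "sphere", levels = levels,
      alpha = as.numeric(alpha),
      config = list(nLevels = nLevels, baseSubdivision = baseSubdivision,
                    rangeMultiplier = rangeMultiplier,
                    alpha = as.numeric(alpha)))
}

#' Build a multiresolution planar lattice
#'
#' Regular-grid node levels over a `rows x cols` pixel domain, with node
#' spacing halving at each level and nodes padded one spacing beyond the
#' domain on every side. Distances are Euclidean in pixel units; lattice
#' edges connect 4-neighbours.
#'
#' @param gridShape integer c(rows, cols), each at least 8.
#' @param nLevels number of levels (default 3).
#' @param rangeMultiplier basis range as a multiple of the node spacing
#'   (default 2.5).
#' @param alpha per-level relative variance weights.
#' @param baseSpacing spacing (pixels) of the coarsest level; default
#'   `max(gridShape) / 8`.
#' @return a [MultiresLattice-class] with domain "plane". Point coordinates
#'   for planar lattices are (x = column, y = row) pixel positions.
#' @export
buildPlanarLattice <- function(gridShape, nLevels = 3, rangeMultiplier = 2.5,
                               alpha = c(1, 0.25, 0.01),
                               baseSpacing = max(gridShape) / 8) {
  gridShape <- as.numeric(gridShape)
  if (length(gridShape) != 2L || any(gridShape < 8))
    stop("gridShape must be c(rows, cols) with both >= 8")
  if (nLevels < 1 || nLevels != round(nLevels))
    stop("nLevels must be a positive integer")
  if (length(alpha) != nLevels)
    stop(sprintf("alpha must have length nLevels (%d), got %d",
                 as.integer(nLevels), length(alpha)))
  finest <- baseSpacing / 2^(nLevels - 1)
  if (finest < 1)
    stop(sprintf(
      "nLevels = %d makes the finest node spacing %.3g < 1 pixel",
      as.integer(nLevels), finest))
  levels <- vector("list", nLevels)
  for (l in seq_len(nLevels)) {
    s <- baseSpacing / 2^(l - 1)
    xs <- seq(1 - s, gridShape[2] + s + 1e-9, by = s)
    ys <- seq(1 - s, gridShape[1] + s + 1e-9, by = s)
    nodes <- as.matrix(expand.grid(x = xs, y = ys))
    nx <- length(xs); ny <- length(ys)
    id <- matrix(seq_len(nx * ny), nx, ny)  # column-major: x fastest
    eH <- cbind(as.vector(id[-nx, ]), as.vector(id[-1, ]))
    eV <- cbind(as.vector(id[, -ny]), as.vector(id[, -1]))
    levels[[l]] <- list(nodes = nodes, range = rangeMultiplier * s,
                        edges = rbind(eH, eV))
  }
  new("MultiresLattice", domain = "plane", levels = levels,
      alpha = as.numeric(alpha),
      config = list(gridShape = gridShape, nLevels = nLevels,
                    rangeMultiplier = rangeMultiplier,
                    alpha = as.numeric(alpha), baseSpacing = baseSpacing))
}

.euclidCrossDist <- function(A, B, chunk = 2048L) {
  n <- nrow(A)
  out <- matrix(0, n, nrow(B))
  b2 <- rowSums(B^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    a <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(a^2), b2, "+") - 2 * tcrossprod(a, B)
    out[s:e, ] <- sqrt(pmax(d2, 0))
  }
  out
}

.checkDomainPoints <- function(lattice, points) {
  points <- as.matrix(points)
  need <- if (lattice@domain == "sphere") 3L else 2L
  if (ncol(points) != need)
    stop(sprintf("%s lattice expects %d-column point coordinates, got %d",
                 lattice@domain, need, ncol(points)))
  if (lattice@domain == "sphere") {
    nrm <- sqrt(rowSums(points^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("sphere lattice expects unit-norm point coordinates")
  }
  points
}

#' Basis matrix of a lattice at a set of points
#'
#' Sparse matrix of Wendland kernel evaluations: entry (i, j) is
#' `wendland(dist(point_i, node_j), range of node_j's level)`, with
#' great-circle distances on the sphere and Euclidean distances on the
#' plane. Rows only touch nodes within range. Points outside every basis
#' support give an all-zero row; their indices are attached as attribute
#' `"zeroRows"` and a warning is emitted.
#'
#' @param lattice a [MultiresLattice-class].
#' @param points matrix of point coordinates (n x 3 unit vectors on the
#'   sphere, n x 2 pixel positions on the plane).
#' @return a sparse `dgCMatrix` (points x total nodes) with attribute
#'   `"levelSizes"` giving the per-level column-block sizes.
#' @export
basisMatrix <- function(lattice, points) {
  stopifnot(is(lattice, "MultiresLattice"))
  points <- .checkDomainPoints(lattice, points)
  blocks <- vector("list", length(lattice@levels))
  for (l in seq_along(lattice@levels)) {
    lev <- lattice@levels[[l]]
    D <- if (lattice@domain == "sphere")
      .arcCrossDist(points, lev$nodes) else .euclidCrossDist(points, lev$nodes)
    idx <- which(D < lev$range, arr.ind = TRUE)
    blocks[[l]] <- Matrix::sparseMatrix(
      i = idx[, 1], j = idx[, 2],
      x = wendland(D[idx], lev$range),
      dims = c(nrow(points), nrow(lev$nodes)))
  }
  Phi <- do.call(cbind, blocks)
  zero <- which(Matrix::rowSums(Phi != 0) == 0)
  if (length(zero))
    warning(sprintf("%d point(s) outside all basis supports", length(zero)))
  attr(Phi, "zeroRows") <- zero
  attr(Phi, "levelSizes") <-
    vapply(lattice@levels, function(l) nrow(l$nodes), numeric(1))
  Phi
}

#' SAR precision matrix of one lattice level
#'
#' The coefficient prior at each level is a spatial autoregression on the
#' lattice neighbour graph: with B = diag(degree + kappa2) - adjacency, the
#' precision is Q = t(B) B, symmetric and positive definite for kappa2 > 0.
#'
#' @param level one element of a lattice's `levels` list (fields `nodes`,
#'   `edges`), or a [MultiresLattice-class] together with `whichLevel`.
#' @param kappa2 nonnegative diagonal augmentation (default 0.01).
#' @param whichLevel level index when `level` is a lattice.
#' @return sparse symmetric positive-(semi)definite matrix.
#' @export
sarPrecision <- function(level, kappa2 = 0.01, whichLevel = 1L) {
  if (is(level, "MultiresLattice")) level <- level@levels[[whichLevel]]
  if (kappa2 < 0) stop("kappa2 must be nonnegative")
  n <- nrow(level$nodes)
  A <- Matrix::sparseMatrix(
    i = c(level$edges[, 1], level$edges[, 2]),
    j = c(level$edges[, 2], level$edges[, 1]),
    x = 1, dims = c(n, n))
  B <- Matrix::Diagonal(x = Matrix::rowSums(A) + kappa2) - A
  Matrix::forceSymmetric(Matrix::crossprod(B))
}

# Block-diagonal multiresolution prior precision: level l block is
# sarPrecision(l) / alpha_l. alpha_l = 0 disables the level (infinite
# penalty is approximated by an error instead).
.latticePrecision <- function(lattice, kappa2 = 0.01) {
  if (any(lattice@alpha <= 0))
    stop("alpha weights must be positive to form the coefficient prior")
  Matrix::forceSymmetric(Matrix::bdiag(lapply(
    seq_along(lattice@levels),
    function(l) sarPrecision(lattice@levels[[l]], kappa2) / lattice@alpha[l])))
}

.fixedDesign <- function(points, fixed) {
  switch(fixed,
         none = matrix(numeric(0), nrow(points), 0),
         intercept = matrix(1, nrow(points), 1),
         `intercept+linear` = cbind(1, points),
         stop("fixed must be 'none', 'intercept' or 'intercept+linear'"))
}

# Basis variance normalization: divide each row of a level block by the
# prior-implied marginal sd sqrt(alpha_l * phi_i Q_l^-1 phi_i^T).
.normalizeBasis <- function(Phi, lattice, kappa2) {
  sizes <- attr(Phi, "levelSizes")
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  out <- Phi
  for (l in seq_along(sizes)) {
    cols <- starts[l]:stops[l]
    block <- Phi[, cols, drop = FALSE]
    Q <- sarPrecision(lattice@levels[[l]], kappa2)
    S <- Matrix::solve(Q, Matrix::t(block))
    v <- lattice@alpha[l] * Matrix::colSums(Matrix::t(block) * S)
    out[, cols] <- block / sqrt(pmax(as.numeric(v), 1e-12))
  }
  attributes(out)$levelSizes <- sizes
  out
}

# Core penalized solve shared by krigFit and selectLambda.
# Minimizes ||y - X b - Phi c||^2 + lambda * t(c) Q c; returns b, c and the
# factorization byproducts needed by the selection criteria.
.krigSolve <- function(y, X, Phi, Q, lambda) {
  q <- ncol(X)
  p <- ncol(Phi)
  A <- cbind(as(X, "sparseMatrix"), Phi)
  M <- Matrix::forceSymmetric(Matrix::crossprod(A))
  if (lambda > 0) {
    pen <- Matrix::bdiag(Matrix::Diagonal(q, 0), lambda * Q)
    M <- Matrix::forceSymmetric(M + pen)
  }
  rhs <- Matrix::crossprod(A, y)
  sol <- tryCatch(Matrix::solve(M, rhs),
                  error = function(e) stop(
                    "penalized system is singular (duplicate locations at ",
                    "lambda = 0?); refit with lambda > 0: ",
                    conditionMessage(e), call. = FALSE))
  sol <- as.numeric(sol)
  list(beta = if (q) sol[seq_len(q)] else numeric(0),
       coef = sol[q + seq_len(p)],
       A = A, M = M, q = q, p = p)
}

#' Fit a lattice kriging model
#'
#' Penalized least squares with the multiresolution SAR prior: the basis
#' coefficients solve `(t(Phi) Phi + lambda Q_alpha) c = t(Phi) (y - X b)`,
#' where `Q_alpha` is block-diagonal with level-l block
#' `sarPrecision(l)/alpha_l`, jointly with the unpenalized fixed part.
#' `lambda` is the noise-to-process variance ratio; `lambda = "auto"`
#' selects it by [selectLambda()].
#'
#' @param values observed scalars (length >= 10).
#' @param locations observation coordinates (rows; unit 3-vectors on the
#'   sphere, (x, y) pixels on the plane).
#' @param lattice a [MultiresLattice-class].
#' @param lambda nonnegative ratio, or "auto".
#' @param fixed "intercept" (default), "intercept+linear", or "none".
#' @param kappa2 SAR diagonal augmentation (default 0.01).
#' @param normalize divide basis rows by the prior-implied marginal sd
#'   (default FALSE).
#' @param basis optional precomputed `basisMatrix(lattice, locations)`.
#' @param Qalpha optional precomputed prior precision.
#' @param ... passed to [selectLambda()] when `lambda = "auto"`.
#' @return a [KrigingModel-class].
#' @export
krigFit <- function(values, locations, lattice, lambda = 1e-3,
                    fixed = c("intercept", "intercept+linear", "none"),
                    kappa2 = 0.01, normalize = FALSE, basis = NULL,
                    Qalpha = NULL, ...) {
  fixed <- match.arg(fixed)
  locations <- .checkDomainPoints(lattice, locations)
  values <- as.numeric(values)
  if (length(values) != nrow(locations))
    stop("values and locations must have matching length")
  if (length(values) < 10) stop("at least 10 observations required")
  if (any(!is.finite(values))) stop("values must be finite")
  Phi <- if (is.null(basis)) basisMatrix(lattice, locations) else basis
  if (normalize) Phi <- .normalizeBasis(Phi, lattice, kappa2)
  Q <- if (is.null(Qalpha)) .latticePrecision(lattice, kappa2) else Qalpha
  info <- list()
  if (identical(lambda, "auto")) {
    lambda <- selectLambda(values, locations, lattice, kappa2 = kappa2,
                           fixed = fixed, basis = Phi, Qalpha = Q, ...)
    info$lambdaCriterion <- attr(lambda, "criterion")
    lambda <- as.numeric(lambda)
  }
  if (!is.numeric(lambda) || lambda < 0)
    stop("lambda must be a nonnegative number or 'auto'")
  X <- .fixedDesign(locations, fixed)
  sol <- .krigSolve(values, X, Phi, Q, lambda)
  new("KrigingModel", lattice = lattice, coefficients = sol$coef,
      fixedCoef = sol$beta, fixed = fixed, lambda = lambda, kappa2 = kappa2,
      normalize = normalize, trainingLocations = locations,
      trainingValues = values, info = info)
}

#' Predict from a fitted lattice kriging model
#'
#' Fixed part plus basis expansion at new points; linear in the training
#' values for fixed lambda. Points outside every basis support receive the
#' fixed part only (with a warning from the basis construction).
#'
#' @param object a [KrigingModel-class].
#' @param points matrix of prediction coordinates.
#' @param basis optional precomputed `basisMatrix(lattice, points)`.
#' @return numeric predictions, one per point.
#' @export
setMethod("predict", "KrigingModel", function(object, points, basis = NULL) {
  points <- .checkDomainPoints(object@lattice, points)
  Phi <- if (is.null(basis)) basisMatrix(object@lattice, points) else basis
  if (object@normalize) Phi <- .normalizeBasis(Phi, object@lattice,
                                               object@kappa2)
  X <- .fixedDesign(points, object@fixed)
  out <- as.numeric(Phi %*% object@coefficients)
  if (ncol(X)) out <- out + as.numeric(X %*% object@fixedCoef)
  out
})

#' Select the regularization ratio lambda on a grid
#'
#' Evaluates a model-selection criterion over a log-spaced grid of
#' candidate noise-to-process ratios and returns the minimizer, breaking
#' exact ties toward the larger (more conservative, heavier-smoothing)
#' candidate. `"profile_likelihood"` (default) is the profiled Gaussian
#' maximum likelihood of the lattice kriging model, computed sparsely via
#' the Woodbury identity; `"gcv"` is generalized cross-validation.
#'
#' @inheritParams krigFit
#' @param grid positive candidate values (default 22 points, 1e-5 to 1e2).
#' @param criterion "profile_likelihood" or "gcv".
#' @return selected lambda (numeric scalar) with the full criterion table in
#'   attribute "criterion".
#' @export
selectLambda <- function(values, locations, lattice,
                         grid = 10^seq(-5, 2, length.out = 22),
                         criterion = c("profile_likelihood", "gcv"),
                         fixed = "intercept", kappa2 = 0.01, basis = NULL,
                         Qalpha = NULL) {
  criterion <- match.arg(criterion)
  if (!length(grid)) stop("candidate grid must be nonempty")
  if (any(grid <= 0)) stop("candidate lambdas must be positive")
  locations <- .checkDomainPoints(lattice, locations)
  y <- as.numeric(values)
  n <- length(y)
  Phi <- if (is.null(basis)) basisMatrix(lattice, locations) else basis
  Q <- if (is.null(Qalpha)) .latticePrecision(lattice, kappa2) else Qalpha
  X <- .fixedDesign(locations, fixed)
  p <- ncol(Phi)
  grid <- sort(as.numeric(grid))
  ldQ <- as.numeric(Matrix::determinant(Q, logarithm = TRUE)$modulus)
  crit <- vapply(grid, function(lam) {
    Mc <- Matrix::forceSymmetric(Matrix::crossprod(Phi) + lam * Q)
    ch <- tryCatch(Matrix::Cholesky(Mc, LDL = FALSE),
                   error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    V0inv <- function(z) {
      (z - as.numeric(Phi %*% Matrix::solve(
        ch, Matrix::crossprod(Phi, z)))) / lam
    }
    if (criterion == "profile_likelihood") {
      if (ncol(X)) {
        VX <- apply(X, 2, V0inv)
        beta <- solve(crossprod(X, VX), crossprod(VX, y))
        r <- y - as.numeric(X %*% beta)
      } else r <- y
      quad <- sum(r * V0inv(r))
      if (quad <= 0) return(NA_real_)
      ldM <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
      ldV0 <- (n - p) * log(lam) + ldM - ldQ
      n * log(quad / n) + ldV0
    } else {
      sol <- .krigSolve(y, X, Phi, Q, lam)
      fitv <- as.numeric(sol$A %*% c(sol$beta, sol$coef))
      rss <- sum((y - fitv)^2)
      chM <- Matrix::Cholesky(sol$M, LDL = FALSE)
      W <- Matrix::solve(chM, Matrix::t(sol$A))
      trH <- sum(as.matrix(Matrix::t(sol$A)) * as.matrix(W))
      if (trH >= n) return(NA_real_)
      n * rss / (n - trH)^2
    }
  }, numeric(1))
  if (all(!is.finite(crit)))
    stop("criterion is non-finite across the whole grid")
  best <- which(crit <= min(crit, na.rm = TRUE) + 0) # exact minima
  best <- max(best[is.finite(crit[best])])           # tie -> larger lambda
  out <- grid[best]
  attr(out, "criterion") <- data.frame(lambda = grid, value = crit)
  out
}

#' Simulate a field from the lattice kriging generative model
#'
#' Draws coefficients from the multiresolution SAR prior
#' (`c_l ~ N(0, rho * alpha_l * Q_l^-1)`), evaluates the basis expansion at
#' the given locations and adds nugget noise of variance `sigma2`. The
#' implied true noise-to-process ratio is `lambda = sigma2 / rho`.
#'
#' @param lattice a [MultiresLattice-class].
#' @param locations evaluation coordinates.
#' @param rho process marginal variance multiplier.
#' @param sigma2 nugget variance.
#' @param kappa2 SAR augmentation used in the prior.
#' @param seed integer seed.
#' @param basis optional precomputed basis matrix.
#' @return list with `values` (numeric), `coefficients`, and `lambdaTrue`.
#' @export
simulateLatticeField <- function(lattice, locations, rho = 1, sigma2 = 0.01,
                                 kappa2 = 0.01, seed = 1, basis = NULL) {
  locations <- .checkDomainPoints(lattice, locations)
  Phi <- if (is.null(basis)) basisMatrix(lattice, locations) else basis
  .withSeed(seed, function() {
    coefs <- lapply(seq_along(lattice@levels), function(l) {
      Q <- as.matrix(sarPrecision(lattice@levels[[l]], kappa2))
      R <- chol(Q)                       # Q = t(R) R ; cov = Q^-1
      z <- rnorm(nrow(Q))
      sqrt(rho * lattice@alpha[l]) * backsolve(R, z)
    })
    cc <- unlist(coefs)
    y <- as.numeric(Phi %*% cc) + rnorm(nrow(Phi), sd = sqrt(sigma2))
    list(values = y, coefficients = cc, lambdaTrue = sigma2 / rho)
  })
}

#' Save / load a fitted kriging model as JSON
#'
#' The lattice is stored as its constructor configuration (node sets are
#' deterministic) together with coefficients, fixed part and lambda.
#'
#' @param model a [KrigingModel-class].
#' @param path output file path (.json).
#' @export
saveKrigingModel <- function(model, path) {
  stopifnot(is(model, "KrigingModel"))
  obj <- list(domain = model@lattice@domain,
              latticeConfig = model@lattice@config,
              coefficients = model@coefficients,
              fixedCoef = model@fixedCoef, fixed = model@fixed,
              lambda = model@lambda, kappa2 = model@kappa2,
              normalize = model@normalize,
              trainingLocations = model@trainingLocations,
              trainingValues = model@trainingValues)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveKrigingModel
#' @export
readKrigingModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$latticeConfig
  lattice <- if (obj$domain == "sphere")
    buildSphereLattice(cfg$nLevels, cfg$baseSubdivision, cfg$rangeMultiplier,
                       cfg$alpha)
  else
    buildPlanarLattice(cfg$gridShape, cfg$nLevels, cfg$rangeMultiplier,
                       cfg$alpha, cfg$baseSpacing)
  new("KrigingModel", lattice = lattice,
      coefficients = as.numeric(obj$coefficients),
      fixedCoef = as.numeric(obj$fixedCoef), fixed = obj$fixed,
      lambda = obj$lambda, kappa2 = obj$kappa2, normalize = obj$normalize,
      trainingLocations = as.matrix(obj$trainingLocations),
      trainingValues = as.numeric(obj$trainingValues), info = list())
}
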