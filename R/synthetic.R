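#' Synthesis specification for surface-map generators
#'
#' Bundles the parameters of the eigenmode-based map generator: a power-law
#' spectral decay exponent `gamma` (larger = smoother maps), the number of
#' eigenmodes carrying signal, the i.i.d. vertex noise level, and a seed.
#' Identical specs give bit-identical outputs.
#'
#' @param gamma nonnegative spectral decay exponent. `gamma = 0` is defined
#'   as white noise (a flat spectrum over the full orthonormal vertex basis
#'   is i.i.d. noise); `gamma >= 3` gives the smooth, strongly
#'   autocorrelated regime.
#' @param nModes number of (non-constant) eigenmodes carrying signal.
#' @param noiseSd standard deviation of the additive i.i.d. vertex noise,
#'   relative to the unit-variance smooth component.
#' @param seed integer seed.
#' @return classed list of generator settings.
#' @export
synthSpec <- function(gamma = 3, nModes = 200, noiseSd = 0.1, seed = 1) {
  if (gamma < 0) stop("gamma must be nonnegative")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  structure(list(gamma = gamma, nModes = nModes, noiseSd = noiseSd,
                 seed = seed), class = "synthSpec")
}

# Draw one standardized field on the valid vertices using the CURRENT RNG
# state. Returns a full-length vector (NA at invalid vertices).
.synthField <- function(mesh, gamma, nModes, noiseSd, basis = NULL) {
  nV <- nVertices(mesh)
  vidx <- which(mesh@valid)
  x <- rep(NA_real_, nV)
  if (gamma == 0 || nModes == 0) {
    # flat spectrum == white noise on vertices
    v <- rnorm(length(vidx))
    if (noiseSd > 0) v <- v + rnorm(length(vidx), sd = noiseSd)
    x[vidx] <- as.numeric(scale(v))
    return(x)
  }
  if (is.null(basis)) basis <- meshEigenmodes(mesh, nModes + 1)
  if (ncol(basis@modes) < nModes + 1)
    stop(sprintf("basis has %d modes; need nModes + 1 = %d",
                 ncol(basis@modes), nModes + 1))
  lam <- basis@eigenvalues[2:(nModes + 1)]
  w <- (lam / lam[1])^(-gamma / 2)
  a <- rnorm(nModes) * w
  sig <- as.numeric(basis@modes[vidx, 2:(nModes + 1), drop = FALSE] %*% a)
  sig <- sig / sd(sig)
  if (noiseSd > 0) sig <- sig + rnorm(length(vidx), sd = noiseSd)
  x[vidx] <- as.numeric(scale(sig))
  x
}

#' Generate a smooth autocorrelated map on a spherical mesh
#'
#' Draws `map = sum_k a_k lambda_k^(-gamma/2) psi_k + noise` with i.i.d.
#' standard-normal `a_k` over the mesh Laplacian eigenmodes `psi_k`
#' (constant mode excluded), then standardizes to zero mean and unit
#' variance over valid vertices, so quantile thresholds behave like
#' z-score contrast maps.
#'
#' @param mesh a [SphericalMesh-class].
#' @param spec a [synthSpec()] (or arguments via `...` overriding it).
#' @param basis optional precomputed [meshEigenmodes()] basis (must carry
#'   at least `nModes + 1` modes); computed (and cached) when NULL.
#' @param name map label.
#' @param ... overrides of individual spec fields.
#' @return a [SurfaceMap-class].
#' @export
synthMap <- function(mesh, spec = synthSpec(), basis = NULL,
                     name = "synthetic", ...) {
  stopifnot(is(mesh, "SphericalMesh"))
  spec <- utils::modifyList(spec, list(...))
  if (spec$gamma < 0) stop("gamma must be nonnegative")
  nv <- sum(mesh@valid)
  if (spec$nModes > nv - 1)
    stop("nModes exceeds the available eigenmodes")
  vals <- .withSeed(spec$seed, function()
    .synthField(mesh, spec$gamma, spec$nModes, spec$noiseSd, basis))
  vals[!mesh@valid] <- 0
  new("SurfaceMap", values = vals, mesh = mesh, name = name)
}

#' Generate a family of task maps with shared and unique components
#'
#' Each task map is `sqrt(w) S + sqrt(1 - w) U_i` with one shared field S
#' and independent task-unique fields U_i (all drawn as in [synthMap()]),
#' so the expected pairwise correlation between tasks equals the shared
#' weight w.
#'
#' @param mesh a [SphericalMesh-class].
#' @param nTasks number of tasks, between 2 and 12.
#' @param sharedWeight w in `[0, 1]`: variance fraction of the shared
#'   component.
#' @param spec a [synthSpec()] for the component fields (`seed` drives the
#'   whole family).
#' @param basis optional precomputed eigenmode basis.
#' @return list of [SurfaceMap-class], named task1..taskN.
#' @export
synthTaskFamily <- function(mesh, nTasks = 7, sharedWeight = 0.5,
                            spec = synthSpec(), basis = NULL) {
  if (nTasks < 2 || nTasks > 12) stop("nTasks must be between 2 and 12")
  if (sharedWeight < 0 || sharedWeight > 1)
    stop("sharedWeight must lie in [0, 1]")
  if (is.null(basis) && spec$gamma > 0 && spec$nModes > 0)
    basis <- meshEigenmodes(mesh, spec$nModes + 1)
  vidx <- which(mesh@valid)
  fields <- .withSeed(spec$seed, function() {
    S <- .synthField(mesh, spec$gamma, spec$nModes, spec$noiseSd, basis)
    lapply(seq_len(nTasks), function(i) {
      U <- .synthField(mesh, spec$gamma, spec$nModes, spec$noiseSd, basis)
      v <- sqrt(sharedWeight) * S + sqrt(1 - sharedWeight) * U
      v[vidx] <- as.numeric(scale(v[vidx]))
      v[!mesh@valid] <- 0
      v
    })
  })
  lapply(seq_len(nTasks), function(i)
    new("SurfaceMap", values = fields[[i]], mesh = mesh,
        name = sprintf("task%d", i)))
}

#' Generate a synthetic network parcellation by balanced region growing
#'
#' Seeds `nNetworks * patchesPerNetwork` patches at random valid vertices
#' and grows them over the valid submesh one vertex at a time, always
#' extending the currently smallest network, which keeps network areas
#' approximately balanced. Disconnected leftovers are assigned to the
#' nearest labeled vertex. `patchesPerNetwork` controls the
#' distributed-versus-compact geometry of each network.
#'
#' @param mesh a [SphericalMesh-class].
#' @param nNetworks number of networks (default 7).
#' @param patchesPerNetwork patches per network (1 = one compact blob).
#' @param seed integer seed.
#' @return integer label per vertex in 1..nNetworks (0 at invalid
#'   vertices).
#' @export
synthNetworks <- function(mesh, nNetworks = 7, patchesPerNetwork = 1,
                          seed = 1) {
  stopifnot(is(mesh, "SphericalMesh"))
  if (nNetworks < 2) stop("at least 2 networks required")
  vidx <- which(mesh@valid)
  nSeeds <- nNetworks * patchesPerNetwork
  if (nSeeds > length(vidx))
    stop("more patch seeds than valid vertices")
  # adjacency over valid vertices (original indexing)
  keepTri <- rowSums(matrix(mesh@valid[mesh@triangles], ncol = 3)) == 3L
  edges <- .meshEdges(mesh@triangles[keepTri, , drop = FALSE])
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  labels <- integer(nVertices(mesh))
  .withSeed(seed, function() {
    seeds <- sample(vidx, nSeeds)
    patchNet <- rep(seq_len(nNetworks), each = patchesPerNetwork)
    labels[seeds] <<- patchNet
    frontier <- as.list(seeds)           # per-patch frontier vertex pool
    alive <- rep(TRUE, nSeeds)
    netSize <- tabulate(patchNet, nNetworks)
    while (any(alive)) {
      # grow the patch whose network is currently smallest
      cand <- which(alive)
      pk <- cand[which.min(netSize[patchNet[cand]])]
      grown <- FALSE
      fr <- frontier[[pk]]
      while (length(fr) && !grown) {
        v <- fr[1]
        nb <- adj[[as.character(v)]]
        nb <- nb[!is.na(nb)]
        free <- nb[labels[nb] == 0L]
        if (length(free)) {
          u <- if (length(free) == 1L) free else sample(free, 1)
          labels[u] <<- patchNet[pk]
          netSize[patchNet[pk]] <- netSize[patchNet[pk]] + 1L
          fr <- c(fr, u)
          grown <- TRUE
        } else fr <- fr[-1]
      }
      frontier[[pk]] <- fr
      if (!grown) alive[pk] <- FALSE
    }
    # disconnected leftovers: nearest labeled vertex wins
    left <- vidx[labels[vidx] == 0L]
    if (length(left)) {
      lab <- which(labels > 0L)
      g <- .arcCrossDist(mesh@coords[left, , drop = FALSE],
                         mesh@coords[lab, , drop = FALSE])
      labels[left] <<- labels[lab[apply(g, 1, which.min)]]
    }
  })
  labels
}

#' Generate a smooth planar image time series
#'
#' Latent frames follow a stationary AR(1) process in time
#' (`F_t = phi F_(t-1) + sqrt(1 - phi^2) E_t`) on smooth spatial
#' innovations `E_t`, drawn by spectral (FFT) synthesis with power-law
#' amplitude decay — the planar analogue of the spherical eigenmode
#' generator. The valid-pixel support is an inscribed ellipse approximating
#' a cortical imaging window.
#'
#' @param gridShape c(rows, cols) of each frame.
#' @param T number of frames (>= 2).
#' @param gamma spatial spectral decay exponent (0 = white noise frames).
#' @param temporalPhi AR(1) coefficient in `[0, 1)`.
#' @param seed integer seed.
#' @param ellipseAxes semi-axes of the valid ellipse as fractions of the
#'   half-dimensions (default 0.9).
#' @return an [ImageSeries-class].
#' @export
synthMovie <- function(gridShape = c(64, 64), T = 40, gamma = 3,
                       temporalPhi = 0.8, seed = 1,
                       ellipseAxes = c(0.9, 0.9)) {
  if (T < 2) stop("T must be at least 2")
  if (abs(temporalPhi) >= 1) stop("temporalPhi must satisfy |phi| < 1")
  if (gamma < 0) stop("gamma must be nonnegative")
  nr <- gridShape[1]; nc <- gridShape[2]
  # radially decaying spectral amplitude, zeroed DC
  kr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
  kc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
  k2 <- outer(kr^2, kc^2, "+")
  amp <- (k2 + (1 / max(nr, nc))^2)^(-gamma / 2)
  amp[1, 1] <- 0
  drawFrame <- function() {
    if (gamma == 0) return(matrix(rnorm(nr * nc), nr, nc))
    z <- matrix(rnorm(nr * nc), nr, nc)
    f <- Re(fft(fft(z) * amp, inverse = TRUE)) / (nr * nc)
    (f - mean(f)) / sd(f)
  }
  frames <- array(NA_real_, c(T, nr, nc))
  .withSeed(seed, function() {
    cur <- drawFrame()
    frames[1, , ] <<- cur
    for (t in 2:T) {
      cur <- temporalPhi * cur +
        sqrt(1 - temporalPhi^2) * drawFrame()
      frames[t, , ] <<- cur
    }
  })
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  valid <- ((rows - (nr + 1) / 2) / (ellipseAxes[1] * nr / 2))^2 +
    ((cols - (nc + 1) / 2) / (ellipseAxes[2] * nc / 2))^2 <= 1
  new("ImageSeries", frames = frames, pixelValid = valid,
      pixelSize = numeric(0))
}
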