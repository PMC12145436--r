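#' Draw a Haar-random rotation or orthogonal matrix
#'
#' QR-based Haar sampling with the sign-corrected diagonal; `proper = TRUE`
#' (default) additionally flips one column if needed so the determinant is
#' +1, giving a uniform random rotation.
#'
#' @param d dimension (3 for sphere spins).
#' @param proper force determinant +1.
#' @return a d x d orthogonal matrix (uses the current RNG state).
#' @export
randomRotation <- function(d = 3L, proper = TRUE) {
  qrd <- qr(matrix(rnorm(d * d), d))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))), d)
  if (proper && det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin-rotate a vertex label map
#'
#' Applies a proper rotation to the spherical coordinate frame and
#' reassigns to each vertex the label of the nearest (great-circle) vertex
#' under the inverse rotation — the standard "spin test" permutation that
#' preserves the spatial structure of a label map while randomizing its
#' alignment.
#'
#' @param mesh a [SphericalMesh-class].
#' @param labels integer label per vertex.
#' @param rotation 3 x 3 proper rotation (orthogonal, det +1 within 1e-9).
#' @return rotated integer labels per vertex.
#' @export
spinRotate <- function(mesh, labels, rotation) {
  stopifnot(is(mesh, "SphericalMesh"))
  if (length(labels) != nVertices(mesh))
    stop("labels length must equal vertex count")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthogonal with determinant +1")
  # label at vertex x comes from the source vertex nearest to R^T x
  src <- mesh@coords %*% rotation
  n <- nVertices(mesh)
  nearest <- integer(n)
  chunk <- 2048L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    g <- tcrossprod(src[s:e, , drop = FALSE], mesh@coords)
    nearest[s:e] <- max.col(g, ties.method = "first")
  }
  labels[nearest]
}

#' Spin-permutation null for network-prediction statistics
#'
#' Recomputes a per-network map statistic (by default the out-of-mask
#' network-prediction Spearman correlation of [networkPrediction()]) under
#' `n` random spin rotations of the label map, and reports one-sided
#' permutation p-values `(1 + #(null >= observed)) / (n + 1)` per network,
#' with Benjamini-Hochberg FDR and Bonferroni corrections side by side.
#' Rotations that leave any network with fewer than 10 valid vertices are
#' resampled (and counted in the output).
#'
#' @param map a [SurfaceMap-class].
#' @param labels integer network labels per vertex (0 = unassigned).
#' @param n number of rotations (default 500).
#' @param seed integer seed; the ensemble is reproducible from
#'   (mesh, labels, n, seed).
#' @param config see [latticeConfig()].
#' @param statistic optional `function(values, labels, networkId)`
#'   returning a scalar; defaults to the network-prediction correlation.
#' @param minNetworkSize networks smaller than this are dropped from
#'   testing.
#' @return list with elements `observed` (named vector), `null`
#'   (n x networks matrix), `pvalues` (data.frame: network, observed, p,
#'   p_fdr, p_bonferroni), `nResampled`, `seed`.
#' @export
spinNull <- function(map, labels, n = 500, seed = 1, config = list(),
                     statistic = NULL, minNetworkSize = 50) {
  stopifnot(is(map, "SurfaceMap"))
  if (n < 100) stop("at least 100 rotations required")
  mesh <- map@mesh
  ids <- sort(unique(labels[labels > 0L & mesh@valid]))
  ids <- ids[vapply(ids, function(k)
    sum(labels == k & mesh@valid) >= minNetworkSize, logical(1))]
  if (!length(ids)) stop("no network reaches minNetworkSize")
  if (is.null(statistic)) {
    cfg <- latticeConfig(config)
    if (identical(cfg$lambda, "auto")) cfg$lambda <- 1e-3
    des <- .resolveSphereDesign(cfg, mesh)
    if (ncol(des$basisFull) > 2000)
      warning("large lattice in spin null; consider a coarser config")
    PhiD <- as.matrix(des$basisFull)
    QD <- as.matrix(des$Qalpha)
    statistic <- function(values, labs, k)
      .networkRhoFast(PhiD, QD, cfg$lambda, values, mesh@valid, labs, k)
  }
  statAll <- function(labs)
    vapply(ids, function(k) statistic(map@values, labs, k), numeric(1))
  obs <- statAll(labels)
  names(obs) <- paste0("net", ids)
  nullMat <- matrix(NA_real_, n, length(ids),
                    dimnames = list(NULL, names(obs)))
  nResampled <- 0L
  .withSeed(seed, function() {
    for (i in seq_len(n)) {
      repeat {
        rl <- spinRotate(mesh, labels, randomRotation())
        ok <- all(vapply(ids, function(k)
          sum(rl == k & mesh@valid) >= 10L, logical(1)))
        if (ok) break
        nResampled <<- nResampled + 1L
      }
      nullMat[i, ] <<- statAll(rl)
    }
  })
  p <- vapply(seq_along(ids), function(j)
    (1 + sum(nullMat[, j] >= obs[j], na.rm = TRUE)) / (n + 1), numeric(1))
  list(observed = obs, null = nullMat,
       pvalues = data.frame(network = names(obs), observed = obs, p = p,
                            p_fdr = p.adjust(p, "BH"),
                            p_bonferroni = p.adjust(p, "bonferroni"),
                            row.names = NULL),
       nResampled = nResampled, seed = seed)
}

# Group mode indices (excluding the constant mode) for coefficient
# rotation: eigenvalue clusters at relative tolerance `tol`, or consecutive
# spherical-harmonic-like blocks of size 2l+1 when the spectrum is
# non-degenerate.
.eigenGroups <- function(eigenvalues, tol = 1e-3) {
  k <- length(eigenvalues)
  if (k < 2) return(list())
  ev <- eigenvalues[-1]
  cl <- integer(length(ev))
  cur <- 1L
  cl[1] <- 1L
  for (i in seq_along(ev)[-1]) {
    ref <- abs(ev[i - 1])
    if (abs(ev[i] - ev[i - 1]) <= tol * max(ref, 1e-12)) cl[i] <- cur
    else {
      cur <- cur + 1L
      cl[i] <- cur
    }
  }
  groups <- split(seq_along(ev) + 1L, cl)  # indices into full mode set
  if (all(lengths(groups) == 1L)) {
    # non-degenerate spectrum: harmonic-like blocks 3, 5, 7, ...
    groups <- list()
    i <- 2L
    l <- 1L
    while (i <= k) {
      sz <- min(2L * l + 1L, k - i + 1L)
      groups[[length(groups) + 1L]] <- seq(i, i + sz - 1L)
      i <- i + sz
      l <- l + 1L
    }
  }
  unname(groups)
}

#' Eigenmode-rotation ("eigenstrapping") surrogate maps
#'
#' Generates surrogate maps with approximately the spatial autocorrelation
#' of the original: the map is projected onto mesh Laplacian eigenmodes,
#' the coefficients within each eigengroup (modes sharing an eigenvalue, or
#' spherical-harmonic-like blocks of size 2l+1 on non-degenerate spectra)
#' receive independent Haar-random orthogonal rotations, the map is
#' reconstructed (keeping the constant component and the out-of-basis
#' projection residual), and — with `resample = TRUE` — values are
#' rank-remapped onto the original value multiset so every surrogate's
#' histogram is exactly the original's.
#'
#' @param map a [SurfaceMap-class].
#' @param basis a [meshEigenmodes()] basis of the map's mesh with at least
#'   50 modes.
#' @param n number of surrogates (default 200).
#' @param seed integer seed.
#' @param resample rank-remap onto the original value multiset (default
#'   TRUE).
#' @return a [SurrogateEnsemble-class].
#' @export
eigenstrap <- function(map, basis, n = 200, seed = 1, resample = TRUE) {
  stopifnot(is(map, "SurfaceMap"), is(basis, "EigenBasis"))
  if (ncol(basis@modes) < 50) stop("basis must have at least 50 modes")
  if (nrow(basis@modes) != nVertices(map))
    stop("basis and map meshes do not match")
  vidx <- which(map@mesh@valid)
  if (any(basis@weights[vidx] <= 0))
    stop("basis and map validity masks do not match")
  x <- map@values[vidx]
  modes <- basis@modes[vidx, , drop = FALSE]
  w <- basis@weights[vidx]
  a <- as.numeric(crossprod(modes, w * x))   # mass-weighted projection
  recon <- as.numeric(modes %*% a)
  projResid <- x - recon                     # out-of-basis component
  groups <- .eigenGroups(basis@eigenvalues)
  sorted <- sort(x)
  out <- matrix(NA_real_, nVertices(map), n)
  .withSeed(seed, function() {
    for (s in seq_len(n)) {
      a2 <- a
      for (g in groups) {
        if (length(g) == 1L) {
          a2[g] <- a[g] * sign(rnorm(1))
        } else {
          O <- randomRotation(length(g), proper = FALSE)
          a2[g] <- as.numeric(O %*% a[g])
        }
      }
      v <- a[1] * modes[, 1] + as.numeric(
        modes[, -1, drop = FALSE] %*% a2[-1]) + projResid
      if (resample) v[order(v)] <- sorted
      out[vidx, s] <<- v
    }
  })
  new("SurrogateEnsemble", maps = out, seed = seed, resample = resample,
      meta = list(nGroups = length(groups), nModes = ncol(modes)))
}

#' Permutation p-value of an observed statistic against an ensemble
#'
#' Add-one permutation estimator `(1 + #(null >= observed)) / (n + 1)`
#' (one-sided "greater"); the two-sided variant doubles the smaller tail
#' (capped at 1).
#'
#' @param observed scalar observed statistic.
#' @param ensembleStats numeric vector of >= 50 null statistics.
#' @param alternative "greater" (default) or "two.sided".
#' @return p-value in (0, 1].
#' @export
surrogatePvalue <- function(observed, ensembleStats,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  ensembleStats <- ensembleStats[is.finite(ensembleStats)]
  n <- length(ensembleStats)
  if (n < 50) stop("at least 50 ensemble values required")
  pg <- (1 + sum(ensembleStats >= observed)) / (n + 1)
  if (alternative == "greater") return(pg)
  pl <- (1 + sum(ensembleStats <= observed)) / (n + 1)
  min(1, 2 * min(pg, pl))
}
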