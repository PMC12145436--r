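#' Construct an icosphere mesh
#'
#' Builds a geodesic sphere by repeated 4-to-1 midpoint subdivision of a
#' regular icosahedron, projecting every new vertex back to the unit sphere.
#' The result has 10 * 4^n + 2 vertices and 20 * 4^n triangles.
#'
#' @param nSubdivisions nonnegative integer, at most 7.
#' @param valid optional logical validity mask (default: all vertices valid).
#' @return a [SphericalMesh-class].
#' @examples
#' mesh <- buildIcosphere(1)
#' nVertices(mesh)  # 42
#' @export
buildIcosphere <- function(nSubdivisions, valid = NULL) {
  if (length(nSubdivisions) != 1L || is.na(nSubdivisions) ||
      nSubdivisions != round(nSubdivisions) || nSubdivisions < 0)
    stop("nSubdivisions must be a nonnegative integer")
  if (nSubdivisions > 7)
    stop("nSubdivisions must be <= 7 (guard against huge meshes)")
  t <- (1 + sqrt(5)) / 2
  coords <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  coords <- coords / sqrt(rowSums(coords^2))
  tris <- 1L + rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  storage.mode(tris) <- "integer"
  n <- as.integer(nSubdivisions)
  while (n > 0L) {
    sub <- .subdivideOnce(coords, tris)
    coords <- sub$coords
    tris <- sub$tris
    n <- n - 1L
  }
  if (is.null(valid)) valid <- rep(TRUE, nrow(coords))
  mesh <- new("SphericalMesh", coords = coords, triangles = tris,
              valid = valid)
  attr(mesh@coords, "icosphere") <- as.integer(nSubdivisions)
  mesh
}

# One 4-to-1 midpoint subdivision step, vectorized with edge deduplication.
.subdivideOnce <- function(coords, tris) {
  nf <- nrow(tris)
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  key <- lo * (nrow(coords) + 1) + hi
  first <- !duplicated(key)
  mid.of <- match(key, key[first]) + nrow(coords)
  ue <- cbind(lo[first], hi[first])
  mids <- (coords[ue[, 1], , drop = FALSE] + coords[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  m12 <- mid.of[seq_len(nf)]
  m23 <- mid.of[nf + seq_len(nf)]
  m31 <- mid.of[2L * nf + seq_len(nf)]
  newtris <- rbind(cbind(tris[, 1], m12, m31),
                   cbind(tris[, 2], m23, m12),
                   cbind(tris[, 3], m31, m23),
                   cbind(m12, m23, m31))
  storage.mode(newtris) <- "integer"
  list(coords = rbind(coords, mids), tris = newtris)
}

#' Great-circle distance between unit vectors
#'
#' Numerically stable arc distance on the unit sphere, computed with the
#' atan2 form (stable near 0 and pi, unlike plain acos). Vectorized over
#' matrix rows with recycling of a single point.
#'
#' @param a,b unit 3-vectors, or matrices with one unit vector per row.
#' @return distances in radians, in `[0, pi]`.
#' @examples
#' greatCircleDistance(c(1, 0, 0), c(0, 1, 0))  # pi/2
#' @export
greatCircleDistance <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na < 1e-12) || any(nb < 1e-12))
    stop("zero-norm input: points must be unit vectors")
  if (any(abs(na - 1) > 1e-6) || any(abs(nb - 1) > 1e-6))
    stop("inputs must be unit-norm within tolerance 1e-6")
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  dotp <- rowSums(a * b)
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  d <- atan2(sqrt(rowSums(cr^2)), dotp)
  as.numeric(d)
}

# Dense great-circle cross-distance matrix between row sets A (n x 3) and
# B (m x 3), chunked to bound peak memory. acos of the clamped dot product
# is sufficient here (used for kernel evaluation and nearest-node queries,
# where ~1e-8 rad rounding is immaterial).
.arcCrossDist <- function(A, B, chunk = 2048L) {
  n <- nrow(A)
  out <- matrix(0, n, nrow(B))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    g <- tcrossprod(A[s:e, , drop = FALSE], B)
    out[s:e, ] <- acos(pmin(1, pmax(-1, g)))
  }
  out
}

#' Geodesic distance from every vertex to a vertex set
#'
#' For each vertex of the mesh, the minimum great-circle distance to any
#' member of the given set. Members get exactly 0.
#'
#' @param mesh a [SphericalMesh-class].
#' @param memberFlags logical per vertex marking the set.
#' @return numeric vector of radians per vertex.
#' @export
geodesicToSet <- function(mesh, memberFlags) {
  stopifnot(is(mesh, "SphericalMesh"))
  if (length(memberFlags) != nVertices(mesh))
    stop("memberFlags length must equal vertex count")
  if (!any(memberFlags)) stop("member set must be nonempty")
  M <- mesh@coords[memberFlags, , drop = FALSE]
  n <- nVertices(mesh)
  d <- numeric(n)
  chunk <- 2048L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    g <- tcrossprod(mesh@coords[s:e, , drop = FALSE], M)
    d[s:e] <- acos(pmin(1, pmax(-1, apply(g, 1, max))))
  }
  d[memberFlags] <- 0
  d
}

# Adjacency (i < j) edge list of a triangulation, deduplicated.
.meshEdges <- function(tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  keep <- !duplicated(lo * (max(hi) + 1) + hi)
  cbind(lo[keep], hi[keep])
}

# Connected components of an undirected graph given by an edge list over
# 1..n; returns an integer component id per node.
.graphComponents <- function(n, edges) {
  adj <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                              j = c(edges[, 2], edges[, 1]),
                              x = 1, dims = c(n, n))
  comp <- integer(n)
  cur <- 0L
  while (any(comp == 0L)) {
    cur <- cur + 1L
    frontier <- logical(n)
    frontier[which(comp == 0L)[1]] <- TRUE
    member <- frontier
    while (any(frontier)) {
      nxt <- as.logical(adj %*% frontier) & !member
      member <- member | nxt
      frontier <- nxt
    }
    comp[member] <- cur
  }
  comp
}

# Cotangent stiffness and lumped-area mass of a triangulation restricted to
# the given vertex subset (triangles entirely inside the subset).
.cotanLaplacian <- function(coords, tris) {
  i1 <- tris[, 1]; i2 <- tris[, 2]; i3 <- tris[, 3]
  p1 <- coords[i1, , drop = FALSE]
  p2 <- coords[i2, , drop = FALSE]
  p3 <- coords[i3, , drop = FALSE]
  cotOf <- function(a, b) {
    # cot of angle between edge vectors a, b (rows)
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    rowSums(a * b) / pmax(sqrt(rowSums(cr^2)), 1e-300)
  }
  c1 <- cotOf(p2 - p1, p3 - p1)  # angle at vertex 1, opposite edge (2,3)
  c2 <- cotOf(p1 - p2, p3 - p2)  # at 2, opposite (1,3)
  c3 <- cotOf(p1 - p3, p2 - p3)  # at 3, opposite (1,2)
  n <- nrow(coords)
  W <- Matrix::sparseMatrix(
    i = c(i2, i3, i1, i3, i1, i2),
    j = c(i3, i2, i3, i1, i2, i1),
    x = 0.5 * c(c1, c1, c2, c2, c3, c3),
    dims = c(n, n))
  C <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  mass <- numeric(n)
  for (k in 1:3) {
    tt <- tapply(area / 3, tris[, k], sum)
    mass[as.integer(names(tt))] <- mass[as.integer(names(tt))] + tt
  }
  list(C = C, mass = mass)
}

# Cheap deterministic fingerprint of a mesh, for caching and compatibility
# checks (same geometry => same fingerprint).
.meshFingerprint <- function(mesh) {
  paste(nrow(mesh@coords), nrow(mesh@triangles), sum(mesh@valid),
        format(sum(mesh@coords * rep(c(1, 2, 3), each = nrow(mesh@coords))),
               digits = 15),
        format(sum(mesh@coords[mesh@valid, , drop = FALSE]^3), digits = 15),
        sep = "|")
}

#' Laplacian eigenmodes of a mesh
#'
#' Computes the k smallest-eigenvalue modes of the discrete Laplacian of the
#' valid submesh (triangles whose three corners are all valid). The default
#' operator is the cotangent-weighted Laplace-Beltrami stiffness with a
#' lumped vertex-area mass, the standard discrete geometric operator; an
#' unweighted graph Laplacian is available as an option. Modes are
#' orthonormal under the mass weighting, have ascending eigenvalues starting
#' at 0 (constant mode), and are sign-fixed so the entry of largest
#' magnitude is positive. Decompositions are cached per (mesh, k, operator).
#'
#' @param mesh a [SphericalMesh-class].
#' @param k number of modes, positive and < number of valid vertices.
#' @param laplacian "cotangent" (default) or "graph".
#' @return an [EigenBasis-class].
#' @export
meshEigenmodes <- function(mesh, k, laplacian = c("cotangent", "graph")) {
  stopifnot(is(mesh, "SphericalMesh"))
  laplacian <- match.arg(laplacian)
  nv <- sum(mesh@valid)
  if (length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a positive integer")
  if (k >= nv)
    stop(sprintf("k (%d) must be smaller than the number of valid vertices (%d)",
                 as.integer(k), nv))
  key <- paste("eig", .meshFingerprint(mesh), laplacian, sep = "|")
  cached <- .geokrigCache[[key]]
  if (!is.null(cached) && ncol(cached$modes) >= k) {
    return(new("EigenBasis", modes = cached$modes[, seq_len(k), drop = FALSE],
               eigenvalues = cached$evals[seq_len(k)],
               weights = cached$weights))
  }
  vidx <- which(mesh@valid)
  remap <- integer(nVertices(mesh)); remap[vidx] <- seq_along(vidx)
  keepTri <- rowSums(matrix(mesh@valid[mesh@triangles],
                            ncol = 3)) == 3L
  tris <- matrix(remap[mesh@triangles[keepTri, , drop = FALSE]], ncol = 3)
  if (nrow(tris) == 0L) stop("valid submesh has no triangles")
  edges <- .meshEdges(tris)
  comp <- .graphComponents(nv, edges)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop(sprintf("valid submesh is disconnected: %d components of sizes %s",
                 max(comp), paste(sizes, collapse = ", ")))
  }
  coordsV <- mesh@coords[vidx, , drop = FALSE]
  if (laplacian == "cotangent") {
    cl <- .cotanLaplacian(coordsV, tris)
    C <- cl$C
    mass <- cl$mass
  } else {
    A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                              j = c(edges[, 2], edges[, 1]),
                              x = 1, dims = c(nv, nv))
    C <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
    mass <- rep(1, nv)
  }
  s <- 1 / sqrt(mass)
  S <- Matrix::Diagonal(x = s) %*% C %*% Matrix::Diagonal(x = s)
  S <- as.matrix(Matrix::forceSymmetric(S))
  ee <- eigen(S, symmetric = TRUE)
  ord <- rev(seq_len(nv))           # ascending eigenvalues
  evals <- pmax(ee$values[ord], 0)
  U <- ee$vectors[, ord, drop = FALSE]
  modesV <- U * s                   # mass-orthonormal generalized modes
  kk <- min(nv, max(k, 256L))       # cache a generous block
  modes <- matrix(0, nVertices(mesh), kk)
  modes[vidx, ] <- modesV[, seq_len(kk), drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(kk)) {
    m <- which.max(abs(modes[, j]))
    if (modes[m, j] < 0) modes[, j] <- -modes[, j]
  }
  weights <- numeric(nVertices(mesh)); weights[vidx] <- mass
  .geokrigCache[[key]] <- list(modes = modes, evals = evals[seq_len(kk)],
                               weights = weights)
  new("EigenBasis", modes = modes[, seq_len(k), drop = FALSE],
      eigenvalues = evals[seq_len(k)], weights = weights)
}

#' Binned spatial variogram of a surface map
#'
#' Mean squared half-difference of map values as a function of great-circle
#' separation between valid vertices, in equal-width distance bins. For
#' large meshes a random subsample of vertex pairs is used (seeded,
#' deterministic).
#'
#' @param map a [SurfaceMap-class].
#' @param nBins number of distance bins.
#' @param maxDist largest separation (radians) to include.
#' @param maxPairs cap on the number of vertex pairs (subsampled beyond).
#' @param seed seed for the pair subsample.
#' @return data.frame with columns dist (bin midpoint), n, gamma.
#' @export
meshVariogram <- function(map, nBins = 10, maxDist = pi / 2,
                          maxPairs = 2e5, seed = 1) {
  stopifnot(is(map, "SurfaceMap"))
  vidx <- which(map@mesh@valid)
  x <- map@values[vidx]
  coords <- map@mesh@coords[vidx, , drop = FALSE]
  n <- length(vidx)
  nAll <- n * (n - 1) / 2
  ij <- if (nAll <= maxPairs) {
    w <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cbind(w[, 1], w[, 2])
  } else {
    .withSeed(seed, function() {
      i <- sample.int(n, maxPairs, replace = TRUE)
      j <- sample.int(n, maxPairs, replace = TRUE)
      keep <- i != j
      cbind(i[keep], j[keep])
    })
  }
  g <- rowSums(coords[ij[, 1], , drop = FALSE] * coords[ij[, 2], , drop = FALSE])
  d <- acos(pmin(1, pmax(-1, g)))
  keep <- d <= maxDist
  d <- d[keep]
  sq <- 0.5 * (x[ij[keep, 1]] - x[ij[keep, 2]])^2
  br <- seq(0, maxDist, length.out = nBins + 1)
  bin <- pmin(nBins, pmax(1L, findInterval(d, br, rightmost.closed = TRUE)))
  data.frame(
    dist = (br[-1] + br[-length(br)]) / 2,
    n = as.integer(tabulate(bin, nBins)),
    gamma = vapply(seq_len(nBins), function(b) {
      s <- bin == b
      if (!any(s)) NA_real_ else mean(sq[s])
    }, numeric(1)))
}
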