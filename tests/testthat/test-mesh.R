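test_that("icosphere construction follows the subdivision recurrence", {
  m0 <- buildIcosphere(0)
  expect_equal(nVertices(m0), 12L)
  expect_equal(nrow(triangles(m0)), 20L)

  # independent oracle: V' = V + E with E counted from the triangulation
  countEdges <- function(tris) {
    e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
    nrow(unique(t(apply(e, 1, sort))))
  }
  expect_equal(countEdges(triangles(m0)), 30L)
  m1 <- buildIcosphere(1)
  expect_equal(nVertices(m1), 12L + countEdges(triangles(m0)))  # 42
  expect_equal(nrow(triangles(m1)), 80L)
  expect_equal(nVertices(buildIcosphere(2)),
               nVertices(m1) + countEdges(triangles(m1)))       # 162

  for (m in list(m0, m1))
    expect_true(all(abs(sqrt(rowSums(vertexCoords(m)^2)) - 1) < 1e-12))

  expect_error(buildIcosphere(-1), "nonnegative")
  expect_error(buildIcosphere(8), "<= 7")
})

test_that("great-circle distance is exact on axes and stable at extremes", {
  expect_equal(greatCircleDistance(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(greatCircleDistance(c(0, 0, 1), c(0, 0, -1)), pi)
  expect_equal(greatCircleDistance(c(1, 0, 0), c(0, 1, 0)), pi / 2)
  # stability near zero: atan2 form resolves tiny separations
  a <- c(1, 0, 0)
  b <- c(cos(1e-9), sin(1e-9), 0)
  expect_equal(greatCircleDistance(a, b), 1e-9, tolerance = 1e-3)
  expect_error(greatCircleDistance(c(0, 0, 0), c(1, 0, 0)), "zero-norm")
})

test_that("great-circle distance is symmetric and satisfies the triangle
           inequality on random triples", {
  p <- randomSpherePoints(3000, seed = 42)
  a <- p[1:1000, ]; b <- p[1001:2000, ]; c3 <- p[2001:3000, ]
  dab <- greatCircleDistance(a, b)
  dba <- greatCircleDistance(b, a)
  expect_equal(dab, dba)
  dac <- greatCircleDistance(a, c3)
  dcb <- greatCircleDistance(c3, b)
  expect_true(all(dab <= dac + dcb + 1e-9))
  expect_true(all(dab >= 0 & dab <= pi + 1e-12))
})

test_that("geodesic distance to a vertex set matches the brute-force
           minimum", {
  mesh <- icoMesh(0)
  flags <- c(TRUE, rep(FALSE, 11))
  d <- geodesicToSet(mesh, flags)
  expect_equal(d[1], 0)
  # icosahedron edge arc: every neighbour of a vertex is acos(1/sqrt(5))
  nb <- sort(unique(round(d, 10)))
  expect_equal(nb[2], acos(1 / sqrt(5)), tolerance = 1e-9)
  expect_equal(max(d), pi, tolerance = 1e-9)  # opposite vertex

  mesh2 <- icoMesh(2)  # 162 vertices, brute-force oracle
  set.seed(7)
  flags2 <- rep(FALSE, nVertices(mesh2))
  flags2[sample(nVertices(mesh2), 9)] <- TRUE
  d2 <- geodesicToSet(mesh2, flags2)
  mem <- which(flags2)
  brute <- vapply(seq_len(nVertices(mesh2)), function(v)
    min(greatCircleDistance(vertexCoords(mesh2)[rep(v, length(mem)), ],
                            vertexCoords(mesh2)[mem, ])), numeric(1))
  brute[flags2] <- 0
  expect_equal(d2, brute, tolerance = 1e-9)
  expect_error(geodesicToSet(mesh2, rep(FALSE, 162)), "nonempty")
})

test_that("mesh eigenmodes start at a constant zero mode and are
           orthonormal under the mass weighting", {
  mesh <- icoMesh(1)
  eb <- meshEigenmodes(mesh, 10)
  expect_lt(eigenValues(eb)[1], 1e-10)
  m0 <- eigenModes(eb)[, 1]
  expect_lt(diff(range(m0)), 1e-8)
  G <- t(eigenModes(eb)) %*% (eb@weights * eigenModes(eb))
  expect_lt(max(abs(G - diag(10))), 1e-6)
  expect_false(is.unsorted(eigenValues(eb)))
})

test_that("graph-Laplacian eigenmodes match a dense independent
           decomposition", {
  mesh <- icoMesh(1)
  eb <- meshEigenmodes(mesh, 10, laplacian = "graph")
  # oracle: dense graph Laplacian built directly from the triangle list
  tris <- triangles(mesh)
  n <- nVertices(mesh)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(tris))) {
    t3 <- tris[r, ]
    A[t3[1], t3[2]] <- A[t3[2], t3[1]] <- 1
    A[t3[2], t3[3]] <- A[t3[3], t3[2]] <- 1
    A[t3[1], t3[3]] <- A[t3[3], t3[1]] <- 1
  }
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(eigenValues(eb), ev[1:10], tolerance = 1e-8)
})

test_that("icosphere spectrum shows the spherical-harmonic degeneracy of
           the first nonzero eigenvalue", {
  eb <- meshEigenmodes(icoMesh(2), 8)
  ev <- eigenValues(eb)
  g1 <- ev[2:4]
  expect_lt(diff(range(g1)) / mean(g1), 1e-6)   # multiplicity 3
  expect_gt(ev[5] - ev[4], 1e-3)                # gap to the next group
})

test_that("eigenmode preconditions and degenerate meshes error cleanly", {
  mesh <- icoMesh(1)
  expect_error(meshEigenmodes(mesh, sum(validMask(mesh))), "smaller")
  # two isolated patches of valid vertices -> disconnected submesh
  valid <- rep(FALSE, 42)
  valid[triangles(mesh)[1, ]] <- TRUE
  valid[triangles(mesh)[40, ]] <- TRUE
  broken <- buildIcosphere(1, valid = valid)
  expect_error(meshEigenmodes(broken, 2), "disconnected")
})

test_that("eigenmodes on a masked mesh exclude the invalid vertices", {
  mesh <- buildIcosphere(2)
  valid <- geodesicToSet(mesh, c(TRUE, rep(FALSE, 161))) > 0.8
  masked <- buildIcosphere(2, valid = valid)
  eb <- meshEigenmodes(masked, 5)
  expect_true(all(eigenModes(eb)[!valid, ] == 0))
  expect_true(all(eb@weights[!valid] == 0))
  expect_lt(diff(range(eigenModes(eb)[valid, 1])), 1e-8)
})
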