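test_that("the Wendland kernel matches direct polynomial evaluation", {
  expect_identical(wendland(0, 1), 1)
  expect_identical(wendland(1, 1), 0)
  expect_identical(wendland(2, 1), 0)
  # oracle: the stated polynomial at r = 1/2
  r <- 0.5
  expect_equal(wendland(0.5, 1), (1 - r)^6 * (35 * r^2 + 18 * r + 3) / 3,
               tolerance = 1e-15)
  expect_equal(wendland(1.5, 3), (1 - r)^6 * (35 * r^2 + 18 * r + 3) / 3,
               tolerance = 1e-15)
  # continuity at the support boundary
  expect_lt(wendland(1 - 1e-8, 1), 1e-6)
  expect_error(wendland(1, 0), "positive")
  expect_error(wendland(-0.1, 1), "nonnegative")
})

test_that("spherical lattices have icosphere node counts, decreasing
           ranges, and the configured alpha", {
  lat <- buildSphereLattice(3, 1, 2.5, c(1, 0.25, 0.01))
  expect_equal(vapply(latticeNodes(lat), nrow, numeric(1)),
               c(42, 162, 642))
  rng <- latticeRanges(lat)
  expect_true(all(diff(rng) < 0))
  expect_equal(alphaWeights(lat), c(1, 0.25, 0.01))
  expect_error(buildSphereLattice(3, 1, 2.5, c(1, 0.5)), "alpha")
  lat1 <- buildSphereLattice(1, 1, 2.5, 1)
  expect_equal(nLevels(lat1), 1L)
})

test_that("planar lattices halve their spacing per level and pad one
           spacing beyond the domain", {
  lat <- buildPlanarLattice(c(400, 400))
  expect_equal(nLevels(lat), 3L)
  sp <- latticeRanges(lat) / lat@config$rangeMultiplier
  expect_equal(sp[1] / sp[2], 2)
  expect_equal(sp[2] / sp[3], 2)
  # counting oracle: nodes from 1 - s to dim + s in steps of s
  for (l in 1:3) {
    s <- 50 / 2^(l - 1)
    perAxis <- length(seq(1 - s, 400 + s + 1e-9, by = s))
    expect_equal(nrow(latticeNodes(lat)[[l]]), perAxis^2)
    expect_lte(min(latticeNodes(lat)[[l]][, 1]), 1)
    expect_gte(max(latticeNodes(lat)[[l]][, 1]), 400)
  }
  expect_error(buildPlanarLattice(c(6, 20)), ">= 8")
  expect_error(buildPlanarLattice(c(16, 16), nLevels = 4,
                                  alpha = rep(1, 4), baseSpacing = 2),
               "< 1 pixel")
})

test_that("the basis matrix equals dense kernel evaluation and flags
           uncovered points", {
  lat <- oneLevelLattice(1)
  pts <- randomSpherePoints(12, seed = 3)
  Phi <- basisMatrix(lat, pts)
  nodes <- latticeNodes(lat)[[1]]
  dense <- matrix(0, 12, nrow(nodes))
  for (i in 1:12) for (j in seq_len(nrow(nodes)))
    dense[i, j] <- wendland(greatCircleDistance(pts[i, ], nodes[j, ]),
                            latticeRanges(lat)[1])
  expect_equal(as.matrix(Phi), dense, tolerance = 1e-10,
               ignore_attr = TRUE)
  # coincident point -> kernel value exactly 1 in that column
  Phi1 <- basisMatrix(lat, nodes[5, , drop = FALSE])
  expect_equal(Phi1[1, 5], 1)
  # a tiny-range lattice leaves far points uncovered
  latSmall <- oneLevelLattice(1, rangeMultiplier = 0.4)
  expect_warning(Phi2 <- basisMatrix(latSmall, randomSpherePoints(30, 5)),
                 "outside all basis supports")
  expect_true(length(attr(Phi2, "zeroRows")) > 0)
  expect_error(basisMatrix(lat, matrix(1, 3, 2)), "3-column")
})

test_that("the SAR precision matches hand algebra on a 3-cycle and
           factorizes on icosphere levels", {
  lev <- list(nodes = matrix(0, 3, 2),
              edges = rbind(c(1, 2), c(2, 3), c(1, 3)))
  Q <- as.matrix(sarPrecision(lev, kappa2 = 1))
  # oracle: B = 3I - A, Q = B'B computed densely
  A <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  B <- 3 * diag(3) - A
  expect_equal(Q, t(B) %*% B, ignore_attr = TRUE)
  expect_equal(Q, t(Q))
  expect_error(sarPrecision(lev, -1), "nonnegative")
  for (s in 0:2) {
    lat <- oneLevelLattice(s)
    Qs <- sarPrecision(lat@levels[[1]], 0.01)
    expect_silent(Matrix::Cholesky(Qs, LDL = FALSE))
  }
})

test_that("sparse fits equal the dense penalized least-squares solution on
           sphere and plane", {
  # sphere
  lat <- oneLevelLattice(1)
  pts <- randomSpherePoints(80, seed = 11)
  set.seed(12); y <- rnorm(80)
  lam <- 0.37
  fit <- krigFit(y, pts, lat, lambda = lam)
  A <- cbind(1, as.matrix(basisMatrix(lat, pts)))
  Q <- as.matrix(sarPrecision(lat@levels[[1]], 0.01))
  P <- rbind(0, cbind(0, lam * Q))
  sol <- solve(crossprod(A) + P, crossprod(A, y))
  expect_equal(c(fit@fixedCoef, fit@coefficients), as.numeric(sol),
               tolerance = 1e-8)
  expect_equal(predict(fit, pts), as.numeric(A %*% sol), tolerance = 1e-8)

  # plane
  latP <- buildPlanarLattice(c(12, 12), 1, 2.5, 1, baseSpacing = 3)
  set.seed(13)
  ptsP <- cbind(runif(60, 1, 12), runif(60, 1, 12))
  yP <- rnorm(60)
  fitP <- krigFit(yP, ptsP, latP, lambda = lam)
  AP <- cbind(1, as.matrix(basisMatrix(latP, ptsP)))
  QP <- as.matrix(sarPrecision(latP@levels[[1]], 0.01))
  PP <- rbind(0, cbind(0, lam * QP))
  solP <- solve(crossprod(AP) + PP, crossprod(AP, yP))
  expect_equal(c(fitP@fixedCoef, fitP@coefficients), as.numeric(solP),
               tolerance = 1e-8)
})

test_that("fits reproduce training data in the interpolation limit and a
           constant field exactly", {
  lat <- oneLevelLattice(1)
  pts <- randomSpherePoints(30, seed = 21)
  set.seed(22); y <- rnorm(30)
  fit <- krigFit(y, pts, lat, lambda = 1e-10)
  expect_lt(max(abs(predict(fit, pts) - y)), 1e-4)
  fitC <- krigFit(rep(5, 30), pts, lat, lambda = 1)
  expect_equal(predict(fitC, randomSpherePoints(50, 23)), rep(5, 50),
               tolerance = 1e-9)
  expect_lt(max(abs(fitC@coefficients)), 1e-10)
  expect_error(krigFit(y[1:5], pts[1:5, ], lat), "at least 10")
})

test_that("prediction is linear in the training values at fixed lambda", {
  lat <- oneLevelLattice(1)
  pts <- randomSpherePoints(40, seed = 31)
  set.seed(32)
  y1 <- rnorm(40); y2 <- rnorm(40)
  q <- randomSpherePoints(60, 33)
  p1 <- predict(krigFit(y1, pts, lat, 0.3, fixed = "none"), q)
  p2 <- predict(krigFit(y2, pts, lat, 0.3, fixed = "none"), q)
  p12 <- predict(krigFit(y1 + y2, pts, lat, 0.3, fixed = "none"), q)
  expect_equal(p12, p1 + p2, tolerance = 1e-8)
})

test_that("training residuals shrink monotonically with lambda", {
  lat <- oneLevelLattice(1)
  pts <- randomSpherePoints(50, seed = 41)
  set.seed(42); y <- rnorm(50)
  grid <- 10^seq(-6, 2, length.out = 12)
  rss <- vapply(grid, function(l)
    sum((predict(krigFit(y, pts, lat, l), pts) - y)^2), numeric(1))
  expect_true(all(diff(rss) > -1e-8))
})

test_that("spherical predictions are equivariant under a global
           rotation", {
  lat <- oneLevelLattice(1)
  pts <- randomSpherePoints(40, seed = 51)
  q <- randomSpherePoints(30, 52)
  set.seed(53); y <- rnorm(40)
  p0 <- predict(krigFit(y, pts, lat, 0.1), q)
  R <- { set.seed(54); randomRotation() }
  latR <- lat
  latR@levels[[1]]$nodes <- lat@levels[[1]]$nodes %*% t(R)
  pR <- predict(krigFit(y, pts %*% t(R), latR, 0.1), q %*% t(R))
  expect_equal(p0, pR, tolerance = 1e-6)
})

test_that("lambda selection returns single candidates, is deterministic,
           and prefers heavier smoothing for noise than for smooth
           fields", {
  lat <- oneLevelLattice(1)
  mesh <- icoMesh(2)
  locs <- vertexCoords(mesh)
  smoothY <- function(s) mapValues(smoothMap(mesh, seed = s,
                                             noiseSd = 0.02))
  noiseY <- function(s) mapValues(whiteNoiseMap(mesh, seed = s))
  expect_equal(as.numeric(selectLambda(smoothY(1), locs, lat, grid = 0.5)),
               0.5)
  g <- 10^seq(-4, 2, length.out = 10)
  l1 <- selectLambda(smoothY(1), locs, lat, grid = g)
  l2 <- selectLambda(smoothY(1), locs, lat, grid = g)
  expect_identical(attr(l1, "criterion")$value,
                   attr(l2, "criterion")$value)
  wins <- vapply(1:20, function(s)
    as.numeric(selectLambda(noiseY(s), locs, lat, grid = g)) >
      as.numeric(selectLambda(smoothY(s), locs, lat, grid = g)),
    logical(1))
  expect_gte(sum(wins), 18)
  expect_error(selectLambda(smoothY(1), locs, lat, grid = numeric(0)),
               "nonempty")
})

test_that("gcv-based selection also separates noise from smooth fields", {
  lat <- oneLevelLattice(1)
  mesh <- icoMesh(2)
  locs <- vertexCoords(mesh)
  g <- 10^seq(-4, 2, length.out = 8)
  ls <- as.numeric(selectLambda(mapValues(smoothMap(mesh, 3,
                                                    noiseSd = 0.02)),
                                locs, lat, grid = g, criterion = "gcv"))
  ln <- as.numeric(selectLambda(mapValues(whiteNoiseMap(mesh, 3)), locs,
                                lat, grid = g, criterion = "gcv"))
  expect_gt(ln, ls)
})

test_that("duplicate locations at lambda = 0 give an actionable error", {
  lat <- oneLevelLattice(0)
  pts <- randomSpherePoints(6, seed = 61)[rep(1:6, 3), ]
  set.seed(62); y <- rnorm(18)
  expect_error(suppressWarnings(krigFit(y, pts, lat, lambda = 0)),
               "lambda > 0")
})

test_that("kriging models survive a JSON save/load roundtrip", {
  lat <- buildSphereLattice(2, 1, 2.5, c(1, 0.25))
  pts <- randomSpherePoints(40, seed = 71)
  set.seed(72); y <- rnorm(40)
  fit <- krigFit(y, pts, lat, lambda = 0.05)
  path <- tempfile(fileext = ".json")
  saveKrigingModel(fit, path)
  fit2 <- readKrigingModel(path)
  q <- randomSpherePoints(25, 73)
  expect_equal(predict(fit2, q), predict(fit, q), tolerance = 1e-12)
})
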