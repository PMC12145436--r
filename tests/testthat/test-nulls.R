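test_that("random rotations are proper and Haar-uniform", {
  set.seed(1)
  R <- randomRotation()
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  # Haar sanity: the mean image of a fixed vector is near the origin
  v <- c(1, 0, 0)
  set.seed(2)
  imgs <- vapply(seq_len(1000), function(i) randomRotation() %*% v,
                 numeric(3))
  expect_lt(sqrt(sum(rowMeans(imgs)^2)), 0.1)
})

test_that("spin rotation preserves labels under the identity and label
           counts under random rotations", {
  mesh <- icoMesh(3)
  labels <- synthNetworks(mesh, 4, seed = 3)
  expect_identical(spinRotate(mesh, labels, diag(3)), labels)
  expect_error(spinRotate(mesh, labels, diag(c(1, 1, -1))), "determinant")
  set.seed(4)
  tab0 <- tabulate(labels, 4)
  for (i in 1:25) {
    rl <- spinRotate(mesh, labels, randomRotation())
    expect_lt(max(abs(tabulate(rl, 4) - tab0) / tab0), 0.25)
  }
  # rotation followed by its inverse restores the labelling when the
  # nearest-neighbour reassignment is bijective
  set.seed(5)
  R <- randomRotation()
  back <- spinRotate(mesh, spinRotate(mesh, labels, R), t(R))
  expect_gt(mean(back == labels), 0.95)
})

test_that("the spin null reports add-one p-values with both corrections
           and respects its seed", {
  mesh <- icoMesh(2)
  labels <- synthNetworks(mesh, 3, seed = 6)
  map <- smoothMap(mesh, seed = 7, nModes = 100)
  cfg <- latticeConfig(nLevels = 1, baseSubdivision = 1, alpha = 1,
                       lambda = 1e-3)
  sn <- spinNull(map, labels, n = 100, seed = 8, config = cfg,
                 minNetworkSize = 20)
  expect_equal(nrow(sn$pvalues), 3L)
  expect_true(all(sn$pvalues$p >= 1 / 101 & sn$pvalues$p <= 1))
  expect_equal(sn$pvalues$p_bonferroni, pmin(1, sn$pvalues$p * 3))
  # p matches counting on the stored null matrix
  expect_equal(sn$pvalues$p[1],
               (1 + sum(sn$null[, 1] >= sn$observed[1])) / 101)
  sn2 <- spinNull(map, labels, n = 100, seed = 8, config = cfg,
                  minNetworkSize = 20)
  expect_identical(sn$null, sn2$null)
  expect_error(spinNull(map, labels, n = 50, seed = 1, config = cfg),
               "at least 100")
})

test_that("eigengroup structure follows eigenvalue clusters, falling back
           to harmonic-like blocks on non-degenerate spectra", {
  # degenerate spectrum: clusters of 3 and 5
  ev <- c(0, rep(2, 3), rep(6, 5))
  g <- geokrig:::.eigenGroups(ev)
  expect_equal(lengths(g), c(3L, 5L))
  expect_equal(g[[1]], 2:4)
  # strictly increasing spectrum: blocks of 3, 5, 7, ...
  g2 <- geokrig:::.eigenGroups(seq(0, 10, length.out = 16))
  expect_equal(lengths(g2), c(3L, 5L, 7L))
})

test_that("the eigenmode reconstruction identity behind surrogate maps is
           exact", {
  mesh <- icoMesh(3)
  basis <- meshEigenmodes(mesh, 150)
  map <- smoothMap(mesh, seed = 21)
  vidx <- which(validMask(mesh))
  x <- mapValues(map)[vidx]
  modes <- eigenModes(basis)[vidx, ]
  w <- basis@weights[vidx]
  a <- as.numeric(crossprod(modes, w * x))
  recon <- as.numeric(modes %*% a)
  # identity rotation in every group, resample off == original map
  expect_equal(recon + (x - recon), x, tolerance = 1e-12)
  # truncated reconstruction alone leaves a residual on rough maps
  rough <- whiteNoiseMap(mesh, 22)
  xr <- mapValues(rough)[vidx]
  ar <- as.numeric(crossprod(modes, w * xr))
  expect_gt(sd(xr - as.numeric(modes %*% ar)), 0)
})

test_that("surrogates preserve the value histogram exactly and are
           reproducible from their seed", {
  mesh <- icoMesh(3)
  basis <- meshEigenmodes(mesh, 150)
  map <- smoothMap(mesh, seed = 23)
  ens <- eigenstrap(map, basis, n = 20, seed = 9)
  vidx <- validMask(mesh)
  for (s in c(1, 10, 20))
    expect_identical(sort(surrogateMaps(ens)[vidx, s]),
                     sort(mapValues(map)[vidx]))
  ens2 <- eigenstrap(map, basis, n = 20, seed = 9)
  expect_identical(surrogateMaps(ens), surrogateMaps(ens2))
  expect_error(eigenstrap(map, meshEigenmodes(mesh, 20), n = 5),
               "at least 50")
})

test_that("surrogates decorrelate map content while matching its
           variogram", {
  mesh <- icoMesh(3)
  basis <- meshEigenmodes(mesh, 150)
  # flat-ish spectrum spreads variance over many eigengroups, so chance
  # alignment between surrogate and original is small
  map <- synthMap(mesh, synthSpec(gamma = 0.7, nModes = 140,
                                  noiseSd = 0.05, seed = 24),
                  basis = meshEigenmodes(mesh, 151))
  ens <- eigenstrap(map, basis, n = 40, seed = 10)
  vidx <- validMask(mesh)
  cors <- cor(mapValues(map)[vidx], surrogateMaps(ens)[vidx, ])
  expect_lt(mean(abs(cors)), 0.2)
  vg0 <- meshVariogram(map, nBins = 6, maxDist = 1.2)
  surrGamma <- vapply(seq_len(40), function(s) {
    sm <- new("SurfaceMap", values = surrogateMaps(ens)[, s],
              mesh = mesh, name = "surr")
    meshVariogram(sm, nBins = 6, maxDist = 1.2)$gamma
  }, numeric(6))
  keep <- vg0$n > 0
  relerr <- abs(rowMeans(surrGamma)[keep] - vg0$gamma[keep]) /
    vg0$gamma[keep]
  expect_lt(max(relerr), 0.15)
})

test_that("permutation p-values match brute-force counting", {
  expect_equal(surrogatePvalue(10, rep(0, 200)), 1 / 201)
  nulls <- seq_len(200)
  expect_equal(surrogatePvalue(100.5, nulls), 101 / 201)
  set.seed(11)
  obs <- rnorm(1)
  ns <- rnorm(300)
  expect_equal(surrogatePvalue(obs, ns),
               (1 + sum(ns >= obs)) / 301)
  expect_equal(surrogatePvalue(obs, ns, "two.sided"),
               min(1, 2 * min((1 + sum(ns >= obs)) / 301,
                              (1 + sum(ns <= obs)) / 301)))
  expect_error(surrogatePvalue(0, rnorm(10)), "at least 50")
})
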