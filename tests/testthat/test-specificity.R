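test_that("conjunction masks are exact set intersections", {
  mesh <- icoMesh(3)
  basis <- meshEigenmodes(mesh, 151)
  spec <- synthSpec(gamma = 1, nModes = 150, noiseSd = 0.1, seed = 4)
  fam <- synthTaskFamily(mesh, 2, 0.6, spec, basis = basis)
  mA <- thresholdMask(fam[[1]])
  mB <- thresholdMask(fam[[2]])
  cj <- conjunctionMask(mA, mB)
  expect_equal(which(maskMembers(cj)),
               intersect(which(maskMembers(mA)), which(maskMembers(mB))))
  expect_equal(cj@quantile, sum(maskMembers(cj)) / sum(validMask(mesh)))
  same <- conjunctionMask(mA, mA)
  expect_identical(maskMembers(same), maskMembers(mA))
  # disjoint masks error with both sizes reported
  v <- mapValues(fam[[1]])
  mHi <- thresholdMask(fam[[1]], 0.25, "high")
  mLo <- thresholdMask(fam[[1]], 0.25, "low")
  mHi@tail <- "low"  # force same-tail comparison of disjoint sets
  expect_error(conjunctionMask(mLo, mHi), "empty conjunction")
})

test_that("identical maps give an exact specificity tie", {
  mesh <- icoMesh(3)
  map <- smoothMap(mesh, seed = 12)
  rep <- pairwiseSpecificity(map, map, config = smallConfig(),
                             minConjunction = 30)
  expect_true(all(rep@table$winner == "tie"))
  expect_equal(rep@table$rho_true, rep@table$rho_alt)
})

test_that("the true task wins against alternatives with independent
           unique components in most seeded pairs", {
  mesh <- icoMesh(3)
  basis <- meshEigenmodes(mesh, 151)
  wins <- 0L
  nPairs <- 8L
  for (s in seq_len(nPairs)) {
    fam <- synthTaskFamily(mesh, 2, 0.5,
                           synthSpec(gamma = 2, nModes = 150,
                                     noiseSd = 0.1, seed = 100 + s),
                           basis = basis)
    rep <- tryCatch(
      pairwiseSpecificity(fam[[1]], fam[[2]], config = smallConfig(),
                          minConjunction = 30),
      error = function(e) NULL)
    if (is.null(rep)) next
    if (rep@table$winner[rep@table$restriction == "none"] == "true")
      wins <- wins + 1L
  }
  expect_gt(wins / nPairs, 0.5)
})

test_that("swapping the pair roles changes the evaluation target
           (reports are independent, not copied)", {
  mesh <- icoMesh(3)
  basis <- meshEigenmodes(mesh, 151)
  fam <- synthTaskFamily(mesh, 2, 0.5,
                         synthSpec(gamma = 2, nModes = 150,
                                   noiseSd = 0.1, seed = 31),
                         basis = basis)
  ab <- pairwiseSpecificity(fam[[1]], fam[[2]], config = smallConfig(),
                            minConjunction = 30)
  ba <- pairwiseSpecificity(fam[[2]], fam[[1]], config = smallConfig(),
                            minConjunction = 30)
  expect_equal(ab@conjunctionSize, ba@conjunctionSize)
  expect_false(isTRUE(all.equal(ab@table$rho_true, ba@table$rho_true)))
  expect_identical(ab@taskPair, rev(ba@taskPair))
})

test_that("all ordered pairs are reported (42 comparisons for 7 maps
           scaled to 3 maps here)", {
  mesh <- icoMesh(3)
  basis <- meshEigenmodes(mesh, 151)
  fam <- synthTaskFamily(mesh, 3, 0.6,
                         synthSpec(gamma = 1.5, nModes = 150,
                                   noiseSd = 0.1, seed = 41),
                         basis = basis)
  df <- pairwiseSpecificityAll(fam, config = smallConfig(),
                               minConjunction = 20)
  expect_equal(length(unique(paste(df$true_task, df$alt_task))), 6L)
  expect_equal(nrow(df), 6L * 3L)  # three restrictions per ordered pair
})

test_that("network prediction with a mask-versus-rest labelling
           reproduces the masked-prediction metric", {
  mesh <- icoMesh(3)
  map <- smoothMap(mesh, seed = 13)
  mk <- thresholdMask(map)
  cfg <- smallConfig()
  res <- krigeFromMask(map, mk, cfg)
  labels <- ifelse(maskMembers(mk), 1L, 2L)
  labels[!validMask(mesh)] <- 0L
  M <- networkPrediction(map, labels, cfg)
  expect_equal(M["net1", 1],
               resultMetrics(res)$spearman_rho[1], tolerance = 1e-6)
})

test_that("network prediction returns a networks-by-tasks matrix and
           flags undersized networks", {
  mesh <- icoMesh(3)
  basis <- meshEigenmodes(mesh, 151)
  fam <- synthTaskFamily(mesh, 3, 0.5,
                         synthSpec(gamma = 2, nModes = 150,
                                   noiseSd = 0.1, seed = 51),
                         basis = basis)
  labels <- synthNetworks(mesh, 7, seed = 52)
  M <- networkPrediction(fam, labels, smallConfig())
  expect_equal(dim(M), c(7L, 3L))
  expect_true(all(is.finite(M)))
  # shrink one network below the size floor
  labels2 <- labels
  small <- which(labels2 == 3L)
  labels2[small[-(1:5)]] <- 1L
  M2 <- networkPrediction(fam[[1]], labels2, smallConfig(),
                          minNetworkSize = 50)
  expect_true("net3" %in% attr(M2, "skipped"))
  expect_true(is.na(M2["net3", 1]))
})

test_that("distributed networks predict the complement better than
           compact ones of equal area", {
  mesh <- icoMesh(3)
  basis <- meshEigenmodes(mesh, 151)
  better <- 0L
  nSeeds <- 10L
  for (s in seq_len(nSeeds)) {
    map <- synthMap(mesh, synthSpec(gamma = 2, nModes = 150,
                                    noiseSd = 0.1, seed = 200 + s),
                    basis = basis)
    compact <- synthNetworks(mesh, 2, 1, seed = 300 + s)
    spread <- synthNetworks(mesh, 2, 8, seed = 300 + s)
    rC <- mean(networkPrediction(map, compact, smallConfig()), na.rm = TRUE)
    rD <- mean(networkPrediction(map, spread, smallConfig()), na.rm = TRUE)
    if (rD > rC) better <- better + 1L
  }
  expect_gte(better, ceiling(0.75 * nSeeds))
})
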