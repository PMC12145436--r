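test_that("frame prediction masks the configured top quantile and scores
           both restrictions", {
  mov <- synthMovie(c(48, 48), T = 2, gamma = 3, temporalPhi = 0,
                    seed = 1)
  fr <- seriesFrames(mov)[1, , ]
  valid <- pixelValid(mov)
  res <- framePredict(fr, valid, planarConfig(c(48, 48), minDistance = 6))
  expect_equal(sum(maskMembers(res)), round(0.25 * sum(valid)))
  expect_true(min(fr[valid][maskMembers(res)]) >=
                max(fr[valid][!maskMembers(res)]))
  m <- resultMetrics(res)
  expect_equal(m$restriction, c("none", "min_distance_6"))
  expect_gt(m$spearman_rho[1], 0.5)
  expect_true(m$n[2] < m$n[1])
  expect_error(framePredict(fr, valid & (row(fr) < 5)), "100 valid")
})

test_that("an all-equal frame yields flagged-undefined metrics", {
  valid <- matrix(TRUE, 20, 20)
  res <- framePredict(matrix(1, 20, 20), valid,
                      planarConfig(c(20, 20), minDistance = 3,
                                   baseSpacing = 4))
  expect_true(all(is.na(resultMetrics(res)$spearman_rho)))
})

test_that("planar kriging matches the dense oracle on a toy grid", {
  lat <- buildPlanarLattice(c(10, 10), 1, 2.5, 1, baseSpacing = 3)
  set.seed(2)
  pts <- cbind(runif(40, 1, 10), runif(40, 1, 10))
  y <- rnorm(40)
  fit <- krigFit(y, pts, lat, lambda = 0.2)
  A <- cbind(1, as.matrix(basisMatrix(lat, pts)))
  Q <- as.matrix(sarPrecision(lat@levels[[1]], 0.01))
  sol <- solve(crossprod(A) + rbind(0, cbind(0, 0.2 * Q)),
               crossprod(A, y))
  expect_equal(c(fit@fixedCoef, fit@coefficients), as.numeric(sol),
               tolerance = 1e-8)
})

test_that("series analysis treats frames independently", {
  mov <- synthMovie(c(32, 32), T = 12, gamma = 3, temporalPhi = 0.5,
                    seed = 3)
  cfg <- planarConfig(c(32, 32), minDistance = 5)
  rep1 <- seriesAnalyze(mov, cfg)
  # identical frames give identical per-frame metrics
  movC <- new("ImageSeries",
              frames = aperm(array(seriesFrames(mov)[1, , ],
                                   c(32, 32, 5)), c(3, 1, 2)),
              pixelValid = pixelValid(mov), pixelSize = numeric(0))
  repC <- seriesAnalyze(movC, cfg)
  expect_equal(length(unique(resultMetrics(repC)$rho_all)), 1L)
  # permuting frame order permutes outputs identically
  perm <- c(4, 1, 12, 7, 2, 9, 3, 11, 5, 10, 6, 8)
  movP <- new("ImageSeries", frames = seriesFrames(mov)[perm, , ],
              pixelValid = pixelValid(mov), pixelSize = numeric(0))
  repP <- seriesAnalyze(movP, cfg)
  expect_equal(resultMetrics(repP)$rho_all,
               resultMetrics(rep1)$rho_all[perm])
})

test_that("smooth movies give mostly positive frames and white-noise
           movies do not", {
  cfg <- planarConfig(c(32, 32), minDistance = 5)
  mov <- synthMovie(c(32, 32), T = 15, gamma = 3, temporalPhi = 0.8,
                    seed = 4)
  rep <- seriesAnalyze(mov, cfg)
  expect_gt(rep@inference$all$frac_positive, 0.9)
  nonsig <- 0L
  for (s in 1:20) {
    movW <- synthMovie(c(32, 32), T = 15, gamma = 0, temporalPhi = 0,
                       seed = 400 + s)
    repW <- seriesAnalyze(movW, cfg)
    if (repW@inference$all$t_p > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 18L)
})

test_that("group inference Fisher-transforms correlations and adjusts for
           AR(1) dependence", {
  gi0 <- groupInference(rep(0, 20))
  expect_equal(gi0$mean_z, 0)
  expect_equal(gi0$t_stat, 0)
  # alternating series: the AR regression is a perfect two-point fit,
  # which makes lm's summary grumble harmlessly
  gi5 <- suppressWarnings(groupInference(rep(c(0.5, 0.3), 10)))
  expect_equal(gi5$mean_z, mean(atanh(c(0.5, 0.3))), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.549306, tolerance = 1e-6)
  expect_warning(groupInference(c(rep(0.5, 11), 1)), "clipped")
  expect_error(groupInference(rep(0.2, 5)), "at least 10")
  # AR-adjusted standard errors exceed i.i.d. ones for persistent series
  set.seed(5)
  wider <- 0L
  for (r in 1:20) {
    z <- as.numeric(arima.sim(list(ar = 0.6), 80, sd = 0.1)) + 0.2
    gi <- suppressWarnings(groupInference(tanh(z)))
    if (gi$ar_phi > 0 && gi$ar_se >= gi$iid_se) wider <- wider + 1L
  }
  expect_gte(wider, 18L)
})

test_that("the t-test branch is calibrated on i.i.d. null z-series", {
  set.seed(6)
  rej <- 0L
  for (r in 1:400) {
    z <- rnorm(40, 0, 0.1)
    if (groupInference(tanh(z))$t_p <= 0.05) rej <- rej + 1L
  }
  # 95% binomial band around 0.05 for 400 replicates
  expect_gte(rej, qbinom(0.025, 400, 0.05))
  expect_lte(rej, qbinom(0.975, 400, 0.05))
})

test_that("synthetic movies follow their AR(1) temporal design", {
  lag1 <- function(mov) {
    f <- seriesFrames(mov)
    mean(vapply(2:dim(f)[1], function(t)
      cor(as.vector(f[t, , ]), as.vector(f[t - 1, , ])), numeric(1)))
  }
  hi <- vapply(1:8, function(s)
    lag1(synthMovie(c(32, 32), T = 30, gamma = 3, temporalPhi = 0.9,
                    seed = s)), numeric(1))
  expect_true(mean(hi) > 0.8 && mean(hi) < 0.95)
  lo <- vapply(1:8, function(s)
    lag1(synthMovie(c(32, 32), T = 30, gamma = 3, temporalPhi = 0,
                    seed = s)), numeric(1))
  expect_lt(abs(mean(lo)), 0.1)
  expect_error(synthMovie(c(32, 32), T = 1), "at least 2")
  expect_error(synthMovie(c(32, 32), temporalPhi = 1), "phi")
})
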