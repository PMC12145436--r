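# Planar pixel coordinates (x = column, y = row) of a logical mask.
.pixelCoords <- function(valid) {
  w <- which(valid, arr.ind = TRUE)
  cbind(x = w[, 2], y = w[, 1])
}

# Distance (pixels) of each query pixel to the nearest mask pixel,
# Euclidean by default, Chebyshev optionally; chunked brute force.
.distToMaskPlane <- function(queryXY, maskXY, metric = c("euclidean",
                                                         "chebyshev")) {
  metric <- match.arg(metric)
  n <- nrow(queryXY)
  out <- numeric(n)
  chunk <- 1024L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    dx <- outer(queryXY[s:e, 1], maskXY[, 1], "-")
    dy <- outer(queryXY[s:e, 2], maskXY[, 2], "-")
    d <- if (metric == "euclidean") sqrt(dx^2 + dy^2)
         else pmax(abs(dx), abs(dy))
    out[s:e] <- apply(d, 1, min)
  }
  out
}

#' Default configuration for the planar (calcium) pipeline
#'
#' @param gridShape frame dimensions c(rows, cols).
#' @param ... overrides; see [latticeConfig()] for shared fields. Planar
#'   defaults: top-quantile masking at 0.25, 25-pixel evaluation distance,
#'   Euclidean distance metric.
#' @return named list.
#' @export
planarConfig <- function(gridShape, ...) {
  cfg <- list(gridShape = gridShape, nLevels = 3, rangeMultiplier = 2.5,
              alpha = c(1, 0.25, 0.01), baseSpacing = max(gridShape) / 8,
              kappa2 = 0.01, lambda = 1e-3, fixed = "intercept",
              quantile = 0.25, tail = "high", minDistance = 25,
              distanceMetric = "euclidean", lattice = NULL,
              basisFull = NULL)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  utils::modifyList(cfg, over)
}

.resolvePlanarDesign <- function(cfg, valid) {
  lattice <- cfg$lattice
  if (is.null(lattice))
    lattice <- buildPlanarLattice(cfg$gridShape, cfg$nLevels,
                                  cfg$rangeMultiplier, cfg$alpha,
                                  cfg$baseSpacing)
  coords <- .pixelCoords(valid)
  basisFull <- cfg$basisFull
  if (is.null(basisFull)) basisFull <- basisMatrix(lattice, coords)
  Qalpha <- .latticePrecision(lattice, cfg$kappa2)
  list(lattice = lattice, coords = coords, basisFull = basisFull,
       Qalpha = Qalpha)
}

#' Krige one image frame from its top-quantile pixels
#'
#' Masks the extreme tail (default the top 25%) of the valid pixels of a
#' frame, fits a planar lattice kriging model on the masked pixels only,
#' predicts every valid pixel, and evaluates out-of-mask agreement both
#' unrestricted and at a minimum Euclidean distance (default 25 pixels)
#' from the mask.
#'
#' @param frame numeric matrix (rows x cols).
#' @param valid logical matrix of analysis-support pixels (>= 100).
#' @param config see [planarConfig()]; built from `dim(frame)` if NULL.
#' @return a [PredictionResult-class] with domain "plane". For an
#'   all-equal frame the metrics are flagged-undefined (NA), not an error.
#' @export
framePredict <- function(frame, valid, config = NULL) {
  frame <- as.matrix(frame)
  if (is.null(config)) config <- planarConfig(dim(frame))
  cfg <- planarConfig(dim(frame), config)
  if (sum(valid) < 100) stop("at least 100 valid pixels required")
  des <- .resolvePlanarDesign(cfg, valid)
  vals <- frame[valid]
  nv <- length(vals)
  m <- max(1L, min(nv, round(cfg$quantile * nv)))
  ord <- if (cfg$tail == "high") order(-vals, seq_len(nv))
         else order(vals, seq_len(nv))
  inMask <- logical(nv)
  inMask[ord[seq_len(m)]] <- TRUE
  fit <- krigFit(vals[inMask], des$coords[inMask, , drop = FALSE],
                 des$lattice, lambda = cfg$lambda, fixed = cfg$fixed,
                 kappa2 = cfg$kappa2,
                 basis = des$basisFull[inMask, , drop = FALSE],
                 Qalpha = des$Qalpha)
  pred <- as.numeric(des$basisFull %*% fit@coefficients)
  X <- .fixedDesign(des$coords, cfg$fixed)
  if (ncol(X)) pred <- pred + as.numeric(X %*% fit@fixedCoef)
  d <- .distToMaskPlane(des$coords, des$coords[inMask, , drop = FALSE],
                        cfg$distanceMetric)
  meta <- list(task = "frame", meshFingerprint = "plane",
               config = cfg[c("nLevels", "rangeMultiplier", "alpha",
                              "baseSpacing", "kappa2", "lambda", "fixed",
                              "quantile", "tail", "minDistance",
                              "distanceMetric")],
               quantile = cfg$quantile, tail = cfg$tail)
  .makePredictionResult("plane", inMask, rep(TRUE, nv), pred, vals, d,
                        NULL, meta, list("none", "min_distance"),
                        cfg$minDistance)
}

#' Analyze a whole image series frame by frame
#'
#' Fits an independent planar kriging model per frame (no information is
#' shared across frames), collecting the out-of-mask Spearman correlation
#' with and without the minimum-distance restriction, and aggregates them
#' with [groupInference()] (Fisher-z t-test and AR(1)-adjusted test).
#' Frames whose model fails are logged and excluded with a count.
#'
#' @param series an [ImageSeries-class].
#' @param config see [planarConfig()].
#' @return a [SeriesReport-class].
#' @export
seriesAnalyze <- function(series, config = NULL) {
  stopifnot(is(series, "ImageSeries"))
  d <- dim(series@frames)
  if (is.null(config)) config <- planarConfig(d[2:3])
  cfg <- planarConfig(d[2:3], config)
  des <- .resolvePlanarDesign(cfg, series@pixelValid)
  cfg$lattice <- des$lattice
  cfg$basisFull <- des$basisFull
  rows <- vector("list", d[1])
  nFailed <- 0L
  for (t in seq_len(d[1])) {
    res <- tryCatch(framePredict(series@frames[t, , ], series@pixelValid,
                                 cfg),
                    error = function(e) NULL)
    if (is.null(res)) {
      nFailed <- nFailed + 1L
      rows[[t]] <- data.frame(frame = t, n_all = NA_integer_,
                              rho_all = NA_real_, n_dist = NA_integer_,
                              rho_dist = NA_real_)
      next
    }
    m <- res@metrics
    rows[[t]] <- data.frame(
      frame = t,
      n_all = m$n[m$restriction == "none"],
      rho_all = m$spearman_rho[m$restriction == "none"],
      n_dist = m$n[startsWith(m$restriction, "min_distance")],
      rho_dist = m$spearman_rho[startsWith(m$restriction, "min_distance")])
  }
  fm <- do.call(rbind, rows)
  clip <- function(r) pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
  fm$fisher_z_all <- atanh(clip(fm$rho_all))
  fm$fisher_z_dist <- atanh(clip(fm$rho_dist))
  safeInference <- function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 10)
      return(list(n = length(r), mean_rho = NA_real_, frac_positive = NA_real_,
                  mean_z = NA_real_, t_stat = NA_real_, t_p = NA_real_,
                  ar_phi = NA_real_, ar_mean = NA_real_, ar_se = NA_real_,
                  ar_z = NA_real_, ar_p = NA_real_, iid_se = NA_real_))
    groupInference(r)
  }
  inference <- list(all = safeInference(fm$rho_all),
                    min_distance = safeInference(fm$rho_dist))
  cfgEcho <- cfg[c("gridShape", "nLevels", "rangeMultiplier", "alpha",
                   "baseSpacing", "kappa2", "lambda", "fixed", "quantile",
                   "tail", "minDistance", "distanceMetric")]
  cfgEcho$nFailed <- nFailed
  new("SeriesReport", frameMetrics = fm, inference = inference,
      config = cfgEcho)
}

#' Group inference over per-frame correlations
#'
#' Fisher-z transforms the correlations (`z = atanh(rho)`, with |rho| = 1
#' clipped to 1 - 1e-12 under a warning) and tests whether the average
#' correlation is above chance in two ways: a one-sample one-sided t-test
#' of mean z > 0, and an AR(1)-adjusted test — an order-1 autoregression
#' with intercept is fitted to the z series, and the process mean
#' `intercept / (1 - phi)` is tested against 0 with a delta-method
#' (autocorrelation-consistent) standard error.
#'
#' @param rhos per-frame correlations (>= 10 finite values).
#' @return list: n, mean_rho, frac_positive, mean_z, t_stat, t_p, ar_phi,
#'   ar_mean, ar_se, ar_z, ar_p.
#' @export
groupInference <- function(rhos) {
  rhos <- rhos[is.finite(rhos)]
  if (length(rhos) < 10) stop("at least 10 frames required")
  if (any(abs(rhos) >= 1)) {
    warning("|rho| = 1 clipped to 1 - 1e-12 before Fisher transform")
    rhos <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rhos))
  }
  z <- atanh(rhos)
  n <- length(z)
  tt <- if (sd(z) == 0) list(statistic = c(t = 0), p.value = 0.5)
        else t.test(z, mu = 0, alternative = "greater")
  # AR(1) with intercept: z_t = c + phi z_(t-1) + e
  fitAR <- lm(z[-1] ~ z[-n])
  cc <- coef(fitAR)
  phi <- unname(cc[2])
  intc <- unname(cc[1])
  mu <- intc / (1 - phi)
  V <- vcov(fitAR)
  grad <- c(1 / (1 - phi), intc / (1 - phi)^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  arz <- mu / se
  list(n = n, mean_rho = mean(rhos), frac_positive = mean(rhos > 0),
       mean_z = mean(z), t_stat = unname(tt$statistic), t_p = tt$p.value,
       ar_phi = phi, ar_mean = mu, ar_se = se, ar_z = arz,
       ar_p = pnorm(arz, lower.tail = FALSE),
       iid_se = sd(z) / sqrt(n))
}
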