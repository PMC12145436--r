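#' Conjunction of two vertex masks
#'
#' Intersection of two same-tail masks on one mesh; the recorded quantile
#' is the effective fraction of valid vertices retained.
#'
#' @param maskA,maskB [VertexMask-class] objects on the same mesh with the
#'   same tail.
#' @return a [VertexMask-class]; empty intersections are an error that
#'   reports both input sizes.
#' @export
conjunctionMask <- function(maskA, maskB) {
  stopifnot(is(maskA, "VertexMask"), is(maskB, "VertexMask"))
  if (!identical(.meshFingerprint(maskA@mesh), .meshFingerprint(maskB@mesh)))
    stop("masks live on different meshes")
  if (maskA@tail != maskB@tail)
    stop("masks must select the same tail")
  members <- maskA@members & maskB@members
  if (!any(members))
    stop(sprintf("empty conjunction (mask sizes %d and %d)",
                 sum(maskA@members), sum(maskB@members)))
  new("VertexMask", members = members, tail = maskA@tail,
      quantile = sum(members) / sum(maskA@mesh@valid), mesh = maskA@mesh)
}

#' Pairwise task-specificity test via conjunction-mask prediction
#'
#' Tests whether prediction from a matched predictor set is specific to the
#' task whose values were used. The conjunction of the two tasks'
#' bottom-quantile masks is used as the predictor set twice — once with
#' task A's values ("true") and once with task B's values
#' ("alternative") — and both predictions are scored against task A's
#' observed values over the complement of A's bottom-quantile mask, under
#' three restrictions computed by pure post-hoc filtering of the same two
#' fits: all out-of-mask vertices, vertices farther than `minDistance`
#' radians from the predictor set, and vertices with observed A values > 0.
#'
#' @param mapA the "true" task map (its observed values are the target).
#' @param mapB the alternative task map.
#' @param quantile mask quantile (default 0.25).
#' @param config see [latticeConfig()].
#' @param minDistance evaluation distance restriction (default 0.1 rad).
#' @param minConjunction smallest usable conjunction size (default 50).
#' @return a [PairwiseReport-class]; `winner` is "true"/"alt" per
#'   restriction, or "tie" when the two correlations agree to 1e-12.
#' @export
pairwiseSpecificity <- function(mapA, mapB, quantile = 0.25,
                                config = list(), minDistance = 0.1,
                                minConjunction = 50) {
  stopifnot(is(mapA, "SurfaceMap"), is(mapB, "SurfaceMap"))
  if (!identical(.meshFingerprint(mapA@mesh), .meshFingerprint(mapB@mesh)))
    stop("maps live on different meshes")
  cfg <- latticeConfig(config)
  cfg$minDistance <- minDistance
  maskA <- thresholdMask(mapA, quantile, "low")
  maskB <- thresholdMask(mapB, quantile, "low")
  conj <- conjunctionMask(maskA, maskB)
  if (sum(conj@members) < minConjunction)
    stop(sprintf("conjunction mask too small (%d < %d vertices)",
                 sum(conj@members), minConjunction))
  mesh <- mapA@mesh
  des <- .resolveSphereDesign(cfg, mesh)
  idx <- which(conj@members)
  if (identical(cfg$lambda, "auto")) {
    # one lambda, selected on the true task's conjunction values, is used
    # for both fits so the two predictions get identical treatment
    cfg$lambda <- as.numeric(selectLambda(
      mapA@values[idx], mesh@coords[idx, , drop = FALSE], des$lattice,
      grid = cfg$lambdaGrid, kappa2 = cfg$kappa2, fixed = cfg$fixed,
      basis = des$basisFull[idx, , drop = FALSE], Qalpha = des$Qalpha))
  }
  fitOne <- function(map) {
    krigFit(map@values[idx], mesh@coords[idx, , drop = FALSE], des$lattice,
            lambda = cfg$lambda, fixed = cfg$fixed, kappa2 = cfg$kappa2,
            basis = des$basisFull[idx, , drop = FALSE], Qalpha = des$Qalpha)
  }
  predictAll <- function(fit) {
    p <- as.numeric(des$basisFull %*% fit@coefficients)
    X <- .fixedDesign(mesh@coords, cfg$fixed)
    if (ncol(X)) p <- p + as.numeric(X %*% fit@fixedCoef)
    p
  }
  predTrue <- predictAll(fitOne(mapA))
  predAlt <- predictAll(fitOne(mapB))
  outSet <- mesh@valid & !maskA@members
  dConj <- geodesicToSet(mesh, conj@members)
  sels <- list(
    none = outSet,
    min_distance = outSet & dConj > minDistance,
    observed_positive = outSet & mapA@values > 0)
  rows <- lapply(names(sels), function(nm) {
    sel <- sels[[nm]]
    n <- sum(sel)
    if (n < 10)
      return(data.frame(restriction = nm, n = n, rho_true = NA_real_,
                        rho_alt = NA_real_, winner = NA_character_))
    rt <- .spearman(predTrue[sel], mapA@values[sel])
    ra <- .spearman(predAlt[sel], mapA@values[sel])
    winner <- if (is.na(rt) || is.na(ra)) NA_character_
      else if (abs(rt - ra) < 1e-12) "tie"
      else if (rt > ra) "true" else "alt"
    data.frame(restriction = nm, n = n, rho_true = rt, rho_alt = ra,
               winner = winner)
  })
  new("PairwiseReport", taskPair = c(mapA@name, mapB@name),
      conjunctionSize = sum(conj@members), table = do.call(rbind, rows))
}

#' All ordered pairwise specificity reports for a set of maps
#'
#' Runs [pairwiseSpecificity()] for every ordered pair (A, B), A != B —
#' 42 comparisons for 7 maps. Reports for (A, B) and (B, A) are computed
#' independently.
#'
#' @param maps list of [SurfaceMap-class] on one mesh.
#' @inheritParams pairwiseSpecificity
#' @return data.frame with one row per pair and restriction.
#' @export
pairwiseSpecificityAll <- function(maps, quantile = 0.25, config = list(),
                                   minDistance = 0.1, minConjunction = 50) {
  cfg <- latticeConfig(config)
  des <- .resolveSphereDesign(cfg, maps[[1]]@mesh)
  cfg$lattice <- des$lattice
  cfg$basisFull <- des$basisFull
  nt <- length(maps)
  rows <- list()
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    rep <- pairwiseSpecificity(maps[[i]], maps[[j]], quantile, cfg,
                               minDistance, minConjunction)
    rows[[length(rows) + 1L]] <-
      cbind(true_task = rep@taskPair[1], alt_task = rep@taskPair[2],
            conjunction = rep@conjunctionSize, rep@table)
  }
  do.call(rbind, rows)
}

# Dense fast path used by network prediction and the spin null when the
# lattice is small: intercept + basis penalized solve and out-of-set
# Spearman score, all in base linear algebra.
.networkRhoFast <- function(PhiD, QD, lambda, values, valid, labels, k) {
  idx <- which(valid & labels == k)
  out <- which(valid & labels != k)
  if (length(idx) < 10 || length(out) < 10) return(NA_real_)
  A <- cbind(1, PhiD[idx, , drop = FALSE])
  M <- crossprod(A)
  M[-1, -1] <- M[-1, -1] + lambda * QD
  sol <- tryCatch(solve(M, crossprod(A, values[idx])),
                  error = function(e) NULL)
  if (is.null(sol)) return(NA_real_)
  pred <- as.numeric(cbind(1, PhiD[out, , drop = FALSE]) %*% sol)
  .spearman(pred, values[out])
}

#' Predict whole-surface activity from network masks
#'
#' For each network label, fits a kriging model on the raw (unthresholded)
#' map values at that network's vertices and predicts the complement,
#' reporting the out-of-mask Spearman correlation. With several maps the
#' result is a networks x tasks matrix. Networks smaller than
#' `minNetworkSize` are flagged and skipped (NA).
#'
#' @param maps a [SurfaceMap-class] or list of them (one mesh).
#' @param labels integer network label per vertex (0 = unassigned, never
#'   fit).
#' @param config see [latticeConfig()].
#' @param minNetworkSize smallest fitted network (default 50 vertices).
#' @return numeric matrix (networks x tasks) of out-of-mask Spearman
#'   correlations, with attribute `"skipped"` naming flagged networks.
#' @export
networkPrediction <- function(maps, labels, config = list(),
                              minNetworkSize = 50) {
  if (is(maps, "SurfaceMap")) maps <- list(maps)
  mesh <- maps[[1]]@mesh
  if (length(labels) != nVertices(mesh))
    stop("labels length must equal vertex count")
  if (any(labels[mesh@valid] == 0L))
    warning("some valid vertices are unlabeled (label 0); they are ",
            "excluded from network fits but still predicted")
  ids <- sort(unique(labels[labels > 0L & mesh@valid]))
  if (length(ids) < 2) stop("at least 2 networks required")
  cfg <- latticeConfig(config)
  # permutation-style per-network refits keep lambda fixed so every
  # network (and every rotation in the spin null) is scored identically
  if (identical(cfg$lambda, "auto")) cfg$lambda <- 1e-3
  des <- .resolveSphereDesign(cfg, mesh)
  p <- ncol(des$basisFull)
  dense <- p <= 800
  if (dense) {
    PhiD <- as.matrix(des$basisFull)
    QD <- as.matrix(des$Qalpha)
  }
  out <- matrix(NA_real_, length(ids), length(maps),
                dimnames = list(network = paste0("net", ids),
                                task = vapply(maps, mapName, character(1))))
  skipped <- character(0)
  for (ki in seq_along(ids)) {
    k <- ids[ki]
    nk <- sum(labels == k & mesh@valid)
    if (nk < minNetworkSize) {
      skipped <- c(skipped, paste0("net", k))
      next
    }
    for (ti in seq_along(maps)) {
      vals <- maps[[ti]]@values
      if (dense) {
        out[ki, ti] <- .networkRhoFast(PhiD, QD, cfg$lambda, vals,
                                       mesh@valid, labels, k)
      } else {
        idx <- which(mesh@valid & labels == k)
        oidx <- which(mesh@valid & labels != k)
        fit <- krigFit(vals[idx], mesh@coords[idx, , drop = FALSE],
                       des$lattice, lambda = cfg$lambda, fixed = cfg$fixed,
                       kappa2 = cfg$kappa2,
                       basis = des$basisFull[idx, , drop = FALSE],
                       Qalpha = des$Qalpha)
        pr <- as.numeric(des$basisFull[oidx, , drop = FALSE] %*%
                           fit@coefficients)
        X <- .fixedDesign(mesh@coords[oidx, , drop = FALSE], cfg$fixed)
        if (ncol(X)) pr <- pr + as.numeric(X %*% fit@fixedCoef)
        out[ki, ti] <- .spearman(pr, vals[oidx])
      }
    }
  }
  attr(out, "skipped") <- skipped
  out
}
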