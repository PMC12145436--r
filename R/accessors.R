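#' @name accessors
#' @title Accessors for geokrig classes
#' @description Slot accessors; user code should prefer these over `@`.
#' @param x object to access.
NULL

#' @rdname accessors
#' @export
setGeneric("vertexCoords", function(x) standardGeneric("vertexCoords"))
#' @rdname accessors
#' @export
setMethod("vertexCoords", "SphericalMesh", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
#' @rdname accessors
#' @export
setMethod("triangles", "SphericalMesh", function(x) x@triangles)

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setMethod("validMask", "SphericalMesh", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("validMask", "SurfaceMap", function(x) x@mesh@valid)

#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setMethod("nVertices", "SphericalMesh", function(x) nrow(x@coords))
#' @rdname accessors
#' @export
setMethod("nVertices", "SurfaceMap", function(x) nrow(x@mesh@coords))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "SurfaceMap", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("mapMesh", function(x) standardGeneric("mapMesh"))
#' @rdname accessors
#' @export
setMethod("mapMesh", "SurfaceMap", function(x) x@mesh)
#' @rdname accessors
#' @export
setMethod("mapMesh", "VertexMask", function(x) x@mesh)

#' @rdname accessors
#' @export
setGeneric("mapName", function(x) standardGeneric("mapName"))
#' @rdname accessors
#' @export
setMethod("mapName", "SurfaceMap", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("maskMembers", function(x) standardGeneric("maskMembers"))
#' @rdname accessors
#' @export
setMethod("maskMembers", "VertexMask", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("maskMembers", "PredictionResult", function(x) x@maskFlags)

#' @rdname accessors
#' @export
setGeneric("eigenModes", function(x) standardGeneric("eigenModes"))
#' @rdname accessors
#' @export
setMethod("eigenModes", "EigenBasis", function(x) x@modes)

#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setMethod("eigenValues", "EigenBasis", function(x) x@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))
#' @rdname accessors
#' @export
setMethod("nLevels", "MultiresLattice", function(x) length(x@levels))

#' @rdname accessors
#' @export
setGeneric("latticeNodes", function(x) standardGeneric("latticeNodes"))
#' @rdname accessors
#' @export
setMethod("latticeNodes", "MultiresLattice",
          function(x) lapply(x@levels, function(l) l$nodes))

#' @rdname accessors
#' @export
setGeneric("latticeRanges", function(x) standardGeneric("latticeRanges"))
#' @rdname accessors
#' @export
setMethod("latticeRanges", "MultiresLattice",
          function(x) vapply(x@levels, function(l) l$range, numeric(1)))

#' @rdname accessors
#' @export
setGeneric("alphaWeights", function(x) standardGeneric("alphaWeights"))
#' @rdname accessors
#' @export
setMethod("alphaWeights", "MultiresLattice", function(x) x@alpha)

#' @rdname accessors
#' @export
setGeneric("predictedValues", function(x) standardGeneric("predictedValues"))
#' @rdname accessors
#' @export
setMethod("predictedValues", "PredictionResult", function(x) x@predicted)

#' @rdname accessors
#' @export
setGeneric("observedValues", function(x) standardGeneric("observedValues"))
#' @rdname accessors
#' @export
setMethod("observedValues", "PredictionResult", function(x) x@observed)

#' @rdname accessors
#' @export
setGeneric("resultMetrics", function(x) standardGeneric("resultMetrics"))
#' @rdname accessors
#' @export
setMethod("resultMetrics", "PredictionResult", function(x) x@metrics)
#' @rdname accessors
#' @export
setMethod("resultMetrics", "SeriesReport", function(x) x@frameMetrics)

#' @rdname accessors
#' @export
setGeneric("surrogateMaps", function(x) standardGeneric("surrogateMaps"))
#' @rdname accessors
#' @export
setMethod("surrogateMaps", "SurrogateEnsemble", function(x) x@maps)

#' @rdname accessors
#' @export
setGeneric("seriesFrames", function(x) standardGeneric("seriesFrames"))
#' @rdname accessors
#' @export
setMethod("seriesFrames", "ImageSeries", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("pixelValid", function(x) standardGeneric("pixelValid"))
#' @rdname accessors
#' @export
setMethod("pixelValid", "ImageSeries", function(x) x@pixelValid)

setMethod("show", "SphericalMesh", function(object) {
  cat(sprintf("SphericalMesh: %d vertices (%d valid), %d triangles\n",
              nrow(object@coords), sum(object@valid), nrow(object@triangles)))
})

setMethod("show", "SurfaceMap", function(object) {
  v <- object@values[object@mesh@valid]
  cat(sprintf("SurfaceMap '%s': %d valid vertices, range [%.3f, %.3f]\n",
              object@name, length(v), min(v), max(v)))
})

setMethod("show", "VertexMask", function(object) {
  cat(sprintf("VertexMask: %d members (%s tail, quantile %.3g)\n",
              sum(object@members), object@tail, object@quantile))
})

setMethod("show", "EigenBasis", function(object) {
  cat(sprintf("EigenBasis: %d modes, eigenvalues [%.3g, %.3g]\n",
              ncol(object@modes), object@eigenvalues[1],
              object@eigenvalues[length(object@eigenvalues)]))
})

setMethod("show", "MultiresLattice", function(object) {
  nn <- vapply(object@levels, function(l) nrow(l$nodes), numeric(1))
  cat(sprintf("MultiresLattice (%s): %d levels, nodes (%s), alpha (%s)\n",
              object@domain, length(object@levels),
              paste(nn, collapse = ", "),
              paste(signif(object@alpha, 3), collapse = ", ")))
})

setMethod("show", "KrigingModel", function(object) {
  cat(sprintf(
    "KrigingModel: %d coefficients over %d levels, lambda = %.3g, fixed = %s\n",
    length(object@coefficients), length(object@lattice@levels),
    object@lambda, object@fixed))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult (%s): %d points, %d in predictor mask\n",
              object@domain, length(object@predicted), sum(object@maskFlags)))
  print(object@metrics, row.names = FALSE)
})

setMethod("show", "SurrogateEnsemble", function(object) {
  cat(sprintf("SurrogateEnsemble: %d surrogates, resample = %s, seed = %d\n",
              ncol(object@maps), object@resample, as.integer(object@seed)))
})

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageSeries: %d frames of %d x %d (%d valid pixels)\n",
              d[1], d[2], d[3], sum(object@pixelValid)))
})

setMethod("show", "PairwiseReport", function(object) {
  cat(sprintf("PairwiseReport %s vs %s (conjunction %d vertices)\n",
              object@taskPair[1], object@taskPair[2], object@conjunctionSize))
  print(object@table, row.names = FALSE)
})

setMethod("show", "SeriesReport", function(object) {
  cat(sprintf("SeriesReport: %d frames\n", nrow(object@frameMetrics)))
  for (nm in names(object@inference)) {
    inf <- object@inference[[nm]]
    cat(sprintf(
      "  [%s] mean rho %.3f, frames rho>0: %.2f, t = %.2f (p = %.3g), AR z = %.2f (p = %.3g)\n",
      nm, inf$mean_rho, inf$frac_positive, inf$t_stat, inf$t_p,
      inf$ar_z, inf$ar_p))
  }
})
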