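# Generics and accessors; slots are never reached into directly by users.

#' @rdname Volume3D-class
#' @param object,x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname Volume3D-class
#' @export
setMethod("voxels", "Volume3D", function(x) x@voxels)

#' @rdname Volume3D-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname Volume3D-class
#' @export
setMethod("voxelSpacing", "Volume3D", function(x) x@spacing)
#' @rdname SegmentationMask-class
#' @export
setMethod("voxelSpacing", "SegmentationMask", function(x) x@spacing)
#' @rdname Volume4D-class
#' @export
setMethod("voxelSpacing", "Volume4D", function(x) x@spacing)

#' @rdname Volume3D-class
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))
#' @rdname Volume3D-class
#' @export
setMethod("worldOrigin", "Volume3D", function(x) x@origin)
#' @rdname SegmentationMask-class
#' @export
setMethod("worldOrigin", "SegmentationMask", function(x) x@origin)
#' @rdname Volume4D-class
#' @export
setMethod("worldOrigin", "Volume4D", function(x) x@origin)

#' @rdname Volume4D-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname Volume4D-class
#' @export
setMethod("frames", "Volume4D", function(x) x@frames)
#' @rdname Volume4D-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname Volume4D-class
#' @export
setMethod("nFrames", "Volume4D", function(x) dim(x@frames)[4])

#' @rdname SegmentationMask-class
#' @export
setGeneric("labels3d", function(x) standardGeneric("labels3d"))
#' @rdname SegmentationMask-class
#' @export
setMethod("labels3d", "SegmentationMask", function(x) x@labels)
#' @rdname SegmentationMask-class
#' @export
setGeneric("labelSet", function(x) standardGeneric("labelSet"))
#' @rdname SegmentationMask-class
#' @export
setMethod("labelSet", "SegmentationMask", function(x) x@labelSet)

#' @rdname TriMesh-class
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname TriMesh-class
#' @export
setMethod("meshVertices", "TriMesh", function(x) x@vertices)
#' @rdname TriMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname TriMesh-class
#' @export
setMethod("meshFaces", "TriMesh", function(x) x@faces)

#' Number of radial planes of a geometry
#'
#' For an angular interval of \eqn{\Delta} degrees, \eqn{180/\Delta} planes
#' cover the full cylinder (each plane covers two opposite azimuths through
#' its signed radius coordinate): 18 planes at 10 degree intervals.
#'
#' @param x a \linkS4class{RadialGeometry} (or numeric angular interval via
#'   \code{\link{planeCount}}).
#' @return integer plane count.
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))
#' @rdname nPlanes
#' @export
setMethod("nPlanes", "RadialGeometry",
          function(x) as.integer(round(180 / x@angularInterval)))

#' @rdname RadialPlaneStack-class
#' @param x a RadialPlaneStack.
#' @export
setGeneric("stackGeometry", function(x) standardGeneric("stackGeometry"))
#' @rdname RadialPlaneStack-class
#' @export
setMethod("stackGeometry", "RadialPlaneStack", function(x) x@geometry)
#' @rdname RadialPlaneStack-class
#' @export
setGeneric("stackPlanes", function(x) standardGeneric("stackPlanes"))
#' @rdname RadialPlaneStack-class
#' @export
setMethod("stackPlanes", "RadialPlaneStack", function(x) x@planes)

#' @rdname UNetModel-class
#' @param x a UNetModel.
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))
#' @rdname UNetModel-class
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname UNetModel-class
#' @export
setMethod("trainingHistory", "UNetModel", function(x) x@history)
#' @rdname UNetModel-class
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))
#' @rdname UNetModel-class
#' @export
setMethod("modelConfigOf", "UNetModel", function(x) x@config)

#' @rdname MetricsReport-class
#' @param x a MetricsReport.
#' @export
setGeneric("perCaseMetrics", function(x) standardGeneric("perCaseMetrics"))
#' @rdname MetricsReport-class
#' @export
setMethod("perCaseMetrics", "MetricsReport", function(x) x@perCase)
#' @rdname MetricsReport-class
#' @export
setGeneric("aggregateMetrics", function(x) standardGeneric("aggregateMetrics"))
#' @rdname MetricsReport-class
#' @export
setMethod("aggregateMetrics", "MetricsReport", function(x) x@aggregate)

#' @rdname AgreementReport-class
#' @param x an AgreementReport.
#' @export
setGeneric("agreementBias", function(x) standardGeneric("agreementBias"))
#' @rdname AgreementReport-class
#' @export
setMethod("agreementBias", "AgreementReport", function(x) x@bias)
#' @rdname AgreementReport-class
#' @export
setGeneric("limitsOfAgreement",
           function(x) standardGeneric("limitsOfAgreement"))
#' @rdname AgreementReport-class
#' @export
setMethod("limitsOfAgreement", "AgreementReport",
          function(x) c(low = x@loaLow, high = x@loaHigh))
#' @rdname AgreementReport-class
#' @export
setGeneric("agreementRsq", function(x) standardGeneric("agreementRsq"))
#' @rdname AgreementReport-class
#' @export
setMethod("agreementRsq", "AgreementReport", function(x) x@rSquared)
#' @rdname AgreementReport-class
#' @export
setGeneric("agreementPairs", function(x) standardGeneric("agreementPairs"))
#' @rdname AgreementReport-class
#' @export
setMethod("agreementPairs", "AgreementReport", function(x) x@pairs)

# ---- show methods ------------------------------------------------------

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Volume3D: %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              paste(signif(object@origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "Volume4D", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Volume4D: %d frames of %d x %d x %d voxels, spacing %s mm\n",
              d[4], d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x ")))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@labels)
  tab <- table(object@labels)
  cat(sprintf("SegmentationMask: %d x %d x %d voxels, labels {%s}\n",
              d[1], d[2], d[3],
              paste(object@labelSet, collapse = ", ")))
  cat("  voxel counts:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "RadialGeometry", function(object) {
  cat(sprintf(
    "RadialGeometry: %d planes at %g deg, half-width %g mm, z [%g, %g] mm\n",
    nPlanes(object), object@angularInterval, object@planeHalfWidth,
    object@zRange[1], object@zRange[2]))
  cat(sprintf("  axis through (%g, %g) mm; context offset +/- %g mm; step %g mm\n",
              object@axisPoint[1], object@axisPoint[2], object@contextOffset,
              object@inPlaneSpacing))
})

setMethod("show", "RadialPlaneStack", function(object) {
  g <- object@geometry
  p1 <- object@planes[[1]]$center
  cat(sprintf("RadialPlaneStack: %d plane triples of %d x %d px (source: %s)\n",
              length(object@planes), nrow(p1@pixels), ncol(p1@pixels),
              object@sourceId))
})

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "UNetModel (%s): depth %d, base width %d, %s trainable parameters\n",
    cfg@modality, cfg@depth, cfg@baseWidth,
    format(nParameters(object), big.mark = ",")))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, best validation DSC %.4f\n",
                nrow(object@history), max(object@history$valMetric)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s): %d cases\n", object@modality,
              length(unique(object@perCase$caseId))))
  print(object@aggregate, digits = 3)
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf(
    "AgreementReport: bias %.2f cm^3, LoA [%.2f, %.2f], R^2 = %.3f (n = %d)\n",
    object@bias, object@loaLow, object@loaHigh, object@rSquared,
    nrow(object@pairs)))
})

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase %s: %.1f cm^3 (%s stratum)\n", object@caseId,
              object@trueVolume, object@stratum))
})
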