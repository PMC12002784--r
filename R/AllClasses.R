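# Central S4 data structures. Coordinate convention throughout: voxel
# indices are 0-based in formulas, world position = origin + index * spacing
# (node-centered); the cylinder/probe axis is the volume z axis; "anterior"
# is the -y direction (the probe sits posterior, at the rectum).

#' Volume3D: an axis-aligned 3D scalar image
#'
#' A voxel grid with physical spacing and origin in millimetres. World
#' position of voxel (i, j, k) (0-based) is \code{origin + c(i, j, k) *
#' spacing}.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacing numeric(3), per-axis voxel size in mm, all > 0.
#' @slot origin numeric(3), world position of voxel (0, 0, 0) in mm.
#' @export
setClass("Volume3D",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@voxels)
    if (length(d) != 3L) msg <- c(msg, "voxels must be a 3D array")
    else if (any(d < 2L)) msg <- c(msg, "grid dimensions must be >= 2 per axis")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values")
    if (length(msg)) msg else TRUE
  })

#' Construct a Volume3D
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric(3) voxel size in mm (default 1 mm isotropic).
#' @param origin numeric(3) world position of voxel (0,0,0) in mm.
#' @return A \linkS4class{Volume3D}.
#' @examples
#' v <- Volume3D(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 1))
#' @export
Volume3D <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume3D", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Volume4D: a time series of co-registered 3D volumes
#'
#' Used for 4D CEUS acquisitions; all frames share one grid.
#'
#' @slot frames 4D numeric array (x, y, z, t).
#' @slot spacing numeric(3) voxel size in mm.
#' @slot origin numeric(3) origin in mm.
#' @slot frameTimes optional acquisition timestamps in s (length = n frames,
#'   or length 0 when unknown).
#' @export
setClass("Volume4D",
  representation(frames = "array", spacing = "numeric", origin = "numeric",
                 frameTimes = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 4L) msg <- c(msg, "frames must be a 4D array (x,y,z,t)")
    else {
      if (d[4] < 1L) msg <- c(msg, "need >= 1 frame")
      if (length(object@frameTimes) &&
          length(object@frameTimes) != d[4])
        msg <- c(msg, "frameTimes length must equal the number of frames")
    }
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a Volume4D
#' @param frames 4D numeric array (x, y, z, t).
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) origin in mm.
#' @param frameTimes optional numeric timestamps in seconds.
#' @return A \linkS4class{Volume4D}.
#' @export
Volume4D <- function(frames, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     frameTimes = numeric()) {
  new("Volume4D", frames = frames, spacing = as.numeric(spacing),
      origin = as.numeric(origin), frameTimes = as.numeric(frameTimes))
}

#' SegmentationMask: an integer label volume aligned to a Volume3D
#'
#' Labels are either binary (0 = background, 1 = structure) or zonal
#' (0 = background, 1 = transition zone, 2 = peripheral zone).
#'
#' @slot labels 3D integer array.
#' @slot spacing numeric(3) voxel size in mm (inherited from the parent
#'   volume).
#' @slot origin numeric(3) origin in mm.
#' @slot labelSet integer vector of admissible label values.
#' @export
setClass("SegmentationMask",
  representation(labels = "array", spacing = "numeric", origin = "numeric",
                 labelSet = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (!all(unique(as.vector(object@labels)) %in% object@labelSet))
      msg <- c(msg, "labels contain values outside the declared label set")
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a SegmentationMask
#' @param labels 3D array of integer labels (logical arrays are coerced,
#'   TRUE -> 1).
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) origin in mm.
#' @param labelSet admissible label values (default \code{0:max(labels)}).
#' @return A \linkS4class{SegmentationMask}.
#' @export
SegmentationMask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             labelSet = NULL) {
  d <- dim(labels)
  lab <- array(as.integer(labels), dim = d)
  if (is.null(labelSet)) labelSet <- 0:max(lab, 0L)
  new("SegmentationMask", labels = lab, spacing = as.numeric(spacing),
      origin = as.numeric(origin), labelSet = as.integer(labelSet))
}

#' TriMesh: a triangle surface mesh in world coordinates
#'
#' @slot vertices n x 3 numeric matrix of points in mm.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
    f <- object@faces
    if (nrow(f)) {
      if (min(f) < 1L || max(f) > nrow(object@vertices))
        msg <- c(msg, "face indices out of range")
      if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
        msg <- c(msg, "degenerate faces (repeated vertex)")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a TriMesh
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @return A \linkS4class{TriMesh}.
#' @export
TriMesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  new("TriMesh", vertices = as.matrix(vertices), faces = as.matrix(faces))
}

#' RadialGeometry: the radial resampling frame
#'
#' Defines a fan of 2D planes containing the (z-aligned) cylinder axis.
#' Plane k (0-based) lies at azimuth \eqn{\theta_k = k \cdot} \code{angularInterval}
#' degrees; a plane point (s, z) maps to world
#' \eqn{(axis_x + s\cos\theta_k, axis_y + s\sin\theta_k, z)}. Each plane has
#' two parallel context planes offset \code{contextOffset} mm along its
#' normal.
#'
#' @slot axisPoint numeric(2), world xy-position the axis passes through (mm).
#' @slot angularInterval degrees between consecutive planes; must divide 180.
#' @slot planeHalfWidth max |s| sampled, mm.
#' @slot zRange numeric(2), axial extent (mm).
#' @slot inPlaneSpacing sampling step in mm.
#' @slot contextOffset distance of each context plane from the central plane
#'   (mm).
#' @export
setClass("RadialGeometry",
  representation(axisPoint = "numeric", angularInterval = "numeric",
                 planeHalfWidth = "numeric", zRange = "numeric",
                 inPlaneSpacing = "numeric", contextOffset = "numeric"),
  validity = function(object) {
    msg <- character()
    ai <- object@angularInterval
    if (length(ai) != 1L || ai <= 0 || ai > 180 ||
        abs(180 / ai - round(180 / ai)) > 1e-9)
      msg <- c(msg, "angularInterval must divide 180 exactly")
    if (object@inPlaneSpacing <= 0) msg <- c(msg, "inPlaneSpacing must be > 0")
    if (object@contextOffset < 0) msg <- c(msg, "contextOffset must be >= 0")
    if (length(object@zRange) != 2L || diff(object@zRange) <= 0)
      msg <- c(msg, "zRange must be increasing")
    if (object@planeHalfWidth <= 0) msg <- c(msg, "planeHalfWidth must be > 0")
    if (length(msg)) msg else TRUE
  })

#' PlaneImage: one resampled 2D radial plane
#'
#' Pixels are indexed by (s, z): rows are signed in-plane radius s (mm, the
#' s = 0 row is the cylinder axis), columns are axial position z (mm).
#'
#' @slot pixels ns x nz numeric matrix.
#' @slot s numeric(ns) signed radii (mm).
#' @slot z numeric(nz) axial positions (mm).
#' @export
setClass("PlaneImage",
  representation(pixels = "matrix", s = "numeric", z = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@pixels) != length(object@s) ||
        ncol(object@pixels) != length(object@z))
      msg <- c(msg, "pixel dimensions must match s/z coordinate vectors")
    if (!any(abs(object@s) < 1e-9))
      msg <- c(msg, "the s grid must contain s = 0 (the axis column)")
    if (length(msg)) msg else TRUE
  })

#' RadialPlaneStack: all radial planes of one volume
#'
#' @slot planes list of length nPlanes; element k+1 is a list with components
#'   \code{center}, \code{lower}, \code{upper} (\linkS4class{PlaneImage}s;
#'   lower/upper are the context planes at -/+ contextOffset).
#' @slot geometry the \linkS4class{RadialGeometry} used.
#' @slot sourceId provenance tag.
#' @export
setClass("RadialPlaneStack",
  representation(planes = "list", geometry = "RadialGeometry",
                 sourceId = "character"),
  validity = function(object) {
    n <- nPlanes(object@geometry)
    if (length(object@planes) != n)
      return(sprintf("expected %d planes, got %d", n, length(object@planes)))
    TRUE
  })

#' PlanePrediction: network output for one radial plane
#'
#' @slot prostateProb ns x nz probability map of the prostate.
#' @slot zoneProb ns x nz probability map of the transition zone.
#' @slot planeIndex 0-based plane index k.
#' @slot s,z plane pixel coordinates in mm.
#' @export
setClass("PlanePrediction",
  representation(prostateProb = "matrix", zoneProb = "matrix",
                 planeIndex = "integer", s = "numeric", z = "numeric"),
  validity = function(object) {
    p <- c(object@prostateProb, object@zoneProb)
    if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
    if (!identical(dim(object@prostateProb), dim(object@zoneProb)))
      return("the two channels must have identical dimensions")
    TRUE
  })

#' ModelConfig: architecture of the 2D segmentation network
#'
#' The network is an encoder-decoder with skip connections; the input has
#' three channels (central plane plus the two context planes) and the output
#' two sigmoid channels (prostate probability; transition-zone probability).
#'
#' @slot inChannels always 3.
#' @slot outChannels always 2.
#' @slot depth number of encoder levels (including the bottleneck).
#' @slot baseWidth feature channels at the first level.
#' @slot modality "bmode" or "ceus".
#' @export
setClass("ModelConfig",
  representation(inChannels = "integer", outChannels = "integer",
                 depth = "integer", baseWidth = "integer",
                 modality = "character"),
  validity = function(object) {
    msg <- character()
    if (object@inChannels != 3L) msg <- c(msg, "inChannels must be 3")
    if (object@outChannels != 2L) msg <- c(msg, "outChannels must be 2")
    if (object@depth < 2L) msg <- c(msg, "depth must be >= 2")
    if (object@baseWidth < 4L) msg <- c(msg, "baseWidth must be >= 4")
    if (!object@modality %in% c("bmode", "ceus"))
      msg <- c(msg, "modality must be 'bmode' or 'ceus'")
    if (length(msg)) msg else TRUE
  })

#' Construct a ModelConfig
#' @param modality "bmode" or "ceus".
#' @param depth encoder levels including the bottleneck (default 3).
#' @param baseWidth first-level feature count (default 8).
#' @return A \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(modality = c("bmode", "ceus"), depth = 3L,
                        baseWidth = 8L) {
  modality <- match.arg(modality)
  new("ModelConfig", inChannels = 3L, outChannels = 2L,
      depth = as.integer(depth), baseWidth = as.integer(baseWidth),
      modality = modality)
}

#' TrainConfig: training scheme
#'
#' Mirrors the study protocol: fivefold cross-validation, at most 60
#' iterations (epochs), early stopping after 10 iterations without
#' improvement of the validation metric (mean validation Dice).
#'
#' @slot nFolds folds for cross-validation (default 5).
#' @slot maxIterations epoch cap (default 60).
#' @slot patience epochs without improvement before stopping (default 10).
#' @slot learningRate Adam step size.
#' @slot batchSize gradient accumulation size.
#' @slot seed master seed for fold assignment, weight init and data order.
#' @export
setClass("TrainConfig",
  representation(nFolds = "integer", maxIterations = "integer",
                 patience = "integer", learningRate = "numeric",
                 batchSize = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
    if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
    if (object@patience < 1L) msg <- c(msg, "patience must be >= 1")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a TrainConfig
#' @param nFolds folds (default 5).
#' @param maxIterations epoch cap (default 60).
#' @param patience early-stopping patience in epochs (default 10).
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize gradient accumulation size (default 8).
#' @param seed master seed (default 1).
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(nFolds = 5L, maxIterations = 60L, patience = 10L,
                        learningRate = 1e-3, batchSize = 8L, seed = 1L) {
  new("TrainConfig", nFolds = as.integer(nFolds),
      maxIterations = as.integer(maxIterations),
      patience = as.integer(patience), learningRate = learningRate,
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' UNetModel: a trained (or freshly initialised) segmentation network
#'
#' @slot config the \linkS4class{ModelConfig}.
#' @slot weights list of layer weights.
#' @slot history data.frame of per-epoch loss / validation metric (empty
#'   before training).
#' @slot meta list of run metadata (plane grid dimensions seen in training,
#'   seeds, normalisation convention).
#' @export
setClass("UNetModel",
  representation(config = "ModelConfig", weights = "list",
                 history = "data.frame", meta = "list"))

#' MetricsReport: per-case and aggregated segmentation metrics
#'
#' Mirrors the structure of a modality x dimensionality (2D/3D) x structure
#' (prostate boundary / zones) table of IoU, DSC, RVD, MSD and HD with mean
#' and 95\% confidence intervals.
#'
#' @slot perCase data.frame with one row per case x dimension x structure and
#'   columns for each metric.
#' @slot aggregate data.frame of mean and 95\% CI per cell.
#' @slot modality modality tag.
#' @export
setClass("MetricsReport",
  representation(perCase = "data.frame", aggregate = "data.frame",
                 modality = "character"))

#' AgreementReport: Bland-Altman volume agreement summary
#'
#' @slot bias mean difference (series b - series a), cm^3.
#' @slot loaLow,loaHigh limits of agreement, bias -/+ 1.96 SD of differences.
#' @slot rSquared squared Pearson correlation of the two volume series.
#' @slot pairs data.frame of per-case volumes, differences and averages.
#' @export
setClass("AgreementReport",
  representation(bias = "numeric", loaLow = "numeric", loaHigh = "numeric",
                 rSquared = "numeric", pairs = "data.frame"),
  validity = function(object) {
    if (object@loaLow > object@bias || object@bias > object@loaHigh)
      return("limits of agreement must bracket the bias")
    TRUE
  })

#' PhantomSpec: parameters of one synthetic prostate phantom
#'
#' @slot semiAxes numeric(3) (a, b, c) of the base ellipsoid, mm.
#' @slot perturbationAmplitude relative radial surface perturbation (0-0.3).
#' @slot tzFraction target transition-zone / prostate volume ratio.
#' @slot bmodeParams list of B-mode rendering parameters.
#' @slot ceusParams list of CEUS rendering parameters.
#' @slot gridDim integer(3) voxel grid dimensions.
#' @slot gridSpacing numeric(3) voxel size, mm.
#' @slot seed random seed.
#' @export
setClass("PhantomSpec",
  representation(semiAxes = "numeric", perturbationAmplitude = "numeric",
                 tzFraction = "numeric", bmodeParams = "list",
                 ceusParams = "list", gridDim = "integer",
                 gridSpacing = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@semiAxes <= 0)) msg <- c(msg, "semiAxes must be positive")
    if (object@perturbationAmplitude < 0 || object@perturbationAmplitude > 0.3)
      msg <- c(msg, "perturbationAmplitude must be in [0, 0.3]")
    if (object@tzFraction < 0.2 || object@tzFraction > 0.7)
      msg <- c(msg, "tzFraction must be in [0.2, 0.7]")
    if (length(msg)) msg else TRUE
  })

#' PhantomCase: one synthetic case with images and exact ground truth
#'
#' @slot caseId identifier.
#' @slot bmode,ceus \linkS4class{Volume3D} renders.
#' @slot prostateMask,tzMask,pzMask \linkS4class{SegmentationMask}s; the
#'   peripheral zone is exactly prostate minus transition zone.
#' @slot trueVolume prostate volume from the mask, cm^3.
#' @slot stratum "small" (< 40 cm^3), "medium" (40-70) or "large" (> 70).
#' @export
setClass("PhantomCase",
  representation(caseId = "character", bmode = "Volume3D", ceus = "Volume3D",
                 prostateMask = "SegmentationMask",
                 tzMask = "SegmentationMask", pzMask = "SegmentationMask",
                 trueVolume = "numeric", stratum = "character"))
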