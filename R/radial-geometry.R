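# Radial resampling: 2D planes through the probe (z) axis. Plane k sits at
# azimuth theta_k = k * angularInterval degrees; its signed radius s covers
# theta_k (s > 0) and theta_k + 180 deg (s < 0), so 180/interval planes span
# the whole cylinder (18 planes at 10 degrees).

#' Number of radial planes for a given angular interval
#'
#' @param angularInterval degrees between consecutive planes; must divide
#'   180 exactly (e.g. 10 degrees gives 18 planes).
#' @return integer plane count, 180 / angularInterval.
#' @examples
#' planeCount(10)  # 18
#' @export
planeCount <- function(angularInterval) {
  if (!is.numeric(angularInterval) || length(angularInterval) != 1L ||
      angularInterval <= 0 || angularInterval > 180)
    stop("angularInterval must be a single value in (0, 180]")
  n <- 180 / angularInterval
  if (abs(n - round(n)) > 1e-9)
    stop("angularInterval must divide 180 exactly (got ", angularInterval, ")")
  as.integer(round(n))
}

#' Construct a RadialGeometry
#'
#' Defaults are derived from a volume when given: the axis passes through
#' the xy-centre of the grid, the axial range is the volume's z extent, and
#' the half-width reaches the nearer xy face.
#'
#' @param vol optional \linkS4class{Volume3D} supplying defaults.
#' @param angularInterval degrees between planes (default 10, i.e. 18
#'   planes).
#' @param axisPoint world xy the axis passes through (mm).
#' @param planeHalfWidth maximum |s| sampled (mm).
#' @param zRange numeric(2) axial extent (mm).
#' @param inPlaneSpacing sampling step (mm, default 0.5).
#' @param contextOffset distance of each parallel context plane from the
#'   central plane (mm, default 4; use 2 for the reading where 4 mm
#'   separates the two context planes from each other).
#' @return A \linkS4class{RadialGeometry}.
#' @export
radialGeometry <- function(vol = NULL, angularInterval = 10,
                           axisPoint = NULL, planeHalfWidth = NULL,
                           zRange = NULL, inPlaneSpacing = 0.5,
                           contextOffset = 4) {
  planeCount(angularInterval)  # validates divisibility
  if (!is.null(vol)) {
    stopifnot(is(vol, "Volume3D") || is(vol, "SegmentationMask"))
    d <- if (is(vol, "Volume3D")) dim(vol@voxels) else dim(vol@labels)
    sp <- vol@spacing
    org <- vol@origin
    ext <- (d - 1) * sp
    if (is.null(axisPoint)) axisPoint <- org[1:2] + ext[1:2] / 2
    if (is.null(planeHalfWidth)) planeHalfWidth <- min(ext[1:2]) / 2
    if (is.null(zRange)) zRange <- c(org[3], org[3] + ext[3])
  }
  if (is.null(axisPoint) || is.null(planeHalfWidth) || is.null(zRange))
    stop("axisPoint, planeHalfWidth and zRange are required without a volume")
  new("RadialGeometry", axisPoint = as.numeric(axisPoint),
      angularInterval = angularInterval,
      planeHalfWidth = as.numeric(planeHalfWidth),
      zRange = as.numeric(zRange), inPlaneSpacing = inPlaneSpacing,
      contextOffset = contextOffset)
}

# pixel coordinate vectors of the plane grid; s is symmetric about 0 so the
# axis column is always present
.planeGrid <- function(geom) {
  ns2 <- floor(geom@planeHalfWidth / geom@inPlaneSpacing + 1e-9)
  s <- seq(-ns2, ns2) * geom@inPlaneSpacing
  nz <- floor(diff(geom@zRange) / geom@inPlaneSpacing + 1e-9)
  z <- geom@zRange[1] + seq(0, nz) * geom@inPlaneSpacing
  list(s = s, z = z)
}

#' Map a plane point to world coordinates
#'
#' The inverse of radial sampling: plane k's point (s, z) lies at
#' \eqn{(axis_x + s\cos\theta_k, axis_y + s\sin\theta_k, z)} with
#' \eqn{\theta_k = k \cdot} angular interval.
#'
#' @param geom a \linkS4class{RadialGeometry}.
#' @param k 0-based plane index.
#' @param s signed in-plane radius (mm), vectorised.
#' @param z axial position (mm), vectorised.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
planePointToWorld <- function(geom, k, s, z) {
  .checkPlaneIndex(geom, k)
  th <- k * geom@angularInterval * pi / 180
  n <- max(length(s), length(z))
  s <- rep_len(s, n)
  z <- rep_len(z, n)
  cbind(x = geom@axisPoint[1] + s * cos(th),
        y = geom@axisPoint[2] + s * sin(th),
        z = z)
}

.checkPlaneIndex <- function(geom, k) {
  n <- nPlanes(geom)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 0 || k >= n)
    stop("plane index k must be an integer in [0, ", n - 1, "]")
}

# sample the volume on plane k shifted by `offset` mm along the plane normal
.samplePlane <- function(vol, geom, k, offset = 0) {
  g <- .planeGrid(geom)
  th <- k * geom@angularInterval * pi / 180
  nrm <- c(-sin(th), cos(th))
  sz <- expand.grid(s = g$s, z = g$z)
  pts <- cbind(geom@axisPoint[1] + sz$s * cos(th) + offset * nrm[1],
               geom@axisPoint[2] + sz$s * sin(th) + offset * nrm[2],
               sz$z)
  vals <- cpp_trilinear_sample(vol@voxels, dim(vol@voxels), vol@spacing,
                               vol@origin, pts)
  new("PlaneImage", pixels = matrix(vals, length(g$s), length(g$z)),
      s = g$s, z = g$z)
}

#' Extract one radial plane from a volume
#'
#' Samples the volume by trilinear interpolation on the plane at angle
#' \eqn{\theta_k} containing the cylinder axis. Samples falling outside the
#' volume use edge-replicate padding.
#'
#' @param vol a \linkS4class{Volume3D}.
#' @param geom a \linkS4class{RadialGeometry}.
#' @param k 0-based plane index in [0, nPlanes - 1].
#' @return A \linkS4class{PlaneImage}.
#' @export
extractPlane <- function(vol, geom, k) {
  stopifnot(is(vol, "Volume3D"))
  .checkPlaneIndex(geom, k)
  .samplePlane(vol, geom, k, 0)
}

#' Extract the two parallel context planes of radial plane k
#'
#' The context planes lie at -/+ \code{contextOffset} mm along plane k's
#' normal and share its (s, z) pixel grid; they give the network
#' out-of-plane context for consistency between neighbouring planes.
#'
#' @inheritParams extractPlane
#' @return list with \code{lower} (offset -contextOffset) and \code{upper}
#'   (+contextOffset) \linkS4class{PlaneImage}s.
#' @export
extractContext <- function(vol, geom, k) {
  stopifnot(is(vol, "Volume3D"))
  .checkPlaneIndex(geom, k)
  list(lower = .samplePlane(vol, geom, k, -geom@contextOffset),
       upper = .samplePlane(vol, geom, k, +geom@contextOffset))
}

#' Extract the full radial plane stack of a volume
#'
#' @inheritParams extractPlane
#' @param sourceId provenance tag stored with the stack.
#' @return A \linkS4class{RadialPlaneStack} with one (center, lower, upper)
#'   triple per plane, ordered by angle.
#' @export
extractStack <- function(vol, geom, sourceId = "volume") {
  stopifnot(is(vol, "Volume3D"))
  n <- nPlanes(geom)
  planes <- lapply(seq_len(n) - 1L, function(k) {
    ctx <- extractContext(vol, geom, k)
    list(center = extractPlane(vol, geom, k),
         lower = ctx$lower, upper = ctx$upper)
  })
  new("RadialPlaneStack", planes = planes, geometry = geom,
      sourceId = sourceId)
}

#' Slice a binary mask along radial plane k
#'
#' The mask is sampled trilinearly (fractional occupancy at the boundary)
#' and thresholded at 0.5, giving a deterministic binary plane mask.
#'
#' @param mask a \linkS4class{SegmentationMask} with labels {0, 1}.
#' @param geom a \linkS4class{RadialGeometry}.
#' @param k 0-based plane index.
#' @return ns x nz logical matrix.
#' @export
slicePlaneMask <- function(mask, geom, k) {
  stopifnot(is(mask, "SegmentationMask"))
  .checkPlaneIndex(geom, k)
  vol <- Volume3D(array(as.numeric(mask@labels > 0), dim(mask@labels)),
                  spacing = mask@spacing, origin = mask@origin)
  .samplePlane(vol, geom, k, 0)@pixels > 0.5
}
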