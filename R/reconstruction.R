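# Cylindrical reconstruction: per-voxel sampling of the two radial planes
# that angularly bracket the voxel, bilinear within each plane, linear blend
# in angle, threshold to binary. Interpolation happens in probability space
# before thresholding, which is what smooths the reconstructed boundary.

#' Construct a ReconstructionConfig
#'
#' @param dim integer(3) output grid dimensions.
#' @param spacing numeric(3) output voxel size (mm).
#' @param origin numeric(3) output grid origin (mm).
#' @param threshold probability threshold in (0, 1), default 0.5.
#' @param closingRadius optional morphological closing radius in voxels
#'   (0 = off, the default; no post-processing is assumed).
#' @return a list-based config used by \code{\link{reconstructMask}}.
#' @export
reconstructionConfig <- function(dim, spacing = c(1, 1, 1),
                                 origin = c(0, 0, 0), threshold = 0.5,
                                 closingRadius = 0) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  list(dim = as.integer(dim), spacing = as.numeric(spacing),
       origin = as.numeric(origin), threshold = threshold,
       closingRadius = closingRadius)
}

# continuous reconstruction of the probability field on the output grid
.reconstructProb <- function(planeImgs, geom, cfg) {
  n <- length(planeImgs)
  d <- cfg$dim
  x <- cfg$origin[1] + (seq_len(d[1]) - 1) * cfg$spacing[1]
  y <- cfg$origin[2] + (seq_len(d[2]) - 1) * cfg$spacing[2]
  z <- cfg$origin[3] + (seq_len(d[3]) - 1) * cfg$spacing[3]
  dx <- array(rep(x - geom@axisPoint[1], times = d[2] * d[3]), d)
  dy <- array(rep(rep(y - geom@axisPoint[2], each = d[1]), times = d[3]), d)
  zz <- array(rep(z, each = d[1] * d[2]), d)
  r <- sqrt(dx^2 + dy^2)
  alpha <- atan2(dy, dx)                  # (-pi, pi]
  alpha[alpha < 0] <- alpha[alpha < 0] + 2 * pi
  dTheta <- geom@angularInterval * pi / 180
  e <- alpha / dTheta                     # extended plane coordinate [0, 2n)
  n2 <- 2L * n
  e[e >= n2] <- e[e >= n2] - n2
  k0 <- floor(e)
  tfrac <- e - k0
  k1 <- (k0 + 1) %% n2
  g1 <- .planeGrid(geom)
  sampleExt <- function(q, rr, zzv) {
    # extended index q in [0, 2n): plane q mod n, sign + for q < n
    plane <- as.integer(q %% n)
    sgn <- ifelse(q < n, 1, -1)
    img <- planeImgs[[plane[1] + 1L]]
    cpp_bilinear_sample(img, g1$s[1], geom@inPlaneSpacing, g1$z[1],
                        geom@inPlaneSpacing, sgn * rr, zzv)
  }
  prob <- array(0, d)
  rv <- as.numeric(r)
  zv <- as.numeric(zz)
  inside <- rv <= geom@planeHalfWidth
  p0 <- numeric(length(rv))
  p1 <- numeric(length(rv))
  for (q in 0:(n2 - 1)) {
    sel0 <- which(inside & as.numeric(k0) == q)
    if (length(sel0))
      p0[sel0] <- sampleExt(rep(q, length(sel0)), rv[sel0], zv[sel0])
    sel1 <- which(inside & as.numeric(k1) == q)
    if (length(sel1))
      p1[sel1] <- sampleExt(rep(q, length(sel1)), rv[sel1], zv[sel1])
  }
  probv <- (1 - as.numeric(tfrac)) * p0 + as.numeric(tfrac) * p1
  probv[!inside] <- 0                     # beyond the sampled cylinder
  array(probv, d)
}

#' Reconstruct a 3D mask from per-plane predictions
#'
#' For every output voxel the cylindrical coordinates (r, theta, z) are
#' computed; the two planes angularly bracketing theta (wrap-aware; the
#' plane at angle theta_k covers theta_k + 180 degrees through negative s)
#' are sampled bilinearly, blended linearly in angle, and the blended
#' probability is thresholded.
#'
#' @param predictions list of \linkS4class{PlanePrediction} covering all
#'   planes of \code{geom}, or a list of plain probability matrices.
#' @param geom the \linkS4class{RadialGeometry} the predictions live in.
#' @param cfg a \code{\link{reconstructionConfig}}.
#' @param channel "prostate" or "zone".
#' @return A \linkS4class{SegmentationMask} on the configured grid.
#' @export
reconstructMask <- function(predictions, geom, cfg,
                            channel = c("prostate", "zone")) {
  channel <- match.arg(channel)
  n <- nPlanes(geom)
  if (length(predictions) != n)
    stop("need ", n, " plane predictions, got ", length(predictions))
  planeImgs <- lapply(predictions, function(p) {
    if (is(p, "PlanePrediction")) {
      if (channel == "prostate") p@prostateProb else p@zoneProb
    } else if (is.matrix(p)) p
    else stop("predictions must be PlanePrediction objects or matrices")
  })
  prob <- .reconstructProb(planeImgs, geom, cfg)
  lab <- prob > cfg$threshold
  if (cfg$closingRadius > 0) lab <- .closeMask(lab, cfg$closingRadius)
  SegmentationMask(lab, spacing = cfg$spacing, origin = cfg$origin,
                   labelSet = c(0L, 1L))
}

# morphological closing with a cubic structuring element of given radius
.closeMask <- function(lab, radius) {
  r <- as.integer(radius)
  dilate <- function(m) {
    out <- m
    for (ax in 1:3) for (s in c(-r:-1, 1:r)) {
      idx <- pmin(pmax(seq_len(dim(m)[ax]) + s, 1L), dim(m)[ax])
      out <- out | switch(ax, m[idx, , ], m[, idx, ], m[, , idx])
    }
    out
  }
  erode <- function(m) !dilate(!m)
  erode(dilate(lab))
}

#' Compose zonal masks from prostate and raw transition-zone predictions
#'
#' The transition zone is confined to the gland (tz = tzRaw intersect
#' prostate) and the peripheral zone is the remainder of the gland
#' (pz = prostate minus tz), so pz and tz always partition the prostate.
#'
#' @param prostate binary \linkS4class{SegmentationMask} of the gland.
#' @param tzRaw binary \linkS4class{SegmentationMask} of the raw
#'   transition-zone prediction (same grid).
#' @return list with \code{tz} and \code{pz} masks and a 3-label \code{zonal}
#'   mask (0 background, 1 TZ, 2 PZ).
#' @export
composeZones <- function(prostate, tzRaw) {
  stopifnot(is(prostate, "SegmentationMask"), is(tzRaw, "SegmentationMask"))
  if (!identical(dim(prostate@labels), dim(tzRaw@labels)) ||
      max(abs(prostate@spacing - tzRaw@spacing)) > 1e-9 ||
      max(abs(prostate@origin - tzRaw@origin)) > 1e-9)
    stop("prostate and transition-zone masks must share one grid")
  p <- prostate@labels > 0
  tz <- (tzRaw@labels > 0) & p
  pz <- p & !tz
  mk <- function(m) SegmentationMask(m, spacing = prostate@spacing,
                                     origin = prostate@origin,
                                     labelSet = c(0L, 1L))
  zonal <- array(0L, dim(p))
  zonal[tz] <- 1L
  zonal[pz] <- 2L
  list(tz = mk(tz), pz = mk(pz),
       zonal = SegmentationMask(zonal, spacing = prostate@spacing,
                                origin = prostate@origin,
                                labelSet = c(0L, 1L, 2L)))
}

#' Extract a triangulated surface from a binary mask
#'
#' The binary field is lightly smoothed (Gaussian, default 0.7 voxel) and
#' the 0.5 level set is triangulated by marching tetrahedra, yielding a
#' closed surface in world millimetres whose area and enclosed volume
#' approximate the underlying smooth shape rather than the voxel staircase.
#'
#' @param mask a non-empty binary \linkS4class{SegmentationMask}.
#' @param smoothSigma smoothing in voxel units before the level set.
#' @return A \linkS4class{TriMesh}.
#' @export
maskToMesh <- function(mask, smoothSigma = 0.7) {
  stopifnot(is(mask, "SegmentationMask"))
  m <- mask@labels > 0
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  # pad one background layer so surfaces touching the grid edge stay closed
  fp <- array(0, d + 2L)
  fp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(m)
  if (smoothSigma > 0)
    fp <- cpp_gauss_blur3(fp, dim(fp), rep(smoothSigma, 3))
  res <- cpp_marching_tets(fp, dim(fp), mask@spacing,
                           mask@origin - mask@spacing, 0.5)
  TriMesh(res$vertices, res$faces)
}

#' Mesh-enclosed volume and surface area
#'
#' Volume by the divergence theorem over the closed, consistently oriented
#' triangle surface; area as the sum of triangle areas.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @return \code{meshVolume}: enclosed volume in cm^3.
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2],
              p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3],
              p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(rowSums(p1 * cr)) / 6) / 1000   # mm^3 -> cm^3
}

#' @rdname meshVolume
#' @return \code{meshArea}: surface area in mm^2.
#' @export
meshArea <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Segment a volume end-to-end
#'
#' Runs the full pipeline: radial plane extraction (with context planes),
#' per-plane network inference, cylindrical reconstruction of both output
#' channels, and zonal composition.
#'
#' @param model a trained \linkS4class{UNetModel}.
#' @param vol the \linkS4class{Volume3D} to segment (B-mode or mean-intensity
#'   CEUS, matching the model's modality).
#' @param geom the \linkS4class{RadialGeometry} used in training.
#' @param cfg optional \code{\link{reconstructionConfig}}; defaults to the
#'   volume's own grid.
#' @return list with \code{prostate}, \code{tz}, \code{pz} and 3-label
#'   \code{zonal} \linkS4class{SegmentationMask}s.
#' @export
segmentVolume <- function(model, vol, geom, cfg = NULL) {
  stopifnot(is(vol, "Volume3D"))
  if (is.null(cfg))
    cfg <- reconstructionConfig(dim(vol@voxels), vol@spacing, vol@origin)
  preds <- predictStack(model, extractStack(vol, geom))
  prostate <- reconstructMask(preds, geom, cfg, "prostate")
  tzRaw <- reconstructMask(preds, geom, cfg, "zone")
  z <- composeZones(prostate, tzRaw)
  list(prostate = prostate, tz = z$tz, pz = z$pz, zonal = z$zonal)
}

#' Rasterise an analytic ellipsoid as a mask (geometry oracle helper)
#'
#' @param semiAxes numeric(3) semi-axes in mm.
#' @param dim integer(3) grid dimensions.
#' @param spacing numeric(3) voxel size in mm.
#' @param center world centre (defaults to the grid centre).
#' @param origin grid origin (default 0).
#' @return A binary \linkS4class{SegmentationMask}.
#' @export
rasterizeEllipsoid <- function(semiAxes, dim, spacing = c(1, 1, 1),
                               center = NULL, origin = c(0, 0, 0)) {
  d <- as.integer(dim)
  if (is.null(center)) center <- origin + (d - 1) * spacing / 2
  x <- origin[1] + (seq_len(d[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(d[2]) - 1) * spacing[2]
  z <- origin[3] + (seq_len(d[3]) - 1) * spacing[3]
  gx <- array(rep((x - center[1]) / semiAxes[1], times = d[2] * d[3]), d)
  gy <- array(rep(rep((y - center[2]) / semiAxes[2], each = d[1]),
                  times = d[3]), d)
  gz <- array(rep((z - center[3]) / semiAxes[3], each = d[1] * d[2]), d)
  SegmentationMask(gx^2 + gy^2 + gz^2 <= 1, spacing = spacing,
                   origin = origin, labelSet = c(0L, 1L))
}
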