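# Overlap and surface agreement metrics, 3D and per-plane 2D, with per-case
# aggregation (mean and 95% Student-t confidence interval). Surfaces are the
# centres of foreground voxels with at least one six-connected background
# neighbour; MSD averages the two directed mean nearest-neighbour distances,
# HD is the exact symmetric Hausdorff maximum ("worst-case agreement").

.asBinary <- function(x) {
  if (is(x, "SegmentationMask")) x@labels > 0
  else if (is.logical(x) || is.numeric(x)) x > 0
  else stop("expected a SegmentationMask or logical array")
}

.checkSameGrid <- function(a, b) {
  da <- if (is(a, "SegmentationMask")) dim(a@labels) else dim(a)
  db <- if (is(b, "SegmentationMask")) dim(b@labels) else dim(b)
  if (!identical(da, db)) stop("masks are not on the same grid")
  if (is(a, "SegmentationMask") && is(b, "SegmentationMask")) {
    if (max(abs(a@spacing - b@spacing)) > 1e-9 ||
        max(abs(a@origin - b@origin)) > 1e-9)
      stop("masks are not on the same grid (spacing/origin differ)")
  }
  invisible(TRUE)
}

#' Dice similarity coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 1 for two empty masks (perfect trivial
#' agreement), 0 for disjoint masks.
#'
#' @param a,b masks on the same grid (\linkS4class{SegmentationMask},
#'   logical array or matrix; nonzero = foreground).
#' @return value in [0, 1].
#' @export
dice <- function(a, b) {
  .checkSameGrid(a, b)
  A <- .asBinary(a)
  B <- .asBinary(b)
  sa <- sum(A)
  sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Intersection over union (Jaccard index)
#'
#' \eqn{|A \cap B| / |A \cup B|}; related to Dice by IoU = DSC / (2 - DSC).
#'
#' @inheritParams dice
#' @return value in [0, 1].
#' @export
iou <- function(a, b) {
  .checkSameGrid(a, b)
  A <- .asBinary(a)
  B <- .asBinary(b)
  u <- sum(A | B)
  if (u == 0) return(1)
  sum(A & B) / u
}

#' Relative volume difference
#'
#' \eqn{(V_{auto} - V_{ref}) / V_{ref} \times 100}: positive when the
#' automated mask over-segments the reference.
#'
#' @param auto automated mask.
#' @param manual reference (manual) mask, non-empty, same grid.
#' @return signed percentage.
#' @export
rvd <- function(auto, manual) {
  .checkSameGrid(auto, manual)
  A <- .asBinary(auto)
  M <- .asBinary(manual)
  if (sum(M) == 0) stop("reference mask is empty")
  (sum(A) - sum(M)) / sum(M) * 100
}

#' Mean surface distance and Hausdorff distance
#'
#' Surface point sets are the world-coordinate centres of boundary voxels
#' (six-connectivity). MSD is the symmetric average of the two directed mean
#' nearest-neighbour distances; HD the maximum of the two directed Hausdorff
#' distances.
#'
#' @param a,b non-empty masks on the same grid.
#' @param spacing,origin used when plain arrays are given.
#' @return named numeric: \code{msd} and \code{hd}, in mm.
#' @export
surfaceDistances <- function(a, b, spacing = c(1, 1, 1),
                             origin = c(0, 0, 0)) {
  .checkSameGrid(a, b)
  if (is(a, "SegmentationMask")) {
    spacing <- a@spacing
    origin <- a@origin
  }
  A <- .asBinary(a)
  B <- .asBinary(b)
  if (!sum(A) || !sum(B)) stop("surface distances need two non-empty masks")
  dimA <- dim(A)
  if (length(dimA) == 2L) {               # 2D planes: treat as single slice
    dimA <- c(dimA, 1L)
    spacing <- c(spacing[1:2], 1)
    origin <- c(origin[1:2], 0)
  }
  pa <- cpp_surface_points(array(as.integer(A), dimA), dimA, spacing, origin)
  pb <- cpp_surface_points(array(as.integer(B), dimA), dimA, spacing, origin)
  dab <- cpp_nn_dists(pa, pb)
  dba <- cpp_nn_dists(pb, pa)
  c(msd = (mean(dab) + mean(dba)) / 2, hd = max(max(dab), max(dba)))
}

#' All five metrics for one mask pair
#'
#' @inheritParams rvd
#' @return named numeric: iou, dsc, rvd, msd, hd.
#' @export
maskMetrics <- function(auto, manual) {
  sd <- surfaceDistances(auto, manual)
  c(iou = iou(auto, manual), dsc = dice(auto, manual),
    rvd = rvd(auto, manual), msd = sd[["msd"]], hd = sd[["hd"]])
}

#' Per-plane (2D) metrics averaged over the planes of a case
#'
#' Each metric is computed per plane with its 2D analogue (pixel sets;
#' boundary pixel curves with 4-connectivity) and then averaged over planes,
#' mirroring reporting of 2D results as the mean over all planes of a case.
#'
#' @param predPlanes,truthPlanes lists of binary matrices of equal length
#'   and dimensions.
#' @param pixelSpacing numeric(2) pixel size in mm.
#' @return named numeric: mean iou, dsc, rvd, msd, hd across planes; surface
#'   metrics average over the planes where both masks are non-empty.
#' @export
perPlaneMetrics <- function(predPlanes, truthPlanes,
                            pixelSpacing = c(0.5, 0.5)) {
  if (length(predPlanes) != length(truthPlanes))
    stop("plane count mismatch")
  vals <- lapply(seq_along(predPlanes), function(i) {
    p <- predPlanes[[i]] > 0
    t <- truthPlanes[[i]] > 0
    sdv <- if (sum(p) && sum(t))
      surfaceDistances(p, t, spacing = pixelSpacing) else c(msd = NA, hd = NA)
    c(iou = iou(p, t), dsc = dice(p, t),
      rvd = if (sum(t)) (sum(p) - sum(t)) / sum(t) * 100 else NA,
      msd = sdv[["msd"]], hd = sdv[["hd"]])
  })
  m <- do.call(rbind, vals)
  colMeans(m, na.rm = TRUE)
}

#' Mean with 95\% confidence interval over cases
#'
#' Student-t interval for the mean of per-case values, the default reading
#' of a "mean (95\% CI)" table cell.
#'
#' @param values per-case metric values.
#' @return named numeric: mean, ciLow, ciHigh. With fewer than 2 values the
#'   mean is returned and the interval is NA (undefined).
#' @export
meanCI <- function(values) {
  values <- values[is.finite(values)]
  m <- mean(values)
  if (length(values) < 2)
    return(c(mean = m, ciLow = NA_real_, ciHigh = NA_real_))
  se <- sd(values) / sqrt(length(values))
  tq <- qt(0.975, df = length(values) - 1)
  c(mean = m, ciLow = m - tq * se, ciHigh = m + tq * se)
}

#' Assemble a MetricsReport from per-case rows
#'
#' @param perCase data.frame with columns caseId, dimension ("2D"/"3D"),
#'   structure ("prostate"/"zones"), iou, dsc, rvd, msd, hd.
#' @param modality modality tag ("bmode" or "ceus").
#' @return A \linkS4class{MetricsReport} whose aggregate table carries mean
#'   and 95\% CI per dimension x structure x metric cell.
#' @export
metricsReport <- function(perCase, modality = "bmode") {
  needed <- c("caseId", "dimension", "structure",
              "iou", "dsc", "rvd", "msd", "hd")
  stopifnot(all(needed %in% names(perCase)))
  cells <- unique(perCase[, c("dimension", "structure")])
  agg <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- perCase$dimension == cells$dimension[i] &
      perCase$structure == cells$structure[i]
    do.call(rbind, lapply(c("iou", "dsc", "rvd", "msd", "hd"), function(mt) {
      ci <- meanCI(perCase[sel, mt])
      data.frame(dimension = cells$dimension[i],
                 structure = cells$structure[i], metric = mt,
                 mean = ci[["mean"]], ciLow = ci[["ciLow"]],
                 ciHigh = ci[["ciHigh"]])
    }))
  }))
  rownames(agg) <- NULL
  new("MetricsReport", perCase = perCase, aggregate = agg,
      modality = modality)
}

#' Evaluate predicted vs ground-truth segmentations for a cohort
#'
#' Computes the full 2D (per-plane mean) and 3D metric set per case for the
#' prostate and for the zonal masks, and aggregates them into a table of
#' means with 95\% confidence intervals. The zonal row reports the mean of
#' the transition-zone and peripheral-zone values per metric.
#'
#' @param predicted list per case: list(prostate=, tz=, pz= masks,
#'   planeProstate=, planeTz= lists of binary matrices).
#' @param truth list per case with the same components for the ground truth.
#' @param modality tag for the report.
#' @param pixelSpacing in-plane pixel size (mm) for 2D surface metrics.
#' @return A \linkS4class{MetricsReport}.
#' @export
evaluateCohort <- function(predicted, truth, modality = "bmode",
                           pixelSpacing = c(0.5, 0.5)) {
  stopifnot(length(predicted) == length(truth))
  ids <- names(predicted)
  if (is.null(ids)) ids <- sprintf("case%03d", seq_along(predicted))
  rows <- list()
  for (i in seq_along(predicted)) {
    pr <- predicted[[i]]
    tr <- truth[[i]]
    m3p <- maskMetrics(pr$prostate, tr$prostate)
    m3t <- maskMetrics(pr$tz, tr$tz)
    m3z <- maskMetrics(pr$pz, tr$pz)
    rows[[length(rows) + 1]] <- data.frame(
      caseId = ids[i], dimension = "3D", structure = "prostate",
      t(m3p))
    rows[[length(rows) + 1]] <- data.frame(
      caseId = ids[i], dimension = "3D", structure = "zones",
      t((m3t + m3z) / 2))
    if (!is.null(pr$planeProstate)) {
      m2p <- perPlaneMetrics(pr$planeProstate, tr$planeProstate,
                             pixelSpacing)
      m2t <- perPlaneMetrics(pr$planeTz, tr$planeTz, pixelSpacing)
      rows[[length(rows) + 1]] <- data.frame(
        caseId = ids[i], dimension = "2D", structure = "prostate", t(m2p))
      rows[[length(rows) + 1]] <- data.frame(
        caseId = ids[i], dimension = "2D", structure = "zones", t(m2t))
    }
  }
  metricsReport(do.call(rbind, rows), modality = modality)
}
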