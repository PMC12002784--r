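# Prostate volume agreement: mask-derived volumes, the ellipsoid formula
# used for MRI triaxial measurements, PSA density, Bland-Altman bias and
# limits of agreement, and the squared Pearson correlation.

#' Volume of a binary mask in cm^3
#'
#' Foreground voxel count times the voxel volume (mm^3), converted to cm^3.
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @return volume in cm^3 (0 for an empty mask).
#' @export
maskVolume <- function(mask) {
  stopifnot(is(mask, "SegmentationMask"))
  sum(mask@labels > 0) * prod(mask@spacing) / 1000
}

#' Prostate volume by the ellipsoid formula
#'
#' \eqn{V = (\pi/6) \cdot L \cdot W \cdot H}, the standard approximation
#' from three orthogonal diameters measured on MRI.
#'
#' @param length,width,height orthogonal diameters in cm.
#' @return volume in cm^3.
#' @examples
#' ellipsoidVolume(2, 2, 2)  # pi * 8 / 6
#' @export
ellipsoidVolume <- function(length, width, height) {
  if (any(c(length, width, height) < 0))
    stop("dimensions must be non-negative")
  pi / 6 * length * width * height
}

#' PSA density
#'
#' Serum PSA divided by prostate volume, the standard risk-stratification
#' quantity.
#'
#' @param psa serum PSA in ng/ml.
#' @param volume prostate volume in cm^3, > 0.
#' @return PSA density in ng/ml/cm^3.
#' @export
psaDensity <- function(psa, volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  psa / volume
}

#' Bland-Altman agreement between two volume series
#'
#' Differences are taken as \code{volumeB - volumeA} (e.g. MRI-derived minus
#' automated, so that a larger MRI volume gives a positive bias); limits of
#' agreement are bias +/- 1.96 times the sample SD of the differences.
#'
#' @param pairs data.frame with columns \code{volumeA} and \code{volumeB}
#'   (cm^3) and optionally \code{caseId} and \code{psa} (ng/ml).
#' @return An \linkS4class{AgreementReport}.
#' @export
blandAltman <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("volumeA", "volumeB") %in%
                                        names(pairs)))
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  if (any(pairs$volumeA <= 0 | pairs$volumeB <= 0))
    stop("volumes must be positive")
  d <- pairs$volumeB - pairs$volumeA
  m <- (pairs$volumeA + pairs$volumeB) / 2
  bias <- mean(d)
  s <- sd(d)
  rsq <- if (sd(pairs$volumeA) > 0 && sd(pairs$volumeB) > 0)
    cor(pairs$volumeA, pairs$volumeB)^2 else NA_real_
  df <- data.frame(caseId = pairs$caseId %||% seq_len(nrow(pairs)),
                   volumeA = pairs$volumeA, volumeB = pairs$volumeB,
                   difference = d, average = m)
  if (!is.null(pairs$psa)) {
    df$psadA <- pairs$psa / pairs$volumeA
    df$psadB <- pairs$psa / pairs$volumeB
  }
  new("AgreementReport", bias = bias, loaLow = bias - 1.96 * s,
      loaHigh = bias + 1.96 * s, rSquared = rsq, pairs = df)
}

#' Squared Pearson correlation of two paired volume series
#'
#' @inheritParams blandAltman
#' @return R^2 in [0, 1].
#' @export
rSquared <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("volumeA", "volumeB") %in%
                                        names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (sd(pairs$volumeA) == 0 || sd(pairs$volumeB) == 0)
    stop("zero variance in a volume series")
  cor(pairs$volumeA, pairs$volumeB)^2
}

#' Assign clinical volume strata
#'
#' Small (< 40 cm^3), medium (40-70 cm^3, inclusive at both cut-offs) and
#' large (> 70 cm^3).
#'
#' @param volumes prostate volumes in cm^3.
#' @return character vector of "small" / "medium" / "large".
#' @examples
#' stratifyByVolume(c(39.9, 40, 70, 70.1))
#' @export
stratifyByVolume <- function(volumes) {
  if (!length(volumes)) return(character())
  if (any(volumes <= 0)) stop("volumes must be positive")
  ifelse(volumes < 40, "small", ifelse(volumes <= 70, "medium", "large"))
}
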