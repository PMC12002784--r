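# Synthetic prostate phantoms: star-convex glands (ellipsoid radius times a
# smooth low-order angular perturbation) with an inner transition zone
# anchored antero-basally, rendered as B-mode (bright boundary rim,
# multiplicative speckle) and mean-intensity CEUS (zone contrast, anterior
# signal suppression, optional slab motion jitter). Ground truth is exact by
# construction. Anterior is -y (the probe sits posterior).

#' Construct a PhantomSpec
#'
#' Defaults describe a mid-size gland on a 64^3 grid at 1.5 mm spacing; see
#' the package vignette for the rationale behind the appearance parameters.
#'
#' @param semiAxes numeric(3) base ellipsoid semi-axes (a, b, c) in mm.
#' @param perturbationAmplitude bound on the relative radial surface
#'   perturbation (0-0.3; default 0.08).
#' @param tzFraction target transition-zone / prostate volume ratio
#'   (default 0.4); achieved within a few percent by bisection.
#' @param bmodeParams list: \code{background}, \code{pz}, \code{tz},
#'   \code{rim} intensity levels, \code{rimWidth} (mm), \code{speckle}
#'   (multiplicative noise strength), \code{blurSigma} (mm).
#' @param ceusParams list: \code{background}, \code{tz}, \code{pz}
#'   enhancement levels, \code{suppression} (anterior suppression strength,
#'   0-1), \code{noise}, \code{blurSigma} (mm), \code{motionJitter} (mm).
#' @param gridDim integer(3) grid dimensions (default 64^3).
#' @param gridSpacing numeric(3) voxel size in mm (default 1.5 mm).
#' @param seed random seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(semiAxes = c(20, 25, 30),
                        perturbationAmplitude = 0.08,
                        tzFraction = 0.4,
                        bmodeParams = list(),
                        ceusParams = list(),
                        gridDim = c(64L, 64L, 64L),
                        gridSpacing = c(1.5, 1.5, 1.5),
                        seed = 1L) {
  bm <- modifyList(list(background = 0.35, pz = 0.57, tz = 0.44, rim = 0.92,
                        rimWidth = 1.2, speckle = 0.25, blurSigma = 0.8),
                   bmodeParams)
  ce <- modifyList(list(background = 0.12, tz = 0.85, pz = 0.42,
                        suppression = 0.45, noise = 0.15, blurSigma = 0.8,
                        motionJitter = 0.5),
                   ceusParams)
  new("PhantomSpec", semiAxes = as.numeric(semiAxes),
      perturbationAmplitude = perturbationAmplitude,
      tzFraction = tzFraction, bmodeParams = bm, ceusParams = ce,
      gridDim = as.integer(gridDim), gridSpacing = as.numeric(gridSpacing),
      seed = as.integer(seed))
}

# evaluate expr with a temporary RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# smooth low-order angular perturbation: bounded combination of quadratic /
# cubic harmonics of the direction cosines; |value| <= amplitude everywhere
.randomPerturbation <- function(amplitude) {
  coef <- rnorm(8)
  bound <- c(0.5, 0.5, 0.5, 1, 2, 0.2, 1, 2)  # sup of each basis on the sphere
  scale <- if (amplitude > 0 && sum(abs(coef) * bound) > 0)
    amplitude / sum(abs(coef) * bound) else 0
  coef <- coef * scale
  function(ux, uy, uz) {
    coef[1] * ux * uy + coef[2] * uy * uz + coef[3] * uz * ux +
      coef[4] * (ux^2 - uy^2) + coef[5] * (2 * uz^2 - ux^2 - uy^2) +
      coef[6] * ux * uy * uz + coef[7] * ux * (ux^2 - 3 * uy^2) +
      coef[8] * uz * (2 * uz^2 - 3 * ux^2 - 3 * uy^2)
  }
}

# star-convex boundary radius along unit directions for an ellipsoid with
# perturbation
.starRadius <- function(ux, uy, uz, semiAxes, pert) {
  base <- 1 / sqrt((ux / semiAxes[1])^2 + (uy / semiAxes[2])^2 +
                     (uz / semiAxes[3])^2)
  base * (1 + pert(ux, uy, uz))
}

#' Sample a phantom gland shape with exact zonal ground truth
#'
#' The prostate is a star-convex region (ellipsoid radius modulated by a
#' smooth seeded perturbation); the transition zone is an inner star-convex
#' region anchored toward the anterior-basal aspect, scaled by bisection to
#' hit the target volume fraction within 5\%; the peripheral zone is exactly
#' the set difference.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{prostate}, \code{tz}, \code{pz}
#'   (\linkS4class{SegmentationMask}s) and a \code{shape} element with the
#'   per-voxel radius fields used by the renderers.
#' @export
sampleShape <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  .withSeed(spec@seed, {
    d <- spec@gridDim
    sp <- spec@gridSpacing
    org <- c(0, 0, 0)
    ctr <- org + (d - 1) * sp / 2
    if (any(spec@semiAxes * (1 + spec@perturbationAmplitude) >
            (d - 1) * sp / 2))
      stop("gland does not fit in the grid: enlarge the grid or shrink ",
           "the semi-axes")
    x <- org[1] + (seq_len(d[1]) - 1) * sp[1]
    y <- org[2] + (seq_len(d[2]) - 1) * sp[2]
    z <- org[3] + (seq_len(d[3]) - 1) * sp[3]
    gx <- array(rep(x - ctr[1], times = d[2] * d[3]), d)
    gy <- array(rep(rep(y - ctr[2], each = d[1]), times = d[3]), d)
    gz <- array(rep(z - ctr[3], each = d[1] * d[2]), d)
    r <- sqrt(gx^2 + gy^2 + gz^2)
    r0 <- pmax(r, 1e-9)
    ux <- gx / r0; uy <- gy / r0; uz <- gz / r0

    pertP <- .randomPerturbation(spec@perturbationAmplitude)
    Rp <- .starRadius(ux, uy, uz, spec@semiAxes, pertP)
    prostate <- r <= Rp

    # transition zone: anchored anterior (-y) and basal (+z)
    tzCtr <- c(0, -0.18 * spec@semiAxes[2], 0.15 * spec@semiAxes[3])
    tx <- gx - tzCtr[1]; ty <- gy - tzCtr[2]; tzz <- gz - tzCtr[3]
    rt <- sqrt(tx^2 + ty^2 + tzz^2)
    rt0 <- pmax(rt, 1e-9)
    vx <- tx / rt0; vy <- ty / rt0; vz <- tzz / rt0
    pertT <- .randomPerturbation(spec@perturbationAmplitude / 2)
    tzAxes <- spec@semiAxes * c(0.95, 0.85, 0.80)
    Rt1 <- .starRadius(vx, vy, vz, tzAxes, pertT)
    nProstate <- sum(prostate)
    # keep the TZ strictly interior: a peripheral shell of >= 15% of the
    # boundary radius always separates it from the capsule
    interior <- r <= 0.85 * Rp
    tzAt <- function(s) (rt <= s * Rt1) & interior
    frac <- function(s) sum(tzAt(s)) / nProstate
    lo <- 0.15; hi <- 1.5
    if (frac(hi) < spec@tzFraction)
      stop("tzFraction unreachable for this shape")
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (frac(mid) < spec@tzFraction) lo <- mid else hi <- mid
      if (abs(frac(mid) / spec@tzFraction - 1) < 0.02) { lo <- hi <- mid; break }
    }
    tz <- tzAt((lo + hi) / 2)
    pz <- prostate & !tz

    mk <- function(m) SegmentationMask(m, spacing = sp, origin = org,
                                       labelSet = c(0L, 1L))
    list(prostate = mk(prostate), tz = mk(tz), pz = mk(pz),
         shape = list(r = r, boundaryRadius = Rp, gy = gy,
                      center = ctr, grid = list(dim = d, spacing = sp,
                                                origin = org)))
  })
}

# multiplicative unit-mean speckle: gamma multiplier, positive skew
.speckle <- function(dim, strength) {
  if (strength <= 0) return(array(1, dim))
  k <- 1 / strength^2
  array(rgamma(prod(dim), shape = k, rate = k), dim)
}

#' Render the B-mode appearance of a phantom
#'
#' Piecewise base intensities per tissue class, a bright rim band at the
#' gland boundary (the prostate boundary is most distinct on B-mode),
#' multiplicative unit-mean speckle, and Gaussian blur. Deterministic under
#' the spec seed.
#'
#' @param shape output of \code{\link{sampleShape}}.
#' @param spec the \linkS4class{PhantomSpec} used to build \code{shape}.
#' @return A \linkS4class{Volume3D}.
#' @export
renderBmode <- function(shape, spec) {
  p <- spec@bmodeParams
  d <- spec@gridDim
  tz <- shape$tz@labels > 0
  pz <- shape$pz@labels > 0
  img <- array(p$background, d)
  img[pz] <- p$pz
  img[tz] <- p$tz
  rim <- abs(shape$shape$r - shape$shape$boundaryRadius) <= p$rimWidth
  img[rim] <- p$rim
  .withSeed(spec@seed + 1000003L, {
    img <- img * .speckle(d, p$speckle)
  })
  if (p$blurSigma > 0)
    img <- cpp_gauss_blur3(img, d, p$blurSigma / spec@gridSpacing)
  Volume3D(array(img, d), spacing = spec@gridSpacing, origin = c(0, 0, 0))
}

#' Render the mean-intensity CEUS appearance of a phantom
#'
#' The zones carry distinct enhancement levels (zonal contrast is higher
#' than on B-mode), an anterior-to-posterior multiplicative suppression
#' gradient emulates tissue suppression away from the probe, and optional
#' slab-wise lateral jitter emulates patient motion over the ~2 min
#' acquisition. Deterministic under the spec seed.
#'
#' @inheritParams renderBmode
#' @return A \linkS4class{Volume3D}.
#' @export
renderCeus <- function(shape, spec) {
  p <- spec@ceusParams
  d <- spec@gridDim
  tz <- shape$tz@labels > 0
  pz <- shape$pz@labels > 0
  img <- array(p$background, d)
  img[pz] <- p$pz
  img[tz] <- p$tz
  # anterior (-y) suppression: multiplier rises from (1 - strength) at the
  # anterior face to 1 at the posterior face
  if (p$suppression > 0) {
    gy <- shape$shape$gy
    yhat <- (gy - min(gy)) / (max(gy) - min(gy))
    img <- img * (1 - p$suppression * (1 - yhat))
  }
  .withSeed(spec@seed + 2000003L, {
    img <- img * .speckle(d, p$noise)
    if (p$motionJitter > 0) {
      slab <- 8L
      nSlab <- ceiling(d[3] / slab)
      shifts <- round(rnorm(nSlab, 0, p$motionJitter) / spec@gridSpacing[1])
      for (si in seq_len(nSlab)) {
        if (shifts[si] == 0) next
        zIdx <- ((si - 1) * slab + 1):min(si * slab, d[3])
        src <- pmin(pmax(seq_len(d[1]) - shifts[si], 1L), d[1])
        img[, , zIdx] <- img[src, , zIdx]
      }
    }
  })
  if (p$blurSigma > 0)
    img <- cpp_gauss_blur3(img, d, p$blurSigma / spec@gridSpacing)
  Volume3D(array(img, d), spacing = spec@gridSpacing, origin = c(0, 0, 0))
}

#' Generate one complete phantom case
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param caseId identifier string.
#' @return A \linkS4class{PhantomCase} with both modality renders, the three
#'   ground-truth masks, the mask-derived volume and its stratum.
#' @export
generatePhantom <- function(spec, caseId = "case") {
  shape <- sampleShape(spec)
  vol <- maskVolume(shape$prostate)
  new("PhantomCase", caseId = caseId,
      bmode = renderBmode(shape, spec),
      ceus = renderCeus(shape, spec),
      prostateMask = shape$prostate, tzMask = shape$tz, pzMask = shape$pz,
      trueVolume = vol, stratum = stratifyByVolume(vol))
}

#' Generate a phantom cohort across volume strata
#'
#' Strata follow the clinical cut-offs: small (< 40 cm^3), medium (40-70
#' cm^3), large (> 70 cm^3). Counts per stratum follow the requested
#' proportions with largest-remainder rounding; the default equal thirds on
#' n = 51 give 17 cases per stratum. Target volumes are drawn uniformly
#' within each stratum (with a margin to the cut-offs so that mask
#' digitisation cannot flip a stratum) and the semi-axes are solved from the
#' target volume with mildly randomised axis ratios.
#'
#' @param n number of cases.
#' @param strataProportions numeric(3) proportions (small, medium, large);
#'   must sum to 1.
#' @param specTemplate \linkS4class{PhantomSpec} supplying grid and
#'   appearance parameters.
#' @param seed master seed; the cohort is a pure function of
#'   (n, proportions, template, seed).
#' @return list of \linkS4class{PhantomCase}.
#' @export
generateCohort <- function(n, strataProportions = c(1, 1, 1) / 3,
                           specTemplate = phantomSpec(), seed = 1L) {
  stopifnot(n >= 1)
  if (abs(sum(strataProportions) - 1) > 1e-9)
    stop("strata proportions must sum to 1")
  counts <- .largestRemainder(n, strataProportions)
  strata <- rep(c("small", "medium", "large"), counts)
  ranges <- list(small = c(22, 38), medium = c(43, 67), large = c(73, 92))
  .withSeed(seed, {
    caseSeeds <- sample.int(2^31 - 2, n)
    targets <- vapply(strata, function(s) runif(1, ranges[[s]][1],
                                                ranges[[s]][2]), 0)
    ratios <- cbind(runif(n, 0.75, 0.9), 1, runif(n, 1.05, 1.25))
    tzf <- runif(n, 0.30, 0.50)
  })
  lapply(seq_len(n), function(i) {
    abc <- targets[i] * 1000 * 3 / (4 * pi)            # product of semi-axes
    b <- (abc / (ratios[i, 1] * ratios[i, 3]))^(1 / 3)
    spec <- phantomSpec(semiAxes = b * ratios[i, ],
                        perturbationAmplitude =
                          specTemplate@perturbationAmplitude,
                        tzFraction = tzf[i],
                        bmodeParams = specTemplate@bmodeParams,
                        ceusParams = specTemplate@ceusParams,
                        gridDim = specTemplate@gridDim,
                        gridSpacing = specTemplate@gridSpacing,
                        seed = caseSeeds[i])
    cs <- generatePhantom(spec, caseId = sprintf("phantom%03d", i))
    if (cs@stratum != strata[i])
      stop("case ", i, " landed outside its assigned stratum")
    cs
  })
}

.largestRemainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order <- order(raw - base, decreasing = TRUE)
    base[order[seq_len(rem)]] <- base[order[seq_len(rem)]] + 1
  }
  as.integer(base)
}
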