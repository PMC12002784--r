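# Synthetic phantom generator: geometry, ground-truth invariants,
# appearance properties of the two modality renders, cohort stratification.

test_that("unperturbed phantom volume matches the closed-form ellipsoid", {
  spec <- phantomSpec(semiAxes = c(20, 25, 30), perturbationAmplitude = 0,
                      gridDim = c(80, 80, 80), gridSpacing = c(1, 1, 1),
                      seed = 1L)
  sh <- sampleShape(spec)
  vol <- maskVolume(sh$prostate)
  analytic <- 4 / 3 * pi * 20 * 25 * 30 / 1000  # 62.83 cm^3
  expect_lt(abs(vol - analytic) / analytic, 0.02)
})

test_that("zone partition and determinism hold for any seed", {
  for (sd in c(3L, 77L)) {
    spec <- phantomSpec(seed = sd)
    sh <- sampleShape(spec)
    p <- labels3d(sh$prostate) > 0
    tz <- labels3d(sh$tz) > 0
    pz <- labels3d(sh$pz) > 0
    expect_true(all(!(tz & !p)))              # tz subset of prostate
    expect_identical(pz, p & !tz)             # pz is the exact complement
    expect_true(all(!(tz & pz)))
    sh2 <- sampleShape(spec)
    expect_identical(labels3d(sh2$prostate), labels3d(sh$prostate))
    expect_identical(labels3d(sh2$tz), labels3d(sh$tz))
  }
})

test_that("transition-zone fraction hits its target within 5%", {
  for (tf in c(0.3, 0.45)) {
    spec <- phantomSpec(tzFraction = tf, seed = 11L)
    sh <- sampleShape(spec)
    achieved <- sum(labels3d(sh$tz)) / sum(labels3d(sh$prostate))
    expect_lt(abs(achieved / tf - 1), 0.05)
  }
})

test_that("noise-free B-mode render is piecewise constant with a rim band", {
  spec <- phantomSpec(seed = 5L,
                      bmodeParams = list(speckle = 0, blurSigma = 0))
  sh <- sampleShape(spec)
  bm <- renderBmode(sh, spec)
  p <- spec@bmodeParams
  vals <- sort(unique(as.vector(voxels(bm))))
  expect_setequal(round(vals, 10),
                  round(c(p$background, p$tz, p$pz, p$rim), 10))
  rim <- abs(sh$shape$r - sh$shape$boundaryRadius) <= p$rimWidth
  expect_true(all(voxels(bm)[rim] == p$rim))
})

test_that("speckled B-mode interior has positive skew", {
  spec <- phantomSpec(seed = 9L)
  sh <- sampleShape(spec)
  bm <- renderBmode(sh, spec)
  x <- voxels(bm)[labels3d(sh$prostate) > 0]
  expect_gt(length(x), 1e4)
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew, 0)
})

test_that("noise-free CEUS zones are piecewise with the configured contrast", {
  spec <- phantomSpec(seed = 5L,
                      ceusParams = list(suppression = 0, noise = 0,
                                        motionJitter = 0, blurSigma = 0))
  sh <- sampleShape(spec)
  ce <- renderCeus(sh, spec)
  v <- voxels(ce)
  tz <- labels3d(sh$tz) > 0
  pz <- labels3d(sh$pz) > 0
  p <- spec@ceusParams
  expect_equal(mean(v[tz]) - mean(v[pz]), p$tz - p$pz, tolerance = 1e-12)
  expect_setequal(round(unique(as.vector(v)), 10),
                  round(c(p$background, p$tz, p$pz), 10))
})

test_that("the prostate boundary is more distinct on B-mode than on CEUS", {
  # peak radial intensity step near the boundary, matched seeds
  spec <- phantomSpec(seed = 7L)
  sh <- sampleShape(spec)
  bm <- renderBmode(sh, spec)
  ce <- renderCeus(sh, spec)
  d <- spec@gridDim
  ctr <- sh$shape$center
  set.seed(1)
  u <- matrix(rnorm(1200), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  prof <- function(vol, rr) trusseg:::cpp_trilinear_sample(
    voxels(vol), d, voxelSpacing(vol), worldOrigin(vol),
    cbind(ctr[1] + rr * u[, 1], ctr[2] + rr * u[, 2], ctr[3] + rr * u[, 3]))
  mv <- Volume3D(array(as.numeric(labels3d(sh$prostate) > 0), d),
                 voxelSpacing(bm), worldOrigin(bm))
  lo <- rep(1, nrow(u)); hi <- rep(46, nrow(u))
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    v <- prof(mv, mid)
    lo <- ifelse(v > 0.5, mid, lo)
    hi <- ifelse(v > 0.5, hi, mid)
  }
  R <- (lo + hi) / 2
  distinct <- function(vol) {
    offs <- seq(-3, 3, by = 1)
    vals <- sapply(offs, function(o) prof(vol, R + o))
    mean(apply(abs(vals[, -1] - vals[, -ncol(vals)]), 1, max))
  }
  expect_gt(distinct(bm), distinct(ce))
})

test_that("zonal contrast is higher on CEUS than on B-mode", {
  for (sd in c(7L, 23L)) {
    spec <- phantomSpec(seed = sd)
    sh <- sampleShape(spec)
    vb <- voxels(renderBmode(sh, spec))
    vc <- voxels(renderCeus(sh, spec))
    tz <- labels3d(sh$tz) > 0
    pz <- labels3d(sh$pz) > 0
    expect_gt(abs(mean(vc[tz]) - mean(vc[pz])),
              abs(mean(vb[tz]) - mean(vb[pz])))
  }
})

test_that("anterior suppression weakens the anterior boundary step", {
  for (sd in c(7L, 23L)) {
    spec <- phantomSpec(seed = sd,
                        ceusParams = list(noise = 0, motionJitter = 0))
    sh <- sampleShape(spec)
    ce <- renderCeus(sh, spec)
    d <- spec@gridDim
    ctr <- sh$shape$center
    set.seed(42)
    u <- matrix(rnorm(6000), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    u <- u[abs(u[, 2]) > 0.5, ]         # strongly anterior/posterior patches
    prof <- function(vol, rr) trusseg:::cpp_trilinear_sample(
      voxels(vol), d, voxelSpacing(vol), worldOrigin(vol),
      cbind(ctr[1] + rr * u[, 1], ctr[2] + rr * u[, 2], ctr[3] + rr * u[, 3]))
    mv <- Volume3D(array(as.numeric(labels3d(sh$prostate) > 0), d),
                   voxelSpacing(ce), worldOrigin(ce))
    lo <- rep(1, nrow(u)); hi <- rep(46, nrow(u))
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      v <- prof(mv, mid)
      lo <- ifelse(v > 0.5, mid, lo)
      hi <- ifelse(v > 0.5, hi, mid)
    }
    R <- (lo + hi) / 2
    stepv <- abs(prof(ce, R - 2) - prof(ce, R + 3.5))
    ant <- u[, 2] < 0                   # anterior is -y
    expect_lt(mean(stepv[ant]), mean(stepv[!ant]))
  }
})

test_that("cohort strata counts and labels are consistent", {
  counts <- trusseg:::.largestRemainder(51, c(1, 1, 1) / 3)
  expect_identical(counts, c(17L, 17L, 17L))
  expect_identical(trusseg:::.largestRemainder(3, c(1, 1, 1) / 3),
                   c(1L, 1L, 1L))
  coh <- generateCohort(6, seed = 12L)
  strata <- vapply(coh, function(cs) cs@stratum, "")
  expect_identical(table(factor(strata, c("small", "medium", "large"))),
                   table(factor(rep(c("small", "medium", "large"), each = 2),
                                c("small", "medium", "large"))))
  for (cs in coh) {
    v <- maskVolume(cs@prostateMask)
    expect_equal(v, cs@trueVolume)
    expect_identical(stratifyByVolume(v), cs@stratum)
    expect_identical(labels3d(cs@pzMask),
                     array(as.integer(labels3d(cs@prostateMask) > 0 &
                                        !(labels3d(cs@tzMask) > 0)),
                           dim(labels3d(cs@pzMask))))
  }
  # determinism of the whole cohort
  coh2 <- generateCohort(6, seed = 12L)
  expect_identical(labels3d(coh2[[3]]@prostateMask),
                   labels3d(coh[[3]]@prostateMask))
  expect_equal(voxels(coh2[[5]]@ceus), voxels(coh[[5]]@ceus))
})

test_that("unreachable targets raise simulation errors", {
  expect_error(sampleShape(phantomSpec(semiAxes = c(60, 60, 60))), "fit")
  expect_error(phantomSpec(tzFraction = 0.9), "tzFraction")
  expect_error(generateCohort(4, c(0.5, 0.4, 0.2)), "sum to 1")
})
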