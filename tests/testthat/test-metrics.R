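# Overlap and surface metrics against exhaustive / all-pairs oracles.

test_that("dice and iou match hand-counted toy masks", {
  a <- array(FALSE, c(4, 4, 2)); a[1:2, 1:2, 1:2] <- TRUE   # |A| = 8
  b <- array(FALSE, c(4, 4, 2)); b[1:2, 1:2, 1] <- TRUE     # |B| = 4, I = 4
  A <- SegmentationMask(a); B <- SegmentationMask(b)
  expect_equal(dice(A, B), 2 * 4 / (8 + 4))
  expect_equal(iou(A, B), 4 / 8)
  expect_equal(dice(A, A), 1)
  expect_equal(iou(A, A), 1)
  disjoint <- SegmentationMask(array(rev(a), dim(a)) & !a)
  expect_equal(dice(A, disjoint), 0)
  expect_error(dice(A, SegmentationMask(array(0L, c(3, 3, 3)))), "grid")
})

test_that("empty-mask conventions hold", {
  e <- SegmentationMask(array(0L, c(16, 16, 16)), labelSet = c(0L, 1L))
  f <- randomBlobMask(c(16L, 16L, 16L))
  expect_equal(dice(e, e), 1)
  expect_equal(iou(e, e), 1)
  expect_equal(dice(e, f), 0)
  expect_error(rvd(f, e), "empty")
  expect_error(surfaceDistances(e, f), "non-empty")
})

test_that("rvd sign convention: over-segmentation is positive", {
  a <- array(FALSE, c(6, 6, 6)); a[1:5, 1:5, 1:5] <- TRUE
  ref <- array(FALSE, c(6, 6, 6)); ref[1:5, 1:5, 1:4] <- TRUE
  expect_gt(rvd(SegmentationMask(a), SegmentationMask(ref)), 0)
  expect_equal(rvd(SegmentationMask(a), SegmentationMask(a)), 0)
  ref2 <- array(FALSE, c(6, 6, 6)); ref2[1:4, 1:5, 1:5] <- TRUE
  expect_equal(rvd(SegmentationMask(a), SegmentationMask(ref2)),
               (100 - 80) / 80 * 100)
})

test_that("translated cube Hausdorff equals the translation", {
  a <- array(FALSE, c(12, 12, 12)); a[3:7, 3:7, 3:7] <- TRUE
  b <- array(FALSE, c(12, 12, 12)); b[5:9, 3:7, 3:7] <- TRUE
  sd <- surfaceDistances(SegmentationMask(a), SegmentationMask(b))
  expect_equal(sd[["hd"]], 2)
  expect_lte(sd[["msd"]], sd[["hd"]])
})

test_that("surface metrics match the all-pairs brute-force oracle", {
  set.seed(5)
  for (i in 1:25) {
    a <- randomBlobMask()
    b <- randomBlobMask()
    got <- surfaceDistances(a, b)
    want <- bruteSurfaceDistances(a, b)
    expect_equal(got[["msd"]], want[["msd"]], tolerance = 1e-9)
    expect_equal(got[["hd"]], want[["hd"]], tolerance = 1e-9)
    o <- bruteOverlap(a, b)
    expect_identical(dice(a, b), o$dice)
    expect_identical(iou(a, b), o$iou)
    expect_equal(iou(a, b), dice(a, b) / (2 - dice(a, b)),
                 tolerance = 1e-12)
    # symmetry
    expect_identical(dice(a, b), dice(b, a))
    expect_identical(surfaceDistances(b, a)[["hd"]], got[["hd"]])
  }
})

test_that("surface metrics scale linearly with voxel spacing", {
  set.seed(6)
  a <- randomBlobMask()
  b <- randomBlobMask()
  s1 <- surfaceDistances(a, b)
  a2 <- SegmentationMask(labels3d(a), spacing = c(2, 2, 2))
  b2 <- SegmentationMask(labels3d(b), spacing = c(2, 2, 2))
  s2 <- surfaceDistances(a2, b2)
  expect_equal(s2[["msd"]], 2 * s1[["msd"]], tolerance = 1e-12)
  expect_equal(s2[["hd"]], 2 * s1[["hd"]], tolerance = 1e-12)
})

test_that("metrics are invariant to a joint 90-degree rotation", {
  set.seed(7)
  a <- randomBlobMask()
  b <- randomBlobMask()
  rot <- function(m) {
    lab <- labels3d(m)
    SegmentationMask(aperm(lab[, dim(lab)[2]:1, ], c(2, 1, 3)))
  }
  expect_identical(dice(a, b), dice(rot(a), rot(b)))
  expect_identical(iou(a, b), iou(rot(a), rot(b)))
  s1 <- surfaceDistances(a, b)
  s2 <- surfaceDistances(rot(a), rot(b))
  expect_equal(s1[["msd"]], s2[["msd"]], tolerance = 1e-9)
  expect_equal(s1[["hd"]], s2[["hd"]], tolerance = 1e-9)
})

test_that("per-plane metrics average plane-wise values", {
  p1 <- matrix(FALSE, 8, 8); p1[3:6, 3:6] <- TRUE
  # plane 2: prediction is half of truth -> dice 2*8/(8+16) = 2/3
  t2 <- p1
  p2 <- matrix(FALSE, 8, 8); p2[3:4, 3:6] <- TRUE
  m <- perPlaneMetrics(list(p1, p2), list(p1, t2))
  expect_equal(m[["dsc"]], mean(c(1, 2 * 8 / 24)))
  # identical pairs on all planes reduce to the single-plane value
  m2 <- perPlaneMetrics(list(p1, p1, p1), list(p1, p1, p1))
  expect_equal(m2[["dsc"]], 1)
  expect_equal(m2[["msd"]], 0)
  # invariance to plane order
  m3 <- perPlaneMetrics(list(p2, p1), list(t2, p1))
  expect_equal(m3, m)
  expect_error(perPlaneMetrics(list(p1), list(p1, p2)), "mismatch")
})

test_that("the aggregate confidence interval matches the t-table oracle", {
  ci <- meanCI(c(0.8, 0.9, 1.0))
  se <- sd(c(0.8, 0.9, 1.0)) / sqrt(3)
  expect_equal(ci[["mean"]], 0.9)
  expect_equal(ci[["ciHigh"]] - ci[["mean"]], 4.302653 * se,
               tolerance = 1e-6)
  expect_equal(unname(meanCI(rep(0.5, 4))), c(0.5, 0.5, 0.5))
  single <- meanCI(0.7)
  expect_equal(single[["mean"]], 0.7)
  expect_true(is.na(single[["ciLow"]]))
})

test_that("evaluateCohort produces the Table-1-shaped aggregate", {
  set.seed(8)
  mk <- function() {
    # central gland with an inner core, jittered per case so surface
    # metrics are non-trivial but never degenerate
    ctr <- c(10, 10, 10) + runif(3, -1, 1)
    p <- rasterizeEllipsoid(c(7, 8, 7), c(20, 20, 20), center = ctr)
    tzr <- rasterizeEllipsoid(c(4, 4, 3), c(20, 20, 20), center = ctr)
    z <- composeZones(p, tzr)
    list(prostate = p, tz = z$tz, pz = z$pz)
  }
  truth <- list(a = mk(), b = mk(), c = mk())
  pred <- lapply(truth, function(t) {
    lab <- labels3d(t$prostate)
    lab[1:3, , ] <- 0L                    # shave one side of the gland
    z <- composeZones(SegmentationMask(lab), t$tz)
    list(prostate = SegmentationMask(lab), tz = z$tz, pz = z$pz)
  })
  rep <- evaluateCohort(pred, truth, modality = "bmode")
  agg <- aggregateMetrics(rep)
  expect_setequal(unique(agg$metric), c("iou", "dsc", "rvd", "msd", "hd"))
  expect_setequal(unique(agg$structure), c("prostate", "zones"))
  pc <- perCaseMetrics(rep)
  expect_true(all(pc$dsc >= 0 & pc$dsc <= 1))
  expect_true(all(pc$msd <= pc$hd))
  expect_true(all(agg$ciLow <= agg$mean & agg$mean <= agg$ciHigh))
})
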