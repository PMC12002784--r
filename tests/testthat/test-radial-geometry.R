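# Radial plane extraction and the plane <-> world mapping.

makeGeom <- function(...) {
  args <- modifyList(list(axisPoint = c(16, 16), planeHalfWidth = 12,
                          zRange = c(0, 20), inPlaneSpacing = 1),
                     list(...))
  do.call(radialGeometry, args)
}

test_that("planeCount follows 180 / interval and rejects non-divisors", {
  expect_identical(planeCount(10), 18L)
  expect_identical(planeCount(90), 2L)
  expect_identical(planeCount(180), 1L)
  expect_error(planeCount(7), "divide 180")
  expect_error(planeCount(0), "in \\(0, 180\\]")
})

test_that("an axis-symmetric volume yields identical planes", {
  d <- c(33L, 33L, 21L)
  x <- (seq_len(d[1]) - 1) - 16
  y <- (seq_len(d[2]) - 1) - 16
  r <- sqrt(outer(x^2, y^2, "+"))
  z <- seq_len(d[3]) - 1
  vox <- array(0, d)
  for (k in seq_len(d[3])) vox[, , k] <- exp(-r / 10) * (1 + 0.05 * z[k])
  vol <- Volume3D(vox, spacing = c(1, 1, 1))
  geom <- makeGeom(angularInterval = 10)
  p0 <- extractPlane(vol, geom, 0)
  # analytic oracle: intensity depends only on (|s|, z)
  sAbs <- abs(p0@s)
  zIdx <- p0@z
  oracle <- exp(-outer(sAbs, rep(1, length(zIdx))) / 10) *
    (1 + 0.05 * outer(rep(1, length(sAbs)), zIdx))
  # trilinear interpolation of a curved radial field at 1 mm spacing is
  # accurate to O(h^2) ~ 1e-3, not machine precision
  expect_equal(p0@pixels, oracle, tolerance = 5e-3,
               ignore_attr = TRUE)
  for (k in c(3, 9, 17))
    expect_equal(extractPlane(vol, geom, k)@pixels, p0@pixels,
                 tolerance = 5e-3)
})

test_that("the s = 0 column always samples the axis", {
  d <- c(17L, 17L, 9L)
  vox <- array(runif(prod(d)), d)
  vox[9, 9, ] <- 7          # axis column value
  vol <- Volume3D(vox, spacing = c(1, 1, 1))
  geom <- radialGeometry(axisPoint = c(8, 8), planeHalfWidth = 6,
                         zRange = c(0, 8), inPlaneSpacing = 1,
                         angularInterval = 30)
  for (k in 0:5) {
    p <- extractPlane(vol, geom, k)
    expect_equal(p@pixels[which(abs(p@s) < 1e-9), ], rep(7, length(p@z)))
  }
})

test_that("plane k+1 equals plane k of the volume rotated by -interval", {
  set.seed(4)
  d <- c(33L, 33L, 9L)
  base <- array(rnorm(prod(d)), d)
  vol <- Volume3D(trusseg:::cpp_gauss_blur3(base, d, c(2, 2, 1)),
                  spacing = c(1, 1, 1))
  geom <- makeGeom(angularInterval = 45, planeHalfWidth = 8,
                   zRange = c(0, 8))
  # rotation oracle: the volume rotated by -45 deg about the axis takes its
  # value at p from the original at R(+45) p
  th <- 45 * pi / 180
  idx <- as.matrix(expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                               z = seq_len(d[3]) - 1))
  cx <- 16; cy <- 16
  rx <- cx + cos(th) * (idx[, 1] - cx) - sin(th) * (idx[, 2] - cy)
  ry <- cy + sin(th) * (idx[, 1] - cx) + cos(th) * (idx[, 2] - cy)
  rot <- trusseg:::cpp_trilinear_sample(voxels(vol), d, c(1, 1, 1), c(0, 0, 0),
                                        cbind(rx, ry, idx[, 3]))
  volRot <- Volume3D(array(rot, d), spacing = c(1, 1, 1))
  pk1 <- extractPlane(vol, geom, 1)
  pk0rot <- extractPlane(volRot, geom, 0)
  # compare away from the rim where double interpolation differs most
  inner <- abs(pk1@s) <= 6
  expect_equal(pk1@pixels[inner, ], pk0rot@pixels[inner, ], tolerance = 0.02)
})

test_that("context planes obey the offset geometry", {
  d <- c(33L, 33L, 9L)
  # linear ramp along plane 0's normal (the y axis): value = y
  vox <- array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), d)
  vol <- Volume3D(vox, spacing = c(1, 1, 1))
  geom0 <- makeGeom(angularInterval = 10, contextOffset = 0)
  ctx0 <- extractContext(vol, geom0, 0)
  p0 <- extractPlane(vol, geom0, 0)
  expect_equal(ctx0$lower@pixels, p0@pixels, tolerance = 1e-12)
  expect_equal(ctx0$upper@pixels, p0@pixels, tolerance = 1e-12)
  geom <- makeGeom(angularInterval = 10, contextOffset = 4)
  ctx <- extractContext(vol, geom, 0)
  inner <- abs(p0@s) <= 10   # interior; edge padding excluded
  expect_equal(ctx$upper@pixels[inner, ] - p0@pixels[inner, ],
               matrix(4, sum(inner), length(p0@z)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(p0@pixels[inner, ] - ctx$lower@pixels[inner, ],
               matrix(4, sum(inner), length(p0@z)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("out-of-volume samples use edge replication", {
  d <- c(9L, 9L, 5L)
  vox <- array(3.25, d)
  vol <- Volume3D(vox, spacing = c(1, 1, 1))
  geom <- radialGeometry(axisPoint = c(4, 4), planeHalfWidth = 20,
                         zRange = c(0, 4), inPlaneSpacing = 1,
                         angularInterval = 90)
  p <- extractPlane(vol, geom, 0)
  expect_true(all(p@pixels == 3.25))   # replication of a constant stays flat
})

test_that("planePointToWorld matches the rotation-matrix oracle", {
  geom <- makeGeom(angularInterval = 10)
  s <- c(-5, 0, 2.5, 7)
  z <- c(1, 2, 3, 4)
  for (k in c(0, 4, 11)) {
    w1 <- planePointToWorld(geom, k, s, z)
    # axis points
    expect_equal(planePointToWorld(geom, k, 0, z)[, 1:2],
                 matrix(16, length(z), 2), ignore_attr = TRUE)
    # advancing one plane rotates by the angular interval about the axis
    w2 <- planePointToWorld(geom, k + 1, s, z)
    th <- 10 * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rel <- cbind(w1[, 1] - 16, w1[, 2] - 16)
    expect_equal(w2[, 1:2], sweep(rel %*% t(R), 2, c(16, 16), "+"),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # sign symmetry: negative s equals theta + 180 with positive s
  w <- planePointToWorld(geom, 3, -4, 7)
  thOpp <- (3 * 10 + 180) * pi / 180
  expect_equal(as.numeric(w),
               c(16 + 4 * cos(thOpp), 16 + 4 * sin(thOpp), 7),
               tolerance = 1e-12)
  expect_error(planePointToWorld(geom, 18, 0, 0), "plane index")
})

test_that("sampling then inverse-mapping reproduces world coordinates", {
  geom <- makeGeom(angularInterval = 30)
  g <- trusseg:::.planeGrid(geom)
  for (k in 0:5) {
    w <- planePointToWorld(geom, k, rep(g$s, length(g$z)),
                           rep(g$z, each = length(g$s)))
    th <- k * 30 * pi / 180
    sBack <- (w[, 1] - 16) * cos(th) + (w[, 2] - 16) * sin(th)
    expect_equal(sBack, rep(g$s, length(g$z)), tolerance = 1e-9)
    expect_equal(w[, 3], rep(g$z, each = length(g$s)), tolerance = 1e-12)
  }
})
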