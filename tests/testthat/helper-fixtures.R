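# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use plain loops / all-pairs search so they share no code with the package
# implementations they check.

# random blobby binary mask on a small grid: union of a few balls
randomBlobMask <- function(dim = c(16L, 16L, 16L), nBalls = 2L,
                           spacing = c(1, 1, 1)) {
  d <- dim
  m <- array(FALSE, d)
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  for (b in seq_len(nBalls)) {
    ctr <- runif(3, 4, d - 3)
    rad <- runif(1, 2, 5)
    m <- m | array(rowSums(sweep(idx, 2, ctr)^2) <= rad^2, d)
  }
  SegmentationMask(m, spacing = spacing, labelSet = c(0L, 1L))
}

# exhaustive voxel-count Dice / IoU via an explicit loop
bruteOverlap <- function(a, b) {
  av <- as.vector(labels3d(a) > 0)
  bv <- as.vector(labels3d(b) > 0)
  nA <- 0L; nB <- 0L; nI <- 0L; nU <- 0L
  for (i in seq_along(av)) {
    if (av[i]) nA <- nA + 1L
    if (bv[i]) nB <- nB + 1L
    if (av[i] && bv[i]) nI <- nI + 1L
    if (av[i] || bv[i]) nU <- nU + 1L
  }
  list(dice = if (nA + nB == 0) 1 else 2 * nI / (nA + nB),
       iou = if (nU == 0) 1 else nI / nU)
}

# boundary voxel centres by explicit 6-neighbour inspection
bruteSurface <- function(mask) {
  m <- labels3d(mask) > 0
  d <- dim(m)
  sp <- voxelSpacing(mask)
  org <- worldOrigin(mask)
  pts <- NULL
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!m[x, y, z]) next
    nb <- c(
      if (x > 1) m[x - 1, y, z] else FALSE,
      if (x < d[1]) m[x + 1, y, z] else FALSE,
      if (y > 1) m[x, y - 1, z] else FALSE,
      if (y < d[2]) m[x, y + 1, z] else FALSE,
      if (z > 1) m[x, y, z - 1] else FALSE,
      if (z < d[3]) m[x, y, z + 1] else FALSE)
    if (!all(nb))
      pts <- rbind(pts, org + (c(x, y, z) - 1) * sp)
  }
  pts
}

# all-pairs symmetric surface distances
bruteSurfaceDistances <- function(a, b) {
  pa <- bruteSurface(a)
  pb <- bruteSurface(b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  dab <- apply(dm, 1, min)
  dba <- apply(dm, 2, min)
  c(msd = (mean(dab) + mean(dba)) / 2, hd = max(max(dab), max(dba)))
}

# brute-force evaluation of the early-stopping rule: walk the sequence and
# re-scan the running best at every epoch
bruteStopEpoch <- function(metrics, patience, cap) {
  n <- min(length(metrics), cap)
  for (e in seq_len(n)) {
    bestSoFar <- which.max(metrics[seq_len(e)])  # first occurrence of max
    if (e - bestSoFar >= patience) return(e)
  }
  n
}

# tiny training sample for loop-mechanics tests
tinySample <- function(H = 8L, W = 8L, seed = 1L) {
  set.seed(seed)
  list(x = matrix(rnorm(H * W * 3), H * W, 3),
       yP = as.numeric(runif(H * W) > 0.7),
       yZ = as.numeric(runif(H * W) > 0.8), H = H, W = W)
}

# analytic cylinder mask (axis = z through the grid centre)
cylinderMask <- function(dim, spacing, radius, z0, z1) {
  d <- as.integer(dim)
  ctr <- (d - 1) * spacing / 2
  x <- (seq_len(d[1]) - 1) * spacing[1] - ctr[1]
  y <- (seq_len(d[2]) - 1) * spacing[2] - ctr[2]
  z <- (seq_len(d[3]) - 1) * spacing[3]
  gx <- array(rep(x, times = d[2] * d[3]), d)
  gy <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  gz <- array(rep(z, each = d[1] * d[2]), d)
  SegmentationMask((gx^2 + gy^2 <= radius^2) & gz >= z0 & gz <= z1,
                   spacing = spacing, labelSet = c(0L, 1L))
}
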