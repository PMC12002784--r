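# Network architecture, gradients, the training loop mechanics
# (early stopping, determinism) and cross-validation partitioning.

test_that("parameter count matches the hand-derived layer formula", {
  # depth 2, base 4: enc1 (3->4, 4->4), enc2 (4->8, 8->8),
  # up1 (8->4), dec1a (8->4), dec1b (4->4), head (4->2, 1x1)
  hand <- (9 * 3 + 1) * 4 + (9 * 4 + 1) * 4 +
    (9 * 4 + 1) * 8 + (9 * 8 + 1) * 8 +
    (9 * 8 + 1) * 4 + (9 * 8 + 1) * 4 + (9 * 4 + 1) * 4 +
    (4 + 1) * 2
  cfg <- modelConfig("bmode", depth = 2L, baseWidth = 4L)
  expect_identical(countParameters(cfg), hand)
  model <- buildNetwork(cfg, seed = 1L)
  expect_identical(nParameters(model), hand)
})

test_that("outputs have input shape, two channels, and live in [0, 1]", {
  model <- buildNetwork(modelConfig("ceus", depth = 2L, baseWidth = 4L),
                        seed = 2L)
  for (hw in list(c(16L, 16L), c(20L, 24L), c(17L, 19L))) {
    x <- matrix(rnorm(prod(hw) * 3) * 10, prod(hw), 3)
    p <- trusseg:::.unetForward(model, x, hw[1], hw[2])$probs
    expect_identical(dim(p), as.integer(c(prod(hw), 2)))
    expect_true(all(p >= 0 & p <= 1))
  }
  # all-zero input is handled without numerical failure
  p0 <- trusseg:::.unetForward(model, matrix(0, 256, 3), 16L, 16L)$probs
  expect_true(all(is.finite(p0)))
})

test_that("inputs smaller than 2^depth are rejected", {
  model <- buildNetwork(modelConfig("bmode", depth = 5L, baseWidth = 4L),
                        seed = 3L)
  x <- matrix(rnorm(16 * 16 * 3), 256, 3)
  expect_error(trusseg:::.unetForward(model, x, 16L, 16L), "2\\^depth")
})

test_that("backpropagation matches finite differences", {
  set.seed(10)
  model <- buildNetwork(modelConfig("bmode", depth = 2L, baseWidth = 4L),
                        seed = 5L)
  H <- 12L; W <- 8L
  x <- matrix(rnorm(H * W * 3), H * W, 3)
  y <- cbind(as.numeric(runif(H * W) > 0.7),
             as.numeric(runif(H * W) > 0.8))
  fw <- trusseg:::.unetForward(model, x, H, W, wantCache = TRUE)
  lg <- trusseg:::.segLossGrad(fw$logits, y)
  gr <- trusseg:::.unetBackward(model, fw$cache, lg$dLogits)
  lossAt <- function(m) trusseg:::.segLossGrad(
    trusseg:::.unetForward(m, x, H, W)$logits, y)$loss
  eps <- 1e-6
  for (nm in c("enc1a", "enc2b", "up1", "dec1a", "out")) {
    Wm <- model@weights[[nm]]$W
    for (i in sample(length(Wm), 3)) {
      m2 <- model; m2@weights[[nm]]$W[i] <- Wm[i] + eps
      m3 <- model; m3@weights[[nm]]$W[i] <- Wm[i] - eps
      num <- (lossAt(m2) - lossAt(m3)) / (2 * eps)
      expect_equal(gr[[nm]]$W[i], num, tolerance = 1e-4)
    }
  }
})

test_that("the early-stopping rule matches brute force on injected metrics", {
  # never improves after epoch 3 -> stops at 13; always improving -> cap
  seqA <- c(0.1, 0.2, 0.9, rep(0.5, 60))
  expect_identical(stoppingEpoch(seqA, 10L, 60L), 13L)
  expect_identical(stoppingEpoch(seq(0.01, 0.60, by = 0.01), 10L, 60L), 60L)
  set.seed(21)
  for (i in 1:50) {
    metrics <- cumsum(rnorm(60, 0.005, 0.05))
    patience <- sample(2:12, 1)
    expect_identical(stoppingEpoch(metrics, patience, 60L),
                     as.integer(bruteStopEpoch(metrics, patience, 60L)))
  }
})

test_that("the training loop stops exactly where the rule says", {
  sm <- tinySample()
  cfg <- trainConfig(maxIterations = 60L, patience = 10L, seed = 4L,
                     batchSize = 1L)
  mockSeq <- c(0.1, 0.2, 0.9, rep(0.5, 60))
  model <- buildNetwork(modelConfig("bmode", depth = 2L, baseWidth = 4L),
                        seed = 6L)
  fit <- trainFold(model, list(sm), list(sm), cfg,
                   valMetricFn = function(m, e) mockSeq[e])
  expect_identical(nrow(trainingHistory(fit)), 13L)
  # improving forever: runs to the cap
  cfg5 <- trainConfig(maxIterations = 5L, patience = 10L, seed = 4L,
                      batchSize = 1L)
  fit2 <- trainFold(model, list(sm), list(sm), cfg5,
                    valMetricFn = function(m, e) e / 100)
  expect_identical(nrow(trainingHistory(fit2)), 5L)
  expect_error(trainFold(model, list(), list(sm), cfg), "empty")
})

test_that("training is deterministic under a fixed seed", {
  sm <- lapply(1:3, function(i) tinySample(seed = i))
  cfg <- trainConfig(maxIterations = 3L, patience = 10L, seed = 11L,
                     batchSize = 2L)
  model <- buildNetwork(modelConfig("bmode", depth = 2L, baseWidth = 4L),
                        seed = 7L)
  f1 <- trainFold(model, sm, sm[1], cfg)
  f2 <- trainFold(model, sm, sm[1], cfg)
  expect_identical(trainingHistory(f1), trainingHistory(f2))
  expect_identical(f1@weights, f2@weights)
})

test_that("cross-validation partitions cases correctly", {
  mkCase <- function(i) lapply(1:2, function(k) tinySample(seed = 10 * i + k))
  samples <- setNames(lapply(1:10, mkCase), sprintf("c%02d", 1:10))
  cfg <- trainConfig(nFolds = 5L, maxIterations = 1L, seed = 13L,
                     batchSize = 4L)
  mc <- modelConfig("bmode", depth = 2L, baseWidth = 4L)
  cv <- crossval(samples, mc, cfg)
  expect_identical(sort(unique(cv$folds)), 1:5)
  expect_true(all(table(cv$folds) == 2))          # 10 cases over 5 folds
  expect_setequal(names(cv$predictions), names(samples))
  expect_true(all(vapply(cv$predictions, length, 0L) == 2))
  # repeated run gives the identical fold assignment
  cv2 <- crossval(samples, mc, cfg)
  expect_identical(cv$folds, cv2$folds)
  # fold sizes differ by at most one for n = 51
  f51 <- trusseg:::.withSeed(13L, sample(rep_len(1:5, 51)))
  expect_lte(diff(range(table(f51))), 1)
  expect_error(crossval(samples[1:3], mc, cfg), "fewer cases")
})

test_that("prediction is deterministic and respects training geometry", {
  spec <- phantomSpec(gridDim = c(24, 24, 24), gridSpacing = c(3, 3, 3),
                      semiAxes = c(18, 20, 22), seed = 31L)
  cs <- generatePhantom(spec, "t1")
  geom <- radialGeometry(cs@bmode, angularInterval = 30,
                         inPlaneSpacing = 3)
  stack <- extractStack(cs@bmode, geom)
  model <- buildNetwork(modelConfig("bmode", depth = 2L, baseWidth = 4L),
                        seed = 8L)
  p1 <- predictStack(model, stack)
  p2 <- predictStack(model, stack)
  expect_length(p1, nPlanes(geom))
  expect_identical(p1[[3]]@prostateProb, p2[[3]]@prostateProb)
  expect_true(all(p1[[1]]@prostateProb >= 0 & p1[[1]]@prostateProb <= 1))
  # geometry mismatch: model trained on different plane dims refuses
  model@meta$planeDim <- c(99L, 99L)
  expect_error(predictStack(model, stack), "does not match")
})
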