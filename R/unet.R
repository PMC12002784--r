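# A compact 2D encoder-decoder segmentation network with skip connections
# ("U-Net style"), written directly on im2col+GEMM primitives (src/). Feature
# maps are (H*W) x C matrices. The input has 3 channels (central radial plane
# and its two context planes), the output 2 sigmoid channels (prostate
# probability; transition-zone probability). Training uses Adam on a
# soft-Dice + binary cross-entropy loss, with the study's schedule: fivefold
# cross-validation, epoch cap, early stopping on the validation Dice.

.widths <- function(cfg) cfg@baseWidth * 2^(seq_len(cfg@depth) - 1)

#' Closed-form trainable parameter count of the network
#'
#' 3x3 convolutions contribute (9 Cin + 1) Cout parameters, the final 1x1
#' convolution (Cin + 1) Cout.
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @return integer parameter count.
#' @export
countParameters <- function(cfg) {
  w <- .widths(cfg)
  D <- cfg@depth
  conv3 <- function(ci, co) (9 * ci + 1) * co
  total <- conv3(cfg@inChannels, w[1]) + conv3(w[1], w[1])
  for (l in 2:D) total <- total + conv3(w[l - 1], w[l]) + conv3(w[l], w[l])
  for (l in (D - 1):1)
    total <- total + conv3(w[l + 1], w[l]) +      # up-convolution
      conv3(2 * w[l], w[l]) + conv3(w[l], w[l])   # after skip concatenation
  total + (w[1] + 1) * cfg@outChannels            # 1x1 output head
}

#' Build (initialise) a segmentation network
#'
#' Encoder-decoder with skip connections; He-initialised weights. The
#' reported parameter count of the built model always equals
#' \code{\link{countParameters}} of its config.
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @param seed optional seed for the weight initialisation.
#' @return A \linkS4class{UNetModel}.
#' @export
buildNetwork <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "ModelConfig"))
  build <- function() {
    w <- .widths(cfg)
    D <- cfg@depth
    conv3 <- function(ci, co)
      list(W = matrix(rnorm(9 * ci * co, 0, sqrt(2 / (9 * ci))), 9 * ci, co),
           b = rep(0, co), kind = "conv3", cin = ci, cout = co)
    layers <- list()
    prev <- cfg@inChannels
    for (l in seq_len(D)) {
      layers[[paste0("enc", l, "a")]] <- conv3(prev, w[l])
      layers[[paste0("enc", l, "b")]] <- conv3(w[l], w[l])
      prev <- w[l]
    }
    for (l in (D - 1):1) {
      layers[[paste0("up", l)]] <- conv3(w[l + 1], w[l])
      layers[[paste0("dec", l, "a")]] <- conv3(2 * w[l], w[l])
      layers[[paste0("dec", l, "b")]] <- conv3(w[l], w[l])
    }
    layers[["out"]] <- list(
      W = matrix(rnorm(w[1] * cfg@outChannels, 0, sqrt(2 / w[1])),
                 w[1], cfg@outChannels),
      b = rep(0, cfg@outChannels), kind = "conv1", cin = w[1],
      cout = cfg@outChannels)
    layers
  }
  weights <- if (is.null(seed)) build() else .withSeed(seed, build())
  new("UNetModel", config = cfg, weights = weights,
      history = data.frame(), meta = list())
}

#' @rdname UNetModel-class
#' @export
setMethod("nParameters", "UNetModel", function(x) {
  n <- sum(vapply(x@weights, function(l) length(l$W) + length(l$b), 0))
  stopifnot(n == countParameters(x@config))  # architectural invariant
  n
})

.relu <- function(x) (x > 0) * x

.sigmoid <- function(z) 1 / (1 + exp(pmin(pmax(-z, -40), 40)))

# replicate-pad / crop feature maps stored as (H*W) x C matrices
.featPad <- function(X, H, W, Hp, Wp) {
  if (Hp == H && Wp == W) return(X)
  ri <- pmin(seq_len(Hp), H)
  ci <- pmin(seq_len(Wp), W)
  idx <- as.vector(outer(ri, (ci - 1) * H, "+"))
  X[idx, , drop = FALSE]
}

.featCrop <- function(X, Hp, Wp, H, W) {
  if (Hp == H && Wp == W) return(X)
  idx <- as.vector(outer(seq_len(H), (seq_len(W) - 1) * Hp, "+"))
  X[idx, , drop = FALSE]
}

.featUncrop <- function(dX, Hp, Wp, H, W) {
  if (Hp == H && Wp == W) return(dX)
  out <- matrix(0, Hp * Wp, ncol(dX))
  idx <- as.vector(outer(seq_len(H), (seq_len(W) - 1) * Hp, "+"))
  out[idx, ] <- dX
  out
}

# forward pass; x is (H*W) x 3. Returns probabilities (cropped to H x W) and,
# optionally, the cache needed for backpropagation.
.unetForward <- function(model, x, H, W, wantCache = FALSE) {
  cfg <- model@config
  D <- cfg@depth
  if (min(H, W) < 2^D)
    stop("input plane (", H, " x ", W, ") is smaller than 2^depth = ", 2^D)
  mult <- 2^(D - 1)
  Hp <- ceiling(H / mult) * mult
  Wp <- ceiling(W / mult) * mult
  cur <- .featPad(x, H, W, Hp, Wp)
  h <- Hp; wpx <- Wp
  wts <- model@weights
  cache <- list(dims = c(H, W, Hp, Wp), conv = list(), pool = list(),
                skips = list())
  convF <- function(name, X, hh, ww) {
    ly <- wts[[name]]
    Z <- cpp_conv3_fwd(X, hh, ww, ly$W, ly$b)
    if (wantCache) cache$conv[[name]] <<- list(X = X, Z = Z, h = hh, w = ww)
    .relu(Z)
  }
  skips <- list()
  for (l in seq_len(D)) {
    cur <- convF(paste0("enc", l, "a"), cur, h, wpx)
    cur <- convF(paste0("enc", l, "b"), cur, h, wpx)
    if (l < D) {
      skips[[l]] <- cur
      pl <- cpp_maxpool2_fwd(cur, h, wpx)
      if (wantCache) cache$pool[[l]] <- list(idx = pl$idx, h = h, w = wpx)
      cur <- pl$Y
      h <- h / 2; wpx <- wpx / 2
    }
  }
  for (l in (D - 1):1) {
    up <- cpp_upsample2_fwd(cur, h, wpx)
    if (wantCache) cache$up[[as.character(l)]] <- c(h, wpx)
    h <- h * 2; wpx <- wpx * 2
    u <- convF(paste0("up", l), up, h, wpx)
    cur <- convF(paste0("dec", l, "a"), cbind(skips[[l]], u), h, wpx)
    cur <- convF(paste0("dec", l, "b"), cur, h, wpx)
  }
  ly <- wts[["out"]]
  logits <- sweep(cur %*% ly$W, 2, ly$b, "+")
  if (wantCache) cache$head <- list(X = cur)
  logitsC <- .featCrop(logits, Hp, Wp, H, W)
  list(probs = .sigmoid(logitsC), logits = logitsC,
       cache = if (wantCache) cache else NULL)
}

# backpropagation from d(loss)/d(logits) (cropped size); returns gradients
# named like the weights
.unetBackward <- function(model, cache, dLogits) {
  cfg <- model@config
  D <- cfg@depth
  dims <- cache$dims
  H <- dims[1]; W <- dims[2]; Hp <- dims[3]; Wp <- dims[4]
  wts <- model@weights
  grads <- list()
  dLog <- .featUncrop(dLogits, Hp, Wp, H, W)
  headX <- cache$head$X
  grads[["out"]] <- list(W = crossprod(headX, dLog), b = colSums(dLog))
  dCur <- dLog %*% t(wts[["out"]]$W)
  convB <- function(name, dOut) {
    cc <- cache$conv[[name]]
    dZ <- dOut * (cc$Z > 0)
    g <- cpp_conv3_bwd(cc$X, cc$h, cc$w, wts[[name]]$W, dZ)
    grads[[name]] <<- list(W = g$dW, b = as.numeric(g$db))
    g$dX
  }
  dSkips <- vector("list", D - 1)
  # decoder in reverse build order: l = 1 .. D-1 (innermost was built last)
  for (l in 1:(D - 1)) {
    dCur <- convB(paste0("dec", l, "b"), dCur)
    dCat <- convB(paste0("dec", l, "a"), dCur)
    wskip <- .widths(cfg)[l]
    dSkips[[l]] <- dCat[, seq_len(wskip), drop = FALSE]
    dU <- dCat[, wskip + seq_len(wskip), drop = FALSE]
    dUp <- convB(paste0("up", l), dU)
    hw <- cache$up[[as.character(l)]]
    dCur <- cpp_upsample2_bwd(dUp, hw[1], hw[2])
    h <- hw[1]; wpx <- hw[2]
  }
  for (l in D:1) {
    if (l < D) {
      pl <- cache$pool[[l]]
      dCur <- cpp_maxpool2_bwd(pl$idx, dCur, pl$h, pl$w)
      dCur <- dCur + dSkips[[l]]
    }
    dCur <- convB(paste0("enc", l, "b"), dCur)
    dCur <- convB(paste0("enc", l, "a"), dCur)
  }
  grads
}

# soft-Dice + binary cross-entropy loss on the two sigmoid channels;
# returns loss value and gradient w.r.t. the logits
.segLossGrad <- function(logits, targets) {
  n <- nrow(logits)
  p <- .sigmoid(logits)
  loss <- 0
  dL <- matrix(0, n, ncol(logits))
  eps <- 1
  for (ch in seq_len(ncol(logits))) {
    y <- targets[, ch]
    pc <- p[, ch]
    pcl <- pmin(pmax(pc, 1e-12), 1 - 1e-12)
    loss <- loss - mean(y * log(pcl) + (1 - y) * log(1 - pcl))
    dBce <- (pc - y) / n
    S <- sum(pc) + sum(y) + eps
    N <- 2 * sum(pc * y) + eps
    loss <- loss + (1 - N / S)
    dDice <- (N - 2 * y * S) / S^2
    dL[, ch] <- dBce + dDice * pc * (1 - pc)
  }
  list(loss = loss, dLogits = dL)
}

# ---- training ----------------------------------------------------------

#' Stopping epoch of the early-stopping rule
#'
#' Training runs for at most \code{maxIterations} epochs and halts at the
#' first epoch at which the validation metric has not improved (strictly)
#' for \code{patience} consecutive epochs.
#'
#' @param metrics per-epoch validation metric values (higher is better).
#' @param patience epochs without improvement tolerated.
#' @param maxIterations epoch cap.
#' @return the 1-based epoch at which training stops.
#' @export
stoppingEpoch <- function(metrics, patience = 10L, maxIterations = 60L) {
  best <- -Inf
  bestEpoch <- 0L
  n <- min(length(metrics), maxIterations)
  for (e in seq_len(n)) {
    if (metrics[e] > best) {
      best <- metrics[e]
      bestEpoch <- e
    }
    if (e - bestEpoch >= patience) return(e)
  }
  as.integer(n)
}

.adamInit <- function(weights)
  lapply(weights, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                   mb = l$b * 0, vb = l$b * 0))

.adamStep <- function(weights, grads, state, t, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    weights[[nm]]$W <- weights[[nm]]$W - lr * (s$mW / c1) /
      (sqrt(s$vW / c2) + eps)
    weights[[nm]]$b <- weights[[nm]]$b - lr * (s$mb / c1) /
      (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(weights = weights, state = state)
}

# plane Dice on binary matrices/vectors; both empty scores 1
.binDice <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Train the network on one fold
#'
#' Runs Adam on the soft-Dice + cross-entropy loss with the study's
#' early-stopping rule (no validation improvement for \code{patience}
#' epochs, cap at \code{maxIterations}); the best-epoch weights are
#' retained. Deterministic for a fixed \code{TrainConfig} seed.
#'
#' @param model a \linkS4class{UNetModel} (freshly built or warm).
#' @param trainSamples,valSamples lists of training samples as produced by
#'   \code{\link{makeTrainingSamples}}; disjoint sets.
#' @param cfg a \linkS4class{TrainConfig}.
#' @param valMetricFn optional function(model, epoch) returning the
#'   validation metric, replacing the default mean validation Dice; used to
#'   exercise the stopping rule in isolation.
#' @return the trained \linkS4class{UNetModel}, with per-epoch
#'   \code{history} (loss, validation metric) attached.
#' @export
trainFold <- function(model, trainSamples, valSamples, cfg,
                      valMetricFn = NULL) {
  stopifnot(is(model, "UNetModel"), is(cfg, "TrainConfig"))
  if (!length(trainSamples)) stop("empty training set")
  .withSeed(cfg@seed, {
    weights <- model@weights
    state <- .adamInit(weights)
    t <- 0L
    best <- -Inf
    bestEpoch <- 0L
    bestWeights <- weights
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       valMetric = numeric())
    for (epoch in seq_len(cfg@maxIterations)) {
      ord <- sample(length(trainSamples))
      epochLoss <- 0
      i <- 1L
      while (i <= length(ord)) {
        bIdx <- ord[i:min(i + cfg@batchSize - 1L, length(ord))]
        acc <- NULL
        for (si in bIdx) {
          sm <- trainSamples[[si]]
          model@weights <- weights
          fw <- .unetForward(model, sm$x, sm$H, sm$W, wantCache = TRUE)
          lg <- .segLossGrad(fw$logits, cbind(sm$yP, sm$yZ))
          epochLoss <- epochLoss + lg$loss
          g <- .unetBackward(model, fw$cache, lg$dLogits)
          acc <- if (is.null(acc)) g else
            mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   acc, g, SIMPLIFY = FALSE)
        }
        acc <- lapply(acc, function(g) list(W = g$W / length(bIdx),
                                            b = g$b / length(bIdx)))
        t <- t + 1L
        upd <- .adamStep(weights, acc, state, t, cfg@learningRate)
        weights <- upd$weights
        state <- upd$state
        i <- i + cfg@batchSize
      }
      model@weights <- weights
      vm <- if (!is.null(valMetricFn)) valMetricFn(model, epoch)
      else .valDice(model, valSamples)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     loss = epochLoss / length(ord),
                                     valMetric = vm))
      if (vm > best) {
        best <- vm
        bestEpoch <- epoch
        bestWeights <- weights
      }
      if (epoch - bestEpoch >= cfg@patience) break
    }
    model@weights <- bestWeights
    model@history <- hist
    model@meta <- list(bestEpoch = bestEpoch, stoppedAt = nrow(hist),
                       seed = cfg@seed,
                       planeDim = if (length(trainSamples))
                         c(trainSamples[[1]]$H, trainSamples[[1]]$W))
    model
  })
}

.valDice <- function(model, valSamples) {
  if (!length(valSamples)) return(NA_real_)
  mean(vapply(valSamples, function(sm) {
    p <- .unetForward(model, sm$x, sm$H, sm$W)$probs
    (.binDice(p[, 1] > 0.5, sm$yP > 0.5) +
       .binDice(p[, 2] > 0.5, sm$yZ > 0.5)) / 2
  }, 0))
}

#' Build per-plane training samples from phantom cases
#'
#' Each radial plane yields one sample: a 3-channel input (central plane and
#' the two context planes, each standardised to zero mean / unit variance)
#' and two target masks (prostate; transition zone) obtained by slicing the
#' 3D ground truth with the same geometry.
#'
#' @param cases list of \linkS4class{PhantomCase}.
#' @param geom a \linkS4class{RadialGeometry} (defaults derived per volume
#'   when NULL).
#' @param modality "bmode" or "ceus".
#' @return named list (one element per case) of lists of samples.
#' @export
makeTrainingSamples <- function(cases, geom = NULL, modality = "bmode") {
  out <- lapply(cases, function(cs) {
    vol <- if (modality == "bmode") cs@bmode else cs@ceus
    g <- if (is.null(geom)) radialGeometry(vol) else geom
    stack <- extractStack(vol, g, sourceId = cs@caseId)
    lapply(seq_len(nPlanes(g)) - 1L, function(k) {
      tri <- stackPlanes(stack)[[k + 1]]
      x <- cbind(.stdz(tri$center@pixels), .stdz(tri$lower@pixels),
                 .stdz(tri$upper@pixels))
      yP <- as.numeric(slicePlaneMask(cs@prostateMask, g, k))
      yZ <- as.numeric(slicePlaneMask(cs@tzMask, g, k))
      list(x = x, yP = yP, yZ = yZ,
           H = nrow(tri$center@pixels), W = ncol(tri$center@pixels),
           s = tri$center@s, z = tri$center@z, k = k)
    })
  })
  names(out) <- vapply(cases, function(cs) cs@caseId, "")
  out
}

.stdz <- function(m) {
  v <- as.numeric(m)
  (v - mean(v)) / (sd(v) + 1e-8)
}

#' Predict all planes of a radial stack
#'
#' Deterministic inference: one \linkS4class{PlanePrediction} per plane.
#'
#' @param model a trained \linkS4class{UNetModel}.
#' @param stack a \linkS4class{RadialPlaneStack} with the geometry used in
#'   training.
#' @return list of \linkS4class{PlanePrediction}.
#' @export
predictStack <- function(model, stack) {
  stopifnot(is(model, "UNetModel"), is(stack, "RadialPlaneStack"))
  tri1 <- stackPlanes(stack)[[1]]
  pd <- dim(tri1$center@pixels)
  if (!is.null(model@meta$planeDim) &&
      !identical(as.integer(model@meta$planeDim), as.integer(pd)))
    stop("stack plane size (", pd[1], " x ", pd[2],
         ") does not match the training geometry (",
         model@meta$planeDim[1], " x ", model@meta$planeDim[2], ")")
  lapply(seq_along(stackPlanes(stack)), function(i) {
    tri <- stackPlanes(stack)[[i]]
    x <- cbind(.stdz(tri$center@pixels), .stdz(tri$lower@pixels),
               .stdz(tri$upper@pixels))
    p <- .unetForward(model, x, pd[1], pd[2])$probs
    new("PlanePrediction",
        prostateProb = matrix(p[, 1], pd[1], pd[2]),
        zoneProb = matrix(p[, 2], pd[1], pd[2]),
        planeIndex = i - 1L, s = tri$center@s, z = tri$center@z)
  })
}

#' Fivefold cross-validation over cases
#'
#' Cases are partitioned into folds by a seeded shuffle (fold sizes differ
#' by at most one); each fold's model is trained on the remaining folds and
#' predicts its own validation cases, so every case is predicted exactly
#' once, by a network that never saw it.
#'
#' @param samplesByCase named list of per-case sample lists from
#'   \code{\link{makeTrainingSamples}}.
#' @param modelCfg a \linkS4class{ModelConfig}.
#' @param trainCfg a \linkS4class{TrainConfig}; its seed drives fold
#'   assignment and per-fold initialisation.
#' @return list with \code{folds} (named integer vector), \code{models}
#'   (per fold) and \code{predictions} (per case, list of per-plane
#'   two-channel probability arrays).
#' @export
crossval <- function(samplesByCase, modelCfg, trainCfg) {
  n <- length(samplesByCase)
  k <- trainCfg@nFolds
  if (n < k) stop("fewer cases (", n, ") than folds (", k, ")")
  folds <- .withSeed(trainCfg@seed, sample(rep_len(seq_len(k), n)))
  names(folds) <- names(samplesByCase)
  models <- vector("list", k)
  predictions <- vector("list", n)
  names(predictions) <- names(samplesByCase)
  for (f in seq_len(k)) {
    trainS <- unlist(samplesByCase[folds != f], recursive = FALSE,
                     use.names = FALSE)
    valS <- unlist(samplesByCase[folds == f], recursive = FALSE,
                   use.names = FALSE)
    foldCfg <- trainConfig(nFolds = trainCfg@nFolds,
                           maxIterations = trainCfg@maxIterations,
                           patience = trainCfg@patience,
                           learningRate = trainCfg@learningRate,
                           batchSize = trainCfg@batchSize,
                           seed = trainCfg@seed + f)
    model <- buildNetwork(modelCfg, seed = trainCfg@seed * 1000L + f)
    model <- trainFold(model, trainS, valS, foldCfg)
    models[[f]] <- model
    for (nm in names(folds)[folds == f]) {
      predictions[[nm]] <- lapply(samplesByCase[[nm]], function(sm) {
        p <- .unetForward(model, sm$x, sm$H, sm$W)$probs
        list(prostate = matrix(p[, 1], sm$H, sm$W),
             zone = matrix(p[, 2], sm$H, sm$W), k = sm$k)
      })
    }
  }
  list(folds = folds, models = models, predictions = predictions)
}
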