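#' @include AllClasses.R
NULL

#' Construct Noise2Inverse hyper-parameters
#'
#' @param depth hidden layers of the mixed-scale dense network (the
#'   published study used 100; 20 is the desk-scale default).
#' @param learningRate Adam step size (published value 1e-3).
#' @param slab odd number of adjacent slices per input (published value 5).
#' @param batchSize minibatch size (published value 12).
#' @param epochs training epochs; the best-validation epoch is kept.
#' @param valFraction held-out fraction of slices (published split 80/20).
#' @param seed seed for weight init and shuffling.
#' @param maxDilation convolution dilations cycle `1..maxDilation`.
#' @return a validated [N2IHyperparams-class].
#' @export
n2iHyperparams <- function(depth = 20L, learningRate = 1e-3, slab = 5L,
                           batchSize = 12L, epochs = 100L, valFraction = 0.2,
                           seed = 1L, maxDilation = 10L) {
  new("N2IHyperparams", depth = as.integer(depth), learningRate = learningRate,
      slab = as.integer(slab), batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), valFraction = valFraction,
      seed = as.integer(seed), maxDilation = as.integer(maxDilation))
}

# stack the slab slices around slice s of volume (nz, H, W) into (H, W, slab)
slabStack <- function(vol, s, slab) {
  nz <- dim(vol)[1]
  idx <- reflectIndex(s + seq_len(slab) - 1L - (slab - 1L) %/% 2L, nz)
  aperm(vol[idx, , , drop = FALSE], c(2, 3, 1))
}

#' Build Noise2Inverse training pairs from sub-reconstructions
#'
#' For `K = 2` both orderings are emitted (A as input with B as target and
#' vice versa); for `K > 2` each leave-one-out assignment is emitted with
#' the mean of the remaining K - 1 sub-reconstructions as input.  Each
#' input is a slab of adjacent slices centred on the target slice, with
#' slice indices reflected at the volume boundary, so the pair count is
#' `K * n_slices`.
#'
#' @param srs a [SubReconSet-class] with K >= 2.
#' @param slab odd slab size.
#' @return an object of class `N2IPairs`: a list with the input array
#'   `(H, W, slab * n_pairs)`, the target array `(H, W, n_pairs)`, the
#'   target slice index of every pair and bookkeeping fields.
#' @export
makeTrainingPairs <- function(srs, slab = 5L) {
  stopifnot(is(srs, "SubReconSet"))
  slab <- as.integer(slab)
  if (srs@K < 2L) stop("K must be >= 2")
  if (slab %% 2L == 0L) stop("slab must be odd")
  K <- srs@K
  d <- dim(srs@subRecons[[1]])
  nz <- d[1]; H <- d[2]; W <- d[3]
  if (nz < 1L) stop("empty sub-reconstructions")
  np <- K * nz
  inputs <- array(0, c(H, W, slab * np))
  targets <- array(0, c(H, W, np))
  sliceIndex <- integer(np)
  p <- 0L
  for (k in seq_len(K)) {
    # input source: for K = 2 the other sub-volume; else mean of the others
    if (K == 2L) {
      src <- srs@subRecons[[3L - k]]
    } else {
      src <- Reduce(`+`, srs@subRecons[-k]) / (K - 1L)
    }
    tgt <- srs@subRecons[[k]]
    for (s in seq_len(nz)) {
      p <- p + 1L
      inputs[, , (p - 1L) * slab + seq_len(slab)] <- slabStack(src, s, slab)
      targets[, , p] <- tgt[s, , ]
      sliceIndex[p] <- s
    }
  }
  structure(list(inputs = inputs, targets = targets,
                 sliceIndex = sliceIndex, nSlices = nz, K = K, slab = slab),
            class = "N2IPairs")
}

# pool pairs from several samples (joint training across samples)
mergeTrainingPairs <- function(pairsList) {
  stopifnot(length(pairsList) >= 1L)
  slab <- pairsList[[1]]$slab
  H <- dim(pairsList[[1]]$targets)[1]
  W <- dim(pairsList[[1]]$targets)[2]
  np <- sum(vapply(pairsList, function(p) dim(p$targets)[3], 1))
  inputs <- array(0, c(H, W, slab * np))
  targets <- array(0, c(H, W, np))
  sliceIndex <- integer(np)
  off <- 0L
  for (p in pairsList) {
    n <- dim(p$targets)[3]
    inputs[, , off * slab + seq_len(n * slab)] <- p$inputs
    targets[, , off + seq_len(n)] <- p$targets
    sliceIndex[off + seq_len(n)] <- p$sliceIndex
    off <- off + n
  }
  structure(list(inputs = inputs, targets = targets, sliceIndex = sliceIndex,
                 nSlices = pairsList[[1]]$nSlices, K = pairsList[[1]]$K,
                 slab = slab),
            class = "N2IPairs")
}

#' Train the Noise2Inverse denoiser
#'
#' Minimizes the mean squared error between network output and target over
#' the training split with Adam; the split is by contiguous slice blocks
#' (the last `valFraction` of slice indices are validation) to limit
#' leakage between adjacent slices.  Inputs and targets are normalized by
#' the global training-set mean and standard deviation, which are stored in
#' the model so inference is self-contained.  The returned weights are
#' those of the best validation-loss epoch.  Training is bit-reproducible
#' for a fixed seed.
#'
#' @param pairs an `N2IPairs` dataset from [makeTrainingPairs()].
#' @param hp an [N2IHyperparams-class].
#' @return a [TrainedDenoiser-class]; `trainingLog(model)` holds the
#'   per-epoch train/validation curves (epoch 0 = untrained network).
#' @export
trainDenoiser <- function(pairs, hp = n2iHyperparams()) {
  stopifnot(inherits(pairs, "N2IPairs"), is(hp, "N2IHyperparams"))
  validObject(hp)
  np <- dim(pairs$targets)[3]
  if (np < 1L) stop("empty training dataset")
  if (pairs$slab != hp@slab)
    stop("pairs were built with slab ", pairs$slab, " but hp requests ", hp@slab)
  nz <- pairs$nSlices
  nVal <- floor(hp@valFraction * nz)
  valSlices <- if (nVal >= 1L) seq(nz - nVal + 1L, nz) else integer(0)
  valIdx <- which(pairs$sliceIndex %in% valSlices) - 1L
  trainIdx <- which(!(pairs$sliceIndex %in% valSlices)) - 1L
  if (length(trainIdx) == 0L) stop("no training pairs left after the split")

  trSel <- rep((trainIdx) * pairs$slab, each = pairs$slab) +
    seq_len(pairs$slab)
  shift <- mean(pairs$inputs[, , trSel])
  scale <- stats::sd(pairs$inputs[, , trSel])
  if (!is.finite(scale) || scale == 0) scale <- 1

  inputs <- (pairs$inputs - shift) / scale
  targets <- (pairs$targets - shift) / scale
  fit <- cpp_msd_train(inputs, targets, pairs$slab, hp@depth,
                       trainIdx, valIdx, hp@learningRate, hp@batchSize,
                       hp@epochs, as.double(hp@seed), hp@maxDilation)
  log <- data.frame(epoch = 0:hp@epochs, train = fit$log[, 1],
                    val = fit$log[, 2])
  new("TrainedDenoiser", weights = as.numeric(fit$params), hyperparams = hp,
      trainingLog = log, normalization = c(shift = shift, scale = scale),
      bestEpoch = as.integer(fit$bestEpoch))
}

#' Apply a trained denoiser to a sub-reconstruction set
#'
#' Runs the network on every sub-reconstruction (slab inputs built exactly
#' as in training) and averages the K outputs, the Noise2Inverse inference
#' rule.  The averaging is symmetric, so the result does not depend on the
#' order of the sub-reconstructions.
#'
#' @param model a [TrainedDenoiser-class].
#' @param srs a [SubReconSet-class] (any in-plane size; the network is
#'   fully convolutional).
#' @return denoised volume, array `(n_slices, H, W)`.
#' @export
denoiseVolume <- function(model, srs) {
  stopifnot(is(model, "TrainedDenoiser"), is(srs, "SubReconSet"))
  hp <- model@hyperparams
  d <- dim(srs@subRecons[[1]])
  nz <- d[1]
  shift <- model@normalization[1]
  scale <- model@normalization[2]
  acc <- array(0, d)
  for (k in seq_len(srs@K)) {
    # inference inputs mirror training: the other sub-volume for K = 2,
    # the K-1 leave-one-out mean otherwise
    vol <- if (srs@K == 2L) srs@subRecons[[k]] else
      Reduce(`+`, srs@subRecons[-k]) / (srs@K - 1L)
    inputs <- array(0, c(d[2], d[3], hp@slab * nz))
    for (s in seq_len(nz))
      inputs[, , (s - 1L) * hp@slab + seq_len(hp@slab)] <- slabStack(vol, s, hp@slab)
    pred <- cpp_msd_predict(model@weights, (inputs - shift) / scale,
                            hp@slab, hp@depth, hp@maxDilation)
    acc <- acc + aperm(array(pred, c(d[2], d[3], nz)), c(3, 1, 2))
  }
  acc / srs@K * scale + shift
}
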