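# build a SubReconSet directly from K volumes (bypassing reconstruction)
makeSrs <- function(vols) {
  K <- length(vols)
  new("SubReconSet", K = as.integer(K), subRecons = vols,
      angleSets = lapply(seq_len(K), function(k)
        projectionAngles(K * 4)[seq(k, K * 4, by = K)]),
      pixelSizeUm = 1.6)
}

# a denoiser whose network is the identity on the slab's centre slice:
# all convolution kernels zero, output weight 1 on the centre input channel
identityStub <- function(slab = 3L, depth = 4L) {
  sizes <- 9L * (slab + seq_len(depth) - 1L) + 1L
  outOff <- sum(sizes)
  nPar <- outOff + slab + depth + 1L
  P <- numeric(nPar)
  P[outOff + (slab + 1L) / 2L] <- 1
  new("TrainedDenoiser", weights = P,
      hyperparams = n2iHyperparams(depth = depth, slab = slab, epochs = 1),
      trainingLog = data.frame(epoch = 0:1, train = c(1, 1), val = c(1, 1)),
      normalization = c(shift = 0, scale = 1), bestEpoch = 1L)
}

randomVolume <- function(nz, n, seed) {
  set.seed(seed)
  array(rnorm(nz * n * n), c(nz, n, n))
}

test_that("training pairs follow the K x n_slices counting rule", {
  vols <- list(randomVolume(10, 12, 1), randomVolume(10, 12, 2))
  pairs <- makeTrainingPairs(makeSrs(vols), slab = 5)
  expect_identical(dim(pairs$targets)[3], 20L)        # K * n_slices
  expect_identical(dim(pairs$inputs)[3], 100L)        # slab per pair
  expect_error(makeTrainingPairs(makeSrs(vols), slab = 4), "odd")
})

test_that("for K = 2 both orderings are emitted, for K > 2 the leave-one-out mean", {
  A <- randomVolume(4, 8, 3); B <- randomVolume(4, 8, 4)
  pairs <- makeTrainingPairs(makeSrs(list(A, B)), slab = 3)
  # first block: input source B, target A; second block: input A, target B
  expect_equal(pairs$targets[, , 1], A[1, , ])
  expect_equal(pairs$inputs[, , 2], B[1, , ])         # centre of slab 1
  expect_equal(pairs$targets[, , 5], B[1, , ])
  expect_equal(pairs$inputs[, , 14], A[1, , ])      # centre of slab 5
  # K = 3 with identical sub-volumes: every input slab centre == its target
  V <- randomVolume(5, 8, 5)
  p3 <- makeTrainingPairs(makeSrs(list(V, V, V)), slab = 3)
  for (p in seq_len(dim(p3$targets)[3]))
    expect_equal(p3$inputs[, , (p - 1) * 3 + 2], p3$targets[, , p])
})

test_that("slab indices reflect at the boundary without repeating the edge", {
  # volume whose slice z is constant z: the slab at slice 1 must read 3,2,1,2,3
  nz <- 6
  V <- array(rep(seq_len(nz), 8 * 8), c(nz, 8, 8))   # V[z, y, x] = z
  pairs <- makeTrainingPairs(makeSrs(list(V, V)), slab = 5)
  got <- vapply(1:5, function(j) pairs$inputs[1, 1, j], 1)
  expect_equal(got, c(3, 2, 1, 2, 3))
})

test_that("training on identical sub-volumes drives the loss to near zero", {
  # degenerate target: input == target, so the network needs only to pass
  # its centre channel through; relative MSE should fall below 1e-4
  base <- randomVolume(6, 16, 6)
  smooth <- medianBaseline(base, 1)
  pairs <- makeTrainingPairs(makeSrs(list(smooth, smooth)), slab = 3)
  hp <- n2iHyperparams(depth = 8, slab = 3, epochs = 400, batchSize = 4,
                       learningRate = 5e-3, seed = 2)
  model <- trainDenoiser(pairs, hp)
  lg <- trainingLog(model)
  expect_lt(min(lg$train), 1e-4)    # inputs are normalized to unit variance
})

test_that("training is bit-reproducible for a fixed seed", {
  A <- randomVolume(5, 12, 7); B <- randomVolume(5, 12, 8)
  pairs <- makeTrainingPairs(makeSrs(list(A, B)), slab = 3)
  hp <- n2iHyperparams(depth = 4, slab = 3, epochs = 5, seed = 9)
  m1 <- trainDenoiser(pairs, hp)
  m2 <- trainDenoiser(pairs, hp)
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(m1@weights, m2@weights)
  hp2 <- hp; hp2@seed <- 10L
  m3 <- trainDenoiser(pairs, hp2)
  expect_false(identical(trainingLog(m1)$train, trainingLog(m3)$train))
})

test_that("denoising averages the network outputs symmetrically", {
  A <- randomVolume(5, 10, 11); B <- randomVolume(5, 10, 12)
  stub <- identityStub(slab = 3, depth = 4)
  srsAA <- makeSrs(list(A, A))
  expect_equal(denoiseVolume(stub, srsAA), A, tolerance = 1e-12)
  srsAB <- makeSrs(list(A, B))
  expect_equal(denoiseVolume(stub, srsAB), (A + B) / 2, tolerance = 1e-12)
  # order invariance
  srsBA <- makeSrs(list(B, A))
  expect_equal(denoiseVolume(stub, srsAB), denoiseVolume(stub, srsBA),
               tolerance = 1e-12)
})

test_that("validation loss decreases on a seeded noisy training run", {
  clean <- array(rep(diskImage(24, 8, 1), each = 8), c(8, 24, 24))
  set.seed(13)
  A <- clean + array(rnorm(length(clean), sd = 0.5), dim(clean))
  B <- clean + array(rnorm(length(clean), sd = 0.5), dim(clean))
  pairs <- makeTrainingPairs(makeSrs(list(A, B)), slab = 3)
  hp <- n2iHyperparams(depth = 8, slab = 3, epochs = 25, batchSize = 4, seed = 3)
  model <- trainDenoiser(pairs, hp)
  lg <- trainingLog(model)
  expect_lt(min(lg$val), lg$val[1])
  expect_identical(lg$val[model@bestEpoch + 1L], min(lg$val))
  # denoising with independent noise per split beats the single sub-volume
  den <- denoiseVolume(model, makeSrs(list(A, B)))
  mseDen <- mean((den - clean)^2)
  mseSub <- (mean((A - clean)^2) + mean((B - clean)^2)) / 2
  expect_lt(mseDen, mseSub)
})
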