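test_that("projection is zero at zero and linear in the volume", {
  a1 <- projectionAngles(36)
  z <- projectVolume(matrix(0, 32, 32), a1, voxelSizeUm = 1.6)[[1]]
  expect_equal(max(abs(sinogramData(z))), 0)
  set.seed(2)
  va <- matrix(runif(32 * 32), 32, 32)
  vb <- matrix(runif(32 * 32), 32, 32)
  pa <- sinogramData(projectVolume(va, a1, voxelSizeUm = 1.6)[[1]])
  pb <- sinogramData(projectVolume(vb, a1, voxelSizeUm = 1.6)[[1]])
  pab <- sinogramData(projectVolume(va + vb, a1, voxelSizeUm = 1.6)[[1]])
  expect_equal(pab, pa + pb, tolerance = 1e-10)
  expect_error(projectVolume(va, c(0, pi), voxelSizeUm = 1.6), "\\[0, pi\\)")
})

test_that("central ray through a uniform disk integrates to the chord length", {
  n <- 128; r <- 40; mu <- 0.3; h <- 1.6
  s <- projectVolume(diskImage(n, r, mu), projectionAngles(8),
                     voxelSizeUm = h)[[1]]
  central <- sinogramData(s)[1, round((n + 1) / 2)]
  analytic <- 2 * r * mu * h / 1000       # mu * mm
  expect_equal(central, analytic, tolerance = 0.02)
})

test_that("Poisson noise model matches the delta-method variance", {
  # 10^4 zero line integrals at I0 = 1000: post-log mean ~ 0, var ~ 1/I0
  s <- sinogram(matrix(0, 100, 100), projectionAngles(100))
  noisy <- simulateCounts(s, 1000, seed = 7)
  x <- as.numeric(sinogramData(noisy))
  expect_lt(abs(mean(x)), 3 * sqrt(1 / 1000 / length(x)) + 1e-3)
  expect_equal(var(x), 1 / 1000, tolerance = 0.1)
  expect_equal(photonsPerPixel(noisy), 1000)
})

test_that("noiseless passthrough, determinism and error cases of the noise model", {
  s <- sinogram(matrix(runif(50 * 20), 50, 20), projectionAngles(50))
  expect_identical(sinogramData(simulateCounts(s, Inf, seed = 1)),
                   sinogramData(s))
  n1 <- simulateCounts(s, 500, seed = 42)
  n2 <- simulateCounts(s, 500, seed = 42)
  expect_identical(sinogramData(n1), sinogramData(n2))
  expect_error(simulateCounts(s, 0, seed = 1), "positive")
  expect_error(simulateCounts(s, -5, seed = 1), "positive")
})

test_that("post-log noise is unbiased for transmissions away from zero", {
  p0 <- 0.5
  s <- sinogram(matrix(p0, 80, 80), projectionAngles(80))
  I0 <- 5000
  x <- as.numeric(sinogramData(simulateCounts(s, I0, seed = 3)))
  # delta-method bias bound ~ 1 / (2 I0 T)
  expect_lt(abs(mean(x) - p0), 1 / (2 * I0 * exp(-p0)) + 3e-3)
})

test_that("angular subsampling reproduces the projection-count arithmetic", {
  s <- sinogram(matrix(0, 3937, 4), projectionAngles(3937))
  expect_identical(nAngles(subsampleAngles(s, 2)), 1969L)
  expect_identical(nAngles(subsampleAngles(s, 3)), 1313L)
  expect_identical(nAngles(subsampleAngles(s, 4)), 985L)
  expect_identical(nAngles(subsampleAngles(s, 6)), 657L)
  expect_identical(sinogramData(subsampleAngles(s, 1)), sinogramData(s))
  expect_error(subsampleAngles(s, 4000), "exceeds")
  expect_error(subsampleAngles(s, 3, offset = 3), "offset")
})

test_that("subsampling composes as a stride product", {
  s <- sinogram(matrix(seq_len(360 * 3), 360, 3), projectionAngles(360))
  for (ab in list(c(2, 3), c(3, 2), c(2, 2), c(5, 4))) {
    twice <- subsampleAngles(subsampleAngles(s, ab[1]), ab[2])
    once <- subsampleAngles(s, ab[1] * ab[2])
    expect_identical(sinogramData(twice), sinogramData(once))
    expect_identical(angles(twice), angles(once))
  }
})
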