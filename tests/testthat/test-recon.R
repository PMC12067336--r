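test_that("FBP is zero at zero and linear in the sinogram", {
  z <- sinogram(matrix(0, 90, 32), projectionAngles(90))
  expect_equal(max(abs(fbp(z))), 0)
  set.seed(8)
  a <- matrix(runif(90 * 32), 90, 32)
  b <- matrix(runif(90 * 32), 90, 32)
  sa <- sinogram(a, projectionAngles(90))
  sb <- sinogram(b, projectionAngles(90))
  sab <- sinogram(2 * a + 3 * b, projectionAngles(90))
  expect_equal(fbp(sab), 2 * fbp(sa) + 3 * fbp(sb), tolerance = 1e-9)
  expect_error(fbp(sinogram(matrix(0, 1, 8), 0.1)), "at least 2")
})

test_that("FBP round-trips a uniform disk within 5%", {
  n <- 128; r <- 40; mu <- 0.3
  img <- diskImage(n, r, mu)
  s <- projectVolume(img, projectionAngles(360), voxelSizeUm = 1.6)[[1]]
  rec <- fbp(s)
  ctr <- (n + 1) / 2
  inside <- (row(rec) - ctr)^2 + (col(rec) - ctr)^2 <= (r - 3)^2
  expect_lt(sqrt(mean((rec[inside] - mu)^2)) / mu, 0.05)
})

test_that("fewer projections produce larger reconstruction error", {
  # low-projection artefact property: streaks grow as angles are removed
  img <- diskImage(96, 12, 0.3) +
    diskImage(96, 30, 0.1)
  few <- fbp(projectVolume(img, projectionAngles(48), voxelSizeUm = 1.6)[[1]])
  many <- fbp(projectVolume(img, projectionAngles(360), voxelSizeUm = 1.6)[[1]])
  expect_gt(sqrt(mean((few - img)^2)), sqrt(mean((many - img)^2)))
})

test_that("sinogram splitting partitions the angles by stride", {
  s <- sinogram(matrix(seq_len(657 * 4), 657, 4), projectionAngles(657))
  parts <- splitSinogram(s, 3)
  expect_identical(vapply(parts, nAngles, 1L), c(219L, 219L, 219L))
  one <- splitSinogram(s, 1)
  expect_length(one, 1)
  expect_identical(sinogramData(one[[1]]), sinogramData(s))
  s4 <- sinogram(matrix(1:8, 4, 2), projectionAngles(4))
  p2 <- splitSinogram(s4, 2)
  expect_equal(angles(p2[[1]]), projectionAngles(4)[c(1, 3)])
  expect_equal(angles(p2[[2]]), projectionAngles(4)[c(2, 4)])
  expect_error(splitSinogram(s4, 5), "exceeds")
})

test_that("split angle sets are disjoint and conserve the parent multiset", {
  set.seed(9)
  for (trial in 1:12) {
    n <- sample(10:1000, 1)
    K <- sample(2:6, 1)
    if (K > n) next
    s <- sinogram(matrix(0, n, 2), projectionAngles(n))
    parts <- splitSinogram(s, K)
    all_angles <- sort(unlist(lapply(parts, angles)))
    expect_equal(all_angles, sort(angles(s)))
    expect_false(anyDuplicated(unlist(lapply(parts, angles))) > 0)
    sizes <- vapply(parts, nAngles, 1L)
    expect_lte(diff(range(sizes)), 1L)
    expect_gte(sizes[1], sizes[K])    # the extra angle goes to split 0
  }
})

test_that("sub-reconstructions average back to the parent reconstruction", {
  img <- diskImage(64, 20, 0.3)
  s <- projectVolume(img, projectionAngles(180), voxelSizeUm = 1.6)[[1]]
  srs <- makeSubrecons(s, 2)
  parent <- fbp(s)
  avg <- (subRecons(srs)[[1]][1, , ] + subRecons(srs)[[2]][1, , ]) / 2
  rng <- max(parent) - min(parent)
  expect_lt(sqrt(mean((avg - parent)^2)) / rng, 0.05)
  # 657 angles at K = 2 -> sizes {329, 328}
  s657 <- sinogram(matrix(0, 657, 8), projectionAngles(657))
  srs2 <- makeSubrecons(s657, 2)
  expect_identical(vapply(angleSets(srs2), length, 1L), c(329L, 328L))
  expect_error(makeSubrecons(s, 1), "K >= 2")
})

test_that("Paganin retrieval has the right limits and strength", {
  flat <- matrix(1, 16, 16)
  pp <- paganinParams(distanceMm = 50)
  expect_equal(max(abs(paganinFilter(flat, pp))), 0, tolerance = 1e-12)
  # contact limit: distance -> 0 reduces to -log(transmission)
  set.seed(10)
  trans <- matrix(runif(24 * 24, 0.5, 1), 24, 24)
  p0 <- paganinParams(distanceMm = 0)
  expect_equal(paganinFilter(trans, p0), -log(trans), tolerance = 1e-9)
  # the packaged delta/beta ratio
  expect_equal(pp$delta / pp$beta, 232.46, tolerance = 1e-3)
  expect_error(paganinFilter(matrix(c(1, -0.1, 1, 1), 2, 2), pp), "positive")
})

test_that("the Paganin kernel is non-expansive on zero-mean perturbations", {
  set.seed(11)
  eps <- matrix(rnorm(32 * 32, sd = 0.01), 32, 32)
  eps <- eps - mean(eps)
  pp <- paganinParams(distanceMm = 100)
  out <- paganinFilter(1 + eps, pp)       # ~ -filtered(eps) to first order
  expect_lte(sqrt(sum(out^2)), sqrt(sum(eps^2)) * 1.02)
})

test_that("median baseline removes impulses and preserves constants", {
  const <- array(2.5, c(4, 8, 8))
  expect_equal(medianBaseline(const, 1), const)
  imp <- array(0, c(5, 9, 9)); imp[3, 5, 5] <- 10
  expect_equal(max(abs(medianBaseline(imp, 1))), 0)
  # salt-and-pepper denoising reduces MSE to the clean image
  set.seed(12)
  clean <- array(rep(diskImage(32, 10, 1), each = 4), c(4, 32, 32))
  noisy <- clean
  idx <- sample(length(noisy), 200)
  noisy[idx] <- sample(c(0, 2), 200, replace = TRUE)
  den <- medianBaseline(noisy, 1)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
})
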