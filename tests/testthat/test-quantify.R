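test_that("thresholds land between two well-separated modes", {
  x <- c(rep(10, 600), rep(200, 400))
  for (m in c("yen", "otsu")) {
    thr <- autoThreshold(x, m)
    expect_gt(thr, 10)
    expect_lt(thr, 200)
  }
  expect_error(autoThreshold(rep(5, 10)), "constant")
})

test_that("Yen and Otsu equal exhaustive brute-force criterion search", {
  for (seed in 1:100) {
    set.seed(seed)
    n1 <- sample(200:800, 1)
    x <- c(rnorm(n1, 30, sample(2:6, 1)),
           rnorm(1000 - n1, 90, sample(2:10, 1)))
    expect_equal(autoThreshold(x, "yen"), bruteForceYen(x), tolerance = 1e-12)
    expect_equal(autoThreshold(x, "otsu"), bruteForceOtsu(x), tolerance = 1e-12)
  }
})

test_that("component labeling, volume arithmetic and the 50-2000 um^3 filter", {
  m <- array(FALSE, c(8, 8, 8))
  m[2, 2, 2] <- TRUE                       # 1 voxel = 4.096 um^3 -> dropped
  lt <- labelLacunae(m, 1.6)
  expect_identical(nrow(lt), 0L)
  expect_identical(attr(lt, "nComponents"), 1L)
  expect_identical(attr(lt, "nRejected"), 1L)

  # 100-voxel blob: 409.6 um^3, kept
  m2 <- array(FALSE, c(10, 10, 10))
  m2[2:6, 2:6, 2:5] <- TRUE                # 5*5*4 = 100 voxels
  lt2 <- labelLacunae(m2, 1.6)
  expect_identical(nrow(lt2), 1L)
  expect_equal(lt2$volume_um3, 409.6)
  expect_equal(lt2$voxel_count * 1.6^3, lt2$volume_um3)

  # kept + rejected == total components
  set.seed(20)
  m3 <- array(runif(20^3) < 0.02, c(20, 20, 20))
  lt3 <- labelLacunae(m3, 5, vmin = 300, vmax = 2000)
  expect_identical(nrow(lt3) + attr(lt3, "nRejected"), attr(lt3, "nComponents"))
  expect_true(all(lt3$volume_um3 >= 300 & lt3$volume_um3 <= 2000))
  expect_error(labelLacunae(array(c(0, 2, 1), c(3, 1, 1)), 1.6), "binary")
})

test_that("26-connectivity joins diagonal voxels into one component", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE                       # corner-touching neighbour
  lt <- labelLacunae(m, 10, vmin = 0, vmax = Inf)
  expect_identical(attr(lt, "nComponents"), 1L)
})

test_that("aspect ratios match analytic second moments of digital shapes", {
  ball <- digitalEllipsoid(5, 5, 5)
  expect_equal(labelLacunae(ball, 1, vmin = 0, vmax = Inf)$aspect_ratio, 1,
               tolerance = 0.05)
  rod <- digitalEllipsoid(10, 5, 5)        # 2:1:1 -> 0.50
  expect_equal(labelLacunae(rod, 1, vmin = 0, vmax = Inf)$aspect_ratio, 0.5,
               tolerance = 0.05)
  # eigenvalue convention: the square of the axis ratio
  expect_equal(labelLacunae(rod, 1, vmin = 0, vmax = Inf,
                            aspectMethod = "eigenvalue")$aspect_ratio, 0.25,
               tolerance = 0.05)
})

test_that("aspect ratio is invariant under rigid rotation of the mask", {
  for (th in c(0, pi / 7, pi / 4, 1.1)) {
    m <- digitalEllipsoid(9, 4.5, 4.5, R = rotZ(th))
    ar <- labelLacunae(m, 1, vmin = 0, vmax = Inf)$aspect_ratio
    expect_equal(ar, 0.5, tolerance = 0.05)
  }
})

test_that("the KDE mode estimator is exact on degenerate input and on mixtures", {
  expect_equal(distributionMode(c(7, 7, 7)), 7)
  expect_equal(distributionMode(42), 42)
  expect_error(distributionMode(numeric(0)), "at least one")
  set.seed(21)
  x <- c(rnorm(8000, 400, 50), rnorm(2000, 1200, 100))
  expect_equal(distributionMode(x), 400, tolerance = 25 / 400)
  # duplication invariance at fixed bandwidth
  y <- rnorm(500, 10, 2)
  expect_equal(distributionMode(y, bandwidth = 0.5),
               distributionMode(c(y, y), bandwidth = 0.5))
})

test_that("mineral calibration is exact through two reference points", {
  # identity case: apparent densities equal the known densities
  vol <- array(0, c(4, 10, 10))
  r1 <- array(FALSE, dim(vol)); r1[, 1:3, ] <- TRUE
  r2 <- array(FALSE, dim(vol)); r2[, 8:10, ] <- TRUE
  vol[r1] <- 1.00 * massAttenuation("water") / 10
  vol[r2] <- 3.95 * massAttenuation("alumina") / 10
  cal <- calibrateMineralization(vol, list(r1, r2), c("water", "alumina"))
  expect_equal(cal$calibration@slope, 1, tolerance = 1e-9)
  expect_equal(cal$calibration@intercept, 0, tolerance = 1e-9)

  # hand-solved two-point system: apparent (0.8, 3.2) -> known (1.0, 3.95)
  vol2 <- array(0, c(4, 10, 10))
  vol2[r1] <- 0.08                         # gray: apparent 0.8 at mu/rho = 1
  vol2[r2] <- 0.32
  cal2 <- calibrateMineralization(vol2, list(r1, r2), c("water", "alumina"),
                                  knownDensities = c(1.0, 3.95),
                                  massAtten = c(1, 1))
  expect_equal(cal2$calibration@slope, 2.95 / 2.4, tolerance = 1e-9)
  expect_equal(applyCalibration(cal2$calibration, 0.08, haMassAtten = 1),
               1000, tolerance = 1e-9)
  expect_equal(applyCalibration(cal2$calibration, 0.32, haMassAtten = 1),
               3950, tolerance = 1e-9)

  # degenerate references refuse to fit
  volBad <- array(0.1, c(4, 10, 10))
  expect_error(calibrateMineralization(volBad, list(r1, r2),
                                       c("water", "alumina"),
                                       massAtten = c(1, 1)),
               "degenerate")
})

test_that("paired comparison reports tests, flags degeneracy, antisymmetric t", {
  set.seed(22)
  a <- rnorm(8, 100, 5)
  degenerate <- comparePaired(a, a)
  expect_true(degenerate@degenerate)
  expect_true(is.na(degenerate@pValue))

  d <- rnorm(8, 0, 1)
  b <- a + d - mean(d) + 3 * stats::sd(d)   # shift = 3 SD of differences
  cmp <- comparePaired(a, b)
  expect_false(cmp@degenerate)
  expect_lt(cmp@pValue, 0.01)
  expect_true(cmp@shapiroP >= 0 && cmp@shapiroP <= 1)
  expect_true(cmp@leveneP >= 0 && cmp@leveneP <= 1)
  swap <- comparePaired(b, a)
  expect_equal(swap@tStatistic, -cmp@tStatistic, tolerance = 1e-12)
  expect_equal(swap@pValue, cmp@pValue, tolerance = 1e-12)
  expect_error(comparePaired(1:2, 1:2), "3 pairs")
  expect_error(comparePaired(1:4, 1:5), "equal length")
})
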