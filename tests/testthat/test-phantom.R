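test_that("an empty phantom has no labels and an empty truth table", {
  spec <- defaultBoneSpec(gridShape = c(4, 48, 48), nLacunae = 0)
  vol <- generatePhantom(spec)
  expect_true(all(labelGrid(vol) == 0L))
  expect_identical(nrow(truthTable(vol)), 0L)
  # material map is still in place
  expect_equal(sort(unique(as.numeric(attenuationGrid(vol)))),
               sort(unique(c(spec@bathAttenuation, spec@matrixAttenuation,
                             spec@referenceInclusion$attenuation))))
})

test_that("generation is deterministic for a fixed seed", {
  v1 <- generatePhantom(tinySpec(seed = 11))
  v2 <- generatePhantom(tinySpec(seed = 11))
  expect_identical(attenuationGrid(v1), attenuationGrid(v2))
  expect_identical(labelGrid(v1), labelGrid(v2))
  expect_identical(truthTable(v1), truthTable(v2))
  v3 <- generatePhantom(tinySpec(seed = 12))
  expect_false(identical(labelGrid(v1), labelGrid(v3)))
})

test_that("voxelized lacuna volumes track the analytic ellipsoid volumes", {
  # digital ellipsoid with semi-axes (6.2, 4.0, 4.0) um at 1.6 um voxels:
  # analytic volume 4/3 pi a b c ~ 415.6 um^3 ~ 101.5 voxels
  h <- 1.6
  m <- digitalEllipsoid(6.2 / h, 4.0 / h, 4.0 / h)
  analytic <- 4 / 3 * pi * 6.2 * 4.0 * 4.0
  expect_equal(analytic, 415.6, tolerance = 1e-3)
  expect_lt(abs(sum(m) - analytic / h^3) / (analytic / h^3), 0.15)

  # and the generator's own truth table obeys the same 15% bound
  tr <- truthTable(generatePhantom(defaultBoneSpec(seed = 2)))
  relErr <- abs(tr$voxel_count * 1.6^3 - tr$volume_um3) / tr$volume_um3
  expect_true(all(relErr[tr$volume_um3 >= 50] <= 0.15))
})

test_that("default spec encodes the study conditions", {
  spec <- defaultBoneSpec()
  expect_equal(spec@voxelSizeUm, 1.6)
  expect_equal(spec@volumeModeUm3, 393)
  expect_equal(spec@aspectMean, 0.46)
  expect_equal(spec@boneCrossSectionMm2, 3.28)
  # matrix gray maps through the hydroxyapatite calibration to 1226 mgHA/cm^3
  expect_equal(spec@matrixAttenuation * 10 /
                 unname(massAttenuation("hydroxyapatite")),
               1.226, tolerance = 1e-9)
})

test_that("impossible placements fail with informative errors", {
  # volume range exceeding the grid is rejected up front
  expect_error(defaultBoneSpec(gridShape = c(4, 16, 16),
                               volumeRangeUm3 = c(100, 1e6)),
               "grid volume")
  # a lacuna too thick for the slab errors regardless of orientation
  expect_error(
    generatePhantom(defaultBoneSpec(gridShape = c(4, 64, 64), nLacunae = 1,
                                    volumeRangeUm3 = c(1400, 1600),
                                    aspectRatioRange = c(0.75, 0.85),
                                    seed = 1)),
    "cannot fit")
  # overcrowded bone region reports the achieved count
  expect_error(
    generatePhantom(defaultBoneSpec(gridShape = c(8, 48, 48),
                                    nLacunae = 50,
                                    volumeRangeUm3 = c(100, 300), seed = 1),
                    maxAttempts = 2000L),
    "placed only")
})

test_that("quantifying the noise-free phantom recovers the truth", {
  vol <- generatePhantom(defaultBoneSpec(seed = 4))
  tr <- truthTable(vol)
  win <- analysisWindow(vol)
  att <- attenuationGrid(vol)[win$z, win$y, win$x]
  thr <- autoThreshold(att, "yen")
  lt <- labelLacunae(att < thr, voxelSize(vol))
  inRange <- tr[tr$volume_um3 >= 50 & tr$volume_um3 <= 2000, ]
  # >= 95% of truth lacunae recovered within the filter window
  expect_gte(nrow(lt), ceiling(0.95 * nrow(inRange)))
  # match recovered components to truth by nearest centroid
  offY <- (win$y[1] - 1) * voxelSize(vol)
  offX <- (win$x[1] - 1) * voxelSize(vol)
  offZ <- (win$z[1] - 1) * voxelSize(vol)
  for (i in seq_len(nrow(lt))) {
    d2 <- (inRange$cx - (lt$cx[i] + offX))^2 +
      (inRange$cy - (lt$cy[i] + offY))^2 +
      (inRange$cz - (lt$cz[i] + offZ))^2
    j <- which.min(d2)
    expect_lt(sqrt(d2[j]), 10)     # um
    expect_lt(abs(lt$volume_um3[i] - inRange$volume_um3[j]) /
                inRange$volume_um3[j], 0.15)
    if (inRange$volume_um3[j] >= 100)
      expect_lt(abs(lt$aspect_ratio[i] - inRange$aspect_ratio[j]), 0.05)
  }
})
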