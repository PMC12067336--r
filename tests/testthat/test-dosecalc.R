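test_that("transmission follows Beer-Lambert with unit consistency", {
  expect_equal(transmission(data.frame(thickness_mm = numeric(0),
                                       mass_atten_cm2g = numeric(0),
                                       density_g_cm3 = numeric(0))), 1)
  # single medium with (mu/rho) * rho * t = ln 2 halves the beam
  expect_equal(transmission(data.frame(thickness_mm = 10,
                                       mass_atten_cm2g = log(2),
                                       density_g_cm3 = 1)), 0.5)
  # multiplicative over path concatenation
  m1 <- data.frame(thickness_mm = 3, mass_atten_cm2g = 0.4, density_g_cm3 = 1.2)
  m2 <- data.frame(thickness_mm = 7, mass_atten_cm2g = 1.1, density_g_cm3 = 2.5)
  expect_equal(transmission(rbind(m1, m2)),
               transmission(m1) * transmission(m2))
  expect_error(transmission(data.frame(thickness_mm = -1,
                                       mass_atten_cm2g = 1,
                                       density_g_cm3 = 1)), "thickness")
})

test_that("dose per scan is linear in projections and hits the preset point", {
  p <- paperGeometryPreset()
  expect_equal(dosePerScan(p), 8.0, tolerance = 1e-10)
  half <- p; half@nProjections <- p@nProjections / 2
  expect_equal(dosePerScan(half), dosePerScan(p) / 2)
  zero <- p; zero@nProjections <- 0
  expect_equal(dosePerScan(zero), 0)
  # exact scaling: k * dose(n) == dose(k * n)
  for (k in c(2, 3, 7)) {
    kn <- p; kn@nProjections <- p@nProjections * k
    expect_equal(dosePerScan(kn), k * dosePerScan(p))
  }
  # calibrated effective flux lands in the plausible beamline range
  expect_gt(p@fluxDensity, 25300)
  expect_lt(p@fluxDensity, 137000)
})

test_that("scan budget floors the unrounded dose and is monotone", {
  expect_identical(scansBeforeDamage(8), 4L)
  expect_identical(scansBeforeDamage(8 / 2), 8L)
  expect_identical(scansBeforeDamage(8 / 3), 13L)  # 13.125, not 12.96
  expect_identical(scansBeforeDamage(8 / 4), 17L)
  expect_identical(scansBeforeDamage(8 / 6), 26L)
  expect_error(scansBeforeDamage(0), "positive")
  doses <- sort(runif(20, 0.5, 20))
  scans <- scansBeforeDamage(doses)
  expect_true(all(diff(scans) <= 0L))
})

test_that("the dose table reproduces the full budget from one operating point", {
  tab <- doseTable(fractions = c(1, 2, 3, 4, 6))
  expect_identical(tab$projections, c(3937L, 1969L, 1313L, 985L, 657L))
  expect_equal(tab$dose_kGy_display, c(8.0, 4.0, 2.7, 2.0, 1.3))
  expect_identical(tab$scans_before_damage, c(4L, 8L, 13L, 17L, 26L))
})
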