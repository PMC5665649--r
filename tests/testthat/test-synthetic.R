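# Scenario presets, dataset generation, determinism, noise calibration and
# the incompetent-fraction injection.

test_that("presets encode the study designs and ground-truth constants", {
  sc <- buildScenario("GluK2_x_GluK5_titration")
  expect_equal(sc@tracerConc, 1e-9)
  expect_equal(range(sc@series), c(2e-10, 1.2e-6))
  expect_equal(1 / sc@system@KXY, 9.4e-9, tolerance = 1e-12)
  expect_false(sc@selfAssociation)
  sc2 <- buildScenario("GluA4_self_dilution")
  expect_equal(range(sc2@series), c(5e-10, 1.2e-6))
  expect_equal(1 / sc2@system@modelX@K12, 318e-9, tolerance = 1e-12)
  expect_true(sc2@selfAssociation)
  sc3 <- buildScenario("GluK1_self_titration")
  expect_equal(range(sc3@series), c(3e-10, 4e-5))
  expect_equal(1 / sc3@system@modelX@K12, 1.2e-6, tolerance = 1e-12)
  expect_error(buildScenario("no_such_preset"), "unknown preset")
  expect_error(buildScenario(design = "titration", kdX = 1e-6,
                             tracerConc = 1e-9, series = numeric(0)),
               "empty concentration series")
})

test_that("generation is deterministic under a fixed seed and matches the
           noiseless simulator at zero noise", {
  base <- buildScenario("GluK2_self_titration", nSeries = 3, nScans = 6,
                        scanInterval = 600,
                        geometry = RadialGeometry(nPoints = 100L))
  quiet <- base
  quiet@noise <- NoiseSpec(rms = 0, seed = 3L)
  ds0 <- generateDataset(quiet)
  # zero noise: output equals the deterministic reacting simulation
  i <- 2
  ld <- ds0$loadings
  sim <- simulateReactingSystem(base@system, base@rates,
                                loadingX = ld$loadingX[i],
                                geometry = base@geometry,
                                conditions = base@conditions,
                                times = base@scanTimes,
                                signalPerProtomer =
                                  ds0$truth$signalPerProtomer *
                                  ld$labeledFraction[i])
  expect_equal(ds0$scans[[i]]@signal, sim@signal, tolerance = 1e-12)
  # identical seed, identical bits
  noisy <- base
  noisy@noise <- NoiseSpec(rms = 0.01, seed = 11L)
  a <- generateDataset(noisy)
  b <- generateDataset(noisy)
  expect_identical(
    lapply(a$scans, scanSignal), lapply(b$scans, scanSignal))
  # different seed, different noise
  noisy2 <- base
  noisy2@noise <- NoiseSpec(rms = 0.01, seed = 12L)
  c2 <- generateDataset(noisy2)
  expect_false(identical(a$scans[[1]]@signal, c2$scans[[1]]@signal))
})

test_that("the empirical noise rms matches the nominal level within 10%", {
  base <- buildScenario("GluK2_self_titration", nSeries = 2, nScans = 8,
                        scanInterval = 600,
                        geometry = RadialGeometry(nPoints = 150L))
  quiet <- base; quiet@noise <- NoiseSpec(rms = 0, seed = 5L)
  noisy <- base; noisy@noise <- NoiseSpec(rms = 0.01, seed = 5L)
  d0 <- generateDataset(quiet)
  d1 <- generateDataset(noisy)
  for (i in 1:2) {
    resid <- d1$scans[[i]]@signal - d0$scans[[i]]@signal
    nominal <- 0.01 * max(d0$scans[[i]]@signal[1, ])
    expect_equal(sd(as.vector(resid)), nominal, tolerance = 0.1)
  }
})

test_that("incompetent fraction injection lowers the normalized sw plateau
           to 1 - fraction", {
  sc <- buildScenario("GluK2_self_titration", nSeries = 2, nScans = 4,
                      scanInterval = 900,
                      geometry = RadialGeometry(nPoints = 100L))
  expect_error(injectIncompetentFraction(sc, 1.2), "fraction")
  same <- injectIncompetentFraction(sc, 0)
  expect_equal(same@incompetentFraction, 0)
  inj <- injectIncompetentFraction(sc, 0.23)
  expect_equal(inj@truth$incompetent_fraction, 0.23)
  # algebraic plateau check at saturating concentration
  m <- HomoDimerModel(KD = 1 / inj@system@modelX@K12, s1 = 3.8, s2 = 5.8,
                      fInc = 0.23)
  expect_equal(normalizeSw(swHomoIsotherm(1, m), 3.8, 5.8), 0.77,
               tolerance = 1e-3)
  # and the generated signal contains the extra monomer contribution
  inj@noise <- NoiseSpec(rms = 0, seed = 1L)
  sc@noise <- NoiseSpec(rms = 0, seed = 1L)
  dInj <- generateDataset(inj)
  d0 <- generateDataset(sc)
  expect_false(isTRUE(all.equal(dInj$scans[[2]]@signal,
                                d0$scans[[2]]@signal)))
})

test_that("isotherm-level simulation reproduces the algebraic model plus
           noise", {
  sc <- buildScenario("GluK2_x_GluK5_titration", nSeries = 8)
  iso <- simulateSwIsotherm(sc, swNoiseSd = 0, seed = 1L)
  expect_equal(iso@sw,
               swHeteroIsotherm(rep(sc@tracerConc, 8), sc@series, sc@system),
               tolerance = 1e-12)
  iso2 <- simulateSwIsotherm(sc, swNoiseSd = 0.02, seed = 2L)
  expect_false(isTRUE(all.equal(iso@sw, iso2@sw)))
  expect_equal(length(iso2@sw), 8)
})

test_that("reference constants carry the measured values and bound flags", {
  k <- referenceConstants("kainate")
  g25 <- k[k$unlabeled == "GluK2" & k$labeled == "GluK5", ]
  expect_equal(g25$kd_M, 9.4e-9)
  expect_equal(c(g25$ci_lower_M, g25$ci_upper_M), c(8e-9, 1.1e-8))
  expect_equal(k[k$unlabeled == "GluK3" & k$labeled == "GluK3", "bound"],
               "upper")
  expect_equal(k[k$unlabeled == "GluK4" & k$labeled == "GluK4", "bound"],
               "lower")
  a <- referenceConstants("ampa")
  expect_equal(a[a$unlabeled == "GluA2" & a$labeled == "GluA2", "kd_M"],
               21.1e-9)
  # CIs bracket the point estimates everywhere they exist
  all <- referenceConstants()
  ok <- !is.na(all$ci_lower_M)
  expect_true(all(all$ci_lower_M[ok] <= all$kd_M[ok] &
                  all$kd_M[ok] <= all$ci_upper_M[ok]))
})
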