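# c(s) inversion, transport-method sw, background handling and peaks.

test_that("a noiseless single species is recovered at its s-value with the
           loading signal", {
  sp <- SedimentingSpecies("dimer", 5.8, frictionalRatio = 1.5)
  sc <- solveLamm(sp, fixGeom, fixCond, 1e-6, fixTimes)
  d <- fitCS(sc, fixGrid, "maxent", kernel = sharedKernel())
  ds <- mean(diff(fixGrid@sValues))
  expect_equal(swTransport(d, 2, 8), 5.8, tolerance = ds / 5.8)
  expect_equal(d@metadata$totalSignal, 1e-6, tolerance = 0.01)
  pk <- peakPositions(d)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$s, 5.8, tolerance = 0.15 / 5.8)
})

test_that("all-zero data give an empty distribution, not an error", {
  sc <- ScanSet(fixTimes, sharedKernel()$radii,
                matrix(0, length(fixTimes), length(sharedKernel()$radii)),
                conditions = fixCond, geometry = fixGeom)
  d <- fitCS(sc, fixGrid, kernel = sharedKernel())
  expect_true(all(d@coefficients == 0))
  expect_error(swTransport(d, 2, 8), "zero integrated signal")
})

test_that("two species at equal signal resolve into two peaks with a 1:1
           integral ratio", {
  s1 <- solveLamm(SedimentingSpecies("m", 3.8, frictionalRatio = 1.5),
                  fixGeom, fixCond, 1e-6, fixTimes)
  s2 <- solveLamm(SedimentingSpecies("d", 5.8, frictionalRatio = 1.5),
                  fixGeom, fixCond, 1e-6, fixTimes)
  mix <- ScanSet(fixTimes, s1@radii, s1@signal + s2@signal,
                 conditions = fixCond, geometry = fixGeom)
  d <- fitCS(mix, fixGrid, "maxent", kernel = sharedKernel())
  pk <- peakPositions(d)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$s, c(3.8, 5.8), tolerance = 0.04)
  expect_equal(pk$signal[1] / pk$signal[2], 1, tolerance = 0.05)
  # sw equals the signal-weighted average of the input s-values within 1%
  expect_equal(swTransport(d, 2, 8), 4.8, tolerance = 0.01)
  # tikhonov route recovers the same transport average
  dt <- fitCS(mix, fixGrid, "tikhonov", kernel = sharedKernel())
  expect_equal(swTransport(dt, 2, 8), 4.8, tolerance = 0.01)
})

test_that("an all-dimer sample shows a single peak at the dimer s-value", {
  # very tight dimer: no dissociation anywhere in the dilution range
  sysK3 <- HeteroSystemModel(HomoDimerModel(KD = 5e-11, s1 = 3.8, s2 = 5.8),
                             HomoDimerModel(K12 = 0, s1 = 3.8, s2 = 5.8),
                             KXY = 0, sXY = 5.6)
  sim <- simulateReactingSystem(sysK3, RateParams(), loadingX = 1e-8,
                                geometry = fixGeom, conditions = fixCond,
                                times = fixTimes)
  d <- fitCS(sim, fixGrid, "maxent", kernel = sharedKernel())
  pk <- peakPositions(d)
  expect_equal(pk$s[which.max(pk$signal)], 5.8, tolerance = 0.15 / 5.8)
})

test_that("a free-label contaminant appears as an extra low-s peak that the
           integration window can exclude", {
  grid <- SGrid(1.5, 8, n = 40, frictionalRatio = 1.5)
  dim6 <- solveLamm(SedimentingSpecies("d", 6.25, frictionalRatio = 1.5),
                    fixGeom, fixCond, 1e-6, fixTimes)
  egfp <- solveLamm(SedimentingSpecies("egfp", 2.5, frictionalRatio = 1.5),
                    fixGeom, fixCond, 2e-7, fixTimes)
  mix <- ScanSet(fixTimes, dim6@radii, dim6@signal + egfp@signal,
                 conditions = fixCond, geometry = fixGeom)
  d <- fitCS(mix, grid, "maxent")
  pk <- peakPositions(d)
  expect_gte(nrow(pk), 2)
  expect_equal(min(pk$s), 2.5, tolerance = 0.1)
  # integrating from 3 S up excludes the contaminant
  expect_equal(swTransport(d, 3, 8), 6.25, tolerance = 0.01)
})

test_that("background subtraction round-trips and checks compatibility", {
  sp <- SedimentingSpecies("m", 3.8, frictionalRatio = 1.5)
  sc <- solveLamm(sp, fixGeom, fixCond, 1e-7, fixTimes)
  zero <- ScanSet(fixTimes, sc@radii, matrix(0, nrow(sc@signal),
                                             ncol(sc@signal)),
                  conditions = fixCond, geometry = fixGeom)
  expect_equal(subtractBackground(sc, zero)@signal, sc@signal)
  self <- subtractBackground(sc, sc)
  expect_true(all(self@signal == 0))
  # injected constant offset is removed exactly
  bsa <- ScanSet(fixTimes, sc@radii, matrix(0.37, nrow(sc@signal),
                                            ncol(sc@signal)),
                 conditions = fixCond, geometry = fixGeom)
  noisy <- ScanSet(fixTimes, sc@radii, sc@signal + 0.37,
                   conditions = fixCond, geometry = fixGeom)
  rec <- subtractBackground(noisy, bsa)
  # absolute rounding of (signal + 0.37) - 0.37 limits the attainable
  # agreement for the ~1e-7 signal levels
  expect_equal(rec@signal, sc@signal, tolerance = 1e-8)
  expect_true(isTRUE(rec@metadata$backgroundSubtracted))
  bad <- ScanSet(fixTimes, sc@radii[10:100], sc@signal[, 10:100],
                 conditions = fixCond,
                 geometry = RadialGeometry(sc@radii[10] - 1e-4,
                                           sc@radii[100] + 1e-4,
                                           nPoints = 91L))
  expect_error(subtractBackground(sc, bad), "incompatible")
})
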