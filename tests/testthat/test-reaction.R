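# Reaction-coupled boundary simulation: equilibrium projection, kinetic
# limits, conservation and consistency with independent single-species runs.

test_that("equilibrium projection solves the local mass-action system", {
  expect_equal(localEquilibriumProjection(0, 0, systemK2K5),
               list(cX1 = 0, cX2 = 0, cY1 = 0, cY2 = 0, cXY = 0))
  # single component at ctot = KD: protomer monomer fraction 1/2
  sysHomo <- HeteroSystemModel(modelK2, HomoDimerModel(K12 = 0, s1 = 3.8,
                                                       s2 = 5.8),
                               KXY = 0, sXY = 5.6)
  eq <- localEquilibriumProjection(163e-9, 0, sysHomo)
  expect_equal(eq$cX1 / 163e-9, 0.5, tolerance = 1e-10)
  # random totals agree with the brute-force oracle
  set.seed(7)
  for (k in 1:25) {
    KX <- 10^runif(1, 4, 10); KY <- 10^runif(1, 4, 10)
    KXY <- 10^runif(1, 4, 10)
    xt <- 10^runif(1, -10, -5); yt <- 10^runif(1, -10, -5)
    sys <- HeteroSystemModel(HomoDimerModel(K12 = KX, s1 = 3.8, s2 = 5.8),
                             HomoDimerModel(K12 = KY, s1 = 3.8, s2 = 5.8),
                             KXY = KXY, sXY = 5.6)
    eq <- localEquilibriumProjection(xt, yt, sys)
    bf <- bruteForceHetero(xt, yt, KX, KY, KXY)
    expect_lt(abs(eq$cX1 - bf$cX1) / bf$cX1, 1e-8)
  }
})

test_that("a non-associating system equals the superposition of independent
           single-species solutions", {
  sys0 <- HeteroSystemModel(HomoDimerModel(K12 = 0, s1 = 3.8, s2 = 5.8),
                            HomoDimerModel(K12 = 0, s1 = 4.4, s2 = 6.25),
                            KXY = 0, sXY = 5.6)
  times <- fixTimes[seq(1, 18, by = 3)]
  sim <- simulateReactingSystem(sys0, RateParams(), loadingX = 1e-9,
                                loadingY = 3e-9, geometry = fixGeom,
                                conditions = fixCond, times = times)
  mono <- solveLamm(SedimentingSpecies("x", 3.8, frictionalRatio = 1.5),
                    fixGeom, fixCond, 1e-9, times)
  # Y is unlabeled: the observed signal is the X monomer alone (the two
  # runs use slightly different internal sub-steps, hence the tolerance)
  expect_equal(sim@signal, mono@signal, tolerance = 5e-3)
})

test_that("instantaneous-equilibrium mode keeps the local mass-action
           residual at zero and conserves protomers", {
  sys <- HeteroSystemModel(modelK1, modelK2, KDXY = 1.8e-6, sXY = 5.6)
  times <- fixTimes[seq(1, 18, by = 3)]
  sim <- simulateReactingSystem(sys, RateParams(), loadingX = 1e-9,
                                loadingY = 1e-6, geometry = fixGeom,
                                conditions = fixCond, times = times,
                                keepSpecies = TRUE)
  expect_lt(sim@metadata$massErrorX, 1e-3)
  expect_lt(sim@metadata$massErrorY, 1e-3)
  sp <- sim@metadata$species
  j <- length(times)
  KXY <- sys@KXY
  resid <- abs(sp$cXY[j, ] - KXY * sp$cX1[j, ] * sp$cY1[j, ])
  denom <- pmax(sp$cXY[j, ], 1e-15 * 1e-9)
  expect_lt(max(resid / denom), 1e-6)
})

test_that("fast finite-rate kinetics converge to the equilibrium limit", {
  sysHomo <- HeteroSystemModel(modelK2, HomoDimerModel(K12 = 0, s1 = 3.8,
                                                       s2 = 5.8),
                               KXY = 0, sXY = 5.6)
  times <- c(1800, 5400)
  eqm <- simulateReactingSystem(sysHomo, RateParams(), loadingX = 163e-9,
                                geometry = fixGeom, conditions = fixCond,
                                times = times)
  fast <- simulateReactingSystem(sysHomo,
                                 RateParams(koff = c(XX = 10),
                                            instantaneous = FALSE),
                                 loadingX = 163e-9, geometry = fixGeom,
                                 conditions = fixCond, times = times)
  # compare within the boundary region (the back-diffusion pileup at the
  # bottom dominates the raw maximum and would mask boundary differences)
  win <- eqm@radii <= fixGeom@bottom - 0.15
  relRMS <- function(a, b) sqrt(mean((a@signal[2, win] - b@signal[2, win])^2)) /
    max(a@signal[2, win])
  expect_lt(relRMS(eqm, fast), 0.005)
  # slow kinetics deviate visibly from the equilibrium limit
  slow <- simulateReactingSystem(sysHomo,
                                 RateParams(koff = c(XX = 1e-5),
                                            instantaneous = FALSE),
                                 loadingX = 163e-9, geometry = fixGeom,
                                 conditions = fixCond, times = times)
  expect_gt(relRMS(eqm, slow), 0.02)
})

test_that("finite-rate hetero kinetics conserve protomers per component", {
  sys <- systemK2K5
  rates <- RateParams(koff = c(XX = 1e-3, YY = 1e-3, XY = 1e-3),
                      instantaneous = FALSE)
  sim <- simulateReactingSystem(sys, rates, loadingX = 1e-9,
                                loadingY = 2e-7, geometry = fixGeom,
                                conditions = fixCond, times = c(2700, 5400))
  expect_lt(sim@metadata$massErrorX, 1e-3)
  expect_lt(sim@metadata$massErrorY, 1e-3)
})

test_that("rate consistency kon = koff K is enforced", {
  expect_error(RateParams(koff = c(XX = 1e-3), kon = c(XX = 2e3),
                          K = c(XX = 1e6), instantaneous = FALSE),
               "inconsistent")
  expect_silent(RateParams(koff = c(XX = 1e-3), kon = c(XX = 1e3),
                           K = c(XX = 1e6), instantaneous = FALSE))
})
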