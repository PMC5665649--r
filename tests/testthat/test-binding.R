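# Mass-action algebra, sw isotherm models and thermodynamic conversions.

test_that("monomer-dimer equilibrium has the closed-form limits", {
  expect_equal(solveHomo(3e-7, HomoDimerModel(K12 = 0, s1 = 3.8, s2 = 5.8)),
               list(c1 = 3e-7, c2 = 0))
  # at ctot = KD the protomer monomer fraction is exactly 1/2
  eq <- solveHomo(163e-9, modelK2)
  expect_equal(eq$c1 / 163e-9, 0.5, tolerance = 1e-12)
  expect_equal(eq$c1 + 2 * eq$c2, 163e-9, tolerance = 1e-12)
  # 15 uM of a 163 nM-KD species is dimer-dominated
  eq2 <- solveHomo(15e-6, modelK2)
  expect_lt(eq2$c1 / 15e-6, 0.1)
})

test_that("coupled hetero equilibrium matches the bisection oracle on random
           draws and reduces to the homo solution", {
  set.seed(42)
  n <- 400
  KX <- 10^runif(n, 3, 12); KY <- 10^runif(n, 3, 12)
  KXY <- 10^runif(n, 3, 12)
  xt <- 10^runif(n, -12, -4); yt <- 10^runif(n, -12, -4)
  for (i in seq_len(n)) {
    sys <- HeteroSystemModel(
      HomoDimerModel(K12 = KX[i], s1 = 3.8, s2 = 5.8),
      HomoDimerModel(K12 = KY[i], s1 = 3.8, s2 = 5.8),
      KXY = KXY[i], sXY = 5.6)
    eq <- solveHetero(xt[i], yt[i], sys)
    bf <- bruteForceHetero(xt[i], yt[i], KX[i], KY[i], KXY[i])
    expect_lt(abs(eq$cX1 - bf$cX1) / bf$cX1, 1e-6)
    # conservation at the solution
    expect_lt(abs(eq$cX1 + 2 * eq$cX2 + eq$cXY - xt[i]) / xt[i], 1e-10)
    expect_lt(abs(eq$cY1 + 2 * eq$cY2 + eq$cXY - yt[i]) / yt[i], 1e-10)
  }
  # KXY = 0 decouples into two independent homo equilibria
  sys0 <- HeteroSystemModel(modelK1, modelK2, KXY = 0, sXY = 5.6)
  eq <- solveHetero(2e-7, 5e-8, sys0)
  expect_equal(eq$cX1, solveHomo(2e-7, modelK1)$c1, tolerance = 1e-12)
  expect_equal(eq$cY1, solveHomo(5e-8, modelK2)$c1, tolerance = 1e-12)
  expect_equal(eq$cXY, 0)
  # degenerate Y (both constants zero) equals solveHomo exactly
  sysD <- HeteroSystemModel(modelK1, HomoDimerModel(K12 = 0, s1 = 3.8,
                                                    s2 = 5.8),
                            KXY = 0, sXY = 5.6)
  eqD <- solveHetero(1e-6, 0, sysD)
  expect_equal(eqD$cX1, solveHomo(1e-6, modelK1)$c1, tolerance = 1e-14)
})

test_that("tracer limit gives the analytic bound fraction", {
  sys <- systemK2K5
  yt <- 2e-7
  cY1 <- solveHomo(yt, modelK2)$c1
  boundAnalytic <- sys@KXY * cY1 / (1 + sys@KXY * cY1)
  eq <- solveHetero(1e-13, yt, sys)       # X far below every KD
  expect_equal(eq$cXY / 1e-13, boundAnalytic, tolerance = 1e-4)
})

test_that("sw isotherms have the right asymptotes, midpoint and monotonicity", {
  expect_equal(swHomoIsotherm(1e-15, modelK2), 3.8, tolerance = 1e-4)
  expect_equal(swHomoIsotherm(10, modelK2), 5.8, tolerance = 1e-3)
  expect_equal(swHomoIsotherm(163e-9, modelK2), (3.8 + 5.8) / 2,
               tolerance = 1e-12)
  ct <- 10^seq(-10, -4, length.out = 40)
  expect_true(all(diff(swHomoIsotherm(ct, modelK2)) > 0))
  # incompetent fraction caps the normalized plateau at 1 - fInc
  mInc <- HomoDimerModel(KD = 28.4e-9, s1 = 4.4, s2 = 6.25, fInc = 0.23)
  plateau <- normalizeSw(swHomoIsotherm(1, mInc), 4.4, 6.25)
  expect_equal(plateau, 0.77, tolerance = 1e-3)
  # hetero: reduces to homo at zero titrant, saturates at sXY
  swv <- swHeteroIsotherm(1e-9, 0, systemK2K5)
  expect_equal(swv, swHomoIsotherm(1e-9, modelK5), tolerance = 1e-10)
  expect_equal(swHeteroIsotherm(1e-9, 0.3, systemK2K5), 5.6,
               tolerance = 1e-2)
  yc <- 10^seq(-10, -5, length.out = 30)
  expect_true(all(diff(swHeteroIsotherm(1e-9, yc, systemK2K5)) > 0))
})

test_that("GluK1/GluK2 competition leaves the tracer short of saturation at
           20 uM titrant", {
  sys <- HeteroSystemModel(modelK1, modelK2, KDXY = 1.8e-6, sXY = 5.6)
  swv <- swHeteroIsotherm(1e-9, 20e-6, sys)
  # well below saturation (significant free tracer monomer), yet clearly
  # shifted from the pure monomer
  expect_lt(normalizeSw(swv, 3.8, 5.6), 0.9)
  expect_gt(normalizeSw(swv, 3.8, 5.6), 0.2)
})

test_that("raising a competing homo constant strictly lowers heterodimer", {
  KYgrid <- 10^seq(5, 9, length.out = 9)
  cXY <- vapply(KYgrid, function(KY) {
    sys <- HeteroSystemModel(modelK1,
                             HomoDimerModel(K12 = KY, s1 = 3.8, s2 = 5.8),
                             KDXY = 5e-8, sXY = 5.6)
    solveHetero(1e-7, 1e-7, sys)$cXY
  }, numeric(1))
  expect_true(all(diff(cXY) < 0))
  # and raising KXY never lowers it
  KXYgrid <- 10^seq(5, 9, length.out = 9)
  cXY2 <- vapply(KXYgrid, function(KXY) {
    sys <- HeteroSystemModel(modelK1, modelK2, KXY = KXY, sXY = 5.6)
    solveHetero(1e-7, 1e-7, sys)$cXY
  }, numeric(1))
  expect_true(all(diff(cXY2) > 0))
})

test_that("free-energy and rate conversions reproduce their identities", {
  expect_equal(deltaGFromKd(1), 0)
  expect_true(all(diff(deltaGFromKd(10^seq(-9, -3))) > 0))
  expect_equal(konFromKoffKd(0, 1e-8), 0, ignore_attr = TRUE)
  k <- konFromKoffKd(3e-3, 21.1e-9, bound = "lower")
  expect_equal(attr(k, "bound"), "lower")
  # fold ratio is antisymmetric under swap
  r <- foldRatio(21.1e-9, 1.3e-9)
  expect_equal(attr(foldRatio(1.3e-9, 21.1e-9), "raw"),
               1 / attr(r, "raw"), tolerance = 1e-12)
  expect_equal(foldRatio(5e-8, 5e-8), 1, ignore_attr = TRUE)
})

test_that("normalizeSw maps the monomer-dimer range onto [0, 1]", {
  expect_equal(normalizeSw(3.8, 3.8, 5.8), 0)
  expect_equal(normalizeSw(5.8, 3.8, 5.8), 1)
  expect_equal(normalizeSw(swHomoIsotherm(163e-9, modelK2), 3.8, 5.8), 0.5,
               tolerance = 1e-12)
  expect_error(normalizeSw(4, 5.8, 3.8), "exceed")
})
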