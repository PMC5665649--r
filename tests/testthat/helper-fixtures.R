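# Shared small fixtures: reduced radial grids and scan schedules keep the
# suite fast while staying well inside the solver's resolved regime.

fixCond <- RunConditions()
fixGeom <- RadialGeometry(nPoints = 160L)
fixTimes <- seq(300, 5400, by = 300)          # 18 scans
fixGrid <- SGrid(2, 8, n = 40, frictionalRatio = 1.5)

# kainate-like monomer-dimer models
modelK1 <- HomoDimerModel(KD = 1.2e-6, s1 = 3.8, s2 = 5.8)
modelK2 <- HomoDimerModel(KD = 163e-9, s1 = 3.8, s2 = 5.8)
modelK5 <- HomoDimerModel(KD = 3.5e-4, s1 = 3.8, s2 = 5.8)
systemK2K5 <- HeteroSystemModel(modelK5, modelK2, KDXY = 9.4e-9, sXY = 5.6)

# one shared c(s) kernel for the standard layout, built on first use
.kernelCache <- new.env(parent = emptyenv())
sharedKernel <- function() {
  if (is.null(.kernelCache$k)) {
    tmpl <- solveLamm(SedimentingSpecies("tmpl", 5, frictionalRatio = 1.5),
                      fixGeom, fixCond, 1, fixTimes)
    .kernelCache$k <- csKernel(tmpl, fixGrid)
  }
  .kernelCache$k
}

# brute-force coupled-equilibrium oracle: bisection on free X monomer with
# the closed-form quadratic for free Y monomer (independent of the package's
# damped-Newton implementation)
bruteForceHetero <- function(cXtot, cYtot, KX, KY, KXY, iter = 200) {
  if (cXtot == 0) {
    cY1 <- if (KY > 0) 2 * cYtot / (1 + sqrt(1 + 8 * KY * cYtot)) else cYtot
    return(list(cX1 = 0, cY1 = cY1))
  }
  lo <- 0; hi <- cXtot
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    b <- 1 + KXY * mid
    cY1 <- if (KY > 0) 2 * cYtot / (b + sqrt(b^2 + 8 * KY * cYtot)) else
      cYtot / b
    f <- mid + 2 * KX * mid^2 + KXY * mid * cY1 - cXtot
    if (f > 0) hi <- mid else lo <- mid
  }
  cX1 <- (lo + hi) / 2
  b <- 1 + KXY * cX1
  cY1 <- if (KY > 0) 2 * cYtot / (b + sqrt(b^2 + 8 * KY * cYtot)) else
    cYtot / b
  list(cX1 = cX1, cY1 = cY1)
}
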