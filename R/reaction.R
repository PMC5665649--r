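# Forward simulation of sedimentation boundaries for reversibly dimerizing
# systems: coupled Lamm equations with chemical source terms, by operator
# splitting. Each sub-step transports every species with the finite-volume
# backward-Euler scheme of solveLamm, then applies the local chemistry -- an
# exact mass-action relaxation (homodimer) or sub-cycled explicit integration
# (competitive hetero system) in finite-rate mode, or an algebraic projection
# onto the equilibrium manifold in instantaneous-equilibrium mode.

#' Project local totals onto the mass-action equilibrium manifold
#'
#' Given total protomer concentrations of components X and Y at one (or many)
#' grid points, returns the unique non-negative species concentrations
#' satisfying the coupled equilibria and conservation.
#'
#' @param cXtot,cYtot total protomer concentrations (M), vectorized.
#' @param system A [HeteroSystemModel-class].
#' @return List `cX1`, `cX2`, `cY1`, `cY2`, `cXY`.
#' @export
localEquilibriumProjection <- function(cXtot, cYtot, system) {
  solveHetero(cXtot, cYtot, system)
}

# Exact relaxation of the homodimer mass action system over time dt at fixed
# local protomer total: c2' = kon (ctot - 2 c2)^2 - koff c2 is a constant
# coefficient Riccati equation with closed-form solution.
.relaxHomo <- function(c1, c2, kon, koff, dt) {
  ctot <- c1 + 2 * c2
  if (kon == 0) {
    c2n <- c2 * exp(-koff * dt)
    return(list(c1 = ctot - 2 * c2n, c2 = c2n))
  }
  a <- 4 * kon
  b <- -(4 * kon * ctot + koff)
  cc <- kon * ctot^2
  disc <- sqrt(pmax(b^2 - 4 * a * cc, 0))     # = sqrt(koff^2 + 8 kon koff ctot)
  r1 <- (-b - disc) / (2 * a)                 # stable equilibrium root
  r2 <- (-b + disc) / (2 * a)
  e <- exp(pmax(-disc * dt, -700))
  u0 <- (c2 - r1) / (c2 - r2)
  u <- u0 * e
  c2n <- (r1 - r2 * u) / (1 - u)
  c2n <- ifelse(disc * dt > 500, r1, c2n)
  c2n <- pmin(pmax(c2n, 0), ctot / 2)
  list(c1 = ctot - 2 * c2n, c2 = c2n)
}

# One finite-rate chemistry step for the 3-reaction competitive system,
# sub-cycled explicit Heun integration.
.relaxHetero <- function(state, kon, koff, dt) {
  rate <- function(s) {
    qXX <- kon[["XX"]] * s$cX1^2 - koff[["XX"]] * s$cX2
    qYY <- kon[["YY"]] * s$cY1^2 - koff[["YY"]] * s$cY2
    qXY <- kon[["XY"]] * s$cX1 * s$cY1 - koff[["XY"]] * s$cXY
    list(cX1 = -2 * qXX - qXY, cX2 = qXX,
         cY1 = -2 * qYY - qXY, cY2 = qYY, cXY = qXY)
  }
  cmax <- max(state$cX1, state$cY1, 0)
  fastest <- max(koff, kon * cmax, 0)
  nsub <- max(1L, min(50000L, ceiling(dt * fastest / 0.1)))
  h <- dt / nsub
  nms <- names(state)
  for (k in seq_len(nsub)) {
    k1 <- rate(state)
    mid <- stats::setNames(lapply(nms, function(nm)
      pmax(state[[nm]] + h * k1[[nm]], 0)), nms)
    k2 <- rate(mid)
    state <- stats::setNames(lapply(nms, function(nm)
      pmax(state[[nm]] + h * (k1[[nm]] + k2[[nm]]) / 2, 0)), nms)
  }
  state
}

#' Simulate sedimentation boundaries of a reversibly dimerizing system
#'
#' Solves the coupled sedimentation/diffusion/chemical-reaction PDE for a
#' self-associating component X, optionally in competition with a second
#' component Y and their heterodimer XY. In instantaneous-equilibrium mode
#' the species concentrations are projected onto the mass-action manifold at
#' every sub-step; in finite-rate mode the chemical rate equations
#' (qXX = kon cX1^2 - koff cX2, qXY = kon cX1 cY1 - koff cXY) are integrated
#' locally. The observed signal is the labeled-channel weighted sum over
#' species: the labeled homodimer carries two labeled protomers, a
#' heterodimer with an unlabeled partner carries one.
#'
#' @param system A [HeteroSystemModel-class] (modelY/KXY ignored when
#'   `loadingY = 0`).
#' @param rates A [RateParams-class]; instantaneous or named koff per
#'   reaction ("XX", "YY", "XY").
#' @param loadingX,loadingY uniform initial protomer loadings (mol/L).
#' @param geometry [RadialGeometry-class].
#' @param conditions [RunConditions-class].
#' @param times output times (s), strictly increasing.
#' @param frictionalRatio f/f0 used to assign diffusion coefficients to all
#'   protein species; default 1.5.
#' @param signalPerProtomer detector signal per mol/L per labeled protomer.
#' @param labeled which component carries the fluorophore ("X").
#' @param courant advective Courant number per sub-step.
#' @param keepSpecies logical, store per-species concentration profiles in
#'   the metadata.
#' @return A [ScanSet-class]; metadata records loadings, constants, the mode
#'   and per-component protomer mass-conservation errors.
#' @export
simulateReactingSystem <- function(system, rates, loadingX, loadingY = 0,
                                   geometry = RadialGeometry(),
                                   conditions = RunConditions(), times,
                                   frictionalRatio = 1.5,
                                   signalPerProtomer = 1, labeled = "X",
                                   courant = 0.5, keepSpecies = FALSE) {
  stopifnot(loadingX >= 0, loadingY >= 0, all(diff(times) > 0))
  hasY <- loadingY > 0
  mx <- system@modelX; my <- system@modelY
  D <- function(s) diffusionFromS(s, frictionalRatio, conditions)
  ops <- list(X1 = .lammOperator(mx@s1, D(mx@s1), geometry, conditions),
              X2 = .lammOperator(mx@s2, D(mx@s2), geometry, conditions))
  if (hasY) {
    ops$Y1 <- .lammOperator(my@s1, D(my@s1), geometry, conditions)
    ops$Y2 <- .lammOperator(my@s2, D(my@s2), geometry, conditions)
    ops$XY <- .lammOperator(system@sXY, D(system@sXY), geometry, conditions)
  }
  n <- geometry@nPoints
  rc <- ops$X1$rc
  # samples equilibrate before the run: start from the equilibrium composition
  eq <- solveHetero(loadingX, if (hasY) loadingY else 0, system)
  state <- list(cX1 = rep(eq$cX1, n), cX2 = rep(eq$cX2, n),
                cY1 = rep(if (hasY) eq$cY1 else 0, n),
                cY2 = rep(if (hasY) eq$cY2 else 0, n),
                cXY = rep(if (hasY) eq$cXY else 0, n))
  K <- c(XX = mx@K12, YY = my@K12, XY = system@KXY)
  if (!rates@instantaneous) {
    koff <- c(XX = 0, YY = 0, XY = 0)
    koff[names(rates@koff)] <- rates@koff
    kon <- koff * K
  }
  vmax <- max(vapply(ops, function(o) o$vmax, numeric(1)))
  dtTarget <- if (vmax > 0) courant * ops$X1$dr / vmax else diff(range(times))
  wX <- c(cX1 = 1, cX2 = 2, cY1 = 0, cY2 = 0, cXY = 1)   # X protomers
  wY <- c(cX1 = 0, cX2 = 0, cY1 = 1, cY2 = 2, cXY = 1)
  sig <- if (labeled == "X") wX * signalPerProtomer else wY * signalPerProtomer
  massOf <- function(state, w) {
    tot <- Reduce(`+`, Map(function(cn, wi) wi * cn, state, as.list(w)))
    sum(tot * ops$X1$Vc)
  }
  m0X <- massOf(state, wX); m0Y <- massOf(state, wY)
  out <- matrix(0, nrow = length(times), ncol = n)
  speciesOut <- if (keepSpecies)
    lapply(state, function(x) matrix(0, length(times), n)) else NULL
  spNames <- c("cX1", "cX2", if (hasY) c("cY1", "cY2", "cXY"))
  tPrev <- 0
  for (j in seq_along(times)) {
    span <- times[j] - tPrev
    if (span > 0) {
      nsub <- max(1L, ceiling(span / dtTarget))
      dt <- span / nsub
      fac <- lapply(spNames, function(nm) {
        opnm <- sub("^c", "", nm)
        .thomasFactor(ops[[opnm]], dt)
      })
      names(fac) <- spNames
      for (k in seq_len(nsub)) {
        for (nm in spNames) state[[nm]] <- .thomasSolve(fac[[nm]], state[[nm]])
        # chemistry
        if (rates@instantaneous) {
          if (hasY) {
            xt <- state$cX1 + 2 * state$cX2 + state$cXY
            yt <- state$cY1 + 2 * state$cY2 + state$cXY
            state <- localEquilibriumProjection(xt, yt, system)
          } else {
            xt <- state$cX1 + 2 * state$cX2
            eqh <- solveHomo(xt, mx)
            state$cX1 <- eqh$c1; state$cX2 <- eqh$c2
          }
        } else {
          if (hasY) {
            state <- .relaxHetero(state, kon, koff, dt)
          } else {
            rl <- .relaxHomo(state$cX1, state$cX2, kon[["XX"]], koff[["XX"]], dt)
            state$cX1 <- rl$c1; state$cX2 <- rl$c2
          }
        }
        neg <- vapply(state, function(x) min(x), numeric(1))
        if (any(neg < -1e-15 * max(loadingX, loadingY)))
          stop("negative concentrations beyond clipping tolerance")
        state <- lapply(state, function(x) pmax(x, 0))
      }
    }
    tPrev <- times[j]
    out[j, ] <- Reduce(`+`, Map(function(cn, w) w * cn, state, as.list(sig)))
    if (keepSpecies)
      for (nm in names(state)) speciesOut[[nm]][j, ] <- state[[nm]]
  }
  mErrX <- if (m0X > 0) abs(massOf(state, wX) / m0X - 1) else 0
  mErrY <- if (m0Y > 0) abs(massOf(state, wY) / m0Y - 1) else 0
  md <- list(loadingX_M = loadingX, loadingY_M = loadingY,
             KD_XX_M = if (mx@K12 > 0) 1 / mx@K12 else Inf,
             KD_YY_M = if (my@K12 > 0) 1 / my@K12 else Inf,
             KD_XY_M = if (system@KXY > 0) 1 / system@KXY else Inf,
             mode = if (rates@instantaneous) "instantaneous" else "finite-rate",
             massErrorX = mErrX, massErrorY = mErrY,
             signalPerProtomer = signalPerProtomer)
  if (!rates@instantaneous) md$koff <- rates@koff
  if (keepSpecies) md$species <- speciesOut
  ScanSet(times = times, radii = rc, signal = out,
          conditions = conditions, geometry = geometry, metadata = md)
}
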