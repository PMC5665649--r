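# Lamm equation solver and hydrodynamic relations.
#
# The Lamm equation for a single species in a sector-shaped cell,
#   dc/dt = (1/r) d/dr [ r D dc/dr - s w^2 r^2 c ],
# is discretized by a finite-volume scheme on cell centers with
# Scharfetter-Gummel (exponential-fitting) interface fluxes and backward-Euler
# time stepping. Zero total flux is imposed at meniscus and bottom, so the
# sector-weighted integral of c is conserved to round-off before and after
# back-diffusion equilibrium.

.kB <- 1.380649e-16    # erg/K
.NA <- 6.02214076e23
.RGAS <- 8.31446e7     # erg/(mol K)

#' Diffusion coefficient from s under the compact-particle scaling law
#'
#' For a compact particle of frictional ratio f/f0, the diffusion coefficient
#' follows from the sedimentation coefficient as
#' D(s) = (sqrt(2)/(18 pi)) kT s^(-1/2) (eta f/f0)^(-3/2) ((1 - vbar rho)/vbar)^(1/2),
#' the scaling law that underlies the c(s) distribution model.
#'
#' @param sValue sedimentation coefficient in Svedberg (> 0).
#' @param frictionalRatio f/f0 (>= 1).
#' @param conditions [RunConditions-class] supplying T, eta, rho, vbar.
#' @return Diffusion coefficient in cm^2/s.
#' @examples
#' diffusionFromS(5.8, 1.5)
#' @export
diffusionFromS <- function(sValue, frictionalRatio, conditions = RunConditions()) {
  stopifnot(all(sValue > 0), all(frictionalRatio >= 1))
  buoy <- 1 - conditions@partialSpecificVolume * conditions@solventDensity
  if (buoy <= 0)
    stop("(1 - vbar*rho) <= 0: floating species have no defined D(s) here")
  sSec <- sValue * 1e-13
  kT <- .kB * conditions@temperature
  (sqrt(2) / (18 * pi)) * kT * sSec^(-1/2) *
    (conditions@solventViscosity * frictionalRatio)^(-3/2) *
    (buoy / conditions@partialSpecificVolume)^(1/2)
}

#' Molar mass from the Svedberg relation
#'
#' M = s R T / (D (1 - vbar rho)), with s in seconds and D in cm^2/s.
#'
#' @param sValue sedimentation coefficient (Svedberg).
#' @param D diffusion coefficient (cm^2/s).
#' @param conditions [RunConditions-class].
#' @return Molar mass in g/mol.
#' @export
svedbergMass <- function(sValue, D, conditions = RunConditions()) {
  buoy <- 1 - conditions@partialSpecificVolume * conditions@solventDensity
  (sValue * 1e-13) * .RGAS * conditions@temperature / (D * buoy)
}

# Bernoulli function B(x) = x / (exp(x) - 1), stable near 0 and at large |x|.
.bernoulli <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2
  xs <- x[!small]
  out[!small] <- ifelse(xs > 700, 0, xs / expm1(xs))
  out
}

# Build the finite-volume transport operator for one species.
# Returns the tridiagonal coefficients of L where dc/dt = L c:
# lower a (length n, a[1] unused), diag b, upper d (d[n] unused).
.lammOperator <- function(sSvedberg, D, geometry, conditions) {
  n <- geometry@nPoints
  rm <- geometry@meniscus; rb <- geometry@bottom
  dr <- (rb - rm) / n
  rc <- rm + (seq_len(n) - 0.5) * dr          # cell centers
  re <- rm + seq_len(n - 1) * dr              # interior interfaces
  w2 <- omegaRadS(conditions)^2
  sSec <- sSvedberg * 1e-13
  v <- sSec * w2 * re                         # drift velocity at interfaces
  # sector-shaped: area factor proportional to r; rectangular: 1
  Ae <- if (geometry@sectorShaped) re else rep(1, n - 1)
  Vc <- if (geometry@sectorShaped) rc * dr else rep(dr, n)
  if (D > 0) {
    P <- v * dr / D
    # flux F_e = Ae * (D/dr) * (B(-P) cL - B(P) cR); B(-P) -> P upwinds the
    # drift term as P -> Inf, B(.) -> 1 recovers central diffusion as P -> 0
    fL <- Ae * (D / dr) * .bernoulli(-P)      # coefficient of left cell
    fR <- Ae * (D / dr) * .bernoulli(P)       # coefficient of right cell
  } else {
    fL <- Ae * pmax(v, 0)
    fR <- Ae * pmax(-v, 0)
  }
  # dc_i/dt = (F_{i-1/2} - F_{i+1/2}) / V_i, zero flux at both walls
  a <- c(0, fL / Vc[-1])                       # from cell i-1
  b <- numeric(n)
  b[1] <- -fL[1] / Vc[1]
  if (n > 2) b[2:(n - 1)] <- -(fR[1:(n - 2)] + fL[2:(n - 1)]) / Vc[2:(n - 1)]
  b[n] <- -fR[n - 1] / Vc[n]
  d <- c(fR / Vc[-n], 0)                       # from cell i+1
  list(a = a, b = b, d = d, rc = rc, dr = dr, vmax = max(abs(sSec * w2 * rb)),
       Vc = Vc)
}

# Solve (I - dt L) x = rhs for the tridiagonal operator; Thomas algorithm.
# Precomputes the elimination coefficients for a fixed dt.
.thomasFactor <- function(op, dt) {
  n <- length(op$b)
  A <- -dt * op$a; B <- 1 - dt * op$b; D <- -dt * op$d
  cp <- numeric(n); denom <- numeric(n)
  denom[1] <- 1 / B[1]
  cp[1] <- D[1] * denom[1]
  for (i in 2:n) {
    denom[i] <- 1 / (B[i] - A[i] * cp[i - 1])
    cp[i] <- D[i] * denom[i]
  }
  list(A = A, cp = cp, denom = denom, n = n)
}

.thomasSolve <- function(f, rhs) {
  n <- f$n
  dp <- numeric(n)
  dp[1] <- rhs[1] * f$denom[1]
  for (i in 2:n) dp[i] <- (rhs[i] - f$A[i] * dp[i - 1]) * f$denom[i]
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - f$cp[i] * x[i + 1]
  x
}

# Advance one species from time t0 to t1 with backward-Euler sub-steps whose
# advective Courant number does not exceed `courant`.
.lammAdvance <- function(conc, op, t0, t1, courant = 0.5, dtMax = Inf) {
  span <- t1 - t0
  if (span <= 0) return(conc)
  dtTarget <- if (op$vmax > 0) courant * op$dr / op$vmax else span
  dtTarget <- min(dtTarget, dtMax)
  nsub <- max(1L, ceiling(span / dtTarget))
  dt <- span / nsub
  f <- .thomasFactor(op, dt)
  for (k in seq_len(nsub)) conc <- .thomasSolve(f, conc)
  conc
}

#' Solve the single-species Lamm equation
#'
#' Concentration profiles of one sedimenting species under a uniform initial
#' loading in a sector-shaped cell with impermeable walls. Time steps are
#' chosen automatically from the advective Courant condition and subdivided
#' as needed; the scheme is unconditionally stable.
#'
#' @param species [SedimentingSpecies-class] (s in Svedberg, D in cm^2/s).
#' @param geometry [RadialGeometry-class].
#' @param conditions [RunConditions-class].
#' @param initialConc uniform loading concentration (mol/L).
#' @param times output times (s since full rotor speed), strictly increasing.
#' @param courant advective Courant number per sub-step; default 0.5.
#' @return A [ScanSet-class] whose signal matrix holds molar concentration
#'   profiles (multiply by signal coefficients to obtain detector signal).
#' @examples
#' sp <- SedimentingSpecies("dimer", 5.8, frictionalRatio = 1.5)
#' scans <- solveLamm(sp, RadialGeometry(nPoints = 100L), RunConditions(),
#'                    1e-6, times = c(600, 1200))
#' @export
solveLamm <- function(species, geometry, conditions, initialConc, times,
                      courant = 0.5) {
  stopifnot(length(times) >= 1, all(diff(times) > 0), all(times >= 0))
  if (species@diffusionCoeff <= 0 && species@sValue > 0 &&
      geometry@nPoints > 1 && species@diffusionCoeff < 0)
    stop("negative diffusion coefficient")
  op <- .lammOperator(species@sValue, species@diffusionCoeff, geometry,
                      conditions)
  n <- geometry@nPoints
  out <- matrix(0, nrow = length(times), ncol = n)
  conc <- rep(initialConc, n)
  tPrev <- 0
  if (species@sValue == 0 && species@diffusionCoeff == 0) {
    out[] <- rep(conc, each = length(times))
  } else {
    for (j in seq_along(times)) {
      conc <- .lammAdvance(conc, op, tPrev, times[j], courant)
      tPrev <- times[j]
      out[j, ] <- conc
    }
  }
  ScanSet(times = times, radii = op$rc, signal = out,
          channel = "fluorescence", conditions = conditions,
          geometry = geometry,
          metadata = list(species = species@name, s_S = species@sValue,
                          D_cm2s = species@diffusionCoeff,
                          initial_conc_M = initialConc))
}

#' Sector-weighted total amount in a scan profile
#'
#' The radial integral of c r dr (per unit sector angle and path length),
#' the conserved quantity of the Lamm equation with impermeable walls.
#'
#' @param scans A [ScanSet-class].
#' @return Numeric vector, one total per scan.
#' @export
sectorMass <- function(scans) {
  r <- scans@radii
  w <- if (scans@geometry@sectorShaped) r else rep(1, length(r))
  dr <- (scans@geometry@bottom - scans@geometry@meniscus) / length(r)
  as.numeric(scans@signal %*% (w * dr))
}
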