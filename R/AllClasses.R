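#' @import methods
NULL

#' Radial geometry of a sector-shaped centrifuge cell
#'
#' Describes the solution column of a standard double-sector centerpiece:
#' meniscus and bottom radii (cm from the rotor axis) and the number of
#' radial grid points used by the finite-volume Lamm solver.
#'
#' @slot meniscus numeric, meniscus radius in cm.
#' @slot bottom numeric, bottom radius in cm.
#' @slot nPoints integer, number of radial cells (>= 50).
#' @slot sectorShaped logical, sector-shaped cell (radial dilution) flag.
#' @export
setClass("RadialGeometry",
  representation(meniscus = "numeric", bottom = "numeric",
                 nPoints = "integer", sectorShaped = "logical"),
  prototype(meniscus = 6.0, bottom = 7.2, nPoints = 400L, sectorShaped = TRUE))

setValidity("RadialGeometry", function(object) {
  msg <- NULL
  if (length(object@meniscus) != 1 || length(object@bottom) != 1)
    msg <- c(msg, "meniscus and bottom must be scalars")
  else if (!(object@meniscus > 0 && object@bottom > object@meniscus))
    msg <- c(msg, "require 0 < meniscus < bottom")
  if (length(object@nPoints) != 1 || object@nPoints < 50L)
    msg <- c(msg, "nPoints must be a single integer >= 50")
  if (is.null(msg)) TRUE else msg
})

#' Constructor for RadialGeometry
#'
#' @param meniscus meniscus radius (cm); default 6.0.
#' @param bottom bottom radius (cm); default 7.2 (12 mm column).
#' @param nPoints number of radial cells; default 400.
#' @param sectorShaped logical; default TRUE.
#' @return A [RadialGeometry-class] object.
#' @export
RadialGeometry <- function(meniscus = 6.0, bottom = 7.2, nPoints = 400L,
                           sectorShaped = TRUE) {
  new("RadialGeometry", meniscus = as.numeric(meniscus),
      bottom = as.numeric(bottom), nPoints = as.integer(nPoints),
      sectorShaped = isTRUE(sectorShaped))
}

#' Run conditions of a sedimentation velocity experiment
#'
#' Rotor speed, temperature and solvent properties. Defaults correspond to
#' 50,000 rpm at 20 C in an aqueous buffer with no standard-condition
#' corrections applied; solvent properties enter only through the
#' hydrodynamic scaling law linking s and D.
#'
#' @slot rotorSpeed numeric, rotor speed in rpm.
#' @slot temperature numeric, absolute temperature (K).
#' @slot solventDensity numeric, g/mL.
#' @slot solventViscosity numeric, poise.
#' @slot partialSpecificVolume numeric, mL/g.
#' @export
setClass("RunConditions",
  representation(rotorSpeed = "numeric", temperature = "numeric",
                 solventDensity = "numeric", solventViscosity = "numeric",
                 partialSpecificVolume = "numeric"),
  prototype(rotorSpeed = 50000, temperature = 293.15, solventDensity = 1.000,
            solventViscosity = 0.01002, partialSpecificVolume = 0.73))

setValidity("RunConditions", function(object) {
  v <- c(object@rotorSpeed, object@temperature, object@solventDensity,
         object@solventViscosity, object@partialSpecificVolume)
  if (any(!is.finite(v)) || any(v <= 0)) "all run condition values must be positive" else TRUE
})

#' Constructor for RunConditions
#'
#' @param rotorSpeed rpm; default 50000.
#' @param temperature K; default 293.15 (20 C).
#' @param solventDensity g/mL; default 1.000.
#' @param solventViscosity poise; default 0.01002 (water, 20 C).
#' @param partialSpecificVolume mL/g; default 0.73.
#' @return A [RunConditions-class] object.
#' @export
RunConditions <- function(rotorSpeed = 50000, temperature = 293.15,
                          solventDensity = 1.000, solventViscosity = 0.01002,
                          partialSpecificVolume = 0.73) {
  new("RunConditions", rotorSpeed = rotorSpeed, temperature = temperature,
      solventDensity = solventDensity, solventViscosity = solventViscosity,
      partialSpecificVolume = partialSpecificVolume)
}

#' Angular velocity (rad/s) of run conditions
#' @param conditions A [RunConditions-class] object.
#' @return Angular velocity omega in rad/s.
#' @export
omegaRadS <- function(conditions) conditions@rotorSpeed * 2 * pi / 60

#' A sedimenting species
#'
#' One hydrodynamically distinct species: sedimentation coefficient (Svedberg,
#' 1 S = 1e-13 s), diffusion coefficient (cm^2/s, possibly derived from the
#' frictional ratio via [diffusionFromS]), molar signal increment per protomer
#' and the number of labeled protomers it carries.
#'
#' @slot name character.
#' @slot sValue numeric, Svedberg.
#' @slot diffusionCoeff numeric, cm^2/s.
#' @slot signalCoefficient numeric, signal/(mol/L) per labeled protomer.
#' @slot labeledProtomers numeric, number of labeled protomers per particle.
#' @export
setClass("SedimentingSpecies",
  representation(name = "character", sValue = "numeric",
                 diffusionCoeff = "numeric", signalCoefficient = "numeric",
                 labeledProtomers = "numeric"))

setValidity("SedimentingSpecies", function(object) {
  msg <- NULL
  if (object@sValue < 0) msg <- c(msg, "sValue must be >= 0")
  if (object@diffusionCoeff < 0) msg <- c(msg, "diffusionCoeff must be >= 0")
  if (object@signalCoefficient < 0) msg <- c(msg, "signalCoefficient must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Constructor for SedimentingSpecies
#'
#' If `diffusionCoeff` is missing it is derived from `frictionalRatio` via the
#' compact-particle scaling law ([diffusionFromS]).
#'
#' @param name species name.
#' @param sValue sedimentation coefficient (S).
#' @param diffusionCoeff diffusion coefficient (cm^2/s); optional.
#' @param frictionalRatio frictional ratio f/f0 used when `diffusionCoeff`
#'   is missing; default 1.5.
#' @param signalCoefficient signal per (mol/L) per labeled protomer; default 1.
#' @param labeledProtomers labeled protomers per particle; default 1.
#' @param conditions [RunConditions-class] used for the s-to-D conversion.
#' @return A [SedimentingSpecies-class] object.
#' @export
SedimentingSpecies <- function(name, sValue, diffusionCoeff = NULL,
                               frictionalRatio = 1.5, signalCoefficient = 1,
                               labeledProtomers = 1,
                               conditions = RunConditions()) {
  if (is.null(diffusionCoeff)) {
    diffusionCoeff <- if (sValue > 0)
      diffusionFromS(sValue, frictionalRatio, conditions) else 0
  }
  new("SedimentingSpecies", name = name, sValue = as.numeric(sValue),
      diffusionCoeff = as.numeric(diffusionCoeff),
      signalCoefficient = as.numeric(signalCoefficient),
      labeledProtomers = as.numeric(labeledProtomers))
}

#' A scan set: time series of radial signal profiles
#'
#' The raw unit of sedimentation velocity data: a matrix of signal values over
#' (time x radius) with run metadata. Radii are cell-center positions of the
#' finite-volume grid when produced by the solver.
#'
#' @slot times numeric, seconds since start of sedimentation, strictly increasing.
#' @slot radii numeric, cm, strictly increasing within [meniscus, bottom].
#' @slot signal matrix, dim (length(times), length(radii)).
#' @slot channel character, "fluorescence" or "absorbance".
#' @slot conditions RunConditions.
#' @slot geometry RadialGeometry.
#' @slot metadata list, free-form provenance.
#' @export
setClass("ScanSet",
  representation(times = "numeric", radii = "numeric", signal = "matrix",
                 channel = "character", conditions = "RunConditions",
                 geometry = "RadialGeometry", metadata = "list"),
  prototype(channel = "fluorescence", metadata = list()))

setValidity("ScanSet", function(object) {
  msg <- NULL
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(diff(object@radii) <= 0))
    msg <- c(msg, "radii must be strictly increasing")
  if (!all(is.finite(object@signal)))
    msg <- c(msg, "signal must be finite")
  if (!identical(dim(object@signal),
                 c(length(object@times), length(object@radii))))
    msg <- c(msg, "signal must be a (time x radius) matrix")
  if (min(object@radii) < object@geometry@meniscus - 1e-9 ||
      max(object@radii) > object@geometry@bottom + 1e-9)
    msg <- c(msg, "radii must lie within [meniscus, bottom]")
  if (!object@channel %in% c("fluorescence", "absorbance"))
    msg <- c(msg, "channel must be 'fluorescence' or 'absorbance'")
  if (is.null(msg)) TRUE else msg
})

#' Constructor for ScanSet
#' @param times scan times (s), strictly increasing.
#' @param radii radial positions (cm).
#' @param signal (time x radius) signal matrix.
#' @param channel "fluorescence" (default) or "absorbance".
#' @param conditions [RunConditions-class].
#' @param geometry [RadialGeometry-class].
#' @param metadata free-form list.
#' @return A [ScanSet-class] object.
#' @export
ScanSet <- function(times, radii, signal, channel = "fluorescence",
                    conditions = RunConditions(), geometry = RadialGeometry(),
                    metadata = list()) {
  new("ScanSet", times = as.numeric(times), radii = as.numeric(radii),
      signal = signal, channel = channel, conditions = conditions,
      geometry = geometry, metadata = metadata)
}

setMethod("show", "ScanSet", function(object) {
  cat("ScanSet:", length(object@times), "scans x", length(object@radii),
      "radii [", object@channel, "]\n")
  cat("  t:", min(object@times), "-", max(object@times), "s;  r:",
      object@geometry@meniscus, "-", object@geometry@bottom, "cm;",
      object@conditions@rotorSpeed, "rpm\n")
})

#' Accessors for ScanSet
#' @param x A [ScanSet-class].
#' @return `scanTimes`: numeric times (s); `scanRadii`: numeric radii (cm);
#'   `scanSignal`: the (time x radius) signal matrix.
#' @export
scanTimes <- function(x) x@times
#' @rdname scanTimes
#' @export
scanRadii <- function(x) x@radii
#' @rdname scanTimes
#' @export
scanSignal <- function(x) x@signal

#' Sedimentation coefficient grid for c(s) analysis
#'
#' @slot sValues numeric, strictly increasing s grid (Svedberg).
#' @slot frictionalRatio numeric, common f/f0 (>= 1) of the scaling law.
#' @export
setClass("SGrid",
  representation(sValues = "numeric", frictionalRatio = "numeric"))

setValidity("SGrid", function(object) {
  msg <- NULL
  if (length(object@sValues) < 30) msg <- c(msg, "need >= 30 s grid points")
  if (any(diff(object@sValues) <= 0)) msg <- c(msg, "s grid must be strictly increasing")
  if (object@frictionalRatio < 1) msg <- c(msg, "frictional ratio must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Constructor for SGrid
#' @param sMin lower s bound (S).
#' @param sMax upper s bound (S).
#' @param n number of grid points (>= 30); default 50.
#' @param frictionalRatio common f/f0; default 1.5.
#' @param sValues explicit grid overriding sMin/sMax/n.
#' @return An [SGrid-class] object.
#' @export
SGrid <- function(sMin = 2, sMax = 8, n = 50, frictionalRatio = 1.5,
                  sValues = NULL) {
  if (is.null(sValues)) sValues <- seq(sMin, sMax, length.out = n)
  new("SGrid", sValues = as.numeric(sValues),
      frictionalRatio = as.numeric(frictionalRatio))
}

#' Diffusion-deconvoluted sedimentation coefficient distribution c(s)
#'
#' @slot grid SGrid.
#' @slot coefficients numeric, c(s) in signal per Svedberg, >= 0.
#' @slot regularization character, "maxent", "tikhonov" or "none".
#' @slot lambda numeric, regularization strength actually used.
#' @slot confidenceLevel numeric, P used for the chi-square criterion.
#' @slot rmsd numeric, root-mean-square deviation of the fit.
#' @slot baseline numeric, fitted constant baseline (0 when not fitted).
#' @slot metadata list.
#' @export
setClass("CSDistribution",
  representation(grid = "SGrid", coefficients = "numeric",
                 regularization = "character", lambda = "numeric",
                 confidenceLevel = "numeric", rmsd = "numeric",
                 baseline = "numeric", metadata = "list"),
  prototype(regularization = "maxent", lambda = 0, confidenceLevel = 0.68,
            rmsd = NA_real_, baseline = 0, metadata = list()))

setValidity("CSDistribution", function(object) {
  msg <- NULL
  if (length(object@coefficients) != length(object@grid@sValues))
    msg <- c(msg, "coefficients must match the s grid length")
  if (any(object@coefficients < -1e-12))
    msg <- c(msg, "coefficients must be non-negative")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CSDistribution", function(object) {
  cat("c(s) distribution on", length(object@grid@sValues), "points,",
      sprintf("s in [%.2f, %.2f] S, f/f0 = %.2f\n",
              min(object@grid@sValues), max(object@grid@sValues),
              object@grid@frictionalRatio))
  cat(sprintf("  regularization: %s (lambda = %.3g, P = %.2f); rmsd = %.4g\n",
              object@regularization, object@lambda, object@confidenceLevel,
              object@rmsd))
})

#' s grid and coefficients of a c(s) distribution
#' @param x A [CSDistribution-class].
#' @return `csValues`: data.frame with columns `s` (Svedberg) and `c`
#'   (signal per Svedberg).
#' @export
csValues <- function(x) data.frame(s = x@grid@sValues, c = x@coefficients)

#' Monomer-dimer mass action model
#'
#' Self-association of a component X: monomer at molar concentration c1 and
#' dimer at c2 linked by the mass action law c2 = K12 c1^2 with association
#' constant K12 = 1/KD. An optional dimerization-incompetent fraction
#' contributes signal permanently at the monomer s-value.
#'
#' @slot K12 numeric, association constant (1/M).
#' @slot s1 numeric, monomer s (S).
#' @slot s2 numeric, dimer s (S).
#' @slot fInc numeric, incompetent fraction in [0, 1).
#' @export
setClass("HomoDimerModel",
  representation(K12 = "numeric", s1 = "numeric", s2 = "numeric",
                 fInc = "numeric"),
  prototype(fInc = 0))

setValidity("HomoDimerModel", function(object) {
  msg <- NULL
  if (object@K12 < 0) msg <- c(msg, "K12 must be >= 0")
  if (object@s2 <= object@s1) msg <- c(msg, "dimer s2 must exceed monomer s1")
  if (object@fInc < 0 || object@fInc >= 1) msg <- c(msg, "fInc must be in [0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Constructor for HomoDimerModel
#' @param KD dissociation constant (M); K12 = 1/KD. Use `K12` to give the
#'   association constant directly (KD ignored then).
#' @param s1 monomer s-value (S).
#' @param s2 dimer s-value (S).
#' @param fInc dimerization-incompetent fraction; default 0.
#' @param K12 association constant (1/M); optional.
#' @return A [HomoDimerModel-class] object.
#' @export
HomoDimerModel <- function(KD = NULL, s1 = 3.8, s2 = 5.8, fInc = 0, K12 = NULL) {
  if (is.null(K12)) {
    if (is.null(KD)) stop("give KD or K12")
    K12 <- if (is.finite(KD)) 1 / KD else 0
  }
  new("HomoDimerModel", K12 = as.numeric(K12), s1 = as.numeric(s1),
      s2 = as.numeric(s2), fInc = as.numeric(fInc))
}

#' Competitive homo/hetero-dimerization system
#'
#' Two components X and Y, each with its own monomer-dimer self-association,
#' coupled by heterodimer formation cXY = KXY cX1 cY1. The three equilibria
#' share the free monomer pools, rendering homo- and hetero-dimerization
#' competitive.
#'
#' @slot modelX HomoDimerModel for component X (the labeled tracer by convention).
#' @slot modelY HomoDimerModel for component Y.
#' @slot KXY numeric, heterodimer association constant (1/M).
#' @slot sXY numeric, heterodimer s-value (S).
#' @export
setClass("HeteroSystemModel",
  representation(modelX = "HomoDimerModel", modelY = "HomoDimerModel",
                 KXY = "numeric", sXY = "numeric"))

setValidity("HeteroSystemModel", function(object) {
  msg <- NULL
  if (object@KXY < 0) msg <- c(msg, "KXY must be >= 0")
  if (object@sXY <= max(object@modelX@s1, object@modelY@s1))
    msg <- c(msg, "heterodimer s must exceed both monomer s-values")
  if (is.null(msg)) TRUE else msg
})

#' Constructor for HeteroSystemModel
#' @param modelX,modelY [HomoDimerModel-class] objects for the two components.
#' @param KDXY heterodimer dissociation constant (M); or give `KXY`.
#' @param sXY heterodimer s-value (S); default 5.6.
#' @param KXY heterodimer association constant (1/M); optional.
#' @return A [HeteroSystemModel-class] object.
#' @export
HeteroSystemModel <- function(modelX, modelY, KDXY = NULL, sXY = 5.6,
                              KXY = NULL) {
  if (is.null(KXY)) {
    if (is.null(KDXY)) stop("give KDXY or KXY")
    KXY <- if (is.finite(KDXY)) 1 / KDXY else 0
  }
  new("HeteroSystemModel", modelX = modelX, modelY = modelY,
      KXY = as.numeric(KXY), sXY = as.numeric(sXY))
}

#' Kinetic rate parameters for dimerization reactions
#'
#' Off-rate constants per reaction (named "XX", "YY", "XY") or an
#' instantaneous-equilibrium flag. On-rates follow kon = koff * K, enforced
#' to relative tolerance 1e-9 when both are supplied.
#'
#' @slot koff numeric, named off-rate constants (1/s).
#' @slot instantaneous logical, instantaneous local equilibrium.
#' @export
setClass("RateParams",
  representation(koff = "numeric", instantaneous = "logical"),
  prototype(koff = numeric(0), instantaneous = TRUE))

#' Constructor for RateParams
#' @param koff named numeric of off-rate constants (1/s), names among
#'   "XX", "YY", "XY". Ignored when `instantaneous = TRUE`.
#' @param instantaneous logical; default TRUE.
#' @param kon optional named on-rates (1/(M s)); checked for consistency
#'   kon = koff * K against `K` when given.
#' @param K optional named association constants used for the check.
#' @return A [RateParams-class] object.
#' @export
RateParams <- function(koff = numeric(0), instantaneous = length(koff) == 0,
                       kon = NULL, K = NULL) {
  if (!is.null(kon) && !is.null(K)) {
    for (nm in names(kon)) {
      expect <- koff[[nm]] * K[[nm]]
      if (expect > 0 && abs(kon[[nm]] - expect) > 1e-9 * expect)
        stop("inconsistent rates for reaction ", nm,
             ": kon must equal koff * K")
    }
  }
  new("RateParams", koff = koff, instantaneous = isTRUE(instantaneous))
}

#' An sw isotherm dataset
#'
#' Rows of (labeled total concentration, unlabeled total concentration,
#' signal-weighted average sedimentation coefficient, weight), typically
#' assembled from transport-method integration of c(s) distributions over a
#' concentration series.
#'
#' @slot cLabeled numeric, labeled (tracer) total protomer concentration (M).
#' @slot cUnlabeled numeric, unlabeled total protomer concentration (M).
#' @slot sw numeric, signal-weighted average s (S).
#' @slot weight numeric, fit weights.
#' @slot componentX,componentY character, component identities.
#' @slot provenance list.
#' @export
setClass("IsothermDataset",
  representation(cLabeled = "numeric", cUnlabeled = "numeric", sw = "numeric",
                 weight = "numeric", componentX = "character",
                 componentY = "character", provenance = "list"),
  prototype(componentX = "X", componentY = "Y", provenance = list()))

setValidity("IsothermDataset", function(object) {
  n <- length(object@sw)
  msg <- NULL
  if (length(object@cLabeled) != n || length(object@cUnlabeled) != n ||
      length(object@weight) != n)
    msg <- c(msg, "column lengths must match")
  if (any(object@cLabeled < 0) || any(object@cUnlabeled < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (any(object@weight < 0)) msg <- c(msg, "weights must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Constructor for IsothermDataset
#' @param cLabeled labeled total protomer concentrations (M).
#' @param cUnlabeled unlabeled total protomer concentrations (M); default 0.
#' @param sw measured sw values (S).
#' @param weight fit weights; default 1.
#' @param componentX,componentY component names.
#' @param provenance free-form list.
#' @return An [IsothermDataset-class] object.
#' @export
IsothermDataset <- function(cLabeled, sw, cUnlabeled = rep(0, length(sw)),
                            weight = rep(1, length(sw)), componentX = "X",
                            componentY = "Y", provenance = list()) {
  new("IsothermDataset", cLabeled = as.numeric(cLabeled),
      cUnlabeled = as.numeric(cUnlabeled), sw = as.numeric(sw),
      weight = as.numeric(weight), componentX = componentX,
      componentY = componentY, provenance = provenance)
}

setMethod("show", "IsothermDataset", function(object) {
  cat("sw isotherm:", length(object@sw), "points,",
      object@componentX, "x", object@componentY, "\n")
})

#' As data.frame
#' @param x An [IsothermDataset-class].
#' @return data.frame with columns c_labeled_M, c_unlabeled_M, sw_S, weight.
#' @export
isothermData <- function(x) {
  data.frame(c_labeled_M = x@cLabeled, c_unlabeled_M = x@cUnlabeled,
             sw_S = x@sw, weight = x@weight)
}

#' Result of a nonlinear isotherm fit
#'
#' @slot estimates numeric, named best-fit values of the free parameters
#'   (KD-type parameters on the molar scale).
#' @slot fixed numeric, named fixed parameter values.
#' @slot ci95 matrix, rows = free parameters, columns lower/upper (NA when
#'   open-ended; see `flags`).
#' @slot chisq numeric, weighted sum of squared residuals at the optimum.
#' @slot rms numeric, root-mean-square residual.
#' @slot nObs integer.
#' @slot flags list, e.g. bound-only markers ("lower"/"upper") per parameter.
#' @slot convergence list, optimizer diagnostics.
#' @slot objective function, maps a named full parameter vector to chi-square
#'   (used by the error-projection profiler).
#' @slot freeNames character.
#' @export
setClass("FitResult",
  representation(estimates = "numeric", fixed = "numeric", ci95 = "matrix",
                 chisq = "numeric", rms = "numeric", nObs = "integer",
                 flags = "list", convergence = "list", objective = "function",
                 freeNames = "character"),
  prototype(flags = list(), convergence = list()))

setMethod("show", "FitResult", function(object) {
  cat("Isotherm fit:", length(object@freeNames), "free parameter(s), n =",
      object@nObs, sprintf(", chisq = %.4g, rms = %.4g\n",
                           object@chisq, object@rms))
  for (nm in object@freeNames) {
    ci <- object@ci95[nm, ]
    fl <- object@flags[[nm]]
    cat(sprintf("  %-8s %.4g  [95%% CI %.4g, %.4g]%s\n", nm,
                object@estimates[[nm]], ci[1], ci[2],
                if (!is.null(fl)) paste0("  (", fl, " bound)") else ""))
  }
})

#' Accessors for FitResult
#' @param x A [FitResult-class].
#' @param name parameter name; when NULL all estimates are returned.
#' @return `fitEstimates`: named numeric; `fitCI`: the 95 percent CI matrix;
#'   `fitFlags`: list of bound flags.
#' @export
fitEstimates <- function(x, name = NULL)
  if (is.null(name)) x@estimates else x@estimates[[name]]
#' @rdname fitEstimates
#' @export
fitCI <- function(x) x@ci95
#' @rdname fitEstimates
#' @export
fitFlags <- function(x) x@flags

#' Result of a kinetic (reaction-coupled Lamm) boundary fit
#'
#' @slot koff numeric, estimate or bound (1/s).
#' @slot KD numeric, co-refined dissociation constant (M).
#' @slot kon numeric, derived on-rate (1/(M s)).
#' @slot chisq numeric.
#' @slot ci numeric length 2, 95 percent CI for koff (NA side = open).
#' @slot classification character, "estimate", "lower_limit" or "upper_limit".
#' @slot profile data.frame, columns koff and chisq.
#' @slot details list.
#' @export
setClass("KineticFitResult",
  representation(koff = "numeric", KD = "numeric", kon = "numeric",
                 chisq = "numeric", ci = "numeric",
                 classification = "character", profile = "data.frame",
                 details = "list"),
  prototype(details = list()))

setMethod("show", "KineticFitResult", function(object) {
  cat(sprintf("Kinetic boundary fit: koff = %.3g 1/s (%s), KD = %.3g M, kon = %.3g 1/(M s)\n",
              object@koff, object@classification, object@KD, object@kon))
  cat(sprintf("  95%% CI koff: [%.3g, %.3g]; chisq = %.4g\n",
              object@ci[1], object@ci[2], object@chisq))
})

#' Noise model for synthetic scan data
#'
#' @slot rms numeric, gaussian noise rms as a fraction of the plateau signal.
#' @slot baseline numeric, constant background level (signal units),
#'   emulating residual carrier-protein (BSA) signal.
#' @slot scanJitter numeric, per-scan additive offset rms (signal units).
#' @slot seed integer.
#' @export
setClass("NoiseSpec",
  representation(rms = "numeric", baseline = "numeric", scanJitter = "numeric",
                 seed = "integer"),
  prototype(rms = 0.01, baseline = 0, scanJitter = 0, seed = 1L))

setValidity("NoiseSpec", function(object) {
  if (object@rms < 0 || object@scanJitter < 0)
    "noise magnitudes must be >= 0" else TRUE
})

#' Constructor for NoiseSpec
#' @param rms gaussian rms as a fraction of plateau signal; default 0.01.
#' @param baseline constant background (signal units); default 0.
#' @param scanJitter per-scan offset rms; default 0.
#' @param seed RNG seed.
#' @return A [NoiseSpec-class] object.
#' @export
NoiseSpec <- function(rms = 0.01, baseline = 0, scanJitter = 0, seed = 1L) {
  new("NoiseSpec", rms = as.numeric(rms), baseline = as.numeric(baseline),
      scanJitter = as.numeric(scanJitter), seed = as.integer(seed))
}

#' A synthetic FDS-SV experiment scenario
#'
#' Fully specifies one concentration series (tracer titration or dilution),
#' the underlying interaction system and kinetics, species hydrodynamics,
#' scan schedule and noise, so that the generator can produce one ScanSet per
#' sample plus a ground-truth record.
#'
#' @slot name character.
#' @slot design character, "titration" or "dilution".
#' @slot tracerConc numeric, constant labeled concentration (M; titration) or
#'   NA (dilution).
#' @slot series numeric, titrant totals (titration) or loading series (dilution), M.
#' @slot system HeteroSystemModel (modelY ignored for self-association).
#' @slot selfAssociation logical, TRUE when the series titrates the same
#'   component as the tracer.
#' @slot rates RateParams.
#' @slot frictionalRatio numeric, f/f0 for all protein species.
#' @slot incompetentFraction numeric.
#' @slot contaminantS numeric, s-value of a free-label contaminant (S; NA = none).
#' @slot contaminantFraction numeric, its signal fraction.
#' @slot scanTimes numeric, s.
#' @slot geometry RadialGeometry.
#' @slot conditions RunConditions.
#' @slot noise NoiseSpec.
#' @slot plateauSignal numeric, target counts of the brightest sample.
#' @slot truth list, generating constants (KD values, rates, flags).
#' @export
setClass("ExperimentScenario",
  representation(name = "character", design = "character",
                 tracerConc = "numeric", series = "numeric",
                 system = "HeteroSystemModel", selfAssociation = "logical",
                 rates = "RateParams", frictionalRatio = "numeric",
                 incompetentFraction = "numeric", contaminantS = "numeric",
                 contaminantFraction = "numeric", scanTimes = "numeric",
                 geometry = "RadialGeometry", conditions = "RunConditions",
                 noise = "NoiseSpec", plateauSignal = "numeric",
                 truth = "list"),
  prototype(incompetentFraction = 0, contaminantS = NA_real_,
            contaminantFraction = 0, plateauSignal = 3000, truth = list()))

setValidity("ExperimentScenario", function(object) {
  msg <- NULL
  if (!object@design %in% c("titration", "dilution"))
    msg <- c(msg, "design must be 'titration' or 'dilution'")
  if (length(object@series) < 1) msg <- c(msg, "empty concentration series")
  if (any(object@series < 0)) msg <- c(msg, "series concentrations must be >= 0")
  if (object@design == "titration" &&
      (!is.finite(object@tracerConc) || object@tracerConc <= 0))
    msg <- c(msg, "titration requires a positive tracer concentration")
  if (object@incompetentFraction < 0 || object@incompetentFraction >= 1)
    msg <- c(msg, "incompetent fraction must be in [0, 1)")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ExperimentScenario", function(object) {
  cat(sprintf("Scenario '%s': %s, %d samples (%.3g - %.3g M), %d scans\n",
              object@name, object@design, length(object@series),
              min(object@series), max(object@series),
              length(object@scanTimes)))
})
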