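# Synthetic FDS-SV data generation: tracer-titration and dilution designs
# replicating the measured iGluR amino-terminal domain interaction systems,
# with the measured dissociation constants as ground truth. Every downstream
# stage (c(s), sw isotherms, equilibrium and kinetic fitting) is testable on
# this output without any external data.

.presetRegistry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "presets.json", package = "sedimer")
      if (path == "") path <- file.path("inst", "extdata", "presets.json")
      cache <<- jsonlite::fromJSON(path, simplifyVector = TRUE)$presets
    }
    cache
  }
})

#' Names of the available experiment presets
#' @return Character vector of preset names.
#' @export
scenarioPresets <- function() names(.presetRegistry())

#' Reference dissociation constants for iGluR ATD dimer assembly
#'
#' The measured KD values (with 95 percent confidence limits and bound flags
#' for the one-sided entries) for all kainate and AMPA receptor
#' amino-terminal domain pairs, shipped as package data.
#'
#' @param family optional filter, "kainate" or "ampa".
#' @return data.frame with columns family, unlabeled, labeled, kd_M,
#'   ci_lower_M, ci_upper_M, bound, label_type.
#' @examples
#' head(referenceConstants("kainate"))
#' @export
referenceConstants <- function(family = NULL) {
  path <- system.file("extdata", "reference_constants.json", package = "sedimer")
  if (path == "") path <- file.path("inst", "extdata", "reference_constants.json")
  df <- jsonlite::fromJSON(path, simplifyVector = TRUE)$constants
  if (!is.null(family)) df <- df[df$family == family, ]
  df
}

#' Build a synthetic experiment scenario
#'
#' Returns a fully specified [ExperimentScenario-class], either from a named
#' preset (see [scenarioPresets]) with optional overrides, or from explicit
#' parameters. Presets cover the homo- and hetero-dimerization concentration
#' series of the kainate and AMPA ATD study designs.
#'
#' @param preset preset name, or NULL to specify everything explicitly.
#' @param design "titration" or "dilution".
#' @param tracerConc labeled-component concentration (M; titration designs).
#' @param series titrant (titration) or loading (dilution) concentrations (M);
#'   when NULL, a log-spaced grid of `nSeries` points over the preset range.
#' @param nSeries number of concentration points; default from preset (12).
#' @param kdX,kdY,kdXY dissociation constants (M); kdY/kdXY NULL for
#'   self-association.
#' @param s1X,s2X,s1Y,s2Y,sXY species s-values (S).
#' @param frictionalRatio f/f0 for all protein species; default 1.5.
#' @param koff off-rate constant (1/s) applied to every reaction; NULL means
#'   instantaneous equilibrium.
#' @param incompetentFraction dimerization-incompetent fraction of the
#'   labeled component; default 0.
#' @param contaminantS,contaminantFraction s-value (S) and signal fraction of
#'   a free-label contaminant (e.g. cleaved EGFP at 2.5 S); NA/0 for none.
#' @param nScans,scanInterval scan schedule; default 60 scans, 90 s apart.
#' @param geometry [RadialGeometry-class]; default standard 12 mm cell.
#' @param conditions [RunConditions-class]; default 50,000 rpm, 20 C.
#' @param noise [NoiseSpec-class]; default 1 percent-of-plateau rms.
#' @param plateauSignal counts of the brightest sample; default 3000.
#' @param name scenario name.
#' @return An [ExperimentScenario-class].
#' @examples
#' sc <- buildScenario("GluK2_x_GluK5_titration")
#' @export
buildScenario <- function(preset = NULL, design = NULL, tracerConc = NULL,
                          series = NULL, nSeries = NULL, kdX = NULL,
                          kdY = NULL, kdXY = NULL, s1X = 3.8, s2X = 5.8,
                          s1Y = 3.8, s2Y = 5.8, sXY = 5.6,
                          frictionalRatio = 1.5, koff = NULL,
                          incompetentFraction = 0, contaminantS = NA,
                          contaminantFraction = 0, nScans = 60L,
                          scanInterval = 90, geometry = RadialGeometry(),
                          conditions = RunConditions(), noise = NoiseSpec(),
                          plateauSignal = 3000, name = NULL) {
  self <- TRUE
  boundFlag <- NULL
  if (!is.null(preset)) {
    reg <- .presetRegistry()
    if (!preset %in% names(reg)) stop("unknown preset: ", preset)
    p <- reg[[preset]]
    design <- design %||% p$design
    self <- isTRUE(p$self)
    if (is.null(tracerConc) && !is.null(p$tracer_M)) tracerConc <- p$tracer_M
    nSeries <- nSeries %||% p$n_series
    if (is.null(series))
      series <- 10^seq(log10(p$series_min_M), log10(p$series_max_M),
                       length.out = nSeries)
    kdX <- kdX %||% p$kd_x_M
    kdY <- kdY %||% p$kd_y_M
    kdXY <- kdXY %||% p$kd_xy_M
    s1X <- p$s1_x %||% s1X; s2X <- p$s2_x %||% s2X
    s1Y <- p$s1_y %||% s1Y; s2Y <- p$s2_y %||% s2Y
    sXY <- p$s_xy %||% sXY
    frictionalRatio <- p$ffr %||% frictionalRatio
    if (is.null(koff) && !is.null(p$koff_s)) koff <- p$koff_s
    if (!is.null(p$contaminant_s)) contaminantS <- p$contaminant_s
    if (!is.null(p$contaminant_fraction))
      contaminantFraction <- p$contaminant_fraction
    boundFlag <- p$kd_bound
    name <- name %||% preset
  } else {
    if (is.null(design) || is.null(kdX)) stop("incomplete scenario parameters")
    self <- is.null(kdXY)
    name <- name %||% "custom"
  }
  if (is.null(series) || length(series) == 0)
    stop("empty concentration series")
  modelX <- HomoDimerModel(KD = kdX, s1 = s1X, s2 = s2X)
  modelY <- if (!self && !is.null(kdY))
    HomoDimerModel(KD = kdY, s1 = s1Y, s2 = s2Y) else
    HomoDimerModel(K12 = 0, s1 = s1Y, s2 = s2Y)
  system <- if (self)
    HeteroSystemModel(modelX, modelY, KXY = 0, sXY = sXY) else
    HeteroSystemModel(modelX, modelY, KDXY = kdXY, sXY = sXY)
  rates <- if (is.null(koff)) RateParams() else
    RateParams(koff = c(XX = koff, YY = koff, XY = koff),
               instantaneous = FALSE)
  truth <- list(name = name, kd_x_M = kdX, kd_y_M = kdY, kd_xy_M = kdXY,
                s1_x = s1X, s2_x = s2X, s1_y = s1Y, s2_y = s2Y, s_xy = sXY,
                koff_s = koff, incompetent_fraction = incompetentFraction,
                contaminant_s = contaminantS,
                contaminant_fraction = contaminantFraction,
                kd_bound = boundFlag, seed = noise@seed)
  new("ExperimentScenario", name = name, design = design,
      tracerConc = if (is.null(tracerConc)) NA_real_ else tracerConc,
      series = as.numeric(series), system = system,
      selfAssociation = self, rates = rates,
      frictionalRatio = frictionalRatio,
      incompetentFraction = incompetentFraction,
      contaminantS = as.numeric(contaminantS),
      contaminantFraction = contaminantFraction,
      scanTimes = seq_len(nScans) * scanInterval, geometry = geometry,
      conditions = conditions, noise = noise,
      plateauSignal = plateauSignal, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add a dimerization-incompetent fraction to a scenario
#'
#' The given fraction of the labeled component is generated as a permanently
#' monomeric species with monomer hydrodynamics, emulating preparations with
#' a binding-incompetent sub-population.
#'
#' @param scenario An [ExperimentScenario-class].
#' @param fraction in [0, 1).
#' @return The modified scenario (truth record updated).
#' @export
injectIncompetentFraction <- function(scenario, fraction) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  scenario@incompetentFraction <- fraction
  scenario@truth$incompetent_fraction <- fraction
  scenario
}

# per-sample loadings and labeled fraction for a scenario
.scenarioLoadings <- function(scenario) {
  if (scenario@design == "titration") {
    if (scenario@selfAssociation) {
      tot <- scenario@tracerConc + scenario@series
      data.frame(loadingX = tot, loadingY = 0,
                 labeledFraction = scenario@tracerConc / tot,
                 cLabeled = scenario@tracerConc, cUnlabeled = scenario@series)
    } else {
      data.frame(loadingX = scenario@tracerConc, loadingY = scenario@series,
                 labeledFraction = 1,
                 cLabeled = scenario@tracerConc, cUnlabeled = scenario@series)
    }
  } else {
    data.frame(loadingX = scenario@series, loadingY = 0, labeledFraction = 1,
               cLabeled = scenario@series, cUnlabeled = 0)
  }
}

#' Generate a synthetic dataset from a scenario
#'
#' Runs the reaction-coupled simulator for every concentration point of the
#' scenario, adds the incompetent-fraction and free-label contaminant species
#' where configured, scales the fluorescence so the brightest sample reaches
#' the target plateau counts, and applies the noise model. Identical seeds
#' give identical output.
#'
#' @param scenario An [ExperimentScenario-class].
#' @return List with `scans` (list of [ScanSet-class], one per sample),
#'   `loadings` (data.frame of per-sample composition) and `truth` (the
#'   generating parameters, including the signal scale and seed).
#' @export
generateDataset <- function(scenario) {
  ld <- .scenarioLoadings(scenario)
  n <- nrow(ld)
  fInc <- scenario@incompetentFraction
  # signal scale: brightest sample's labeled protomer concentration -> plateau
  epsBase <- scenario@plateauSignal / max(ld$cLabeled)
  set.seed(scenario@noise@seed)
  geom <- scenario@geometry
  cond <- scenario@conditions
  times <- scenario@scanTimes
  mono <- SedimentingSpecies("incompetent", scenario@system@modelX@s1,
                             frictionalRatio = scenario@frictionalRatio,
                             conditions = cond)
  contam <- if (is.finite(scenario@contaminantS))
    SedimentingSpecies("free-label", scenario@contaminantS,
                       frictionalRatio = scenario@frictionalRatio,
                       conditions = cond) else NULL
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    eps <- epsBase * ld$labeledFraction[i]
    sim <- simulateReactingSystem(scenario@system, scenario@rates,
                                  loadingX = (1 - fInc) * ld$loadingX[i],
                                  loadingY = ld$loadingY[i],
                                  geometry = geom, conditions = cond,
                                  times = times,
                                  frictionalRatio = scenario@frictionalRatio,
                                  signalPerProtomer = eps)
    signal <- sim@signal
    if (fInc > 0 && ld$loadingX[i] > 0) {
      incSim <- solveLamm(mono, geom, cond, fInc * ld$loadingX[i], times)
      signal <- signal + eps * incSim@signal
    }
    if (!is.null(contam) && scenario@contaminantFraction > 0) {
      cc <- scenario@contaminantFraction * ld$cLabeled[i]
      cSim <- solveLamm(contam, geom, cond, cc, times)
      signal <- signal + epsBase * cSim@signal
    }
    plateau <- max(signal[1, ])
    if (scenario@noise@rms > 0)
      signal <- signal + matrix(stats::rnorm(length(signal), 0,
                                             scenario@noise@rms * plateau),
                                nrow = nrow(signal))
    if (scenario@noise@scanJitter > 0)
      signal <- signal + stats::rnorm(nrow(signal), 0, scenario@noise@scanJitter)
    signal <- signal + scenario@noise@baseline
    md <- sim@metadata
    md$sample <- i
    md$cLabeled_M <- ld$cLabeled[i]
    md$cUnlabeled_M <- ld$cUnlabeled[i]
    md$signalPerLabeledProtomer <- eps
    md$noise <- list(rms_fraction = scenario@noise@rms,
                     baseline = scenario@noise@baseline,
                     plateau = plateau)
    scans[[i]] <- ScanSet(times, sim@radii, signal, conditions = cond,
                          geometry = geom, metadata = md)
  }
  truth <- scenario@truth
  truth$signalPerProtomer <- epsBase
  truth$noise_rms_fraction <- scenario@noise@rms
  list(scans = scans, loadings = ld, truth = truth)
}

#' Simulate a noisy sw isotherm directly from the equilibrium model
#'
#' Bypasses the scan-level simulation: evaluates the algebraic sw isotherm of
#' the scenario's interaction system at its concentration series and adds
#' gaussian noise to the sw values. Used for replicate (coverage) studies of
#' the isotherm fit.
#'
#' @param scenario An [ExperimentScenario-class].
#' @param swNoiseSd gaussian sd added to sw (S); default 1 percent of
#'   (s2 - s1) of the labeled component.
#' @param seed RNG seed; default the scenario seed.
#' @return An [IsothermDataset-class].
#' @export
simulateSwIsotherm <- function(scenario, swNoiseSd = NULL, seed = NULL) {
  ld <- .scenarioLoadings(scenario)
  mx <- scenario@system@modelX
  if (is.null(swNoiseSd)) swNoiseSd <- 0.01 * (mx@s2 - mx@s1)
  sw <- if (scenario@selfAssociation || all(ld$loadingY == 0))
    swHomoIsotherm(ld$loadingX, mx)
  else
    swHeteroIsotherm(ld$loadingX, ld$loadingY, scenario@system)
  set.seed(seed %||% scenario@noise@seed)
  sw <- sw + stats::rnorm(length(sw), 0, swNoiseSd)
  IsothermDataset(cLabeled = ld$cLabeled, cUnlabeled = ld$cUnlabeled,
                  sw = sw, componentX = scenario@name,
                  provenance = list(simulated = TRUE, swNoiseSd = swNoiseSd))
}
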