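# End-to-end orchestration: simulate a scenario, run c(s) on every sample,
# integrate sw, assemble and fit the isotherm, and map free energies --
# the full analysis sequence on synthetic data, deterministic under a seed.

#' Assemble an sw isotherm from a concentration series of scan sets
#'
#' Fits a c(s) distribution to every sample (sharing one kernel when the scan
#' layouts match) and integrates it over [sMin, sMax] to the transport-method
#' sw, returning the isotherm dataset with per-sample provenance.
#'
#' @param scansList list of [ScanSet-class]; metadata fields `cLabeled_M` and
#'   `cUnlabeled_M` supply the concentration columns unless given explicitly.
#' @param grid An [SGrid-class].
#' @param sMin,sMax integration range (S), e.g. 2-8 for the kainate systems,
#'   3-8 to exclude a 2.5 S free-label contaminant.
#' @param cLabeled,cUnlabeled optional explicit concentration vectors (M).
#' @param regularization passed to [fitCS].
#' @param ... further arguments to [fitCS].
#' @return An [IsothermDataset-class]; the c(s) fits are attached as the
#'   provenance element `distributions`.
#' @export
isothermFromScans <- function(scansList, grid, sMin, sMax, cLabeled = NULL,
                              cUnlabeled = NULL, regularization = "maxent",
                              ...) {
  stopifnot(length(scansList) >= 1)
  if (is.null(cLabeled))
    cLabeled <- vapply(scansList, function(s)
      s@metadata$cLabeled_M %||% NA_real_, numeric(1))
  if (is.null(cUnlabeled))
    cUnlabeled <- vapply(scansList, function(s)
      s@metadata$cUnlabeled_M %||% 0, numeric(1))
  if (any(!is.finite(cLabeled))) stop("labeled concentrations required")
  layout <- function(s) c(length(s@times), length(s@radii), s@times[1],
                          s@geometry@meniscus, s@geometry@bottom)
  l1 <- layout(scansList[[1]])
  shared <- all(vapply(scansList, function(s)
    isTRUE(all.equal(layout(s), l1)), logical(1)))
  kernel <- if (shared) csKernel(scansList[[1]], grid) else NULL
  dists <- lapply(scansList, function(s)
    fitCS(s, grid, regularization, kernel = kernel, ...))
  sw <- vapply(dists, swTransport, numeric(1), sMin = sMin, sMax = sMax)
  IsothermDataset(cLabeled = cLabeled, cUnlabeled = cUnlabeled, sw = sw,
                  provenance = list(distributions = dists,
                                    integration_S = c(sMin, sMax)))
}

#' Pairwise Gibbs free-energy map from a constants table
#'
#' @param constants data.frame as from [referenceConstants] (columns
#'   unlabeled, labeled, kd_M, bound).
#' @param temperature K; default 293.15.
#' @return The table with a `delta_g_kcal_mol` column appended; bound entries
#'   keep their direction flag (a bound on KD is a bound on Delta G).
#' @examples
#' deltaGMap(referenceConstants("kainate"))
#' @export
deltaGMap <- function(constants, temperature = 293.15) {
  constants$delta_g_kcal_mol <- deltaGFromKd(constants$kd_M, temperature)
  constants
}

#' Run the full synthetic-replay pipeline
#'
#' For each scenario: generate the noisy dataset, fit c(s) per sample,
#' integrate to the sw isotherm, and fit the appropriate binding model
#' (monomer-dimer for self-association; competitive coupled equilibria with
#' the homo constants fixed at their independently known values for
#' hetero titrations). Deterministic under the configured seed.
#'
#' @param config list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{scenarios}{character vector of preset names (may be empty).}
#'     \item{seed}{integer base seed; scenario i uses seed + i - 1.}
#'     \item{cs}{list(sMin, sMax, n, frictionalRatio, regularization).}
#'     \item{integration}{numeric c(sMin, sMax) for the sw integral.}
#'     \item{overrides}{list of [buildScenario] overrides applied to every
#'       scenario (e.g. nScans, nSeries, geometry).}
#'     \item{outDir}{optional directory; datasets and results are written
#'       there (scan TSV directories, isotherm CSVs, results JSON).}
#'   }
#' @return List with one result per scenario (truth, isotherm, fit,
#'   estimates) plus `deltaG` (the reference free-energy map) and
#'   `provenance` (seed, config echo, package version, timings).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  stopifnot(is.list(config))
  scenarios <- config$scenarios %||% character(0)
  seed <- as.integer(config$seed %||% 1L)
  cs <- config$cs %||% list()
  grid <- SGrid(cs$sMin %||% 2, cs$sMax %||% 8, n = cs$n %||% 45,
                frictionalRatio = cs$frictionalRatio %||% 1.5)
  reg <- cs$regularization %||% "maxent"
  integ <- config$integration %||% c(cs$sMin %||% 2, cs$sMax %||% 8)
  overrides <- config$overrides %||% list()
  outDir <- config$outDir
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  results <- list()
  t0 <- proc.time()[3]
  for (i in seq_along(scenarios)) {
    nm <- scenarios[[i]]
    args <- c(list(preset = nm,
                   noise = NoiseSpec(rms = overrides$noiseRms %||% 0.01,
                                     seed = seed + i - 1L)),
              overrides[setdiff(names(overrides), "noiseRms")])
    scen <- tryCatch(do.call(buildScenario, args),
                     error = function(e) stop("scenario '", nm, "': ",
                                              conditionMessage(e)))
    ds <- tryCatch(generateDataset(scen),
                   error = function(e) stop("simulation stage '", nm, "': ",
                                            conditionMessage(e)))
    iso <- tryCatch(
      isothermFromScans(ds$scans, grid, integ[1], integ[2],
                        regularization = reg),
      error = function(e) stop("c(s)/sw stage '", nm, "': ",
                               conditionMessage(e)))
    tr <- ds$truth
    fit <- tryCatch({
      if (scen@selfAssociation) {
        fitHomoIsotherm(iso, free = "KD",
                        start = list(KD = stats::median(iso@cLabeled +
                                                          iso@cUnlabeled),
                                     s1 = tr$s1_x, s2 = tr$s2_x,
                                     fInc = tr$incompetent_fraction))
      } else {
        fitHeteroIsotherm(iso, scen@system)
      }
    }, error = function(e) stop("isotherm fit stage '", nm, "': ",
                                conditionMessage(e)))
    kdName <- if (scen@selfAssociation) "KD" else "KDXY"
    kdTrue <- if (scen@selfAssociation) tr$kd_x_M else tr$kd_xy_M
    res <- list(scenario = nm, truth = tr, isotherm = isothermData(iso),
                fit = fitResultRecord(fit),
                kd_estimate_M = fitEstimates(fit, kdName),
                kd_true_M = kdTrue,
                kd_ci95_M = fitCI(fit)[kdName, ])
    if (!is.null(outDir)) {
      writeIsotherm(iso, file.path(outDir, paste0(nm, "_isotherm.csv")))
      jsonlite::write_json(res[c("scenario", "truth", "fit", "kd_estimate_M",
                                 "kd_true_M")],
                           file.path(outDir, paste0(nm, "_fit.json")),
                           auto_unbox = TRUE, digits = NA, na = "null")
    }
    results[[nm]] <- res
  }
  bundle <- list(
    results = results,
    deltaG = deltaGMap(referenceConstants()),
    provenance = list(seed = seed, scenarios = scenarios,
                      config = config[setdiff(names(config), "outDir")],
                      package_version = tryCatch(
                        as.character(utils::packageVersion("sedimer")),
                        error = function(e) NA_character_),
                      elapsed_s = proc.time()[3] - t0))
  if (!is.null(outDir))
    jsonlite::write_json(bundle$provenance,
                         file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  bundle
}
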