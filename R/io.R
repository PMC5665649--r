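# File formats: the scan TSV dialect (one file per scan, '# key: value'
# comment header plus two tab-separated columns radius_cm, signal; a ScanSet
# is a directory with a manifest), the isotherm CSV, and constants/fit JSON.
# All round-trips preserve the numeric payload to full double precision.

.fmt <- function(x) sprintf("%.17g", x)

#' Write a ScanSet to a directory of scan TSV files
#'
#' One TSV per scan with a commented metadata header (speed_rpm,
#' temperature_C, time_s, channel, meniscus_cm, bottom_cm) and columns
#' radius_cm, signal, plus a manifest JSON naming the files and carrying the
#' free-form metadata (e.g. generating truth parameters).
#'
#' @param scans A [ScanSet-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScanSet <- function(scans, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(scans@times))
  for (j in seq_along(scans@times)) {
    f <- sprintf("scan_%04d.tsv", j)
    files[j] <- f
    con <- file(file.path(dir, f), "w")
    hdr <- c(speed_rpm = .fmt(scans@conditions@rotorSpeed),
             temperature_C = .fmt(scans@conditions@temperature - 273.15),
             time_s = .fmt(scans@times[j]),
             channel = scans@channel,
             meniscus_cm = .fmt(scans@geometry@meniscus),
             bottom_cm = .fmt(scans@geometry@bottom))
    writeLines(paste0("# ", names(hdr), ": ", hdr), con)
    writeLines(paste(.fmt(scans@radii), .fmt(scans@signal[j, ]), sep = "\t"),
               con)
    close(con)
  }
  manifest <- list(files = files,
                   times_s = scans@times,
                   channel = scans@channel,
                   n_radii = length(scans@radii),
                   solvent = list(
                     density_g_mL = scans@conditions@solventDensity,
                     viscosity_poise = scans@conditions@solventViscosity,
                     partial_specific_volume_mL_g =
                       scans@conditions@partialSpecificVolume),
                   sector_shaped = scans@geometry@sectorShaped,
                   metadata = scans@metadata)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

.parseScanFile <- function(path) {
  lines <- readLines(path)
  isHdr <- grepl("^#", lines)
  hdr <- lines[isHdr]
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3) trimws(m[2]) else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) trimws(m[3]) else NA_character_,
                 character(1))
  meta <- stats::setNames(as.list(vals), keys)
  need <- c("speed_rpm", "temperature_C", "time_s", "channel",
            "meniscus_cm", "bottom_cm")
  miss <- setdiff(need, keys)
  if (length(miss) > 0)
    stop("scan file ", basename(path), ": missing metadata keys: ",
         paste(miss, collapse = ", "))
  body <- which(!isHdr & nzchar(lines))
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0)
    stop("scan file ", basename(path), " line ", body[bad[1]],
         ": expected two tab-separated columns")
  radius <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1)))
  signal <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  if (any(!is.finite(radius)) || any(!is.finite(signal))) {
    bad <- which(!is.finite(radius) | !is.finite(signal))[1]
    stop("scan file ", basename(path), " line ", body[bad],
         ": non-numeric value")
  }
  list(meta = meta, radius = radius, signal = signal)
}

#' Read a ScanSet from a directory written by [writeScanSet]
#'
#' @param dir directory containing scan TSV files and manifest.json.
#' @return A [ScanSet-class].
#' @export
readScanSet <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  scans <- lapply(file.path(dir, manifest$files), .parseScanFile)
  radii <- scans[[1]]$radius
  signal <- do.call(rbind, lapply(scans, `[[`, "signal"))
  m1 <- scans[[1]]$meta
  cond <- RunConditions(
    rotorSpeed = as.numeric(m1$speed_rpm),
    temperature = as.numeric(m1$temperature_C) + 273.15,
    solventDensity = manifest$solvent$density_g_mL %||% 1.000,
    solventViscosity = manifest$solvent$viscosity_poise %||% 0.01002,
    partialSpecificVolume =
      manifest$solvent$partial_specific_volume_mL_g %||% 0.73)
  geom <- RadialGeometry(as.numeric(m1$meniscus_cm),
                         as.numeric(m1$bottom_cm),
                         nPoints = length(radii),
                         sectorShaped = manifest$sector_shaped %||% TRUE)
  times <- vapply(scans, function(s) as.numeric(s$meta$time_s), numeric(1))
  md <- manifest$metadata
  ScanSet(times = times, radii = radii, signal = signal,
          channel = m1$channel, conditions = cond, geometry = geom,
          metadata = if (is.null(md)) list() else md)
}

#' Write / read an isotherm CSV
#'
#' Columns: c_labeled_M, c_unlabeled_M, sw_S, weight.
#'
#' @param isotherm An [IsothermDataset-class].
#' @param path CSV path.
#' @return `writeIsotherm`: the path, invisibly; `readIsotherm`: an
#'   [IsothermDataset-class].
#' @export
writeIsotherm <- function(isotherm, path) {
  df <- isothermData(isotherm)
  df[] <- lapply(df, .fmt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeIsotherm
#' @export
readIsotherm <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("c_labeled_M", "c_unlabeled_M", "sw_S", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("isotherm CSV ", basename(path), ": missing column(s): ",
         paste(miss, collapse = ", "))
  IsothermDataset(cLabeled = df$c_labeled_M, cUnlabeled = df$c_unlabeled_M,
                  sw = df$sw_S, weight = df$weight)
}

#' Write / read a constants table as JSON
#'
#' @param constants data.frame in the layout of [referenceConstants].
#' @param path JSON path.
#' @return `writeConstants`: the path, invisibly; `readConstants`: the
#'   data.frame.
#' @export
writeConstants <- function(constants, path) {
  jsonlite::write_json(list(constants = constants), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname writeConstants
#' @export
readConstants <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)$constants
}

#' Export a FitResult as a JSON-ready list
#'
#' @param fit A [FitResult-class].
#' @return List with estimates, fixed, ci95, chisq, rms, n and flags.
#' @export
fitResultRecord <- function(fit) {
  list(estimates = as.list(fit@estimates), fixed = as.list(fit@fixed),
       ci95 = apply(fit@ci95, 1, function(r) list(lower = r[[1]],
                                                  upper = r[[2]])),
       chisq = fit@chisq, rms = fit@rms, n = fit@nObs, flags = fit@flags)
}
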