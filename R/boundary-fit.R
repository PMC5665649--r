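# Direct fitting of sedimentation boundaries with the reaction-coupled Lamm
# model to estimate the dissociation rate constant koff (complex lifetime),
# with profile-based bound detection, and the peak-shift diagnostic of the
# kinetic regime from c(s) overlays of a concentration series.

# chi-square of the finite-rate forward model against one or more scan sets,
# with an analytically optimized global amplitude factor.
.kineticChisq <- function(scanSets, loadings, koff, KD, s1, s2,
                          frictionalRatio, excludeBottom = 0.15) {
  sim <- 0; dat <- 0; ss <- 0; sd <- 0; dd <- 0
  mx <- HomoDimerModel(KD = KD, s1 = s1, s2 = s2)
  sys <- HeteroSystemModel(mx, HomoDimerModel(K12 = 0, s1 = s1, s2 = s2),
                           KXY = 0, sXY = s2)
  rates <- RateParams(koff = c(XX = koff), instantaneous = FALSE)
  total <- 0
  for (i in seq_along(scanSets)) {
    sc <- scanSets[[i]]
    keep <- sc@radii <= sc@geometry@bottom - excludeBottom
    eps <- sc@metadata$signalPerLabeledProtomer %||%
      sc@metadata$signalPerProtomer %||% 1
    fw <- simulateReactingSystem(sys, rates, loadingX = loadings[i],
                                 geometry = sc@geometry,
                                 conditions = sc@conditions,
                                 times = sc@times,
                                 frictionalRatio = frictionalRatio,
                                 signalPerProtomer = eps)
    s <- as.vector(fw@signal[, keep]); d <- as.vector(sc@signal[, keep])
    ss <- ss + sum(s * s); sd <- sd + sum(s * d); dd <- dd + sum(d * d)
    total <- total + length(d)
  }
  scale <- if (ss > 0) sd / ss else 0
  list(chisq = dd - 2 * scale * sd + scale^2 * ss, scale = scale, n = total)
}

#' Fit the dissociation rate constant from sedimentation boundaries
#'
#' Least-squares fit of one or more scan sets with numerical solutions of the
#' reaction-coupled Lamm equation for a monomer-dimer system, with the
#' monomer and dimer s-values fixed (at isotherm/c(s)-derived values) and
#' koff refined along with KD. koff is searched on a log grid with KD
#' re-optimized at each point and the best point polished; the 95 percent
#' confidence interval follows from the F-statistic threshold on the koff
#' profile, with flat profile tails reported as one-sided bounds.
#'
#' @param scanSets list of [ScanSet-class] (or one ScanSet) at concentrations
#'   producing mixed monomer/dimer populations.
#' @param model [HomoDimerModel-class] with s1, s2 fixed and the KD start value.
#' @param loadings protomer loading concentrations (M) per scan set; defaults
#'   to the `loadingX_M` metadata.
#' @param koffRange search range (1/s); default c(1e-6, 1).
#' @param gridPerDecade koff grid density; default 7.
#' @param frictionalRatio f/f0 of the species; default 1.5.
#' @param refineKD logical; re-optimize log KD at every koff (default TRUE).
#' @return A [KineticFitResult-class].
#' @export
fitKoff <- function(scanSets, model, loadings = NULL,
                    koffRange = c(1e-6, 1), gridPerDecade = 7,
                    frictionalRatio = 1.5, refineKD = TRUE) {
  if (is(scanSets, "ScanSet")) scanSets <- list(scanSets)
  if (is.null(loadings))
    loadings <- vapply(scanSets, function(s)
      s@metadata$loadingX_M %||% NA_real_, numeric(1))
  if (any(!is.finite(loadings))) stop("loading concentrations required")
  # identifiability guard: need a mixed population somewhere
  fracD <- vapply(loadings, function(ct) {
    eq <- solveHomo(ct, model); 2 * eq$c2 / ct
  }, numeric(1))
  if (all(fracD < 0.03) || all(fracD > 0.97))
    stop("data fully dissociated or fully saturated: koff is unidentifiable")
  s1 <- model@s1; s2 <- model@s2
  kdStart <- if (model@K12 > 0) 1 / model@K12 else stats::median(loadings)
  nDec <- log10(koffRange[2] / koffRange[1])
  koffGrid <- 10^seq(log10(koffRange[1]), log10(koffRange[2]),
                     length.out = max(2, ceiling(nDec * gridPerDecade) + 1))
  profile <- data.frame(koff = koffGrid, chisq = NA_real_, KD = NA_real_)
  for (i in seq_along(koffGrid)) {
    if (refineKD) {
      op <- stats::optimize(function(lkd)
        .kineticChisq(scanSets, loadings, koffGrid[i], 10^lkd, s1, s2,
                      frictionalRatio)$chisq,
        interval = log10(kdStart) + c(-1.5, 1.5), tol = 0.02)
      profile$chisq[i] <- op$objective
      profile$KD[i] <- 10^op$minimum
    } else {
      profile$chisq[i] <-
        .kineticChisq(scanSets, loadings, koffGrid[i], kdStart, s1, s2,
                      frictionalRatio)$chisq
      profile$KD[i] <- kdStart
    }
  }
  iBest <- which.min(profile$chisq)
  # polish jointly on (log koff, log KD) around the best grid point
  pol <- stats::nlminb(c(log10(profile$koff[iBest]), log10(profile$KD[iBest])),
                       function(p) .kineticChisq(scanSets, loadings, 10^p[1],
                                                 10^p[2], s1, s2,
                                                 frictionalRatio)$chisq,
                       lower = c(log10(koffRange[1]) - 0.2, -13),
                       upper = c(log10(koffRange[2]) + 0.2, 0),
                       control = list(rel.tol = 1e-8, step.min = 1e-4))
  koffHat <- 10^pol$par[1]; kdHat <- 10^pol$par[2]
  chisqMin <- min(pol$objective, profile$chisq[iBest])
  nObs <- .kineticChisq(scanSets, loadings, koffHat, kdHat, s1, s2,
                        frictionalRatio)$n
  cls <- .classifyKoffProfile(profile, chisqMin, nObs, nPar = 2)
  new("KineticFitResult", koff = koffHat, KD = kdHat,
      kon = koffHat / kdHat, chisq = chisqMin, ci = cls$ci,
      classification = cls$classification, profile = profile,
      details = list(threshold = cls$threshold, scaleFitted = TRUE,
                     s1 = s1, s2 = s2, loadings = loadings))
}

# classify a chi-square vs log-koff profile against the F threshold
.classifyKoffProfile <- function(profile, chisqMin, nObs, nPar) {
  ndf <- max(nObs - nPar, 1)
  threshold <- chisqMin * (1 + stats::qf(0.95, 1, ndf) / ndf)
  below <- profile$chisq <= threshold
  lk <- log10(profile$koff)
  crossing <- function(i1, i2) {  # linear interpolation in log koff
    10^(lk[i1] + (threshold - profile$chisq[i1]) *
          (lk[i2] - lk[i1]) / (profile$chisq[i2] - profile$chisq[i1]))
  }
  firstBelow <- which(below)[1]
  lastBelow <- utils::tail(which(below), 1)
  lowerOpen <- below[1]
  upperOpen <- below[length(below)]
  ci <- c(NA_real_, NA_real_)
  if (!lowerOpen && length(firstBelow))
    ci[1] <- crossing(firstBelow - 1, firstBelow)
  if (!upperOpen && length(lastBelow) && lastBelow < nrow(profile))
    ci[2] <- crossing(lastBelow + 1, lastBelow)
  classification <- if (lowerOpen && upperOpen) "indeterminate"
  else if (upperOpen) "lower_limit"
  else if (lowerOpen) "upper_limit"
  else "estimate"
  list(classification = classification, ci = ci, threshold = threshold)
}

#' Profile chi-square over koff and classify the kinetic information content
#'
#' Re-examines (or re-computes on a new range) the chi-square profile of a
#' kinetic boundary fit. A profile that stays below the F-statistic threshold
#' toward fast kinetics yields a lower limit (the boundary shapes cannot
#' distinguish faster exchange); toward slow kinetics an upper limit.
#'
#' @param fit A [KineticFitResult-class] from [fitKoff].
#' @param scanSets,model,loadings,frictionalRatio as in [fitKoff]; when
#'   `scanSets` is NULL the stored profile is re-used.
#' @param searchRange optional new koff range (1/s).
#' @param gridPerDecade grid density for a re-computed profile.
#' @return List with `profile` (data.frame koff, chisq, KD),
#'   `classification`, `ci` and `threshold`.
#' @export
koffProfile <- function(fit, scanSets = NULL, model = NULL, loadings = NULL,
                        searchRange = NULL, gridPerDecade = 7,
                        frictionalRatio = 1.5) {
  if (is.null(scanSets)) {
    profile <- fit@profile
  } else {
    refit <- fitKoff(scanSets, model, loadings,
                     koffRange = searchRange %||% range(fit@profile$koff),
                     gridPerDecade = gridPerDecade,
                     frictionalRatio = frictionalRatio)
    profile <- refit@profile
  }
  nObs <- max(fit@details$nObs %||% 0, 100)
  cls <- .classifyKoffProfile(profile, min(profile$chisq, fit@chisq), nObs,
                              nPar = 2)
  c(list(profile = profile), cls)
}

#' Kinetic regime from c(s) peak shifts across a concentration series
#'
#' For a monomer-dimer system, slow dissociation on the sedimentation time
#' scale leaves the c(s) peaks near the monomer and dimer s-values with only
#' amplitude exchange as concentration increases, while fast interconversion
#' produces a single reaction boundary whose peak moves through intermediate
#' s-values. Classifies a series of c(s) distributions accordingly.
#'
#' @param csList list of [CSDistribution-class] across a concentration series
#'   (at least 3, spanning the monomer-dimer transition).
#' @param s1,s2 monomer and dimer s-values (S).
#' @param edgeBand fraction of (s2 - s1) around s1/s2 within which a dominant
#'   peak counts as "at" a species position; default 0.15.
#' @param midBand fraction of (s2 - s1) beyond which a dominant peak counts
#'   as intermediate; default 0.25.
#' @return "slow", "fast" or "indeterminate".
#' @export
peakShiftRegime <- function(csList, s1, s2, edgeBand = 0.15, midBand = 0.25) {
  if (length(csList) < 3) return("indeterminate")
  gap <- s2 - s1
  gPos <- vapply(csList, function(d) {
    pk <- peakPositions(d)
    if (nrow(pk) == 0) return(NA_real_)
    # the dominant mode is the robust discriminator: a bimodal distribution
    # with a shallow valley keeps its modes at the species positions, while
    # a fast reaction boundary has its single mode mid-gap
    (pk$sMode[which.max(pk$amplitude)] - s1) / gap
  }, numeric(1))
  sat <- vapply(csList, function(d) {
    sw <- tryCatch(swTransport(d, min(d@grid@sValues), max(d@grid@sValues)),
                   error = function(e) NA_real_)
    (sw - s1) / gap
  }, numeric(1))
  if (any(!is.finite(gPos))) stop("unresolved distributions in the series")
  atEdge <- gPos <= edgeBand | gPos >= 1 - edgeBand
  intermediate <- gPos > midBand & gPos < 1 - midBand
  transitionSampled <- any(sat > 0.2 & sat < 0.8, na.rm = TRUE)
  if (!transitionSampled) return("indeterminate")
  if (any(intermediate & sat > 0.2 & sat < 0.8, na.rm = TRUE)) return("fast")
  if (all(atEdge)) return("slow")
  "indeterminate"
}
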