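# Nonlinear least-squares fitting of sw isotherms to the monomer-dimer and
# competitive homo/hetero-dimerization models, with fixed-constraint handling
# and error-projection (profile chi-square, F-statistic) confidence
# intervals. KD-type parameters are optimized in log space with multistart.

.LOG10KD.MIN <- -13
.LOG10KD.MAX <- 0

# parameter transforms: KD-type parameters on log10 scale, fInc on identity
.isLogParam <- function(nm) nm %in% c("KD", "KDXY")

.toInternal <- function(par) {
  out <- par
  for (nm in names(par)) if (.isLogParam(nm)) out[[nm]] <- log10(par[[nm]])
  out
}
.fromInternal <- function(par) {
  out <- par
  for (nm in names(par)) if (.isLogParam(nm)) out[[nm]] <- 10^par[[nm]]
  out
}

.parBounds <- function(nms, swRange) {
  lower <- vapply(nms, function(nm) switch(nm,
    KD = .LOG10KD.MIN, KDXY = .LOG10KD.MIN, fInc = 0,
    s1 = 0.2, s2 = 0.2, sXY = 0.2), numeric(1))
  upper <- vapply(nms, function(nm) switch(nm,
    KD = .LOG10KD.MAX, KDXY = .LOG10KD.MAX, fInc = 0.95,
    s1 = 30, s2 = 30, sXY = 30), numeric(1))
  list(lower = lower, upper = upper)
}

# generic weighted-SSR fit driver with multistart over log-KD
.fitIsotherm <- function(data, modelFun, free, init, nObsMin) {
  n <- length(data@sw)
  if (n < nObsMin)
    stop("need at least ", nObsMin, " isotherm points for this fit")
  if (length(free) < 1) stop("at least one free parameter required")
  span <- range(data@cLabeled + data@cUnlabeled)
  if (span[1] > 0 && log10(span[2] / span[1]) < 2)
    warning("concentration span below two decades; parameters may be poorly determined")
  w <- data@weight
  chisqFun <- function(parFull) {
    swModel <- modelFun(parFull)
    sum(w * (swModel - data@sw)^2)
  }
  objective <- function(parInternalFree, fixedInternal) {
    p <- c(parInternalFree, fixedInternal)
    chisqFun(.fromInternal(p[names(init)]))
  }
  initInternal <- unlist(.toInternal(init))
  bounds <- .parBounds(free, range(data@sw))
  fixedInternal <- initInternal[setdiff(names(init), free)]
  # multistart: KD-type starts spread over the concentration span
  starts <- list(initInternal[free])
  kdFree <- free[.isLogParam(free)]
  if (length(kdFree) > 0 && span[2] > 0) {
    for (shift in c(-1.5, 1.5)) {
      s <- initInternal[free]
      s[kdFree] <- pmin(pmax(s[kdFree] + shift, .LOG10KD.MIN), .LOG10KD.MAX)
      starts <- c(starts, list(s))
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- stats::nlminb(st, function(p) {
      names(p) <- free; objective(p, fixedInternal)
    }, lower = bounds$lower, upper = bounds$upper,
    control = list(rel.tol = 1e-12, x.tol = 1e-10))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  est <- best$par; names(est) <- free
  chisqMin <- best$objective
  list(estInternal = est, fixedInternal = fixedInternal, chisq = chisqMin,
       objective = objective, chisqFun = chisqFun, n = n, free = free,
       init = init, convergence = list(code = best$convergence,
                                       message = best$message,
                                       iterations = best$iterations))
}

# profile chi-square CI for one free parameter (internal scale), F-statistic
# acceptance threshold; re-optimizes the remaining free parameters.
.profileCI <- function(fit, parameter, level, maxExpand = 8,
                       bounds = NULL) {
  free <- fit$free
  others <- setdiff(free, parameter)
  ndf <- max(fit$n - length(free), 1)
  threshold <- fit$chisq * (1 + stats::qf(level, 1, ndf) / ndf)
  if (is.null(bounds)) bounds <- .parBounds(free, NULL)
  profChisq <- function(val) {
    if (length(others) == 0) {
      p <- c(val); names(p) <- parameter
      return(fit$objective(p, fit$fixedInternal))
    }
    io <- match(others, free)
    opt <- stats::nlminb(fit$estInternal[others], function(po) {
      p <- c(po, val); names(p) <- c(others, parameter)
      fit$objective(p, fit$fixedInternal)
    }, lower = bounds$lower[io], upper = bounds$upper[io],
    control = list(rel.tol = 1e-10))
    opt$objective
  }
  est <- fit$estInternal[[parameter]]
  step0 <- if (.isLogParam(parameter)) 0.25 else
    max(0.02 * max(abs(est), 1), 1e-3)
  ib <- match(parameter, free)
  searchEdge <- c(bounds$lower[ib], bounds$upper[ib])
  oneSide <- function(dir) {
    lo <- est; chiLo <- fit$chisq
    step <- step0
    for (k in seq_len(4 * maxExpand)) {
      hi <- est + dir * step
      atEdge <- (dir < 0 && hi <= searchEdge[1]) ||
                (dir > 0 && hi >= searchEdge[2])
      hi <- min(max(hi, searchEdge[1]), searchEdge[2])
      chiHi <- profChisq(hi)
      if (chiHi >= threshold) {
        for (b in 1:25) {             # bisect the crossing
          mid <- (lo + hi) / 2
          chiMid <- profChisq(mid)
          if (chiMid >= threshold) { hi <- mid; chiHi <- chiMid }
          else { lo <- mid; chiLo <- chiMid }
        }
        return(list(value = (lo + hi) / 2, open = FALSE))
      }
      if (atEdge) return(list(value = hi, open = TRUE))
      lo <- hi; chiLo <- chiHi
      step <- step * 1.6
    }
    list(value = lo, open = TRUE)
  }
  lower <- oneSide(-1); upper <- oneSide(+1)
  list(lower = lower, upper = upper, threshold = threshold)
}

.buildFitResult <- function(fit, level = 0.95) {
  free <- fit$free
  estimates <- unlist(.fromInternal(as.list(fit$estInternal)))
  fixed <- if (length(fit$fixedInternal))
    unlist(.fromInternal(as.list(fit$fixedInternal))) else numeric(0)
  ci <- matrix(NA_real_, nrow = length(free), ncol = 2,
               dimnames = list(free, c("lower", "upper")))
  flags <- list()
  for (nm in free) {
    pr <- .profileCI(fit, nm, level)
    lo <- pr$lower$value; hi <- pr$upper$value
    if (.isLogParam(nm)) { lo <- 10^lo; hi <- 10^hi }
    ci[nm, ] <- c(lo, hi)
    if (pr$lower$open && pr$upper$open) flags[[nm]] <- "unidentified"
    else if (pr$upper$open) { flags[[nm]] <- "lower"; ci[nm, 2] <- NA }
    else if (pr$lower$open) { flags[[nm]] <- "upper"; ci[nm, 1] <- NA }
  }
  rms <- sqrt(fit$chisq / fit$n)
  obj <- function(parFull) fit$chisqFun(parFull)
  new("FitResult", estimates = estimates, fixed = fixed, ci95 = ci,
      chisq = fit$chisq, rms = rms, nObs = as.integer(fit$n), flags = flags,
      convergence = fit$convergence, objective = obj, freeNames = free)
}

#' Fit a monomer-dimer sw isotherm
#'
#' Weighted nonlinear least squares of the self-association isotherm
#' (see [swHomoIsotherm]) to an [IsothermDataset-class]. KD is optimized in
#' log space with multistart; s-values and the incompetent fraction can be
#' fixed (e.g. at c(s)-derived values) or refined. Confidence intervals are
#' error-projection (profile chi-square) intervals at the 95 percent level;
#' parameters whose profile never crosses the F-statistic threshold are
#' flagged as one-sided bounds.
#'
#' @param data An [IsothermDataset-class] (>= 4 points). Total concentration
#'   per point is cLabeled + cUnlabeled.
#' @param free character subset of c("KD", "s1", "s2", "fInc").
#' @param start named list of start/fixed values; defaults: KD from the
#'   median concentration, s1/s2 from the sw range, fInc 0.
#' @return A [FitResult-class].
#' @export
fitHomoIsotherm <- function(data, free = "KD", start = list()) {
  ctot <- data@cLabeled + data@cUnlabeled
  init <- list(KD = start$KD %||% stats::median(ctot),
               s1 = start$s1 %||% min(data@sw),
               s2 = start$s2 %||% max(data@sw),
               fInc = start$fInc %||% 0)
  modelFun <- function(p) {
    .swHomoRaw(ctot, 1 / p[["KD"]], p[["s1"]], p[["s2"]], p[["fInc"]])
  }
  fit <- .fitIsotherm(data, modelFun, free, init, nObsMin = 4)
  res <- .buildFitResult(fit)
  if (!is.null(res@flags$KD))
    message("KD reported as a ", res@flags$KD, "-bound-only result")
  res
}

#' Fit a competitive hetero-dimerization sw isotherm
#'
#' Fits the coupled-equilibrium isotherm (see [swHeteroIsotherm]) with the
#' two homo-dimerization models fixed at independently determined values,
#' refining the heterodimer KD (log space) and s-value.
#'
#' @param data An [IsothermDataset-class] (>= 5 points) with the tracer in
#'   the cLabeled column and the titrant in cUnlabeled.
#' @param system A [HeteroSystemModel-class] carrying the fixed homo models;
#'   its KXY/sXY serve as start values.
#' @param free character subset of c("KDXY", "sXY"); default both.
#' @return A [FitResult-class]. Warns when the titration reaches less than
#'   80 percent saturation at the highest titrant concentration (asymmetric
#'   CIs expected).
#' @export
fitHeteroIsotherm <- function(data, system, free = c("KDXY", "sXY")) {
  init <- list(KDXY = if (system@KXY > 0) 1 / system@KXY else
                 stats::median(data@cUnlabeled[data@cUnlabeled > 0]),
               sXY = system@sXY)
  mx <- system@modelX; my <- system@modelY
  modelFun <- function(p) {
    .swHeteroRaw(data@cLabeled, data@cUnlabeled, mx@K12, my@K12,
                 1 / p[["KDXY"]], mx@s1, mx@s2, p[["sXY"]], mx@fInc, my@fInc)
  }
  fit <- .fitIsotherm(data, modelFun, free, init, nObsMin = 5)
  res <- .buildFitResult(fit)
  # saturation diagnostic at the best fit
  est <- res@estimates
  sysFit <- HeteroSystemModel(system@modelX, system@modelY,
                              KDXY = est[["KDXY"]],
                              sXY = if ("sXY" %in% names(est))
                                est[["sXY"]] else system@sXY)
  iMax <- which.max(data@cUnlabeled)
  swMax <- swHeteroIsotherm(data@cLabeled[iMax], data@cUnlabeled[iMax], sysFit)
  sat <- (swMax - system@modelX@s1) / (sysFit@sXY - system@modelX@s1)
  if (is.finite(sat) && sat < 0.8)
    warning(sprintf("titration reaches only %.0f%% saturation; expect an asymmetric KD interval", 100 * sat))
  res
}

#' Error-projection confidence interval for a fitted parameter
#'
#' Profiles the chi-square surface over one parameter (log grid for KD-type
#' parameters), re-optimizing all other free parameters at each point, and
#' reports the region where chi-square stays below
#' chisq_min (1 + F(level; 1, N - M)/(N - M)). Open-ended profiles yield
#' one-sided bounds with a warning.
#'
#' @param data the [IsothermDataset-class] that was fit.
#' @param fit a [FitResult-class] from [fitHomoIsotherm] or
#'   [fitHeteroIsotherm].
#' @param parameter free parameter name.
#' @param level confidence level; default 0.95.
#' @param system the [HeteroSystemModel-class] when `fit` is a hetero fit.
#' @return Numeric c(lower, upper) on the natural parameter scale; NA marks
#'   an open side.
#' @export
errorProjectionCI <- function(data, fit, parameter, level = 0.95,
                              system = NULL) {
  if (!parameter %in% fit@freeNames) stop("not a free parameter: ", parameter)
  refit <- .refitHandle(data, fit, system)
  pr <- .profileCI(refit, parameter, level)
  lo <- pr$lower$value; hi <- pr$upper$value
  if (.isLogParam(parameter)) { lo <- 10^lo; hi <- 10^hi }
  if (pr$lower$open) { warning("lower profile not bracketed; one-sided CI"); lo <- NA }
  if (pr$upper$open) { warning("upper profile not bracketed; one-sided CI"); hi <- NA }
  c(lower = lo, upper = hi)
}

# rebuild the internal fit handle from a FitResult for re-profiling
.refitHandle <- function(data, fit, system = NULL) {
  isHetero <- "KDXY" %in% c(fit@freeNames, names(fit@fixed))
  if (isHetero) {
    if (is.null(system)) stop("hetero fits need the system for re-profiling")
    mx <- system@modelX; my <- system@modelY
    modelFun <- function(p) {
      .swHeteroRaw(data@cLabeled, data@cUnlabeled, mx@K12, my@K12,
                   1 / p[["KDXY"]], mx@s1, mx@s2, p[["sXY"]],
                   mx@fInc, my@fInc)
    }
    init <- as.list(c(fit@estimates, fit@fixed))[c("KDXY", "sXY")]
  } else {
    ctot <- data@cLabeled + data@cUnlabeled
    modelFun <- function(p) {
      .swHomoRaw(ctot, 1 / p[["KD"]], p[["s1"]], p[["s2"]], p[["fInc"]])
    }
    init <- as.list(c(fit@estimates, fit@fixed))[c("KD", "s1", "s2", "fInc")]
  }
  .fitIsotherm(data, modelFun, fit@freeNames, init,
               nObsMin = length(data@sw))
}
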