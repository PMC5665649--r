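# Diffusion-deconvoluted sedimentation coefficient distributions c(s):
# regularized non-negative linear inversion of scan data against a family of
# single-species Lamm solutions sharing one frictional ratio, plus the
# transport-method sw integration and peak analysis.

#' Precompute the c(s) kernel matrix for a scan layout
#'
#' Solves the single-species Lamm equation at unit loading for every grid
#' s-value (diffusion from the common frictional ratio) on the geometry and
#' scan schedule of `scans`. The kernel can be reused for every sample of a
#' concentration series that shares geometry, rotor speed and scan times.
#'
#' @param scans A [ScanSet-class] defining geometry, conditions, times, radii.
#' @param grid An [SGrid-class].
#' @param courant solver Courant number.
#' @return List with the kernel matrix `A` (rows = stacked scans x radii,
#'   columns = s grid) and layout descriptors, for use by [fitCS].
#' @export
csKernel <- function(scans, grid, courant = 0.5) {
  geom <- RadialGeometry(scans@geometry@meniscus, scans@geometry@bottom,
                         nPoints = length(scans@radii),
                         sectorShaped = scans@geometry@sectorShaped)
  nr <- length(scans@radii); nt <- length(scans@times)
  A <- matrix(0, nrow = nt * nr, ncol = length(grid@sValues))
  for (i in seq_along(grid@sValues)) {
    s <- grid@sValues[i]
    sp <- SedimentingSpecies(sprintf("s%.3f", s), s,
                             frictionalRatio = grid@frictionalRatio,
                             conditions = scans@conditions)
    sol <- solveLamm(sp, geom, scans@conditions, 1, scans@times, courant)
    prof <- sol@signal
    if (max(abs(sol@radii - scans@radii)) > 1e-9) {
      prof <- t(apply(prof, 1, function(row)
        stats::approx(sol@radii, row, xout = scans@radii, rule = 2)$y))
    }
    A[, i] <- as.vector(t(prof))      # scan-major stacking
  }
  list(A = A, sValues = grid@sValues, frictionalRatio = grid@frictionalRatio,
       times = scans@times, radii = scans@radii)
}

# Non-negative least squares solved as a strictly convex quadratic program
# (active-set dual method). A minute ridge guards positive definiteness on
# the near-degenerate augmented systems of the lambda search; it is far below
# the reported precision of the coefficients.
.nnlsSafe <- function(M, v) {
  n <- ncol(M)
  D <- crossprod(M)
  dvec <- crossprod(M, v)
  scl <- mean(diag(D))
  sol <- tryCatch(
    quadprog::solve.QP(D + diag(1e-12 * scl, n), dvec, diag(n),
                       rep(0, n))$solution,
    error = function(e)
      quadprog::solve.QP(D + diag(1e-8 * scl, n), dvec, diag(n),
                         rep(0, n))$solution)
  list(x = pmax(sol, 0))
}

# Non-negative least squares on a reduced (QR-compressed) system, optionally
# with quadratic penalty rows sqrt(lambda) * L and zero penalty targets.
.nnlsPenalized <- function(R, Qtb, L = NULL, lambda = 0) {
  if (lambda > 0 && !is.null(L)) {
    M <- rbind(R, sqrt(lambda) * L)
    v <- c(Qtb, rep(0, nrow(L)))
  } else {
    M <- R; v <- Qtb
  }
  fit <- .nnlsSafe(M, v)
  x <- fit$x
  list(x = x, rss = sum((R %*% x - Qtb)^2))
}

# Second-difference smoothness operator on the grid (Tikhonov penalty).
.diff2Matrix <- function(n, nFree) {
  if (n < 3) return(matrix(0, 1, nFree))
  L <- matrix(0, n - 2, nFree)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}

#' Fit a c(s) sedimentation coefficient distribution
#'
#' Solves the non-negative linear inversion signal(r, t) = sum_i c_i
#' chi(s_i, D(s_i); r, t) with kernels from the Lamm solver. The
#' regularization strength is chosen as the largest penalty for which the
#' regularized chi-square does not exceed the unregularized minimum by more
#' than the one-parameter F-statistic ratio at `confidenceLevel`. Maximum
#' entropy is implemented as an iteratively reweighted quadratic penalty
#' favouring parsimonious (low-information) distributions; Tikhonov as a
#' second-difference smoothness penalty.
#'
#' @param scans A [ScanSet-class] (>= 2 scans; >= 10 recommended).
#' @param grid An [SGrid-class] spanning the sedimenting signal.
#' @param regularization "maxent" (default), "tikhonov" or "none".
#' @param confidenceLevel P for the chi-square acceptance ratio; default 0.68.
#' @param baseline logical, co-fit a radially constant baseline; default FALSE.
#' @param kernel optional precomputed [csKernel] for this scan layout.
#' @param scanThin use every `scanThin`-th scan; default 1.
#' @param radialThin use every `radialThin`-th radius; default 1.
#' @param excludeBottom radial extent (cm) excluded from the fit at the cell
#'   bottom, where back-diffusion piles up; default 0.15. For reacting
#'   samples the local re-equilibration in the pileup region is not
#'   representable by a superposition of non-interacting species, so the
#'   region is left out of the analysis window, as is conventional.
#' @param excludeMeniscus radial extent (cm) excluded at the meniscus.
#' @return A [CSDistribution-class]; coefficients are signal per Svedberg on
#'   the grid, integrating to the total boundary signal in the fit window.
#' @export
fitCS <- function(scans, grid, regularization = c("maxent", "tikhonov", "none"),
                  confidenceLevel = 0.68, baseline = FALSE, kernel = NULL,
                  scanThin = 1L, radialThin = 1L, excludeBottom = 0.15,
                  excludeMeniscus = 0.02) {
  regularization <- match.arg(regularization)
  if (length(scans@times) < 2) stop("need at least 2 scans")
  if (is.null(kernel)) kernel <- csKernel(scans, grid)
  sVals <- kernel$sValues
  ns <- length(sVals)
  ds <- mean(diff(sVals))
  nt <- length(scans@times); nr <- length(scans@radii)
  b <- as.vector(t(scans@signal))
  A <- kernel$A
  keepScan <- seq(1, nt, by = scanThin)
  inWindow <- which(scans@radii >= scans@geometry@meniscus + excludeMeniscus &
                    scans@radii <= scans@geometry@bottom - excludeBottom)
  keepRad <- inWindow[seq(1, length(inWindow), by = radialThin)]
  keep <- as.vector(outer((keepScan - 1) * nr, keepRad, `+`))
  if (length(keep) < nt * nr) { A <- A[keep, , drop = FALSE]; b <- b[keep] }
  if (baseline) A <- cbind(A, 1, -1)
  M <- ncol(A)
  N <- nrow(A)
  if (max(abs(b)) == 0) {
    return(new("CSDistribution", grid = grid, coefficients = rep(0, ns),
               regularization = regularization, lambda = 0,
               confidenceLevel = confidenceLevel, rmsd = 0, baseline = 0,
               metadata = list(note = "all-zero data")))
  }
  qrA <- qr(A)
  R <- qr.R(qrA)
  Qtb <- qr.qty(qrA, b)[seq_len(M)]
  rss0const <- sum(b^2) - sum(qr.qty(qrA, b)[seq_len(M)]^2)  # projection residual
  fit0 <- .nnlsPenalized(R, Qtb)
  chisq0 <- rss0const + fit0$rss
  if (regularization == "none" || ns < 3) {
    x <- fit0$x; lambda <- 0
  } else {
    ndf <- max(N - M, 1)
    target <- chisq0 * (1 + stats::qf(confidenceLevel, 1, ndf) / ndf)
    evalLambda <- function(lambda) {
      if (regularization == "tikhonov") {
        L <- .diff2Matrix(ns, M)
        f <- .nnlsPenalized(R, Qtb, L, lambda)
      } else {
        # maxent: iteratively reweighted quadratic, weights 1/sqrt(prior).
        # The prior is smoothed over neighbouring grid points so that a
        # species falling between grid nodes is not split into spikes.
        smooth3 <- function(x) {
          n <- length(x)
          (c(x[1], x[-n]) + x + c(x[-1], x[n])) / 3
        }
        prior <- pmax(smooth3(fit0$x[seq_len(ns)]),
                      1e-3 * max(fit0$x, 1e-30))
        for (it in 1:3) {
          L <- cbind(diag(1 / sqrt(prior), ns), matrix(0, ns, M - ns))
          f <- .nnlsPenalized(R, Qtb, L, lambda)
          prior <- pmax(smooth3(f$x[seq_len(ns)]),
                        1e-3 * max(f$x, 1e-30))
        }
      }
      f
    }
    scale0 <- sum(diag(R)^2) / max(sum(fit0$x^2), 1e-300)
    lambda <- 1e-6 * scale0 * max(fit0$x^2)
    lambda <- max(lambda, 1e-300)
    f <- evalLambda(lambda)
    grow <- 0
    while (rss0const + f$rss <= target && grow < 18) {
      lambda <- lambda * 10; f <- evalLambda(lambda); grow <- grow + 1
    }
    lo <- lambda / 10; hi <- lambda
    if (grow == 0) { lo <- 0; hi <- lambda }
    for (it in 1:10) {
      mid <- sqrt(max(lo, hi * 1e-4) * hi)
      f <- evalLambda(mid)
      if (rss0const + f$rss <= target) lo <- mid else hi <- mid
    }
    f <- evalLambda(lo)
    x <- f$x; lambda <- lo
    chisqReg <- rss0const + f$rss
  }
  base <- if (baseline) x[M - 1] - x[M] else 0
  coefs <- x[seq_len(ns)]
  rmsd <- sqrt((rss0const + sum((R %*% x - Qtb)^2)) / N)
  span <- diff(range(sVals))
  if (sum(coefs) > 0) {
    wmean <- sum(sVals * coefs) / sum(coefs)
    if (wmean < min(sVals) + 0.02 * span || wmean > max(sVals) - 0.02 * span)
      warning("c(s) mass concentrated at the grid edge; widen the s range")
  }
  new("CSDistribution", grid = grid, coefficients = coefs / ds,
      regularization = regularization, lambda = lambda,
      confidenceLevel = confidenceLevel, rmsd = rmsd, baseline = base,
      metadata = list(totalSignal = sum(coefs), nScans = length(keepScan)))
}

#' Signal-weighted average sedimentation coefficient (transport method)
#'
#' Integrates the c(s) distribution over [sMin, sMax] to obtain
#' sw = int s c(s) ds / int c(s) ds, the transport-method weighted-average
#' sedimentation coefficient, which reflects overall mass transport
#' regardless of reaction kinetics.
#'
#' @param dist A [CSDistribution-class].
#' @param sMin,sMax integration limits (S) within the grid.
#' @return sw in Svedberg.
#' @export
swTransport <- function(dist, sMin, sMax) {
  s <- dist@grid@sValues
  if (sMin >= sMax) stop("sMin must be below sMax")
  inWin <- s >= sMin & s <= sMax
  c <- dist@coefficients[inWin]
  sIn <- s[inWin]
  tot <- pracma::trapz(sIn, c)
  if (!is.finite(tot) || tot <= 0) stop("zero integrated signal in [sMin, sMax]")
  pracma::trapz(sIn, sIn * c) / tot
}

#' Subtract a background scan set (e.g. carrier-protein signal)
#'
#' Pointwise subtraction of a background ScanSet, interpolated onto the data
#' radii and times when they nearly match.
#'
#' @param scans data [ScanSet-class].
#' @param background background [ScanSet-class] on a compatible radius range.
#' @return A [ScanSet-class] with the background removed; the operation is
#'   recorded in the metadata.
#' @export
subtractBackground <- function(scans, background) {
  if (background@geometry@meniscus > scans@geometry@meniscus + 1e-6 ||
      background@geometry@bottom < scans@geometry@bottom - 1e-6)
    stop("incompatible radius ranges")
  bs <- background@signal
  if (max(abs(background@radii - scans@radii)) > 1e-9 ||
      length(background@radii) != length(scans@radii)) {
    bs <- t(apply(bs, 1, function(row)
      stats::approx(background@radii, row, xout = scans@radii, rule = 2)$y))
  }
  if (length(background@times) != length(scans@times) ||
      max(abs(background@times - scans@times)) > 1e-6) {
    bs <- apply(bs, 2, function(colv)
      stats::approx(background@times, colv, xout = scans@times, rule = 2)$y)
    if (is.null(dim(bs))) bs <- matrix(bs, nrow = length(scans@times))
  }
  md <- scans@metadata
  md$backgroundSubtracted <- TRUE
  ScanSet(scans@times, scans@radii, scans@signal - bs, scans@channel,
          scans@conditions, scans@geometry, md)
}

#' Peak positions of a c(s) distribution
#'
#' Local maxima above a relative amplitude threshold; each peak is reported
#' with its signal-weighted centroid over the contiguous region between the
#' surrounding local minima. Ties in amplitude are broken toward higher s.
#'
#' @param dist A [CSDistribution-class].
#' @param threshold relative amplitude threshold; default 0.05 of the maximum.
#' @param prominence adjacent maxima whose separating valley stays above this
#'   fraction of the smaller maximum are merged into one peak; default 0.5.
#' @param minSeparation maxima closer than this many grid intervals are below
#'   the resolution of the s grid and are merged; default 3.
#' @return data.frame with columns `s` (centroid, S), `sMode` (grid maximum),
#'   `amplitude` and `signal` (integrated area), ordered by s.
#' @export
peakPositions <- function(dist, threshold = 0.05, prominence = 0.5,
                          minSeparation = 3L) {
  s <- dist@grid@sValues
  c <- dist@coefficients
  n <- length(c)
  if (max(c) <= 0) return(data.frame(s = numeric(0), sMode = numeric(0),
                                     amplitude = numeric(0), signal = numeric(0)))
  thr <- threshold * max(c)
  isMax <- which(c >= thr &
                 c >= c(c[-1], -Inf) &     # >= right neighbour: ties -> higher s
                 c > c(-Inf, c[-n]))       # >  left neighbour
  if (length(isMax) == 0) isMax <- which.max(c)
  # merge split peaks: a valley that stays above `prominence` of the smaller
  # neighbouring maximum does not separate two species
  repeat {
    if (length(isMax) < 2) break
    merged <- FALSE
    for (k in seq_len(length(isMax) - 1)) {
      i1 <- isMax[k]; i2 <- isMax[k + 1]
      valley <- min(c[i1:i2])
      if (i2 - i1 < minSeparation ||
          valley > prominence * min(c[i1], c[i2])) {
        keep <- if (c[i1] >= c[i2]) i1 else i2
        isMax <- c(isMax[seq_len(k - 1)], keep,
                   if (k + 2 <= length(isMax)) isMax[(k + 2):length(isMax)])
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # segment boundaries: minima between consecutive peaks
  bounds <- c(1, vapply(seq_len(length(isMax) - 1), function(k) {
    i1 <- isMax[k]; i2 <- isMax[k + 1]
    i1 + which.min(c[i1:i2]) - 1
  }, numeric(1)), n)
  out <- lapply(seq_along(isMax), function(k) {
    idx <- bounds[k]:bounds[k + 1]
    w <- c[idx]
    data.frame(s = sum(s[idx] * w) / sum(w), sMode = s[isMax[k]],
               amplitude = c[isMax[k]], signal = pracma::trapz(s[idx], w))
  })
  do.call(rbind, out)
}
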