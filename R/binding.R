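# Mass-action equilibrium algebra for competitive homo/hetero-dimerization,
# sw isotherm models, and thermodynamic/kinetic conversions.

#' Monomer-dimer equilibrium at a given total protomer concentration
#'
#' Solves the mass action law c2 = K12 c1^2 under protomer conservation
#' ctot = c1 + 2 c2. The monomer concentration has the closed form
#' c1 = 2 ctot / (1 + sqrt(1 + 8 K12 ctot)), numerically stable for all K12
#' including the non-associating limit K12 = 0.
#'
#' @param ctot total protomer concentration(s), mol/L (vectorized).
#' @param model A [HomoDimerModel-class] (only K12 is used), or a numeric
#'   association constant K12 (1/M).
#' @return List with components `c1` (monomer, M) and `c2` (dimer, M).
#' @examples
#' m <- HomoDimerModel(KD = 1.2e-6)
#' solveHomo(1.2e-6, m)   # at ctot = KD the protomer monomer fraction is 1/2
#' @export
solveHomo <- function(ctot, model) {
  K <- if (is(model, "HomoDimerModel")) model@K12 else as.numeric(model)
  stopifnot(all(ctot >= 0), K >= 0)
  c1 <- 2 * ctot / (1 + sqrt(1 + 8 * K * ctot))
  list(c1 = c1, c2 = K * c1^2)
}

# Free monomer of Y given free monomer of X: the quadratic
# 2 KY cY1^2 + (1 + KXY cX1) cY1 - cYtot = 0, stable root.
.freeGivenPartner <- function(cTot, Kself, KXY, cPartner1) {
  b <- 1 + KXY * cPartner1
  if (Kself > 0) 2 * cTot / (b + sqrt(b^2 + 8 * Kself * cTot)) else cTot / b
}

#' Coupled homo/hetero-dimerization equilibrium
#'
#' Unique non-negative solution of the three coupled mass action equilibria
#' cX2 = KX12 cX1^2, cY2 = KY12 cY1^2, cXY = KXY cX1 cY1 under the protomer
#' conservation laws cXtot = cX1 + 2 cX2 + cXY and cYtot = cY1 + 2 cY2 + cXY.
#' Solved by damped Newton iteration on the log free-monomer concentrations
#' with an analytic Jacobian, with a bracketed-bisection fallback; residuals
#' converge below 1e-12 relative.
#'
#' @param cXtot,cYtot total protomer concentrations (M), vectorized.
#' @param system A [HeteroSystemModel-class].
#' @return List of concentration vectors `cX1`, `cX2`, `cY1`, `cY2`, `cXY` (M).
#' @examples
#' sys <- HeteroSystemModel(HomoDimerModel(KD = 1.2e-6),
#'                          HomoDimerModel(KD = 163e-9), KDXY = 1.8e-6)
#' solveHetero(1e-9, 1e-6, sys)
#' @export
solveHetero <- function(cXtot, cYtot, system) {
  .solveHeteroRaw(cXtot, cYtot, system@modelX@K12, system@modelY@K12,
                  system@KXY)
}

.solveHeteroRaw <- function(cXtot, cYtot, KX, KY, KXY) {
  stopifnot(all(cXtot >= 0), all(cYtot >= 0))
  n <- max(length(cXtot), length(cYtot))
  cXtot <- rep_len(cXtot, n); cYtot <- rep_len(cYtot, n)
  cX1 <- numeric(n); cY1 <- numeric(n)
  pos <- cXtot > 0 | cYtot > 0
  if (any(pos)) {
    xt <- cXtot[pos]; yt <- cYtot[pos]
    # start from the uncoupled homo equilibria
    x <- pmax(solveHomo(xt, KX)$c1, 1e-300)
    y <- pmax(solveHomo(yt, KY)$c1, 1e-300)
    x[xt == 0] <- 0; y[yt == 0] <- 0
    resid <- function(x, y) {
      fx <- x + 2 * KX * x^2 + KXY * x * y - xt
      fy <- y + 2 * KY * y^2 + KXY * x * y - yt
      cbind(fx, fy)
    }
    # a few Gauss-Seidel sweeps of exact quadratic updates to get close
    for (k in 1:30) {
      y <- ifelse(yt > 0, .freeGivenPartner(yt, KY, KXY, x), 0)
      x <- ifelse(xt > 0, .freeGivenPartner(xt, KX, KXY, y), 0)
    }
    # damped Newton on (log x, log y) where both totals are positive
    nb <- xt > 0 & yt > 0
    if (any(nb)) {
      xs <- x[nb]; ys <- y[nb]; xtn <- xt[nb]; ytn <- yt[nb]
      scale <- pmax(xtn, ytn)
      for (it in 1:60) {
        fx <- xs + 2 * KX * xs^2 + KXY * xs * ys - xtn
        fy <- ys + 2 * KY * ys^2 + KXY * xs * ys - ytn
        if (max(abs(fx) / xtn, abs(fy) / ytn) < 1e-13) break
        # Jacobian wrt (log x, log y)
        j11 <- xs * (1 + 4 * KX * xs + KXY * ys)
        j22 <- ys * (1 + 4 * KY * ys + KXY * xs)
        j12 <- KXY * xs * ys
        det <- j11 * j22 - j12 * j12
        du <- -( j22 * fx - j12 * fy) / det
        dv <- -(-j12 * fx + j11 * fy) / det
        # limit the log step for global robustness
        cap <- pmax(1, pmax(abs(du), abs(dv)) / 2)
        xs <- xs * exp(du / cap)
        ys <- ys * exp(dv / cap)
      }
      x[nb] <- xs; y[nb] <- ys
    }
    r <- resid(x, y)
    bad <- which(pmax(abs(r[, 1]) / pmax(xt, 1e-300),
                      abs(r[, 2]) / pmax(yt, 1e-300)) > 1e-10 &
                 xt > 0 & yt > 0)
    for (i in bad) {  # bracketed bisection fallback on cX1
      lo <- 0; hi <- xt[i]
      for (k in 1:200) {
        mid <- (lo + hi) / 2
        yv <- .freeGivenPartner(yt[i], KY, KXY, mid)
        f <- mid + 2 * KX * mid^2 + KXY * mid * yv - xt[i]
        if (f > 0) hi <- mid else lo <- mid
      }
      x[i] <- (lo + hi) / 2
      y[i] <- .freeGivenPartner(yt[i], KY, KXY, x[i])
    }
    cX1[pos] <- x; cY1[pos] <- y
  }
  list(cX1 = cX1, cX2 = KX * cX1^2, cY1 = cY1, cY2 = KY * cY1^2,
       cXY = KXY * cX1 * cY1)
}

#' sw isotherm of a monomer-dimer self-association
#'
#' The signal-weighted average sedimentation coefficient of a homodimerizing
#' component, sw = (s1 c1 + 2 s2 c2) / (c1 + 2 c2), evaluated on the
#' dimerization-competent sub-population (1 - fInc) ctot; the incompetent
#' fraction contributes signal permanently at the monomer s-value.
#'
#' @param ctot total protomer concentration(s), M (vectorized).
#' @param model A [HomoDimerModel-class].
#' @return sw in Svedberg.
#' @examples
#' m <- HomoDimerModel(KD = 163e-9, s1 = 3.8, s2 = 5.8)
#' swHomoIsotherm(163e-9, m)     # (s1+s2)/2 at ctot = KD
#' @export
swHomoIsotherm <- function(ctot, model) {
  stopifnot(all(ctot > 0))
  .swHomoRaw(ctot, model@K12, model@s1, model@s2, model@fInc)
}

# unvalidated algebra used by the fit objectives (optimizers may probe
# physically inadmissible corners such as s2 <= s1)
.swHomoRaw <- function(ctot, K12, s1, s2, fInc) {
  c1 <- 2 * (1 - fInc) * ctot / (1 + sqrt(1 + 8 * K12 * (1 - fInc) * ctot))
  c2 <- K12 * c1^2
  (s1 * fInc * ctot + s1 * c1 + 2 * s2 * c2) / ctot
}

#' sw isotherm of competitive homo/hetero-dimerization, traced through X
#'
#' Evaluates sw = (sX1 cX1 + 2 sX2 cX2 + sXY cXY) / (cX1 + 2 cX2 + cXY) on
#' the coupled equilibrium state: only species containing the labeled
#' component X carry signal, with the labeled homodimer counting two labeled
#' protomers and the heterodimer one.
#'
#' @param cXtot labeled-component total protomer concentration (M), vectorized.
#' @param cYtot unlabeled titrant total protomer concentration (M), vectorized.
#' @param system A [HeteroSystemModel-class]; incompetent fractions of the two
#'   [HomoDimerModel-class] components are honoured (incompetent X material
#'   sediments at sX1; incompetent Y material is invisible but withdrawn from
#'   the reactive pool).
#' @return sw in Svedberg.
#' @export
swHeteroIsotherm <- function(cXtot, cYtot, system) {
  stopifnot(all(cXtot > 0), all(cYtot >= 0))
  .swHeteroRaw(cXtot, cYtot, system@modelX@K12, system@modelY@K12,
               system@KXY, system@modelX@s1, system@modelX@s2, system@sXY,
               system@modelX@fInc, system@modelY@fInc)
}

.swHeteroRaw <- function(cXtot, cYtot, KX, KY, KXY, sX1, sX2, sXY,
                         fIncX = 0, fIncY = 0) {
  n <- max(length(cXtot), length(cYtot))
  cXtot <- rep_len(cXtot, n); cYtot <- rep_len(cYtot, n)
  eq <- .solveHeteroRaw((1 - fIncX) * cXtot, (1 - fIncY) * cYtot, KX, KY, KXY)
  (sX1 * fIncX * cXtot + sX1 * eq$cX1 + 2 * sX2 * eq$cX2 + sXY * eq$cXY) /
    cXtot
}

#' Normalize sw to the monomer-dimer range
#'
#' Returns (sw - s1)/(s2 - s1), assigning 0 to a pure monomer and 1 to a pure
#' dimer population, the normalization used for isotherm overlays.
#'
#' @param sw sw value(s), Svedberg.
#' @param s1 monomer s-value (S).
#' @param s2 dimer s-value (S), must exceed s1.
#' @return Dimensionless normalized sw.
#' @export
normalizeSw <- function(sw, s1, s2) {
  if (s2 <= s1) stop("s2 must exceed s1")
  (sw - s1) / (s2 - s1)
}

#' Gibbs free energy of dimerization from KD
#'
#' Delta G = R T ln(KD / 1 M) with R = 1.98720e-3 kcal/(mol K); negative for
#' KD below the 1 M standard state.
#'
#' @param KD dissociation constant(s), M (> 0).
#' @param temperature absolute temperature (K); default 293.15 (20 C).
#' @return Delta G in kcal/mol.
#' @examples
#' deltaGFromKd(1.8e-6)   # about -7.7 kcal/mol
#' @export
deltaGFromKd <- function(KD, temperature = 293.15) {
  stopifnot(all(KD > 0), temperature > 0)
  1.98720e-3 * temperature * log(KD)
}

#' On-rate constant from off-rate and KD
#'
#' kon = koff / KD; a lower-limit koff implies a lower-limit kon, and the
#' bound flag is propagated via an attribute.
#'
#' @param koff off-rate constant (1/s, >= 0).
#' @param KD dissociation constant (M, > 0).
#' @param bound optional bound direction of koff ("lower"/"upper"/NULL).
#' @return kon in 1/(M s); attribute "bound" carries the propagated flag.
#' @examples
#' konFromKoffKd(3e-3, 21.1e-9, bound = "lower")  # >= 1.4e5 per M per s
#' @export
konFromKoffKd <- function(koff, KD, bound = NULL) {
  stopifnot(all(koff >= 0), all(KD > 0))
  out <- koff / KD
  attr(out, "bound") <- bound
  out
}

#' Fold ratio of two dissociation constants
#'
#' @param kdA,kdB positive KD values (M).
#' @return Nearest-integer fold ratio kdA/kdB; attribute "raw" keeps the
#'   unrounded ratio.
#' @examples
#' foldRatio(21.1e-9, 1.3e-9)  # 16
#' @export
foldRatio <- function(kdA, kdB) {
  stopifnot(kdA > 0, kdB > 0)
  r <- kdA / kdB
  out <- round(r)
  attr(out, "raw") <- r
  out
}
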