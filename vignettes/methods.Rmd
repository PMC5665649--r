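---
title: "Models and methods in sedimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sedimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedimer)
```

`sedimer` analyzes sedimentation velocity (SV) experiments on reversibly
dimerizing proteins, with an emphasis on the fluorescence-detected (FDS-SV)
tracer designs used to measure homo- and heterodimerization of ionotropic
glutamate receptor amino-terminal domains (ATDs). This vignette describes
the models, the numerical choices, what the synthetic-data generator does
and does not emulate, and the package's design decisions at points where
more than one convention is defensible.

## Sedimentation transport

A single species in a sector-shaped cell follows the Lamm equation

$$\frac{\partial c}{\partial t} = \frac{1}{r}\frac{\partial}{\partial r}
\left[ r D \frac{\partial c}{\partial r} - s\,\omega^2 r^2 c \right],$$

with impermeable walls at the meniscus $r_m$ and the bottom $r_b$.
`solveLamm` discretizes this with a finite-volume scheme on cell centers.
Interface fluxes use Scharfetter–Gummel exponential fitting: the flux
between cells is
$J = (D/\Delta r)\,[B(-P)\,c_L - B(P)\,c_R]$ with the cell Péclet number
$P = v\,\Delta r/D$ and $B(x) = x/(e^x - 1)$. This one formula degrades
gracefully to pure upwinding in the advection-dominated (non-diffusing)
limit and to central differencing in the diffusive limit, and it is exact
for locally steady drift–diffusion — which keeps the back-diffusion
pileup at the bottom well behaved. Time stepping is backward Euler with
sub-steps chosen so the advective Courant number stays at 0.5; the scheme
is unconditionally stable and, because the discrete fluxes telescope, the
sector-weighted amount $\int c\, r\,\mathrm{d}r$ is conserved to round-off.
Crank–Nicolson stepping was considered and rejected: it oscillates on the
steep 50,000 rpm boundaries unless the time step is cut far below what
backward Euler needs for the same accuracy, and the backward-Euler bias
cancels in all fitting operations because data and model kernels share one
solver.

Defaults: 400 radial cells; meniscus 6.0 cm and bottom 7.2 cm (a standard
12 mm double-sector centerpiece — column radii are conventions, since only
the pathlength is fixed by the cell); 50,000 rpm; 20&nbsp;°C; water-like
solvent ($\rho$ = 1.000 g/mL, $\eta$ = 0.01002 poise, $\bar v$ = 0.73 mL/g).
No standard-condition corrections are applied anywhere; solvent properties
enter only the scaling law
$D(s) = \frac{\sqrt 2}{18\pi} k T\, s^{-1/2} (\eta f/f_0)^{-3/2}
\left(\frac{1-\bar v \rho}{\bar v}\right)^{1/2}$
that assigns a diffusion coefficient to each s-value. Rotor acceleration is
idealized as instantaneous.

## Reaction-coupled boundaries

For a self-associating component (monomer $X_1$, dimer $X_2$), optionally
competing with a partner $Y$ and heterodimer $XY$, each species obeys its
own Lamm equation plus chemical source terms
$q_{XX} = k_{on} c_{X1}^2 - k_{off} c_{X2}$ and
$q_{XY} = k_{on} c_{X1} c_{Y1} - k_{off} c_{XY}$, with stoichiometry
$-2q$ on the monomer and $+q$ on the dimer. `simulateReactingSystem` uses
operator splitting — a transport step for every species, then local
chemistry:

* **Instantaneous equilibrium** projects the local protomer totals onto the
  mass-action manifold algebraically each sub-step. This removes all
  stiffness and is the reference limit for fast exchange.
* **Finite rates** integrate the local ODEs. For the homodimer alone the
  mass-action relaxation at fixed local total is a constant-coefficient
  Riccati equation with a closed-form solution, so that step is *exact* for
  any step size and any koff — the koff range from 1e-5 to 10 per second
  costs the same. The three-reaction competitive system has no closed form
  and is sub-cycled with Heun steps capped at one tenth of the fastest
  local relaxation time.

Samples are assumed pre-equilibrated: the initial composition is the
equilibrium of the uniform loading. Observed signal is the labeled-channel
sum over species — a labeled homodimer counts two labeled protomers, a
heterodimer with an unlabeled partner counts one, unlabeled species are
invisible.

## Mass-action equilibria

`solveHomo` uses the stable closed form
$c_1 = 2 c_{tot}/(1 + \sqrt{1 + 8 K_{12} c_{tot}})$. `solveHetero` solves
the three coupled equilibria under both conservation laws by Gauss–Seidel
sweeps of exact quadratic updates followed by damped Newton iteration on
the log free-monomer concentrations with the analytic Jacobian; points that
fail the 1e-10 relative-residual check (in practice none) fall back to
bracketed bisection, which cannot fail because the reduced one-dimensional
residual has a guaranteed sign change. The test suite and acceptance script
verify agreement with an independent bisection oracle to better than 1e-6
over 1000 random systems spanning K from 1e3 to 1e12 per molar.

## c(s) analysis and the transport method

`fitCS` solves the non-negative inversion
$\mathrm{signal}(r,t) \approx \sum_i c_i\, \chi(s_i, D(s_i); r, t)$ with
kernels from the same Lamm solver, a shared frictional ratio (default 1.5,
a typical value for compact glycosylated domains), and non-negative least
squares as the core solver — implemented as a strictly convex quadratic
program, which is immune to the cycling that plain Lawson–Hanson exhibits
on the near-degenerate augmented systems of the regularization search.

Regularization strength is chosen by the usual statistical criterion: the
largest penalty whose chi-square stays within the one-parameter F-ratio of
the unregularized minimum, at confidence P = 0.68 (the community's one-sigma
convention; the method prescribes the criterion, not the level). Two
penalties are exposed: `maxent` (default), an iteratively reweighted
quadratic with weights $1/\sqrt{\text{prior}}$ where the prior is the
neighbour-smoothed previous iterate — favouring parsimonious distributions
without splitting a species that falls between grid nodes into spikes — and
`tikhonov`, a second-difference smoothness penalty. The exact maximum-entropy
scaling of other implementations is not reproduced coefficient-by-coefficient;
equivalence is at the level of peak positions and integrals, which is what
the downstream analysis consumes.

Two windowing choices matter. The fit excludes 0.15 cm above the cell
bottom (and 0.02 cm below the meniscus): for *reacting* samples the
concentration pileup at the bottom locally re-equilibrates toward dimer,
which a superposition of non-interacting species cannot represent, and
including it biases the recovered distribution. With the window in place,
the transport-method average `swTransport` —
$s_w = \int s\,c(s)\,ds / \int c(s)\,ds$ — from simulated reacting
boundaries matches the algebraic isotherm within half a percent of
$(s_2 - s_1)$ across a full titration, for fast and slow kinetics alike,
which is the central internal-consistency property of the method.

`peakPositions` reports local maxima above 5% of the distribution maximum
(ties broken toward higher s), with signal-weighted centroids per peak.
Maxima closer than three grid intervals, or separated by a valley shallower
than half the smaller maximum, are merged — below that separation the grid
cannot resolve two species, and regularized inversions of noiseless data
otherwise fragment single species into adjacent spikes.

## Isotherm models and fitting

The sw isotherm of a homodimer follows
$s_w = (s_1 c_1 + 2 s_2 c_2)/(c_1 + 2 c_2)$ on the dimerization-competent
sub-population; a dimerization-incompetent fraction contributes signal
permanently at the monomer s-value (its hydrodynamics are taken as
monomeric — the natural reading of a binding-dead but folded species), so
the normalized isotherm plateaus at $1 - f_{inc}$. The competitive hetero
isotherm weighs only tracer-containing species. In titration designs the
labeled and unlabeled protomers of the same component are treated as
chemically identical (label inertness), so the tracer sw equals the
population sw.

`fitHomoIsotherm`/`fitHeteroIsotherm` minimize the weighted SSR with KD-type
parameters in log10 space, three starts spread over the concentration span,
uniform weights by default (per-point weights are accepted). Confidence
intervals are error-projection intervals: the parameter is profiled with all
other free parameters re-optimized, and the 95% region is where
$\chi^2 \le \chi^2_{min}\,(1 + F(0.95; 1, N{-}M)/(N{-}M))$. A profile that
never crosses the threshold before the search boundary (KD from 1e-13 to
1 M) yields a one-sided bound, reported as a "lower"/"upper" flag —
emulating entries like "KD > 1 mM" for a species that never dimerizes in
the measured range, or "< 50 pM" for one that never dissociates. The
sequential strategy — fix homo constants from independent measurements,
refine only the heterodimer KD and s-value — is the default hetero
interface; s-values can also be refined where a dataset determines them.

## Kinetic information

`fitKoff` fits scan data directly with the finite-rate forward model,
s-values fixed, koff on a log grid (default 7 points per decade over
1e-6–1 per second) with KD re-optimized at each point, a joint polish at the
best grid point, and a global amplitude factor fitted analytically. The
same F-statistic threshold applied to the koff profile gives either a
closed interval or a one-sided bound: boundary shapes lose sensitivity once
exchange is fast on the sedimentation time scale, so fast-truth data yield
lower limits only. A guard rejects data that are fully monomeric or fully
dimeric at loading (below 3% or above 97% dimerized protomer), where koff
is structurally unidentifiable.

`peakShiftRegime` classifies a c(s) concentration series as slow (dominant
modes stay within 15% of $(s_2-s_1)$ of the species positions, with only
amplitude exchange) or fast (a dominant mode more than 25% into the gap at
intermediate saturation). The 15%/25% thresholds were calibrated once on
simulated series across the 1e-5–1e-1 koff sweep; between roughly 3e-4 and
3e-3 per second the signatures genuinely overlap and "indeterminate" is the
honest answer. The dominant *mode* (not the merged-peak centroid) is the
discriminator, because a bimodal distribution with a shallow valley keeps
its modes at the species positions.

## Thermodynamic map

`deltaGFromKd` uses $\Delta G = RT \ln(K_D / 1\,\mathrm{M})$ with
R = 1.98720e-3 kcal/(mol·K) and T = 293.15 K — the only convention
consistent with the free-energy values the constants imply at 20&nbsp;°C.
`deltaGMap` converts a full constants table; where a pair was measured in
both labeling orientations (e.g. GluK2/GluK5 at 9.4 and 12 nM), the map
keeps both rather than electing one, and one-sided KD bounds propagate as
one-sided energy bounds.

## The synthetic-data generator

`buildScenario`/`generateDataset` replicate the study designs: tracer
titrations (constant 0.2–1 nM labeled species, unlabeled titrant from
sub-nanomolar to tens of micromolar) and dilution series (50 pM–1.2 µM),
at 50,000 rpm and 20&nbsp;°C in a 12 mm cell, with monomer/dimer s-values of
3.8/5.8 S for the kainate ATDs (heterodimer 5.6 S) and 4.4/6.25 S for the
EGFP-fused AMPA constructs, a 2.5 S free-EGFP contaminant where
configured, and the measured dissociation constants as ground truth
(`referenceConstants`; one-sided bounds are simulated at the bound value
and flagged in the truth record). Defaults the experiments do not pin
down are fixed once: 60 scans at 90 s intervals; fluorescence scaled so the
brightest sample reaches about 3000 counts; gaussian noise with rms 1% of
the plateau signal; a BSA-like constant background and per-scan jitter
available but off by default. Generation is bit-reproducible under the
scenario seed.

What the generator does *not* emulate: label-specific artifacts (FAM-type
sticky labels), photobleaching, concentration-dependent quantum yield,
radial-dependent detector sensitivity, time-invariant systematic noise, or
rotor acceleration. Passing tests therefore demonstrate correctness of the
transport/mass-action analysis chain under idealized optics, not robustness
to every instrumental artifact of real detectors.

## Problem sizes

The shipped tests and the acceptance script run reduced problem sizes
chosen to stay well inside the solver's resolved regime: 130–160 radial
cells and 15–18 scans for simulation-analysis loops (solver self-consistency
holds to better than 0.2% under grid refinement there), 400 cells for the
solver-analytics checks, 40-point s grids, 100 replicates for coverage,
and 1000 random systems for the equilibrium oracle. These are the sizes the
reported numbers refer to.

## Known limitations

* Only monomer–dimer and three-reaction competitive systems; no higher
  oligomers or mixed schemes.
* Kinetic fitting is implemented for homodimers (the competitive system's
  kinetics are simulated but not fitted), matching what tracer-level
  signal/noise supports.
* Absorbance optics are a channel tag, not a physical model; interference
  fringes and multi-wavelength detection are out of scope.
* The c(s) implementation claims agreement with established software at the
  level of peak positions, integrals and sw — not coefficient-level
  identity, since the reference maximum-entropy scaling is unpublished.
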