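---
title: "Models and methods behind notchcis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind notchcis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchcis)
```

This vignette documents the models implemented in `notchcis`, the
assumptions behind them, the tunable parameters with their defaults and
units, and the design choices made where several reasonable options
existed.  Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The cis-inhibition kinetic model

A cell produces Notch at rate $\beta_N$ (units: concentration/time) and
degrades it at $\gamma_N N$; a cis-ligand is produced at $\beta_D$ and
degraded at $\gamma_D D$.  Receptor and ligand in the *same* cell bind
reversibly ($k_{C\pm}$) and the bound complex is irreversibly removed
at $k_I$ (mutual inactivation).  Receptor and *trans* ligand on a
neighbouring cell bind with $k_{D\pm}$ and produce signal at $k_S$.
All quantities are in dimensionless model units; only the synthetic
data generators convert to fluorescence.

Assuming the cis complex is at quasi-steady state, the three ODEs
(`cis_ode_rhs()`) reduce to

$$N_{ss} = \frac{\beta_N/\gamma_N}{1 + D_{ss}/(k_c\gamma_N)},
\qquad k_c^{-1} = \frac{k_{C+}\,k_I}{k_{C-}+k_I},$$

implemented in `qss_available_notch()` and `effective_kc()`.  Two
properties anchor the test suite: $N_{ss}(0)=\beta_N/\gamma_N$, and
$D = k_c\gamma_N$ halves available Notch *exactly*, for any positive
parameters.  Because a true steady state also has $\dot C = 0$, the
reduced algebra is exact there — the algebraic solver and a stiff ODE
integration (`integrate_cis_ode()`, `deSolve::lsoda`, atol $10^{-12}$,
rtol $10^{-8}$) must agree to numerical precision, which the tests
check on random parameter sets drawn in the fast-complex regime
($k_I, k_{C-} \ge 10\gamma_N$).

**Two cis-ligands.** The assay model is single-ligand; for cells
expressing Dll1 and Jag1 (or Delta and Serrate) we use the minimal
extension consistent with the stoichiometry: independent cis reactions
sharing the Notch pool,
$\beta_N = N(\gamma_N + \sum_\ell D_\ell/k_{c\ell})$ and
$\beta_{D\ell} = D_\ell(\gamma_{D\ell} + N/k_{c\ell})$.
`solve_cis_steady_state()` uses the closed-form quadratic root for one
ligand and a damped fixed point on $N$ (fall-back: bracketed root
solve, tolerance $10^{-10}$ relative) for several; the balance is
monotone in $N$, so the root is unique.

**Trans signal rate.** With the trans complex at quasi-steady state the
signal production rate is $k_S k_{D+} N D/(k_{D-}+k_S)$
(`trans_signal_rate()`).  Ligand in the trans complex is not depleted
from the sender; whether it is recycled or consumed is not specified by
the underlying biology we model, and at the plate-bound-ligand and
lattice scales used here the distinction does not enter.

## Fringe modulation

Fringe enzymes re-weight Notch's interactions per ligand.  Directions
are established (Lfng/Mfng strengthen Dll1 cis and trans interactions
and weaken Jag1's; Rfng preserves or strengthens both; Fringe
expression also increases binding of the soluble detection reagent to
Notch), but magnitudes are not.  We therefore model a Fringe as
per-ligand fold-changes applied to the *association* rates
($k_{C+}, k_{D+}$), so that $k_c \to k_c/\text{cis factor}$, plus a
`detection_gain` on the receptor-availability signal.  Modulating
association, dissociation, or the lumped $k_c$ directly are
observationally equivalent at steady state; association was chosen as
the conventional site of affinity modulation.  Preset magnitudes
(`fringe_preset()`, YAML-overridable): Lfng/Mfng — Dll1 ×2, Jag1 ×0.2
(cis and trans); Rfng — ×1.5 for both; detection gain 1.5 for all
three.  The factor-of-5 weakening for Jag1 is the smallest round value
that cleanly separates the endpoint states below while a 10-fold
expression excess still dominates it; it is a preset, not an inference.

## Synthetic availability data

`generate_availability_dataset()` emulates the availability assay:

* **Dose–expression**: median total-ligand fluorescence follows a Hill
  curve in inducer dose (coefficient 2, EC50 25 ng/ml, basal 20,
  maximum 10^4 fluorescence units) across eight doses, 0–200 ng/ml;
  cells scatter log-normally around the median with $\sigma = 0.5$
  natural-log units, reproducing the order-of-magnitude per-dose spread
  of single-cell data.  Cell-to-cell variance and measurement CV are
  stated assumptions, not measured values.
* **Surface ligand**: proportional to total fluorescence with a
  per-ligand efficiency (defaults $10^{-3}$ for Dll1, $2\times10^{-3}$
  for Jag1 model units per fluorescence unit; Jag1 reaches the surface
  more efficiently, which the effective-ligand normalization must
  undo).
* **Availability**: free receptor and ligand from the cis steady state
  at the cell's (Fringe-modified) parameters; receptor signal scaled by
  `gain * detection_gain`, ligand signal by `gain` alone — the
  detection-gain change is a property of the Notch-binding reagent, so
  it does not apply to the ligand assay.
* **Noise**: multiplicative log-normal (CV 0.1) plus additive Gaussian
  background (mean 100, sd 20), clipped at zero.  With noise and
  background at zero the generated signal equals the gain-scaled model
  prediction exactly (tested).

The default kinetic condition (`assay_kinetic_params()`) uses
$k_c = 5$, placing the half-inhibition at an unopposed surface-ligand
level of 5.5 units — mid-range of the induced expression spread, so the
dose range brackets `L50` on both sides.  `generating_half_inhibition()`
returns the implied ground truth
($T_{1/2} = k_c\gamma_N(1+\beta_N/(2\gamma_N k_c\gamma_D))/\text{eff}$ =
5500 fluorescence units at the defaults) for recovery checks.

What the generator does *not* emulate: optical point-spread functions,
flow-cytometer optics, cell-cycle or density effects, receptor
trafficking.  Passing recovery tests therefore shows the pipeline is
consistent and well-calibrated under its own noise model — not that
real microscopes behave this way.

## The cis-inhibition fit

`fit_cis_inhibition()` fits
$\text{avail} = bg + A/(1 + L/L_{50})$ to *single cells* (each cell
weighted equally; fitting bin medians instead would discard the
per-bin sample sizes).  Because measurement noise is multiplicative,
residuals are taken on the log scale by default
(`log_residuals = FALSE` gives plain least squares).  Starting values
come from the data (high-ligand plateau for `bg`, low-ligand median for
`A`, running-median crossing for `L50`); optimisation is
Levenberg–Marquardt (`minpack.lm::nlsLM`) with non-negativity bounds.
Fits are flagged non-identifiable — with a warning, never an error —
when `L50` leaves the sampled ligand range, its relative standard error
exceeds 100%, or the optimiser fails (e.g. ligand-independent data).
The fitted `L50` is the fluorescence-scale analogue of $k_c\gamma_N$;
note it estimates the *total*-ligand level at half depletion, which
exceeds $k_c\gamma_N/\text{eff}$ slightly because free ligand is itself
depleted by the receptor (the closed-form truth above accounts for
this).  `half_inhibition_ratio()` compares two fits with first-order
error propagation.

`fit_saturation()` (calibration isotherm $aD/(D+K)$) uses
inverse-squared-fitted-signal weights (two-pass) for the same reason;
with 10% multiplicative noise on a two-replicate 8-point grid this
estimator recovers $K$ within ±25% in ≥90% of seeds, which unweighted
least squares does not achieve.

## Profiles, normalizations and tests

* `binned_median_profile()`: 12 bins evenly spaced in $\log_{10} x$,
  per-bin median with a percentile bootstrap CI (1000 resamples, 95%);
  bins with fewer than 10 points are flagged.  Bin/bootstrap counts are
  package defaults; only the 95% level is inherited from the assay
  convention.
* `normalize_effective_ligand()`: per-ligand straight-line fit of
  ligand-only availability against total fluorescence; slope ratios
  rescale each ligand's axis ("effective total ligand") so surface-
  efficiency differences cancel.  An intercept is included in the fit
  so the additive background does not bias the slope.
* `normalize_to_uninduced()`: divides a profile by the uninduced
  availability level, cancelling the Fringe detection gain.
* `compare_conditions()`: two-sided Wilcoxon rank-sum per shared bin,
  requiring ≥10 points per table per bin.  No multiple-testing
  correction by default — each bin is starred on its own p-value,
  matching the per-bin starring convention — with Benjamini–Hochberg
  available via `p_adjust = "BH"`.

## Dilution time courses and onset detection

`generate_dilution_timecourses()` models the washout assay: cis-ligand
decays at $\ln 2/T_{div} + \gamma_D$ (half per division, default
$T_{div}$ = 18 h; frames every 20 min over 60 h), free Notch tracks the
quasi-steady dose response at the current ligand level, and the
reporter integrates the trans rate from the plate-bound ligand with the
receiver's Fringe factors.  `dilution_kinetic_params()` sets
$k_c = 0.5$ and $\gamma_D = 0.02$/h, so pre-induced ligand (median 25
units) suppresses Notch ~50-fold at washout and ligand loss is
dilution-dominated.

`detect_t_on()` smooths the reporter with a 5-frame moving average,
estimates slopes by centered finite differences, takes the final slope
from a regression over the last 20% of frames (a regression, because
the moving-average pad at the series end deflates finite-difference
slopes there), and reports the first time the slope strictly exceeds
10% of the final slope.  A tiny relative epsilon ($10^{-9}$) on the
threshold keeps the marginal smoothing frame of an abrupt onset — where
the smoothed slope equals the threshold exactly — from triggering on
floating-point rounding; an ideal piecewise-linear onset is then
localized one frame early, within the frame interval.  Traces whose
final slope is non-positive yield a flagged no-onset result.  The
detector is invariant to positive rescaling of the reporter.

## Signaling states

`classify_state()` derives a cell's capabilities from its component
levels: Fringe-modified per-ligand parameters, the multi-ligand cis
steady state, then

* **receive from** ligand $\ell$ iff free Notch
  $\ge 0.2\,\beta_N/\gamma_N$ *and* the receiver's trans factor for
  $\ell$ is at least the blocking cutoff 0.5 (Lfng/Mfng "block"
  Jag1→Notch1 trans signaling; a five-fold weakened preset is treated
  as blocked);
* **send with** ligand $\ell$ iff free $D_\ell \ge 0.2 \times$ the
  cell's *dominant* unopposed expression level
  $\max(\beta_N/\gamma_N, \max_m \beta_{Dm}/\gamma_{Dm})$.

The send threshold is deliberately relative to the dominant expression
scale rather than to the ligand's own unopposed level.  The endpoint
states are defined by which component is in *excess*: a minority ligand
that escapes cis-inhibition only because it is barely expressed (e.g.
Jag1 under Lfng in a Notch-dominated cell) retains most of its —
negligible — unopposed level, so an own-level threshold would
mislabel it a sender even though it presents almost no ligand.  The
free-level depletion of the minority species is symmetric between
receptor and ligand, so no symmetric own-level rule can classify both
Notch-dominated and ligand-dominated Lfng/Jag1 cells correctly; the
dominant-scale rule does, and it reduces to the own-level rule whenever
the ligand *is* the dominant component.  All thresholds (0.2, 0.2, 0.5)
are configurable.

`build_state_graph()` draws an edge (sender, receiver, ligand) exactly
when the sender's send set and receiver's receive set share the ligand,
and reports self-edges and directed cycles (depth-first search) rather
than suppressing them: on the canonical endpoint set
(`canonical_states()`, 10:1 expression ratios, $k_c = 1$) the graph is
self-edge-free and acyclic — a consequence of strong mutual
cis-inhibition, as the tests demonstrate by constructing a weak-cis
counterexample ($k_c = 10^4$) that produces a reported self-edge.  The
no-cycle property is asserted for the enumerated states only, not
claimed as a theorem for arbitrary levels.

## Dorsal–ventral boundary lattice

`simulate_dv_boundary()` integrates a rectangular grid (default 8×6,
rows 1–4 dorsal) with 4-neighbour trans coupling.  Per step the cis
steady state is recomputed per cell (cis equilibration fast relative to
signal accumulation), trans flux uses the receiver's Fringe trans
factors with sub-cutoff factors treated as complete blocks, and
accumulated signal up-regulates Delta production in ventral cells
through a Hill function (coefficient 2, half-maximal at $S = 2$, +3
production units at saturation).  Scenario specifics:

* Dorsal cells express Notch (1), Serrate (3) and Fringe (the `"fly"`
  preset = Lfng factors with ligands relabelled); dorsal *Delta*
  production defaults to 0 — reports of low-level dorsal-Delta
  signaling exist but give no magnitude, so it is a configurable
  parameter left off by default.
* Ventral cells express Notch (1) and Delta (0.3), no Fringe.
* Delta cannot activate Fringe-negative receivers
  (`delta_requires_fringe = TRUE`), the known fly-specific requirement;
  this is what confines phase-2 signaling to the dorsal side of the
  interface.
* Activation threshold: 50% of the maximal ventral signal at the end of
  the run; when comparing a perturbation (e.g. a Serrate knockout)
  against the default scenario, pass the reference run's absolute
  `threshold` so "activated" means the same signal level in both runs.

With these defaults the simulation reproduces the two-phase order:
Serrate from dorsal cells (free because Fringe weakens its cis
interaction) activates the first ventral row; those cells up-regulate
Delta and activate the first dorsal row (Fringe-enhanced Delta
reception); activation stays confined to the two interface rows.
Removing dorsal Fringe strengthens cis-Serrate (dorsal free Notch
falls) and unblocks Serrate–Notch trans signaling among dorsal cells,
collapsing the stripe into compartment-wide dorsal activation.  Euler
step 0.05, horizon $t = 10$ model time units; the integration is
deterministic unless per-step noise is enabled.

## Image quantification

`segment_cytoplasm()` thresholds a Gaussian-smoothed cytoplasm channel
(Otsu), labels components, and removes those below 50 px.  Two accuracy
choices matter on the ~10 px-radius cells of the synthetic fields:

* **Smoothing sigma 1 px** (not heavier): with σ = 2 the blur halo
  dilates small-cell masks by 1–2 px (up to +16% area), dragging
  background-subtracted means ~10% low; σ = 1 suppresses read noise at
  the contrasts involved without the dilation.
* **Local half-max refinement** (`refine = TRUE`): a single global
  threshold places edges systematically outward where the background is
  high (illumination gradients), so each component is re-thresholded at
  the midpoint between its plateau intensity (80th percentile) and its
  local background median.  On 50-cell gradient fields with read noise
  this reduces the worst per-cell mean error from ~6% to <2%.

`measure_cells()` implements per-cell local background subtraction: the
background is the median of unsegmented pixels within a 20 px disc
dilation of the cell (the neighborhood size is a package default; cells
with no unsegmented neighborhood fall back, flagged, to the global
unsegmented median), subtracted pixel-wise before averaging; negative
means are recorded as-is, and the measurement is invariant to adding a
constant to the whole image.  `gate_cells()` keeps cells inside an area
window and farther than 5 px (edge-to-edge) from any other mask — a
reproducible surrogate for manual screening of single, isolated cells,
declared as such rather than inferred; merged doublets are caught by
the area gate instead of watershed splitting.  Reject counts per reason
are reported and partition the input exactly.

## Problem sizes and numerical conventions

The test suite and acceptance script run at the sizes the analyses are
designed for: 2000 cells per availability dataset (20 seeds for
recovery), 100 random parameter sets for solver-vs-ODE agreement, 100
calibration seeds, 1000 null replicates for the Wilcoxon type-I check,
200 replicates (n = 500) for bootstrap CI coverage, 50-cell 400×400
image fields, 8×6 lattices over 200 Euler steps.  Seeded generators
save and restore the session RNG state, so a fixed seed gives
bit-identical output without side effects.

## Known limitations

* No spatial ligand diffusion, endocytosis/trafficking, or
  transcriptional target modelling beyond the lumped reporter rate.
* Fringe preset magnitudes are conventions; only their directions are
  constrained by data.
* The boundary model stops at the first Delta-up-regulation feedback;
  later refinement circuits (and hence the final refined stripe width)
  are out of scope.
* The two-ligand competition assumes independent cis reactions; shared
  machinery (e.g. limited trafficking capacity) would couple them.
* Time-lapse analysis works on population frame means and per-trace
  onset detection; no per-cell kinetic fitting or tracking.
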