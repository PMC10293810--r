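---
title: "Measuring direct transfer of polynucleotides between protein binding events"
author: "dtkin package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring direct transfer of polynucleotides between protein binding events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtkin)
```

## The question the package answers

Classically, the lifetime of a protein–ligand complex is an intrinsic
property: the complex dissociates at a rate $k_{-1}$ that does not depend on
what else is in solution, and a competitor only matters after dissociation,
by capturing the free protein. Many nucleic-acid-binding proteins violate
this picture: a free polynucleotide can partially invade the occupied
binding surface, form a short-lived ternary intermediate, and actively
displace the resident ligand. This *direct transfer* (also called
facilitated dissociation) makes the apparent off-rate grow with free
competitor concentration:

$$k_{off}^{obs}(D) \;=\; \underbrace{k_{-1}\,\frac{D}{D + K_c}}_{\text{classic
capture}} \;+\; \underbrace{k_\theta\, D}_{\text{direct transfer}}$$

where $D$ is the free competitor concentration, $K_c$ a capture constant
describing the kinetic competition between competitor capture of free
protein and rebinding of the trace labelled ligand, and $k_\theta$
(M$^{-1}$s$^{-1}$) the second-order direct-transfer rate constant. Classic
competition is the special case $k_\theta = 0$: the apparent off-rate
*plateaus* at $k_{-1}$; direct transfer makes it *keep rising linearly*.
Distinguishing the two, and estimating $(k_{-1}, k_\theta)$, is the
package's central task — from two kinds of data:

* **FPCD plates** — fluorescence-polarization competitive-dissociation
  time courses: a pre-formed complex of protein with trace fluorescent
  ligand is chased with unlabelled competitor and polarization is read over
  time in a microplate reader;
* **single-molecule dwell times** — residence times of individual labelled
  ligands on surface-tethered protein from TIRF intensity traces, with and
  without competitor.

## Reaction schemes

`simulate_scheme()` integrates mass-action kinetics for two scheme
variants with deSolve's stiff-capable `lsoda` (relative tolerance $10^{-8}$,
absolute $10^{-12}$ M; both configurable).

The **simplified scheme** has species $\{E, P, D, EP, ED\}$ (protein,
labelled ligand, competitor, and their binary complexes) with association
($k_{1P}, k_{1D}$), dissociation ($k_{-1P}, k_{-1D}$) and two concerted
transfer steps $EP + D \to ED + P$ ($k_{\theta D}$) and $ED + P \to EP + D$
($k_{\theta P}$).

The **complete scheme** resolves what the concerted step abbreviates:
partially associated complexes $EP^*, ED^*$ that interconvert with the
stable complexes at an exchange rate $\lambda$, and a ternary species $T$
in which one protein partially engages both polynucleotides:

$$E + P \rightleftharpoons EP^* \rightleftharpoons EP, \qquad
EP^* + D \rightleftharpoons T \rightleftharpoons ED^* + P, \qquad
ED^* \rightleftharpoons ED$$

We implement a single shared ternary species rather than two
direction-specific ones: the complex with both polynucleotides partially
bound is one physical state regardless of which ligand arrived last. The
micro-rates are constructed so that in the fast-exchange limit the stable
pools obey the simplified scheme exactly: with equal opening and closing
rates $\lambda$, half the bound pool is in the partial state, so
micro-dissociation is $2k_{-1}$, ternary formation is $4k_\theta$ (half
occupancy $\times$ half branching of $T$), and $T$ decays at $\lambda$
toward either side. The test suite verifies that with $\lambda$ at 100
times every other (pseudo-)first-order rate the two schemes agree within
2% everywhere, and checks the complete scheme against an independent
fixed-fine-step Runge–Kutta integration.

Thermodynamic consistency: a transfer reaction is a kinetic shortcut, so
its equilibrium constant must match the ratio of binding equilibria,
$k_{\theta D}/k_{\theta P} = K_{dP}/K_{dD}$. `rate_constants()` derives
$k_{\theta P}$ this way when it is not supplied; supplying an inconsistent
pair warns by default (experimentally fitted transfer constants are not
constrained this way) and errors in strict mode. `equilibrium_state()`
solves the coupled binding equilibria by monotone root-finding on free
protein, and falls back to Newton polishing of the full stationarity
conditions when inconsistent transfer constants make the long-time state a
kinetic steady state rather than a true equilibrium.

## The FPCD pipeline

`analyze_fpcd()` runs the plate-level chase analysis end to end:

1. **Normalization** (`normalize_polarization()`): readings are mapped to
   fraction of initial complex using the signal range across all
   conditions. The default anchors are *condition-structured means*: the
   upper anchor is the mean of the earliest quarter of the highest-signal
   (un-chased) condition, the lower anchor the mean of the latest quarter
   of the lowest-signal (fully chased) condition. We deliberately do not
   anchor on the raw global extrema: the extremes of several thousand
   noisy reads sit ~3.5 noise SDs outside the true range, which compresses
   every normalized amplitude — and therefore every initial-slope
   off-rate — by several percent. Exact-range and percentile anchors
   remain available as options.
2. **One-phase exponential regression** (`fit_exponential_decay()`):
   $F(t) = A e^{-kt} + c$ per well. The model is separable, so fitting is
   a profiled one-dimensional search over $k$ on a deterministic log grid
   with Brent refinement — multi-start without RNG, exact linear solves
   for $A$ and $c$. Because every chase condition starts from the same
   pre-equilibrated complex, whose normalized value is 1 by construction,
   the pipeline constrains $F(0) = A + c = 1$ by default. This matters
   because of the **dead time**: mixing and loading take ~90 s, reads
   before that simply do not exist, and an unconstrained fit must
   back-extrapolate through the delay, which couples $k$ and $A$ so
   strongly that fast decays occasionally collapse to spurious small
   $k \cdot A$. Fits with amplitude below 0.2, or whose plateau is not
   resolved within the observation window, are flagged `partial` and
   carried with that caveat rather than dropped.
3. **Off-rate extraction** (`koff_obs_from_fit()`): the default convention
   is the initial slope of the normalized decay, $k_{off}^{obs} = k\cdot A$,
   which equals the initial dissociation flux even when rebinding leaves a
   plateau (incomplete chase). The alternative convention (plain $k$, the
   relaxation rate) is a config switch; the two agree in the
   full-dissociation limit.
4. **Model comparison** (`fit_competition_models()`): weighted nonlinear
   least squares of the off-rate profile against the classic (2-parameter)
   and direct-transfer (3-parameter) models above, both separable in their
   nonnegative linear coefficients with $K_c$ profiled on a log grid.
   Weights are inverse replicate variances when every concentration has at
   least three replicates, else unweighted. Models are compared with
   $BIC = n\ln(RSS/n) + p\ln n$; the lower BIC wins, a difference within
   ±2 is reported as indeterminate and defaults to the simpler classic
   model, and a selected classic model reports $k_{\theta D} = 0$. RSS is
   floored at $n(10^{-8}\max|y|)^2$ before entering the BIC so that
   noiseless data (where both models reach floating-point noise) still
   compare sanely.

Equilibrium binding is handled separately: `fit_kd()` fits standard
(hyperbolic), Hill ($E^{n_H}/(E^{n_H}+K_d^{n_H})$) and exact
ligand-depletion (quadratic) isotherms with BIC comparison, warning when
the fitted $K_d$ falls below the tested range or the ligand concentration
(the apparent $K_d$ is then ligand-limited). `fit_stoichiometry()` fits
the two-segment rising/plateau model of a tight-binding titration and
reports ligand molecules per protein functional unit from the breakpoint.

## The single-molecule pipeline

`detect_events()` segments intensity traces by hysteresis thresholding:
enter a binding event above the high threshold, leave below the low one.
Default thresholds sit 3 and 2 noise SDs above the unbound baseline, with
baseline and noise estimated from the 5th/25th intensity quantiles so that
bound-state frames do not inflate them (robust to ~75% occupancy). Frames
are 0-based, events half-open $[start, end)$, trailing events are flagged
censored, and events shorter than 2 frames are discarded as unresolvable.

`fit_dwell_exponential()` estimates the apparent off-rate by maximum
likelihood for a left-truncated exponential, which has the closed form
$\hat k_{off} = n / \sum_i (t_i - t_{min})$ over uncensored dwells;
memorylessness makes it unbiased for any truncation point $t_{min}$.
Censored dwells are excluded by default (matching naive density
regression) or contribute survival terms on request.

Photobleaching terminates fluorescence as a competing exponential, so the
apparent rate is $k_{-1} + k_\theta D + k_b$ and `photobleach_correct()`
subtracts a measured bleach rate, reporting the attributable fraction.
`estimate_rate_constants()` then reads $k_{-1}$ off the zero-competitor
condition and $k_\theta$ from the difference quotient across the chase.

`detect_transfer_events()` classifies two-colour transfer events: a
departure in one channel matched by an arrival in the other at the same
particle within a ±0.15 s ternary window (the intermediate lives
< 150 ms). Longer double-occupancy or longer gaps are independent binding.
When event tables carry continuous times (as generator ground truth does)
these are preferred over frame indices, because a frame interval
comparable to the window quantizes the gap and drops genuine sub-frame
transfers.

## Synthesis metrics

* `flux_partition()` — the proportion of protein translocations that
  proceed via direct transfer at competitor effective molarity $D$:
  $k_\theta D / (k_\theta D + k_{-1})$; `flux_crossover()` returns the
  equal-flux concentration $k_{-1}/k_\theta$. At the cross-study average
  ratio $k_\theta/k_{-1} \approx 10^5$ M$^{-1}$ the crossover sits at
  ~10 µM, i.e. direct transfer becomes competitive at low-micromolar
  effective concentrations of polynucleotide.
* `theta_vs_k1_regression()` — linear zero-intercept regression of
  $k_\theta$ on $k_{-1}$ across interactions (slope $\sum xy/\sum x^2$),
  with the uncentered $R^2 = 1 - RSS/\sum y^2$ appropriate for
  through-origin models (centered alternative available).
* `hop_score()` — hand-off proficiency,
  $\log_{10}\!\big[(k_\theta/k_{-1})/\text{ref}\big]$, zero meaning
  average transfer propensity. The reference defaults to the fitted slope
  of the loaded record set; a fixed $10^5$ M$^{-1}$ preset is provided.
  Note that published HOP columns involve additional normalization not
  recoverable from their definition as a $k_\theta/k_{-1}$ metric (they
  are not monotone in that ratio), so this package's scores are
  *definitionally* log-ratios and are not expected to reproduce published
  HOP values number-for-number.
* `build_summary_table()` — one row per interaction with $K_d^{app}$,
  $k_{-1}$, $k_\theta$, HOP and footnote flags (partial curves, carrier,
  "BIC favored classic"), aggregating replicate experiments as mean ± SD.

## What the synthetic data emulate — and what they do not

The package ships no instrument data; `generate_fpcd_dataset()`,
`generate_isotherm()` and `generate_sm_dataset()` produce data with the
statistical structure the analyses assume, plus ground-truth sidecars, so
every stage is testable offline. All generators are seed-deterministic.

**Plate generator.** The simplified scheme is integrated from the
pre-equilibrated complex for each competitor concentration; the bound
fraction maps linearly to polarization between 60 mP (free) and 200 mP
(bound, both recorded metadata), i.i.d. Gaussian read noise is added, and
reads before the dead time are dropped. The default design is one plate
row: a zero-competitor control plus an 11-point geometric competitor
ladder, four replicates, 30 s reads for one hour, 90 s dead time, 2.8 mP
noise (2% of the signal span). Both ladder ends are set by assay physics,
not convenience: the bottom sits at 3× the protein concentration because a
chase needs competitor in excess of protein (sub-stoichiometric competitor
merely shifts the equilibrium, producing a shallow sigmoidal foot that no
chase regression model describes), and the top is capped where the
apparent rate reaches ~1.2/dead-time, because faster decays complete
during the delay and become unmeasurable — the fate of over-chased
conditions in real plates. `fp_plate_design_for()` applies these rules to
any preset, stretching the observation window to ~8 intrinsic lifetimes
for slow dissociators. A carrier mode adds a declared non-binding
polynucleotide that holds total polynucleotide constant across the series
(bookkeeping parity with carrier-control designs; it changes no rates).

**Single-molecule generator.** Dwells are drawn from the competing-risks
exponential with total rate $k_{-1} + k_\theta D + k_b$, each termination
labelled dissociation/transfer/bleach in the truth table; dwells shorter
than 2 frames are unobservable, dwells longer than the movie are censored.
Defaults: 0.2 s frames, 1500-frame movies, the single-molecule rate
constants of the TREX1–ssDNA interaction, $k_b = 0.004$ s$^{-1}$ (10% of
the zero-competitor apparent rate, inside the 5–20% band photobleaching
controls typically report), SNR 5, and an 8% per-departure transfer
probability in two-colour mode with arrival gaps inside the ternary
window.

What passing tests on these data do **not** show about real data: the
noise is Gaussian and i.i.d. (no drift, no well effects, no heavy tails),
traces have a single fluorophore level (no blinking, no partial bleaching
steps), colocalization is taken as given (particle ids are shared between
channels), and the generating kinetics are exactly the model being fitted
— recovery here demonstrates correctness of the estimators, not robustness
to model misspecification. The published rate-constant values used as
generating truths enter only as preset parameters (`preset_registry()`),
each with a provenance note; presets whose $K_d$ was not determined at a given
temperature reuse the same interaction's measured value, flagged as a
synthetic stand-in.

## Numerical choices and degenerate inputs

* Units are molar and seconds internally, everywhere; CSV columns declare
  units by suffix (`_M`, `_s`, `_mP`).
* All fitting is deterministic: profiled linear solves plus grid/Brent (or
  Nelder–Mead for the two-parameter Hill search, with fixed multi-starts).
  No RNG is used in any fit; rerunning a pipeline on identical input is
  bit-identical.
* Integrator failures raise errors rather than returning NaN; mass
  conservation holds to $10^{-8}$ relative at every output time.
* Flat plates (range below 5 mP) are degenerate data and error out.
  Dwell sets entirely at the truncation point error out. Titrations with
  no breakpoint in range error out. `flux_partition(0, k, 0)` is
  undefined and errors.
* BIC ties (±2) are reported indeterminate and resolved toward the
  simpler model; a transfer constant pinned at its zero bound warns about
  model ambiguity.

## Problem sizes and known limitations

The bundled tests and the acceptance script run full-pipeline recovery at
one plate (12 conditions × 4 replicates, ~120 reads each) across 3–5
seeds, 800 dwells per single-molecule condition across 5 seeds, and
200-seed model-selection Monte Carlo at the profile level — sizes chosen
to match one real experimental campaign per estimate; everything completes
in well under a minute on one core.

Known limitations:

* Interactions whose intrinsic dissociation completes largely within the
  dead time (e.g. a $k_{-1}$ of ~2×10$^{-2}$ s$^{-1}$ against a 90 s
  delay) are at the resolution limit of the plate assay: their fits carry
  `partial` flags and $k_{-1}$ is systematically underestimated by
  ~20% in our simulations. This mirrors the caveat attached to such rows
  in published tables (early-partial curves, manual baselines); the
  single-molecule route does not share the limitation.
* $K_c$ is rarely identifiable from chase data when all competitor
  concentrations are far above the trace ligand level; it is retained as
  a bounded nuisance parameter, not interpreted.
* Association constants $k_1$ are never fitted (not identifiable in these
  designs); they enter only through $K_d$ when constructing generating
  rates.
* Apparent $K_d$ from isotherms of very tight binders is ligand-limited;
  the quadratic model only helps when $K_d$ is within about an order of
  magnitude of the ligand concentration.

## A worked example

```{r example}
p <- preset_registry()[["TREX1_ssDNA_25C"]]
ds <- generate_fpcd_dataset(p, fp_plate_design_for(p), seed = 1)
fit <- analyze_fpcd(ds$plate)
fit$competition

hop_score(fit$competition$k_neg1P, fit$competition$k_thetaD,
          reference_ratio = 1e5)
flux_crossover(fit$competition$k_neg1P, fit$competition$k_thetaD)
```
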