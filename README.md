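# dtkin — direct-transfer kinetics of protein–polynucleotide competition

Many DNA- and RNA-binding proteins do not wait to fall off their ligand:
a competing polynucleotide can partially invade the occupied binding
surface, form a transient ternary intermediate, and actively displace the
resident ligand ("direct transfer", also called facilitated dissociation).
The experimental signature is that the apparent off-rate of a pre-formed
complex grows with free competitor concentration instead of plateauing:

```
k_off^obs(D) = k_-1 * D / (D + K_c)  +  k_theta * D
               \__ classic capture __/   \_ transfer _/
```

`dtkin` is for biophysicists who run (or simulate) the two assays that
measure this:

* **FPCD** — fluorescence-polarization competitive dissociation: chase a
  protein·labelled-oligo complex with unlabelled competitor in a plate
  reader, extract one-phase decay rates per well, regress the off-rate
  profile against the classic (2-parameter) and direct-transfer
  (3-parameter) models, and pick between them with the Bayesian
  Information Criterion. Equilibrium K_d (standard / Hill / quadratic
  depletion) and stoichiometry-breakpoint fitting are included.
* **Single-molecule TIRF** — detect binding events on intensity traces,
  estimate off-rates from residence times by truncated-exponential maximum
  likelihood, correct for photobleaching as a competing exponential, and
  classify two-colour ligand-transfer events through a <150 ms ternary
  window.

On top sit the cross-interaction synthesis metrics: the pathway-flux
partition `k_theta*D / (k_theta*D + k_-1)` and its crossover
concentration, the zero-intercept k_theta-vs-k_-1 regression, the
hand-off-proficiency (HOP) score `log10((k_theta/k_-1)/reference)`, and a
summary-table builder. A mass-action simulator (`deSolve`) integrates both
the simplified 5-species competition scheme and a complete variant with
partially associated and ternary species, and seed-deterministic
generators (`generate_fpcd_dataset()`, `generate_isotherm()`,
`generate_sm_dataset()`) produce plate and single-molecule data with
ground-truth sidecars so every pipeline stage is testable with no
instrument data. `preset_registry()` carries reported rate-constant sets
for a panel of interactions (TREX1, hnRNP-U, FBF-2, MS2-CP, streptavidin)
as generating truths.

## Worked example

Simulate one FPCD plate from the TREX1–ssDNA preset (k_-1 = 7.0e-3 s^-1,
k_theta = 1500 M^-1 s^-1 as generating truth) and run the full pipeline:

```r
library(dtkin)
p  <- preset_registry()[["TREX1_ssDNA_25C"]]
ds <- generate_fpcd_dataset(p, fp_plate_design_for(p), seed = 1)
fit <- analyze_fpcd(ds$plate)
fit$competition
#> Competition model comparison (BIC):
#>   classic:         k_neg1P = 0.01211 /s, K_c = 3.39e-07 M, BIC = 33.41
#>   direct transfer: k_neg1P = 0.006959 /s, k_thetaD = 1509 /M/s, BIC = -9.35
#>   selected: direct_transfer (delta BIC = 42.76)
```

The BIC strongly favours direct transfer (delta 42.8), and the recovered
constants sit within 1% of the generating truth. The derived metrics:

```r
hop_score(fit$competition$k_neg1P, fit$competition$k_thetaD,
          reference_ratio = 1e5)   # 0.336: above-average transfer propensity
flux_crossover(fit$competition$k_neg1P, fit$competition$k_thetaD)
#> 4.6e-06  (M: transfer flux overtakes classic dissociation at ~5 uM)
```

The single-molecule route, with photobleach correction (k_b = 0.004 s^-1):

```r
d0 <- generate_sm_dataset(sm_design(competitor_M = 0),    n_events = 800, seed = 1)
d1 <- generate_sm_dataset(sm_design(competitor_M = 1e-5), n_events = 800, seed = 2)
analyze_sm_dwells(rbind(d0$dwells, d1$dwells), t_min = 0.4, k_b = 0.004)
#> Single-molecule rate estimate:
#>   competitor_M koff_obs koff_corrected       se   n bleach_fraction
#> 1        0e+00  0.04368        0.03968 0.001560 784         0.09157
#> 2        1e-05  0.13747        0.13347 0.004997 757         0.02910
#>   k_neg1 = 0.03968 /s, k_theta = 9379 /M/s (k_b = 0.004 /s)
```

See `vignettes/direct-transfer-kinetics.Rmd` for the models, the
normalization and dead-time handling, numerical choices, and what the
synthetic data do and do not emulate.

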