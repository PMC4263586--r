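---
title: "Impedance-based toxicology profiling with rtcatox: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impedance-based toxicology profiling with rtcatox: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcatox)
```

## The measurement and the quantities it yields

Real-time cell analysis (RTCA) records the electrical impedance of
electrode-bearing 96-well plates while adherent cells grow on the
electrodes. The raw observable is the electrode resistance at a handful of
frequencies, with (`R_cell(f)`) and without (`R_b(f)`) cells. The **cell
index** condenses a spectrum pair into one dimensionless number,

$$\mathrm{CI} = \max_{i = 1..N}\left(\frac{R_{cell}(f_i)}{R_b(f_i)} - 1\right),$$

so an empty well reads 0 and more (or more spread-out) attached cells read
higher. `compute_cell_index()` implements exactly this maximum and does not
clamp at zero: when the background is recorded with cells already present —
as happens with pre-seeded plates shipped from a supplier — values below
zero are legitimate and must survive into downstream analysis.

Because absolute CI depends on seeding density and coating, analyses work
on the **normalized cell index**: every trace is divided by its value at
the last recorded point before compound addition (`normalize_trace()`,
`default_reference_time()`), making each well exactly 1 at that reference.
Wells whose reference CI falls below the instrument guidance of 0.5 are
flagged degenerate rather than silently dropped; by default
(`rtca_rules(exclude_degenerate = TRUE)`) flagged wells are excluded from
replicate means, but the flag travels with the data so the choice is
auditable.

## Response archetypes and the synthetic-plate generator

The raw traces behind the screening results this pipeline operationalizes
are not publicly deposited, so the package carries a first-class, seeded
generator (`simulate_plate()`, `simulate_mechanism_panel()`) whose wells
follow parametric versions of the characteristic time-dependent cell
response profiles (TCRPs):

| archetype | qualitative shape | parametric mean (post-dose) |
|---|---|---|
| control | growth, then plateau | logistic $K/(1+e^{-r(t-t_0)})$, $K=4$, $r=0.2\,h^{-1}$, $t_0 = $ dose time |
| cytotoxic | gradual CI decline | control $\times\,[(1-h) + h\,e^{-k(t-d)}]$, $k = 0.08\,h^{-1}$ |
| calcium modulator | rapid drop, minimum 5–10 h post-dose | fast exponential drop (time constant 1 h) to depth 0.95, slow 0.01 h$^{-1}$ recovery after the minimum at `effect_delay` (default 7 h) |
| antimitotic | flat/wavy CI, cells alive but arrested | CI frozen at its dose-time level plus $A\sin(2\pi t/P)$, $A = 0.3$, $P = 24$ h |
| DNA damaging | rise above control over ~12 h, then apoptotic fall | linear rise to `elevation_factor` (1.5) over 12 h, then exponential decline at $0.10\,h^{-1}$ (below half of control well before 48 h) |
| nuclear receptor | sustained elevation, no decline | rise to `elevation_factor` over 12 h, then held |

Effect magnitude scales with Hill occupancy
$h(c) = c^s/(c^s + \mathrm{potency}^s)$, so a zero dose reproduces the
control exactly and the treated mean equals the control mean before dosing
by construction. The kinetic forms themselves are this package's modelling
choices — the field describes these shapes verbally, not with equations —
and each is the simplest curve that reproduces the described behaviour.

**Study-condition defaults.** `simulation_design()` encodes the standard
experiment: seeding at $t=0$, dosing at 18 h (after overnight attachment),
sampling every 10 min for 2 h post-dose and every 30 min to 72 h; dose
ladder 0.1/1/10/100 µM; treated wells in triplicate, six vehicle (DMSO)
controls, detergent positive controls in duplicate at three
concentrations. These defaults are fixed design conditions, not tuning
knobs. Randomized compound panels (`draw_archetype_params()`) vary potency
log-uniformly over 0.32–10 µM (so the 100 µM top dose is at ≥ 90%
occupancy), Hill slope over 1–2, and shape parameters over the ranges in
the function's documentation.

**Noise model.** Replicate noise is multiplicative log-normal — CI is
positive and its scatter scales with its level — with marginal standard
deviation `noise_sd` (default 0.05). On the log scale the noise is an
Ornstein–Uhlenbeck process with a 1 h correlation time rather than
independent draws per timepoint: impedance traces are smooth, and
independent 5% jumps every 10 minutes would be unrealistically jagged for
this readout. Every value remains marginally mean × lognormal(0,
`noise_sd`). Noise is independent between wells; no plate-position (edge)
effects are modelled. Seeding is deterministic: one master seed, with
per-well substreams derived by hashing (plate id, well), so adding a
compound to a design never perturbs the other wells' draws.

**What the generator does not emulate.** Medium-change artifacts,
attachment-phase transients, metabolic activation, solubility failures at
high dose, and cell-line-specific expression of a compound's target are
all absent. Classifier and genotoxicity-rule performance on these clean
synthetic plates is therefore an upper bound: it demonstrates that the
rules are consistent with the archetypes they encode, not that real
screens will reach the same percentages.

## The shape classifier

The published practice this replaces is visual comparison of normalized
curves against reference profiles — explicitly flagged in the field as
needing a standardized, quantitative replacement. `extract_features()`
reduces a treated/control pair of replicate-mean normalized traces to a
small feature set (ratios are treated/control, excluded wherever the
control is non-positive):

* `early_slope` — steepest negative central-difference slope of the ratio
  in the first 2 h post-dose;
* `time_to_min`, `min_relative` — when and how deep the ratio bottoms out;
* `peak_relative_0_12h` — maximum ratio in the first 12 h;
* `endpoint_relative` — ratio at 48 h post-dose;
* `flatness` — residual sd of the post-dose treated trace around a linear
  trend, relative to its dose-time level;
* `elevation_persistence` — fraction of post-dose points with ratio above
  control;
* `endpoint_vs_dose`, `control_growth` — treated and control endpoint over
  their own dose-time level.

`classify_signature()` scans concentrations from highest to lowest (the
reference signatures appear at high dose) and assigns the first match,
which still catches profiles present only at one intermediate dose. The
rules, all thresholds in `rtca_rules()`:

| class | rule (defaults) |
|---|---|
| DNA damaging | peak ratio (0–12 h) ≥ 1.10 **and** 48 h ratio ≤ 0.5 |
| calcium modulator | ratio minimum within 10 h, early slope ≤ −0.15 h⁻¹, minimum ≤ 0.5 |
| nuclear receptor | elevation persistence ≥ 0.8 **and** 48 h ratio ≥ 1.10 |
| antimitotic | flatness ≤ 0.15, endpoint within 0.7–1.3 of the dose-time level, while the control grows ≥ 1.5-fold |
| cytotoxic | minimum ≤ 0.5 reached later than 10 h |

Precedence on a multi-match is DNA damaging > calcium modulator > nuclear
receptor > antimitotic > cytotoxic. Three deliberate choices deserve
mention. First, the early slope is computed on the treated/control *ratio*,
not the raw trace, so an untreated well has slope exactly 0 regardless of
growth. Second, the 0.5 "half of control" cut-off is reused across rules —
it is the only mortality quantity with published standing (the
genotoxicity rule's 50% criterion), and harmonizing on it keeps the config
small. Third, antimitotic flatness is judged against the well's own
dose-time level rather than against control, because arrested cells stay
alive without proliferating while the control keeps growing; requiring
`control_growth` ≥ 1.5 makes the rule vacuous on plates read out before
the control has moved, which is the honest behaviour.

Classification is deterministic; `score_reproduction()` /
`signature_success()` turn calls into per-model and combined-union success
percentages (a compound counts for the union once one cellular model
reproduces its signature), reported to one decimal.

## The genotoxicity decision rule

A concentration is genotoxicity-positive when the ratio **(a)** exceeds
1 + `elevation_margin` (default 0.10) at some point within the first 24 h
post-dose and **(b)** subsequently falls to ≤ 0.5 within 48 h of exposure;
a compound is positive when any tested concentration is. The elevation
reflects cell-cycle arrest at the DNA-damage checkpoint (arrested cells
are larger, raising impedance); the fall reflects apoptosis when repair
fails. Both clauses must hold at the *same* concentration — the published
rule does not state this explicitly, and requiring it is this package's
documented interpretation (a cytotoxic dose of one compound should not
combine with an elevating dose of another profile into a positive call).
Concentrations satisfying (a) whose minimum lands in (0.5, 0.55] are
reported **equivocal** and scored negative, mirroring how near-miss
compounds are handled in practice. The 24 h elevation window is a config
default justified by the ~12 h elevation the mechanism produces; the 48 h
mortality window is measured from the (first) compound addition, matching
the normalization convention. Lowering the mortality threshold can only
remove positives, never create them — a monotonicity the test suite
asserts.

`evaluate_predictivity()` reduces calls against reference labels to
sensitivity (100·tp/(tp+fn)), specificity (100·tn/(tn+fp)) and concordance
(100·(tp+tn)/n), per project group and pooled; pooled counts always equal
the per-group sums, and empty denominators report not-applicable rather
than dividing by zero.

## Endpoint cytotoxicity and LC50

`endpoint_viability()` expresses each compound × concentration endpoint as
percent of the vehicle-control mean (set to 100%), using the normalized CI
for impedance and raw per-well signals for an orthogonal fluorescence
viability readout. `cross_readout_correlation()` is the Pearson
product-moment correlation of matched percent values × 100 (the
spreadsheet convention the original analysis used); fewer than three pairs
or zero variance yield not-applicable. Whether such published correlations
are r or r² is ambiguous; r × 100 is assumed here.

`compute_lc50()` implements the bracketing linear fit: choose the adjacent
dose pair whose viabilities straddle 50% (nearest to 50 by summed absolute
deviation; ties go to the lowest doses), fit $y = ax + b$ through the two
points on the **linear** concentration scale — the literal reading of a
two-point spreadsheet regression, with `log_scale = TRUE` available — and
solve for $y = 50$. A tested dose at exactly 50% is itself the LC50; when
all viabilities stay above 50 the result is flagged `> top dose`, and when
the lowest dose already kills more than half the cells, `< lowest dose`
(no extrapolation below the tested range).

```{r lc50-example}
compute_lc50(c(1, 10), c(80, 20))
```

## Numerical choices, problem sizes, limitations

* Round trips through the CSV dialect (`write_plate()` / `read_plate()`)
  preserve values to better than 1e-9 relative tolerance (12 significant
  digits written) and layout fields exactly; every malformed input raises
  a typed error naming the file and well.
* Feature windows use the closest grid point where an exact one is not
  guaranteed (the 48 h endpoint); slopes use central differences on the
  native, non-uniform grid.
* The test suite and the acceptance script size their simulations at 200
  compounds (50 per mechanism class) for classifier recovery and 40–60
  compounds for the genotoxicity rule, on single-plate grids of ~150
  timepoints — large enough for stable percentages, small enough to run
  in seconds.
* Known limitations: the classifier thresholds are calibrated to the
  archetype shapes and the 0.1–100 µM ladder; weak calcium modulators
  with confounding cytotoxicity, nuclear-receptor responses that are
  cell-type specific, and compounds needing metabolic activation are all
  expected failure modes on real data, as they are for the by-eye
  procedure this replaces. Published per-compound outcomes (individual
  real-compound LC50s and real-cell impedance-vs-fluorescence
  correlations) require the undeposited raw traces and are deliberately
  out of scope; the package reproduces the *computations*, exercised on
  synthetic or user data.
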