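---
title: "Methods behind the Agricultural Protection Against Stress Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the Agricultural Protection Against Stress Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apsi)
```

## The problem and the model

Choosing among plant-growth-promoting rhizobacteria (PGPR) candidates
means weighing incommensurable laboratory evidence: centimeters of root,
grams of dry mass, halo diameters, fungal colony suppression, hormone
titers, and yes/no plate reactions. The APSI collapses this evidence into
one 0–100 score per strain so that candidates can be ranked and a
go/no-go decision taken before committing to field trials.

The index has three layers:

1. **Weights.** Each assay category carries a percentage of the index:
   growth stimulation 20, drought protection 27, antifungal protection 28,
   phytohormones 9, nutrient solubilization 8, siderophores 4, urease 4.
   The hormone share is recovered by difference — the other six stated
   shares sum to 91, and the three hormone tests at 3 points each supply
   the remaining 9 — and `default_weights()` documents it as such. Weights
   are ordinarily the output of a Delphi exercise (below) and can be
   replaced wholesale: the index is modular, and a user working in a
   salinity- rather than drought-limited system can re-weight without
   touching the scoring layer.

2. **Budgets.** `allocate_budgets()` splits a category's percentage
   equally over its tests. Equal division is forced by the reference
   battery's structure (27 → 3 × 9, 28 → 4 × 7, 20 → 4 × 5, 9 → 3 × 3,
   8 → 2 × 4), and keeps the invariant
   $\sum_t m_t = \sum_c w_c = 100$ exactly.

3. **Scores.** Raw outcomes map to points bounded by the per-test maximum
   $m_t$, by one of the schemes below.

## Raw-to-score schemes

**Tiered (default for quantitative tests).** With negative- and
positive-control effects $x^-$ and $x^+$, the effect ratio is
$r = \max\{0, (x - x^-)/(x^+ - x^-)\}$ and the score fraction is
quantized on $\{0, \tfrac14, \tfrac12, \tfrac34, 1\}$: 1 when the strain
is not significantly below the positive control or $r \ge 0.75$; 0.75,
0.5 for the middle bands; 0.25 for $0 < r < 0.25$ only if the strain is
significantly above the negative control; else 0. The band edges
0.25/0.5/0.75 are this package's calibration: the reference score table
is consistent with a quartile lattice (71 of its 72 strain-by-test cells
lie on it) but the original raw-to-score rule is not stated, so the rule
here is documented as a reconstruction, not a transcription. Two of its
consequences should be kept in mind: a strain statistically
indistinguishable from the positive reference always earns full marks
regardless of $r$, and the significance gate on the lowest band
suppresses spurious quarter-points from noise-level effects.

**Probit (optional, antifungal tests).** The one cell of the reference
table off the quartile lattice (5.95 of 7) equals
$m_t\,\Phi(z)$ at $z = 1.0364$, which motivates offering the
cumulative-normal map $m_t\,\Phi((x-\mu)/\sigma)$ as a continuous
alternative. For inhibition fractions the default reference is
$\mu = 0.5$, $\sigma = 1/3$: the map is centred on half-suppression and
the ends of the inhibition scale sit at $\mp 1.5\sigma$, which reproduces
the off-lattice cell to within 0.03 points for the corresponding
inhibition level. Both schemes are strictly monotone in the raw
measurement and agree at the extremes.

**Binary.** Positive earns $m_t$, negative earns 0, and an absent
outcome is a first-class *missing* state. Aggregation decides its
treatment: under the default `missing_policy = "zero"` a missing test
contributes nothing (this reproduces the reference FZB42 total, whose
blank urease cell leaves 67.75), while `"renormalize"` rescales to the
attainable maximum.

A note on reported totals: the reference table's column sums (78.95,
67.75, 61.5, 65.25) are internally consistent and are the values this
package adopts and validates on load; the same source also prints a few
divergent in-text totals for two strains, which cannot be reconciled
with the table's own arithmetic and are not used.

## Statistical grading

Replicate groups are compared by the classical pipeline in
`compare_groups()`: iterative Bonferroni outlier screening on the one-way
model residuals (largest absolute studentized residual, adjusted p <
α, one removal per refit — screening residuals rather than raw groups,
since the group structure is what the model knows), a Shapiro–Wilk check
of the screened residuals (recorded as a quality flag, never fatal —
only outliers, not non-normal groups, are excluded), one-way
fixed-effects ANOVA, Tukey HSD with the Tukey–Kramer correction for
unbalanced groups, and a compact-letter display built by
insert-and-absorb, whose defining biconditional — two groups share a
letter iff their adjusted p ≥ α — is property-tested on random matrices.
α defaults to 0.05 everywhere and is overridable.

Degenerate inputs are resolved by convention rather than error: zero
within-group variance gives F = ∞, p = 0 (or F = 0, p = 1 when the means
also coincide), pairwise p-values 0 or 1 by mean equality, and outlier
screening stops when residual scatter reaches rounding level. These
conventions are what make noiseless synthetic panels scoreable.

Two assay families lack replicate structure. Fungal tracks have one
diameter per sampling day; the tier rule's significance gates use a
one-sample t-test of the per-day inhibition fractions against 0 and 1
(constant samples fall back to mean comparison), and the three days are
summarized by their unweighted mean, since no aggregate is prescribed.
Hormone titers are single measurements per time point (the peak over 24 h
and 72 h is used), so their tier rule runs on the effect ratio alone.

## Delphi weight elicitation

`delphi_state()` holds per-expert weight vectors (each summing to 100);
the aggregate is the component-wise **median** — standard Delphi
practice, robust to a single extreme panelist — and dispersion is the
per-component IQR. One round moves every expert toward the aggregate by
the contraction fraction and renormalizes; `delphi_converge()` iterates
until every IQR falls below the tolerance (default 0.1 percentage
points) or a round cap is hit, in which case the aggregate is returned
with a warning flag. Identical experts converge in one round; with
contraction 0 and disagreement the procedure correctly refuses to
converge. Consensus recovery is calibrated on synthetic panels: with
nine experts scattering at sd 5 around a shared prior, the recovered
scheme deviates from the prior by about 1.5–2 points per category on
average (the median of nine such opinions has a standard error near 2,
so single-category deviations above 2 are expected and not a defect).

## Sensitivity analysis

`perturb_weights()` draws weight vectors from a Dirichlet distribution
with parameter `concentration × weights/100` — the unique
simplex-respecting noise family that preserves the baseline as the mean
and the 100-point mass by construction — then reallocates budgets,
rescales subscores proportionally, and recomputes totals and competition
ranks. Reported are per-strain rank-retention probabilities, 95%
percentile intervals, and the probability of falling below the cutoff
band. Concentration 100 represents moderate institutional disagreement
(per-category sd of roughly 1–4 points); concentrations at or above 1e12
short-circuit to the exact baseline. `bootstrap_totals()` instead
resamples replicates within each (strain, assay, condition) group,
re-runs the whole scoring pipeline per resample, and reports percentile
intervals; percentile rather than BCa intervals are used — simpler and
adequate at the scale of a decision table. Both are deterministic given
their seed.

## The synthetic generator

`generate_panel()` emulates exactly the statistical structure the
pipeline consumes — no more. Each strain carries a true effect tier per
test; the generator maps lattice tiers to the midpoint of their tier
band (0, 0.125, 0.375, 0.625, 1), so that at zero noise the tier rule
recovers the profile *exactly* — an identity test linking generator and
scorer; off-lattice tiers pass through as raw effect ratios. Plant
biometry is built from lognormal dry weight and water capacity plus a
truncated-normal RWC, so dry ≤ fresh ≤ turgid holds by construction
without rejection loops; fungal diameters shrink multiplicatively with
the tier; halos use truncated-normal noise (keeping the support
non-negative); titers are lognormal. Qualitative outcomes are positive
iff tier ≥ 0.5, and an `NA` tier yields a *missing* outcome.

Default conditions: 6 replicates per group and a 5% coefficient of
variation — noise typical of careful pot-scale biometry — with control
levels of realistic magnitude (e.g. irrigated control dry weight 1.2 g
against a 1.8 g positive reference; drought RWC 0.35 against 0.80;
colonies growing 4→8 cm over days 5/10/15; a 212 µg/L reference IAA
titer). Under these conditions a reference-strain tier profile is
recovered within ±3 index points across seeds, driven almost entirely by
occasional single-tier slips near band edges.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: growth-curve dynamics, plate geometry,
inter-assay correlation within a strain, batch effects, heteroscedastic
or heavy-tailed measurement error, and real replicate counts (the
reference study does not state them; the schema accepts any n ≥ 1).
Recovery and coverage results are statements about this noise model only.

## Numerical choices and problem sizes

Ties in ranking share the competition rank at an absolute tolerance of
1e-9; weight sums are validated to 1e-9; subscore bounds allow 1e-9 of
slack for float arithmetic; outlier screening stops at residual RMS
below 1e-10 of the data scale. Test-suite simulation sizes — 1000 random
matrices for the letter biconditional, 500 monotonicity trials, 20
recovery seeds, 2000 weight draws, 20–30 bootstrap resamples per panel —
were chosen so the whole suite runs in about a minute and a half on a
single core while keeping Monte-Carlo error well inside the asserted
margins.

## Known limitations

The tier rule is a calibration, not a transcription: where the reference
table's own assignments are mutually inconsistent (equal-halo strains
scored 1 vs 2 of 4; drought subscores of 6.75 for strains reported as
indistinguishable from controls), this package's rule will not reproduce
those cells from raw data, and no rule could without further information.
The probit reference (0.5, 1/3) for inhibition is likewise a documented
choice. The Delphi update is the standard median-contraction scheme; the
original description names the method without its mechanics. The index
itself is a weighted sum — it cannot express interactions between traits,
and a strain weak in a high-weight category cannot compensate through
excellence in a low-weight one beyond that category's budget.
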