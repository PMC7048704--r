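---
title: "Methods: equity and coverage analysis of RMNCH interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equity and coverage analysis of RMNCH interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(rmnch)
```

This vignette is the package's account of its methods: the models and
their assumptions, the defaults and why they were chosen, what the
synthetic data do and do not establish, and the numerical conventions.

## The analysis chain

Household surveys of the DHS family interview ever-married women of
reproductive age and record, per household, asset ownership and
residence; per woman, education and family-planning status; per recent
birth, delivery and antenatal care; and per child under five,
vaccination and illness/treatment. From these the package estimates
intervention coverage, summarises it with the Composite Coverage Index,
quantifies socioeconomic inequity, extrapolates trends, and converts
coverage scale-up into deaths averted.

## Wealth index

Socioeconomic position is the first principal component of the
standardized household asset indicators (the Filmer–Pritchett asset
index). Choices made here:

* **Correlation-matrix PCA.** Assets are standardized before the
  decomposition, so prevalence differences between indicators do not
  dominate the loading pattern.
* **Sign orientation.** A principal component is defined up to sign; we
  fix it by requiring positive correlation with the household's total
  asset count, so "higher score = wealthier" is reproducible.
* **Zero-variance assets** carry no information and are dropped; a
  matrix with *only* constant columns is a degeneracy error rather than
  an arbitrary score.
* **Weighted quintiles.** Households are ranked by score and cut at the
  weighted 20/40/60/80th percentiles, using the cumulative weight at
  the midpoint of each household's mass. Each quintile's weighted share
  is then within one household weight of 20%. Ties in score are broken
  by stable input order. Quintiles are household quintiles (children
  are not re-weighted per capita); this matches the simplest reading of
  ranked household quintiles and is the convention the generator and
  estimator share.

## Coverage estimation

Coverage is the weighted share
`100 · Σ w(numerator) / Σ w(denominator)` with DHS-standard
denominators: births in the 2-year recall window for skilled birth
attendance (SBA), skilled antenatal care (ANC) and tetanus toxoid;
children 12–23 months for vaccination; children 6–59 months for vitamin
A; children with a two-week illness episode for treatment indicators;
women with family-planning demand for demand satisfied. Units with a
missing numerator response are excluded from both numerator and
denominator; a stratum with an empty denominator is returned as `NA`
with an explicit flag, never as zero. Point estimates only — the
design-based variance of a multi-stage cluster sample is out of scope,
and weights are taken as given.

## Composite Coverage Index

$$CCI = \tfrac14\Big(FP + \tfrac{SBA+ANC}{2} +
\tfrac{2\,DPT3+MSL+BCG}{4} + \tfrac{ORT+CPNM}{2}\Big)$$

The weights sum to 1, so the CCI is a convex combination: it equals k
when all components equal k, lies between the component extremes, and
is strictly increasing in every component. Two conventions matter in
practice:

* **The FP term is family-planning demand satisfied, not modern
  contraceptive prevalence.** With Nepal's 2016 components
  (64, 63, 86, 86, 90, 98, 61.4, 84.9) demand satisfied gives
  75.41 → 75, matching the published national value, while modern CPR
  (43) would give 70.2; the 2001 check (56 → 46.34 → 46) agrees.
* **Rounded vs unrounded inputs.** From microdata the CCI is computed
  on unrounded estimates; from a published table it inherits the
  table's rounding. Reproducing stratified published CCIs therefore
  uses printed inputs: rural 2016 gives 72.49 → 72.5 and urban
  77.88 → 77.9 (difference 5.4, ratio 1.07), and the no-education
  stratum gives 73.16 → 73.2. The educated stratum is a known
  discrepancy: rounded inputs give 77.14 → 77.1 against a published
  77.2, presumably because the original computation used unrounded
  coverages. We report our arithmetic and do not force the match.

Display rounding is half-away-from-zero (`round_half_up()`), the
convention of the published tables; all internal computation is full
precision.

## Equity

For each advantaged/disadvantaged pair (wealthiest–poorest,
urban–rural, educated–none) the package reports the difference in
percentage points and the ratio. The gap is signed
(advantaged − disadvantaged); a negative gap means the disadvantaged
stratum is ahead (e.g. measles-rubella, −4.2 points). A zero
disadvantaged coverage leaves the ratio undefined and flagged.

The four-pattern classification (high/low coverage × high/low
inequity) needs thresholds the source material never states
numerically. The defaults — coverage 80%, absolute gap 10 points — are
inferred from the published exemplars (ANC 86/17.6 and measles 90/−4.2
on the high-coverage side; family planning 64/6.9 and diarrhoea
treatment 61.4/16.6 on the low side) and are ordinary arguments, not
constants in the logic. Classification uses |gap|, so a large
pro-disadvantaged gap is still high inequity. Thresholds are inclusive
(≥).

## Trends and projection

The annualized rate of change between surveys is geometric:
$ARC = ((c_{t_2}/c_{t_1})^{1/(t_2-t_1)} - 1)\times 100$, positive for
increasing coverage. (The source's displayed formula carries a leading
minus sign that its own worked expansion and its tables contradict; the
implementation follows the worked expansion.) ARCs recomputed from
rounded printed coverages occasionally differ from published ones by
0.1 — e.g. unmet need recomputes to −1.0 against a printed −1.1 — so
exact-reproduction checks are limited to rows that reproduce from
printed values (SBA 11.7, pneumonia care-seeking 8.2, diarrhoea
treatment 2.5, CCI 3.3).

Projection compounds the ARC from the base year and clamps to
[0, 100]%: compound growth above full coverage is meaningless, and the
series records in which year the cap binds. Only the two-point
2001→2016 ARC is treated as the headline (five-yearly interim changes
are masked by it); any survey-year pair is supported.

## Lives-saved engine

An annual cohort model. Baseline deaths per year, outcome group
(maternal, stillbirth, neonatal, post-neonatal under-five) and cause
are `births(y) · rate / denominator · cause fraction`, with rates per
1000 births for child outcomes and per 100,000 for maternal deaths.
Each intervention averts
`effectiveness × affected fraction × max(ΔCov, 0)` of the deaths from
the causes it acts on, where ΔCov is the scale-up minus counterfactual
coverage as a proportion. Linked interventions acting on one cause
combine on the residual hazard, `1 − Π(1 − Effᵢ·AFᵢ·ΔCovᵢ)`, which is
what prevents a death being averted twice: the combined impact is
strictly below the additive sum for two or more interventions. An
additive-capped mode exists for sensitivity analysis, and a symmetric
mode lets coverage declines increase deaths (the default floors
aversion at zero, since the source does not address declining
coverage). Conservation is exact by construction: scenario deaths +
averted = baseline deaths in every year and group.

Deliberate simplifications: the counterfactual holds coverage at the
base-year level; births are constant unless a growth rate is
configured; no herd effects, nutrition pathways or country database.
The published headline deaths-averted totals depend on exactly those
unpublished inputs, so the bundled scenario
(`scenario_nepal_2016_2030_synthetic.json`) is labelled synthetic: its
baseline mortality rates are published national figures (stillbirth
18/1000, neonatal 21/1000, post-neonatal under-five 17/1000, maternal
239/100,000; ~570,000 births/yr), but its cause structure,
effectiveness values and affected fractions are illustrative. Its
outputs demonstrate the mechanism; the engine's correctness is
established by closed-form and product-oracle tests, not by matching
published totals.

## Synthetic survey generator

The generator emulates the *structure* the analysis needs: a latent
household wealth factor; binary assets whose ownership is logistic in
that factor (loading 2.2 on the logit scale — strong enough that the
asset index is a sharp wealth proxy); log-normal sampling weights with
urban households down-weighted (factor 0.8, emulating urban
oversampling); residence and women's education mildly wealth-graded
(defaults 60% urban, 65% with at least primary education, near the
2016 survey's frame); one ever-married woman per household; Poisson
births in the 2-year recall window (mean 0.25) and Poisson children
under five (mean 0.6); two-week illness prevalences of 8% (diarrhoea)
and 5% (ARI). Default per-quintile coverage gradients are anchored so
the population mean sits near Nepal's 2016 national values with
monotone pro-rich spans of 6–45 points; they are a stated world, chosen
once, not tuned.

A key design choice: outcomes are drawn conditional on the quintile
*constructed from the generated assets* (PCA + weighted cut-points),
not on the latent factor. Re-deriving quintiles downstream therefore
reproduces the generating strata exactly, so coverage recovery is
unbiased and a failed round-trip test indicates a real estimator bug
rather than boundary misclassification noise. The cost is that the
generator does not emulate wealth-measurement error; nor does it
emulate cluster sampling, non-response, recall error, or correlated
outcomes within households. A green round-trip test establishes that
estimation inverts generation — it does not validate the package
against real survey complexities.

## Numerical conventions and edge cases

* Reproducibility: the generator seeds its own RNG (restoring the
  caller's state) and identical config + seed yields byte-identical
  serialized datasets; the pipeline is a pure function of
  (config, seed).
* Rounding: half-away-from-zero with a 1e-9 epsilon against binary
  representation of decimal halves; applied only at presentation.
* ARC is undefined at zero baseline coverage (error), and a missing
  survey year yields a missing ARC, not a failure.
* Quintile ties: stable input order. Asset PCA tolerance against an
  independent eigen-decomposition oracle: 1e-8.
* Lives-saved coverage changes are clamped to [−1, 1] before use;
  effectiveness and affected fractions are validated into [0, 1].
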