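---
title: "Tiered mixture risk assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered mixture risk assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Humans ingest several mycotoxins at once: a single fungal species can
produce many toxins, and co-occurrence in cereal products is the rule
rather than the exception. `tieredmix` implements a tiered workflow for
assessing the risk of such combined dietary exposure under the
dose-addition assumption, from hazard characterisation through
probabilistic exposure to combined risk characterisation and
benchmark-dose based refinement.

## The tiers

**Hazard index (HI).** The crudest screen divides each compound's
exposure by its health-based guidance value (HBGV) and sums the hazard
quotients, `HI = sum(Exp_i / HBGV_i)`. Because HBGVs may rest on
different critical effects, the HI can overstate a coherent combined
risk; it also fails outright when some compounds lack an HBGV. The
package implements it (`hazard_index()`) but the driver may skip it when
HBGVs are incomplete.

**Target-specific index (mRPI).** Compounds are grouped by a common
target organ (kidney, liver, haematological system) or, one tier higher,
by a common phenomenological effect (reduced white blood cell count).
For each member a toxicological reference value (TRV) specific to the
group's effect is derived, and the reference point quotients
`RPQ_i = Exp_i / TRV_i` are summed (`mrpi_sum()`). Summing *percentiles*
of the marginal exposure distributions assumes the same individuals sit
in every upper tail; the alternative (`cumulative_exposure_trv_scaling()`
plus `risk_characterisation()`) scales exposures to reference-compound
equivalents with TRV ratios and sums *within individuals* before taking
percentiles. The first route can only exceed the second for comonotonic
exposures, where they coincide exactly (a quantile-additivity fact the
test suite asserts); on independent exposures the percentile sum tends
to sit above the individual combination at the 95th percentile.

A useful algebraic property: with TRV-ratio scaling the combined risk
metric equals `quantile(sum_i E_i / TRV_i) ` regardless of which member
is declared the reference, so the reference choice cannot change the
answer. The package asserts this invariance to 1e-12.

**Relative potency factors (RPF).** TRV ratios are not potencies: they
inherit different effect sizes (a BMDL05 versus a BMDL10), different
assessment factors and different residual variation in the underlying
studies. The refined tier fits the paired dose-response datasets of the
group members *simultaneously* with shared curve shape and residual
variance but compound-specific background and dose scale
(`simultaneous_fit()`). Parallelism on log-dose makes the relative
potency factor — the ratio of equipotent doses — a single number,
independent of the benchmark response by construction. Exposures are
then combined as reference equivalents via `combine_with_rpf()`. Unlike
TRV-ratio scaling, the resulting metric *does* depend on the reference
compound, by exactly `RPF x TRV_alt / TRV_ref`; reducing this
discrepancy is the point of re-deriving both TRVs from benchmark doses
at a common effect size.

## Hazard characterisation

TRVs are derived as reference point over composed assessment factors
(`derive_trv()`). The default factor scheme
(`compose_assessment_factors()`) uses 10 for interspecies differences
(omitted for human studies), 10 for intraspecies variability, 2 for
extrapolating a subchronic study to chronic exposure, 10 for a
non-chronic human clinical study with intermittent dosing, 3 for a LOEL
in place of a NOAEL, and optional extra data-limitation factors (such as
the 1.5 sometimes applied by EFSA). When the assessment group matches a
compound's critical effect and an HBGV exists, the HBGV is used verbatim
(`trv_from_hbgv()`, and the precedence rule in `derive_trv_table()`).
Internal values keep full precision; only the `reported` field rounds,
to two significant figures, so downstream ratios are computed unrounded.

Two conventions from the worked mycotoxin tables are encoded in
`mycotoxin_reference_points()`: the fumonisin record covers FB1–FB3 by
read-across, and T2 and HT2 toxin share one record (`T2HT2`) with their
group TDI. The nivalenol record in the white-blood-cell group
deliberately omits the extra 1.5 factor of the published TDI because
that factor reflects reproductive-toxicity data gaps, not the
haematological endpoint; its TRV is therefore re-derived (350/200 =
1.75 µg/kg bw/d) rather than taken from the HBGV.

## Exposure

`oim_exposure()` implements the observed individual mean: consumed
amounts (g/day) are mapped to composite samples via a conversion table
(proportional composition), multiplied by the resolved concentration
(µg/kg), summed within an individual across days and foods, divided by
body weight (kg) and by the number of survey days. The explicit
1e-3 g→kg factor is tested against a hand-computed oracle. The OIM is a
simple chronic-exposure estimate; it makes no attempt to separate
within- from between-person variance, and usual-intake models are out of
scope (for the motivating data the transformed intakes were not
normally distributed, so such models did not apply).

Left-censored concentrations are substituted per scenario
(`resolve_concentration()`): zero (lower bound, LB), half the limit
(medium bound, MB) or the full limit (upper bound, UB). The applicable
limit is the LOQ for records flagged `"<LOQ"` (detected, not
quantified) and the LOD for `"<LOD"`; the flag makes a choice the
source convention ("LOD or LOQ") leaves implicit explicit per record.
LB ≤ MB ≤ UB holds pointwise by construction and is asserted on
generated data.

Percentiles use the empirical quantile with linear interpolation
(`stats::quantile()` type 7) — a stated, fixed convention. Uncertainty
comes from a non-parametric bootstrap over individuals
(`percentile_with_uncertainty()`): B resamples, percentile per
replicate, and the *median across replicates* is the reported estimate,
with a central 95% interval. Resampling individuals only (not
concentration values) is a design choice; a two-dimensional resampling
of both consumption and concentration data would widen the intervals
and could be added without changing the interface. Default B = 100, and
a seed is mandatory wherever randomness enters.

One ambiguity deserves note: "averaged over the number of consumption
days" can mean consumption days or survey days. The package divides by
survey days (the two coincide for daily consumers); switching to
consumption days would scale up the exposure of occasional consumers.

## Benchmark-dose engine

Dose-response data arrive as group summaries (dose, arithmetic mean, SD
or SEM, n). Responses are modelled as lognormal: arithmetic moments are
converted to log-scale moments (`mu = log m - lv/2`,
`lv = log(1 + (s/m)^2)`), and the likelihood is the normal likelihood
of the log responses reconstructed from those summaries, with the
converted log variance treated as the (n−1)-denominator sample
variance. The background parameter and the residual variance are
profiled out analytically, leaving 2–3 shape parameters per fit.

The mean functions are `a (1 + (c-1) g(b x))` with
`g(u) = 1 - exp(-u^d)` (exponential) or `g(u) = u^d/(1+u^d)` (Hill);
the 3-parameter variants fix d = 1, and c is the plateau fraction
(c < 1 for a decrease). The benchmark dose solves
`mean(BMD) = mean(0) (1 − BMR)` in closed form; when the plateau never
reaches the benchmark response the BMD is unbounded and flagged.
Optimisation is derivative-free Nelder-Mead from a grid of ≥ 10 starts
spanning log-spaced potency values, with a relative tolerance of 1e-12
on the objective; the shape exponent is softly bounded to [0.25, 8] to
keep step-function fits out.

`model_average_bmd()` weights converged families by AIC and generates a
parametric bootstrap from the weighted-average curve: group means from
the normal sampling distribution, group variances from the scaled
chi-squared, the refit family drawn per replicate by weight. BMDL and
BMDU are the 5th and 95th bootstrap percentiles (a two-sided 90%
interval); the reported BMD is the bootstrap median, so the ordering
BMDL ≤ BMD ≤ BMDU holds on every run. Coverage of the true BMD by the
90% interval is verified by simulation at study-scale group sizes
(n = 10 per group, residual log-SD 0.15) in the test suite.

`simultaneous_fit()` is the joint version: shared shape and variance,
per-compound background and dose-scale. The RPF equals the dose-scale
ratio, hence is exactly BMR-invariant (`rpf_at_bmr()` recomputes it at
any BMR for assertion). A parallelism diagnostic compares the joint fit
against separate per-compound fits of the winning family; if the
separate fits win by more than 2 AIC units per extra parameter the RPF
is still reported but flagged. `select_reference_compound()` picks the
compound with the smallest BMDU/BMDL ratio — the least uncertain
reference point — breaking ties lexicographically. HT2 toxin inherits
T2's RPF without fitting, consistent with their group HBGV.

## Synthetic data

Real total-diet-study concentration data and national food-consumption
surveys are not redistributable, so `mycotoxin_study_fixture()` generates
a study with the same statistical structure: a two-day diary for
lognormal-body-weight toddlers (median 12 kg), a food→composite
conversion table, and per-compound lognormal contamination with heavy
left-censoring (overall ~70–75% censored, matching the sparse
quantification typical of mycotoxin TDS data). Contamination levels
were fixed once so that the liver-like group's upper-bound P95 combined
metric stays below one while the haematological/WBC group's exceeds
one, exercising every branch of `tiered_assessment()`. All randomness
derives from one root seed through named substreams (survey /
concentration / dose-response), so components regenerate independently
and byte-identically.

The shipped dose-response fixture
(`inst/extdata/wbc_doseresponse_synthetic.csv`) is a *synthetic
stand-in* for the paired 90-day rat white-blood-cell-count studies: two
parallel exponential curves with a true potency ratio of 140, dose
ranges chosen so the reference compound's BMD10 (~1200 µg/kg bw/d) and
the model-averaged intervals land on the scale of the published
simultaneous analysis, n = 10 per group, residual log-SD 0.15, one
dataset reported as SD and the other as SEM to exercise the conversion.
With five dose groups of ten animals, a single realisation recovers the
potency ratio only to roughly ±15%; the estimator is unbiased, so the
recovery acceptance check averages over seeded replicates.

What the generator does *not* emulate: brand-level food heterogeneity,
processing factors, unit-to-unit variability within composites,
seasonal sampling, correlated multi-day consumption habits, or
realistic food lists. Passing tests therefore demonstrate correctness
of the computations and the claimed identities, not the magnitude of
any real population's risk.

## Problem sizes and numerical choices

The test suite runs the full pipeline at deliberately modest sizes —
surveys of 40–300 individuals, bootstrap B = 100–500 for percentiles,
B = 200 for benchmark-dose intervals (the documented minimum), 100
seeded replicates for interval coverage and 200 for the
percentile-sum-versus-individual comparison — sizes at which every
stochastic assertion is stable across seeds. Exceedance decisions use
the threshold 1 on the unrounded metric; reports additionally show
two-significant-figure values. CSV schemas fix units (µg/kg, g, kg,
µg/kg bw/d) with no auto-detection, and reject decimal commas: silent
unit drift is the dominant failure mode in exposure pipelines.

## Limitations

Dose addition is assumed throughout; interactions (synergy, antagonism)
are out of scope, as are genotoxic carcinogens (margin-of-exposure
territory), quantal endpoints, Bayesian model averaging and
covariate-adjusted exposure modelling. The bootstrap resamples
individuals only. The interval estimates for the simultaneous fit
condition on the selected family rather than averaging over families.
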