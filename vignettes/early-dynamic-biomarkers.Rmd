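---
title: "Early dynamic biomarkers: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early dynamic biomarkers: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynamark)
```

This vignette documents the scientific conventions behind `dynamark`: what
each classification rule means, which boundaries are inclusive, which
choices were genuinely open and how they were resolved, what the synthetic
cohort generator does and does not emulate, and the package's known
limitations.

## 1. Metabolic response from lesion-level PET tables

The package consumes lesion-level SUV tables, not images. A patient
contributes a baseline scan and an early follow-up scan (day 14 by
default); lesions are matched across timepoints by `lesion_id` supplied by
the caller — no spatial matching is attempted.

**Evaluability.** A lesion is evaluable when its SUVmax is at least
1.5-fold the liver reference uptake (SUVmean + 2 SD in a 3 cm right-lobe
ROI). If the liver is abnormal, the blood-pool branch applies: uptake must
*exceed* 2.0 × (SUVmean + 2 SD) of a 1 cm aortic ROI. The liver branch is
inclusive and the blood-pool branch strict, mirroring the wording of each
rule ("at least 1.5-fold" vs "> 2.0 ×"); both carry a 1e-9 absolute
epsilon so decimal thresholds such as 1.5 × (2.0 + 0.6) = 3.9 behave as
written under floating point.

**Consistent ("dominance") classification.** A lesion *responds* when its
SUVmax reduction is strictly greater than the cut-off (`cutoff_pct`,
default 25; 15 is the common sensitivity threshold — a delta of exactly
−25% is non-responding). Classes:

1. all lesions respond, no progression event → **class 1**, the only
   responder class;
2. mixed response, load-weighted responding share > 0.5 → **class 2**;
3. mixed response, share ≤ 0.5 → **class 3** (a share of exactly 0.5 is
   class 3);
4. any new FDG-avid lesion, any SUVmax increase in a known lesion, or no
   responding lesion at all → **class 4**.

The source description of class 4 ("all target lesions do not respond or a
progressive lesion occurs") leaves open whether an SUVmax increase alone
suffices; we implement *any progression event → class 4*, the literal
reading, and record the per-lesion deltas in the result so an auditor can
re-derive the class. "Majority of whole-body tumor load" is not defined
operationally anywhere we could find; we weight lesions by baseline MATV
(the stated burden surrogate), fall back to baseline SUVmax when any MATV
is missing, and to unweighted counts when all weights are zero — the
weighting actually used is reported in the result. New lesions are taken
as FDG-positive by assertion of the input table; their evaluability is not
re-checked.

**PERCIST.** Targets are baseline lesions with diameter ≥ 1.5 cm and
evaluable uptake; at most the 2 hottest per organ by SUVpeak, at most 10
overall, ties broken lexicographically by `lesion_id` so selection is
deterministic under row permutation. Response compares the hottest
baseline SUVpeak with the hottest follow-up SUVpeak *among the targets* —
the hottest lesion may change identity under treatment, which is the
PERCIST convention. MR requires a decrease strictly greater than 30%.

**QC.** Scan-pair checks (activity difference > 25% of baseline, uptake
time outside 60–70 min or differing by > 10 min, scanner mismatch,
baseline more than 7 days before treatment start, glucose ≥ 200 mg/dL)
are *advisory*: findings are returned as machine-readable codes and never
exclude a pair, because the source protocol does not state that QC
failures excluded patients.

## 2. ctDNA filtering, detection and dynamics

Variant calls are retained when coverage > 100 (strict), the forward-read
fraction lies in [0.10, 0.90] (inclusive — the standard strand-bias
convention), and the consequence is protein-coding (missense, nonsense,
frameshift, splice); silent and intronic changes are excluded. Each
removed call is annotated with the *first* failing rule in that order.
Detection at a timepoint means ≥ 1 retained call with mutated copies/ml
> 0; a missing plasma sample yields `NA`, which is why the sample table is
a separate input — zero calls must not be confused with no sample.

The circulating DNA ratio pools copies across all of a patient's
mutations: CDR = Σ copies/ml(D14) / Σ copies/ml(baseline). Mutations
undetected at D14 contribute 0; mutations first seen at D14 add to the
numerator (the original single-gene definition has no such case; pooling
is the natural multi-mutation extension). CDR is undefined (NA) without
baseline detection or without a D14 sample. Dichotomization at the median
uses the midpoint-of-middle-two convention with the *low* label inclusive
(`value ≤ median`), matching the "≤ median" grouping used for outcome
analysis. VAF strata default to {0} / (0, 20) / [20, ∞): the published
three-way split ("0 vs 10–20% vs ≥20%") leaves (0, 10) unassigned, and we
assign detected-but-low VAF to the middle stratum; the edges are
configurable. Whether detection should count variants of unknown
significance is unknown; the default counts them, `pathogenic_only = TRUE`
restricts.

## 3. Combination and predictive values

`combine_biomarkers()` cross-classifies patients into R/NR × D/ND with an
`incomplete` level when either component is missing. The "negative
predictive value" reported by `npv_early_progression()` is the operational
quantity used in early-biomarker work: P(PFS < horizon | test
unfavorable), horizon 3 months by default. Patients censored before the
horizon without an event have unknowable 3-month status and are excluded
from numerator and denominator (exclusion, not imputation — conservative
and logged in `n_excluded`); the full 2×2 table is attached so textbook
sensitivity/specificity/PPV remain derivable. Percentages are rounded half
away from zero to one decimal, which is how the worked-example values
63.6% (14/22), 64.3% (9/14) and 77.8% (7/9) reproduce exactly.

## 4. Survival layer

`km_median()`, `logrank_test()` and `cox_univariate()` wrap the
`survival` package and pin conventions: the Kaplan–Meier median is the
earliest time with Ŝ(t) ≤ 0.5; ties use the Efron approximation; the
hazard-ratio CI is Wald on the log scale. These are the defaults of modern
survival software; the source analyses do not state their conventions, so
ours are recorded rather than attributed. Monotone likelihood (complete
separation) and non-convergence are *flagged*, never silently estimated.
`forest_univariate()` applies no multiplicity adjustment — each row of a
univariate forest table is a separate exploratory hypothesis.

## 5. Design calculations

Under exponential survival, S(t) = e^{−ht}, so two survival fractions at a
common horizon imply HR = ln(s₁)/ln(s₀) — the horizon cancels.
`schoenfeld_events()` evaluates
d = ⌈(z₁₋α/₂ + z_power)² / (p(1−p) ln²HR)⌉ with normal quantiles at double
precision. The canonical worked example (37% vs 70% six-month PFS → HR
0.36; α = 0.05 two-sided, power 0.90) reproduces 42 events with an
allocation fraction p = 0.59 — the expected metabolic non-responder share
from the pilot phase. Equal allocation gives 41 events, so the printed 42
supports but does not prove the 0.59 reading; allocation is therefore an
explicit parameter, never a hidden constant.

## 6. What the synthetic cohort emulates

`simulate_cohort()` generates lesion, scan, variant, clinical and sample
tables for a configurable cohort (default 47 patients). One latent
Bernoulli *benefit* state (default p = 0.5, chosen to match a ≈ 50%
responder share at the 15% cut-off) drives everything:

* **Lesions:** counts 1 + Poisson(3) capped at 15; baseline SUVmax
  log-normal(log 7, 0.4); day-14 SUVmax = baseline × effect × log-normal
  noise (sd 0.10), effect 0.74 for benefiting patients (a mean 26%
  decrease, the pilot-phase figure) and 1.0 otherwise; non-benefiting
  patients develop a new lesion with probability 0.3.
* **ctDNA:** baseline detection probability 0.565; 1 or 2 mutations
  (P(two) = 0.19 ≈ 5/26, always in different genes, never more than 2 —
  asserted on generated data); baseline copies/ml log-normal(log 50, 1);
  day-14 copies = baseline × clearance factor, log-normal with median 0.05
  (benefit) vs 0.8 (no benefit), sd(log) 0.8; copies below a 5 copies/ml
  detection limit are not reported, which is what makes full clearance and
  D14-negative conversion possible. Progression samples rebound (×1.5
  median). An artifactual call failing the variant filter is injected with
  probability 0.1 per patient so the filter does real work in end-to-end
  runs.
* **Outcome:** PFS exponential with median 6.4 months (benefit) vs 2.2
  (no benefit); independent exponential censoring with median 30 months
  (≈ 15–20% censoring). Plasma missingness 1/47 at baseline and 5/47 at
  day 14 reproduces the 46-baseline / 42-D14 sample counts.

Both biomarkers are noisy readouts of the same latent state, so the
simulated PET and ctDNA groups separate PFS the way the real cohort's do,
while the generating hazard ratio (6.4/2.2 ≈ 2.91 for non-benefit vs
benefit) stays known and recoverable — `recover_parameters()` is the
package's primary validation surface for the survival layer. The joint
distribution of PET response and ctDNA clearance in real patients is
unknowable from published summaries; here their dependence arises solely
through the shared latent state, which is a modelling choice, not an
estimate.

**What it does not emulate:** PET image noise, ROI delineation and
scanner effects (tables are consumed, not images); sequencing reads,
error profiles and clonal hematopoiesis; correlation between lesion count
and ctDNA burden; non-exponential (e.g. cured-fraction) survival;
informative censoring. Passing tests on synthetic cohorts therefore
validate the *pipeline arithmetic and statistical conventions*, not
clinical performance on real data.

## 7. Problem sizes and numerical choices

Validation runs use sizes chosen to keep Monte-Carlo error well inside
the asserted tolerances: Kaplan–Meier median recovery (±0.5 months) and
cut-off monotonicity on one simulated cohort of n = 2000; the configured
detection fraction (±3%) on one n = 3000 cohort (3000 Bernoulli draws,
SE ≈ 0.9%); hazard-ratio CI coverage as 25 replicates at n = 250
(expected coverage 95%, asserted ≥ 21/25); log-rank null uniformity on
500 replicates of n = 40; Cox bias on 100 replicates at n = 2000 (SE of
the mean log-HR ≈ 0.005, asserted bias < 5%). Percent rounding is half
away from zero everywhere a percentage is reported. Degenerate inputs are
rejected loudly: zero baseline SUV (percent change undefined), constant
Cox covariates, empty groups in the log-rank test, all-zero load weights
(fall back to counts, with the weighting recorded).

## 8. Known limitations

* Lesion matching is identifier-based; a renamed lesion silently becomes
  a data error (caught only when a non-new follow-up lesion lacks a
  baseline row).
* PERCIST inevaluability (no targets, or all follow-up SUVpeak missing)
  yields `NA` rather than imputation; patients lost this way simply drop
  from PERCIST summaries.
* The D28 timepoint is treated as just another follow-up label; no
  D14/D28 reconciliation logic is provided beyond `cohen_kappa()` for
  concordance.
* The operational NPV conditions on known 3-month status; with heavy
  early censoring its denominator shrinks and the estimate loses
  precision — the exclusion count is reported for exactly this reason.
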