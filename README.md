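# dynamark

Early dynamic biomarkers of treatment response in metastatic cancer:
patient-level analysis of FDG-PET metabolic response and circulating tumor
DNA (ctDNA) dynamics, with the survival and trial-design calculations that
go with them.

## The problem

In ER+/HER2− metastatic breast cancer treated with endocrine/targeted
combinations, many patients derive no benefit but stay on a toxic drug for
months before radiological progression is declared. Two early (day-14)
readouts can identify likely non-benefiters much sooner:

* **Metabolic response on FDG-PET/CT.** The consistent ("dominance")
  patient-based method requires a *uniform* SUVmax reduction of more than a
  cut-off (25%, or 15% as a sensitivity threshold) in **all** lesions;
  patients are graded into four classes — class 1 (all lesions respond,
  responder), class 2/3 (mixed response, split by whether the load-weighted
  majority of disease responds), class 4 (no responding lesion, or any
  progression event: a new FDG-avid lesion or an SUVmax increase). PERCIST
  (SUVpeak of the hottest of ≤10 target lesions, ≤2 per organ, >30%
  decrease = responder) is computed alongside.
* **ctDNA detection and clearance.** Variant calls from a targeted plasma
  panel are filtered (coverage > 100, forward-read fraction in
  [0.10, 0.90], protein-coding consequences only); a patient-timepoint is
  "detected" if any retained mutation carries mutated copies/ml. Dynamics
  are summarised by the circulating DNA ratio
  **CDR = Σ copies/ml(D14) / Σ copies/ml(baseline)**.

The package combines both tests per patient, computes the probability of
rapid progression (PFS < 3 months) given an unfavorable test (the
operational "negative predictive value"), runs the Kaplan–Meier /
log-rank / univariate Cox outcome analyses, and reproduces the design
arithmetic: under exponential survival, a 6-month PFS of 37% vs 70%
implies HR = ln(0.70)/ln(0.37) ≈ 0.36, and the Schoenfeld formula

    d = ceil( (z_{1−α/2} + z_{power})² / (p(1−p)·ln²HR) )

gives the required event count. A synthetic cohort generator with known
ground truth (latent benefit driving lesion SUV decreases, ctDNA clearance
and exponential PFS) makes every stage testable without patient data.

## Worked example

```r
library(dynamark)

# design calculations
exponential_hr(0.37, 0.70)                    # 0.3587...  (rounds to 0.36)
schoenfeld_events(0.36, 0.05, 0.90, 0.59)     # 42

# simulate a 47-patient cohort and run the full pipeline
co  <- simulate_cohort(cohort_config(), seed = 7)
pet <- classify_pet_cohort(co$lesions, co$scans, cutoffs = c(25, 15))
ct  <- ctdna_status(co$variants, co$samples)
detection_rate(ct, "baseline")
rep <- recover_parameters(co, cutoff_pct = 15)
print(rep)
```

which prints

```
Parameter recovery on synthetic cohort
  hazard ratio (non-benefit vs benefit): true 2.909, Cox 3.271 (95% CI 1.573-6.803)
  hazard ratio via PET non-response call: 2.843
  ctDNA detection: baseline 27/46 (58.7%; configured 56.5%), d14 17/42 (40.5%)
```

`true 2.909` is the generating hazard ratio (PFS medians 2.2 vs 6.4
months); the Cox estimate on the latent groups covers it, the estimate via
the pipeline's own PET non-response call points the same way (the imaging
readout is a noisy surrogate of benefit), and the observed baseline
detection fraction sits near the configured 56.5%.

Predictive value of an unfavorable test for rapid progression:

```r
npv_early_progression(rep(TRUE, 22), c(rep(1.5, 14), rep(6, 8)), rep(1, 22),
                      test_name = "PET non-response")
# PET non-response: 14 / 22 unfavorable patients progressed within 3 months  (NPV 63.6%)
```

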