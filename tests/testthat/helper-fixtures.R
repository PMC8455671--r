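# Shared builders for lesion/scan/variant fixtures, constructed in code.

normal_ref <- function(liver_mean = 2.0, liver_sd = 0.3) {
  list(liver_suvmean = liver_mean, liver_suvsd = liver_sd,
       bloodpool_suvmean = 1.5, bloodpool_suvsd = 0.2,
       liver_abnormal = FALSE)
}

abnormal_liver_ref <- function(bp_mean = 1.5, bp_sd = 0.2) {
  list(liver_suvmean = NA_real_, liver_suvsd = NA_real_,
       bloodpool_suvmean = bp_mean, bloodpool_suvsd = bp_sd,
       liver_abnormal = TRUE)
}

compliant_scan <- function(timepoint = "baseline",
                           activity = 300, uptake = 65, glucose = 100,
                           scanner = "SCN01", days = -2) {
  list(timepoint = timepoint, injected_activity_mbq = activity,
       uptake_time_min = uptake, glucose_mg_dl = glucose,
       scanner_id = scanner, days_from_treatment_start = days)
}

# baseline/follow-up lesion tables from per-lesion percent deltas
lesions_from_deltas <- function(deltas, matv = NULL, new_lesion = FALSE,
                                suv0 = 10) {
  n <- length(deltas)
  ids <- sprintf("L%02d", seq_len(n))
  b <- data.frame(lesion_id = ids, organ = "liver",
                  suvmax = rep(suv0, n), suvpeak = rep(suv0, n) * 0.9,
                  matv_cm3 = if (is.null(matv)) rep(NA_real_, n) else matv,
                  stringsAsFactors = FALSE)
  f <- data.frame(lesion_id = ids, organ = "liver",
                  suvmax = suv0 * (1 + deltas / 100),
                  suvpeak = suv0 * (1 + deltas / 100) * 0.9,
                  is_new = FALSE, stringsAsFactors = FALSE)
  if (new_lesion)
    f <- rbind(f, data.frame(lesion_id = "LNEW", organ = "lung",
                             suvmax = 6, suvpeak = 5.4, is_new = TRUE,
                             stringsAsFactors = FALSE))
  list(baseline = b, followup = f)
}

# Independent rule enumeration for the consistent classification: works on
# the boolean outcome pattern (responds / increased / new lesion), not on
# SUV tables, so it exercises none of the package's arithmetic.
consist_oracle <- function(deltas, cutoff, weights, new_lesion) {
  responds <- deltas < -cutoff
  increased <- deltas > 0
  if (new_lesion || any(increased) || sum(responds) == 0) return(4L)
  if (all(responds)) return(1L)
  share <- sum(weights[responds]) / sum(weights)
  if (share > 0.5) 2L else 3L
}

# one variant-call row with pass-all defaults
variant_row <- function(patient_id = "P1", timepoint = "baseline",
                        gene = "PIK3CA", consequence = "missense",
                        classification = "pathogenic", vaf = 5,
                        copies = 50, total = 1000, coverage = 500,
                        fwd = 0.5) {
  data.frame(patient_id = patient_id, timepoint = timepoint, gene = gene,
             protein_change = "p.X1Y", consequence = consequence,
             classification = classification, vaf_pct = vaf,
             mut_copies_per_ml = copies, total_copies_per_ml = total,
             coverage = coverage, fwd_fraction = fwd,
             stringsAsFactors = FALSE)
}

filter_fixture_path <- function() {
  system.file("extdata", "variants_filter_fixture.tsv",
              package = "dynamark", mustWork = TRUE)
}
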