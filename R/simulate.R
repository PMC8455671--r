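# Synthetic cohort generator with known ground truth.
#
# Emulates a ~47-patient early-biomarker study: a latent treatment-benefit
# status drives (i) multiplicative lesion SUVmax decreases at day 14,
# (ii) clearance of mutated ctDNA copies, and (iii) exponential PFS with
# group-specific medians. Biomarkers are therefore noisy readouts of the
# same latent state, so the pipeline's group contrasts are estimable and
# the generating parameters are recoverable.

.ORGANS <- c("liver", "lung", "bone", "node", "other")
.ORGAN_P <- c(0.30, 0.25, 0.20, 0.15, 0.10)

.GENE_P <- c(ESR1 = 0.31, PIK3CA = 0.27, TP53 = 0.20, AKT1 = 0.11,
             PTEN = 0.06, ERBB2 = 0.05)
.HOTSPOTS <- list(
  ESR1 = c("p.D538G", "p.Y537N", "p.Y537S"),
  PIK3CA = c("p.H1047R", "p.E545K", "p.E542K"),
  TP53 = c("p.R175H", "p.R273H"),
  AKT1 = c("p.E17K"),
  PTEN = c("p.R130Q"),
  ERBB2 = c("p.L755S"))

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the structure of a ~47-patient metastatic breast cancer
#' cohort under early endocrine/targeted therapy: about half the patients
#' carry a latent benefit state; benefiting patients show a mean 26\%
#' multiplicative SUVmax decrease at day 14 (effect 0.74) and clear most of
#' their mutated ctDNA copies, while non-benefiting patients show no
#' systematic SUV change, retain ctDNA, and may develop new lesions;
#' PFS is exponential with medians 6.4 (benefit) and 2.2 (no benefit)
#' months; baseline ctDNA is detectable in 56.5\% of patients; a small
#' fraction of plasma samples is missing (1/47 baseline, 5/47 day-14);
#' at most 2 mutations per patient.
#'
#' @param n_patients cohort size.
#' @param p_latent_benefit probability of the latent benefit state.
#' @param lesion_lambda Poisson mean of extra lesions (counts are
#'   1 + Poisson, capped at \code{max_lesions}).
#' @param max_lesions upper cap on lesions per patient.
#' @param suvmax_meanlog,suvmax_sdlog log-normal baseline SUVmax.
#' @param response_effect_benefit,response_effect_nonbenefit mean
#'   multiplicative day-14 SUVmax change per group.
#' @param lesion_heterogeneity_sd log-scale SD of the per-lesion
#'   multiplicative noise around the group effect.
#' @param p_new_lesion_nonbenefit probability that a non-benefiting patient
#'   develops a new FDG-avid lesion by day 14.
#' @param p_liver_abnormal probability the liver reference is unusable.
#' @param ctdna_p_detect_baseline baseline ctDNA detection probability.
#' @param p_two_mutations probability a detected patient carries 2 (rather
#'   than 1) mutations.
#' @param copies_meanlog,copies_sdlog log-normal baseline mutated copies/ml.
#' @param clearance_meanlog_benefit,clearance_meanlog_nonbenefit,clearance_sdlog
#'   log-normal day-14/baseline clearance factor per group.
#' @param detection_limit_copies copies/ml below which a mutation is not
#'   reported (assay limit of detection).
#' @param p_artifact_call probability of one extra artifactual baseline call
#'   that fails the variant filter (exercises filtering in the pipeline).
#' @param median_pfs_benefit,median_pfs_nonbenefit exponential PFS medians
#'   (months) per latent group.
#' @param censoring_median_months exponential censoring median.
#' @param p_missing_baseline_plasma,p_missing_d14_plasma plasma missingness.
#' @param p_progression_sample probability a progressing patient has a
#'   progression plasma sample.
#' @return object of class \code{cohort_config} (a validated list).
#' @export
cohort_config <- function(n_patients = 47,
                          p_latent_benefit = 0.5,
                          lesion_lambda = 3,
                          max_lesions = 15,
                          suvmax_meanlog = log(7),
                          suvmax_sdlog = 0.4,
                          response_effect_benefit = 0.74,
                          response_effect_nonbenefit = 1.0,
                          lesion_heterogeneity_sd = 0.10,
                          p_new_lesion_nonbenefit = 0.30,
                          p_liver_abnormal = 0.05,
                          ctdna_p_detect_baseline = 0.565,
                          p_two_mutations = 0.19,
                          copies_meanlog = log(50),
                          copies_sdlog = 1.0,
                          clearance_meanlog_benefit = log(0.05),
                          clearance_meanlog_nonbenefit = log(0.8),
                          clearance_sdlog = 0.8,
                          detection_limit_copies = 5,
                          p_artifact_call = 0.10,
                          median_pfs_benefit = 6.4,
                          median_pfs_nonbenefit = 2.2,
                          censoring_median_months = 30,
                          p_missing_baseline_plasma = 1 / 47,
                          p_missing_d14_plasma = 5 / 47,
                          p_progression_sample = 0.5) {
  cfg <- as.list(environment())
  if (cfg$n_patients < 1) .fail("'n_patients' must be at least 1")
  for (nm in c("p_latent_benefit", "p_new_lesion_nonbenefit",
               "p_liver_abnormal", "ctdna_p_detect_baseline",
               "p_two_mutations", "p_artifact_call",
               "p_missing_baseline_plasma", "p_missing_d14_plasma",
               "p_progression_sample"))
    .assert_prob(cfg[[nm]], nm, open = FALSE)
  for (nm in c("lesion_heterogeneity_sd", "clearance_sdlog",
               "suvmax_sdlog", "copies_sdlog"))
    if (cfg[[nm]] < 0) .fail("'", nm, "' must be non-negative")
  for (nm in c("median_pfs_benefit", "median_pfs_nonbenefit",
               "censoring_median_months", "response_effect_benefit",
               "response_effect_nonbenefit", "detection_limit_copies"))
    if (cfg[[nm]] <= 0) .fail("'", nm, "' must be positive")
  structure(cfg, class = "cohort_config")
}

#' Simulate a synthetic early-biomarker cohort
#'
#' Generates lesion, scan, variant, clinical and sample tables plus the
#' ground truth, deterministically for a given seed. See
#' \code{\link{cohort_config}} for the generating model.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer RNG seed.
#' @return list of data frames: \code{lesions}, \code{scans},
#'   \code{variants}, \code{clinical}, \code{samples},
#'   \code{ground_truth}; all readable back through the \code{read_*}
#'   functions after \code{\link{write_cohort}}.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  if (!inherits(config, "cohort_config"))
    .fail("'config' must be built with cohort_config()")
  set.seed(as.integer(seed))
  cfg <- config
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  benefit <- stats::rbinom(n, 1, cfg$p_latent_benefit) == 1
  effect <- ifelse(benefit, cfg$response_effect_benefit,
                   cfg$response_effect_nonbenefit)

  lesions <- vector("list", n)
  scans <- vector("list", n)
  variants <- vector("list", n)
  samples <- vector("list", n)
  clinical <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- ids[i]

    ## --- PFS (drawn early so progression sampling can condition on it)
    med <- if (benefit[i]) cfg$median_pfs_benefit else cfg$median_pfs_nonbenefit
    t_event <- stats::rexp(1, rate = log(2) / med)
    t_cens <- stats::rexp(1, rate = log(2) / cfg$censoring_median_months)
    pfs <- min(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    ## --- lesions
    n_les <- min(1L + stats::rpois(1, cfg$lesion_lambda), cfg$max_lesions)
    lid <- sprintf("%s_L%02d", pid, seq_len(n_les))
    organ <- sample(.ORGANS, n_les, replace = TRUE, prob = .ORGAN_P)
    suv_b <- stats::rlnorm(n_les, cfg$suvmax_meanlog, cfg$suvmax_sdlog)
    peak_ratio <- stats::runif(n_les, 0.75, 0.95)
    diam <- pmax(stats::rlnorm(n_les, log(2.5), 0.4), 0.6)
    matv <- stats::rlnorm(n_les, log(12), 0.9)
    suv_f <- suv_b * effect[i] *
      stats::rlnorm(n_les, 0, cfg$lesion_heterogeneity_sd)

    base_rows <- data.frame(
      patient_id = pid, timepoint = "baseline", lesion_id = lid,
      organ = organ, suvmax = suv_b, suvpeak = suv_b * peak_ratio,
      diameter_cm = diam, matv_cm3 = matv, is_new = FALSE,
      stringsAsFactors = FALSE)
    fu_rows <- data.frame(
      patient_id = pid, timepoint = "d14", lesion_id = lid,
      organ = organ, suvmax = suv_f, suvpeak = suv_f * peak_ratio,
      diameter_cm = diam, matv_cm3 = NA_real_, is_new = FALSE,
      stringsAsFactors = FALSE)
    if (!benefit[i] &&
        stats::runif(1) < cfg$p_new_lesion_nonbenefit) {
      s_new <- stats::rlnorm(1, cfg$suvmax_meanlog, cfg$suvmax_sdlog)
      fu_rows <- rbind(fu_rows, data.frame(
        patient_id = pid, timepoint = "d14",
        lesion_id = sprintf("%s_L%02d", pid, n_les + 1L),
        organ = sample(.ORGANS, 1, prob = .ORGAN_P),
        suvmax = s_new, suvpeak = s_new * stats::runif(1, 0.75, 0.95),
        diameter_cm = pmax(stats::rlnorm(1, log(1.8), 0.3), 0.6),
        matv_cm3 = NA_real_, is_new = TRUE, stringsAsFactors = FALSE))
    }
    lesions[[i]] <- rbind(base_rows, fu_rows)

    ## --- scans (same scanner; compliant acquisition with mild jitter)
    act_b <- stats::runif(1, 220, 350)
    liver_mean <- stats::rnorm(1, 2.2, 0.15)
    liver_sd <- abs(stats::rnorm(1, 0.25, 0.05))
    bp_mean <- stats::rnorm(1, 1.8, 0.10)
    bp_sd <- abs(stats::rnorm(1, 0.20, 0.04))
    scanner <- sprintf("SCN%02d", sample.int(5, 1))
    scans[[i]] <- data.frame(
      patient_id = pid, timepoint = c("baseline", "d14"),
      injected_activity_mbq = c(act_b, act_b * stats::runif(1, 0.9, 1.1)),
      uptake_time_min = stats::runif(2, 60, 70),
      glucose_mg_dl = stats::runif(2, 80, 140),
      scanner_id = scanner,
      days_from_treatment_start = c(-sample.int(7, 1) + 1L, 14L),
      liver_suvmean = liver_mean, liver_suvsd = liver_sd,
      bloodpool_suvmean = bp_mean, bloodpool_suvsd = bp_sd,
      liver_abnormal = stats::runif(1) < cfg$p_liver_abnormal,
      stringsAsFactors = FALSE)

    ## --- plasma samples & variants
    has_b <- stats::runif(1) >= cfg$p_missing_baseline_plasma
    has_d <- stats::runif(1) >= cfg$p_missing_d14_plasma
    has_p <- event == 1 && stats::runif(1) < cfg$p_progression_sample
    tp <- c("baseline", "d14", "progression")[c(has_b, has_d, has_p)]
    samples[[i]] <- if (length(tp)) data.frame(
      patient_id = pid, timepoint = tp, stringsAsFactors = FALSE) else NULL

    detected <- stats::runif(1) < cfg$ctdna_p_detect_baseline
    vrows <- NULL
    if (detected) {
      n_mut <- 1L + stats::rbinom(1, 1, cfg$p_two_mutations)
      genes <- sample(names(.GENE_P), n_mut, prob = .GENE_P)
      copies_b <- stats::rlnorm(n_mut, cfg$copies_meanlog, cfg$copies_sdlog)
      vaf_b <- pmin(stats::rlnorm(n_mut, log(5), 1), 60)
      cl_mean <- if (benefit[i]) cfg$clearance_meanlog_benefit else
        cfg$clearance_meanlog_nonbenefit
      clearance <- stats::rlnorm(n_mut, cl_mean, cfg$clearance_sdlog)
      rebound <- stats::rlnorm(n_mut, log(1.5), 0.5)

      mk <- function(tpname, cp, vaf) data.frame(
        patient_id = pid, timepoint = tpname,
        gene = genes,
        protein_change = vapply(genes, function(g)
          sample(.HOTSPOTS[[g]], 1), character(1)),
        consequence = "missense",
        classification = sample(c("pathogenic", "vus"), n_mut,
                                replace = TRUE, prob = c(0.8, 0.2)),
        vaf_pct = vaf, mut_copies_per_ml = cp,
        total_copies_per_ml = cp / pmax(vaf / 100, 1e-4),
        coverage = as.integer(stats::runif(n_mut, 5000, 20000)),
        fwd_fraction = stats::runif(n_mut, 0.35, 0.65),
        stringsAsFactors = FALSE)

      if (has_b) vrows <- mk("baseline", copies_b, vaf_b)
      if (has_d) {
        cp_d <- copies_b * clearance
        keep <- cp_d >= cfg$detection_limit_copies
        if (any(keep)) {
          r <- mk("d14", cp_d, pmin(vaf_b * clearance, 95))
          vrows <- rbind(vrows, r[keep, , drop = FALSE])
        }
      }
      if (has_p) {
        cp_p <- copies_b * rebound
        keep <- cp_p >= cfg$detection_limit_copies
        if (any(keep)) {
          r <- mk("progression", cp_p, pmin(vaf_b * rebound, 95))
          vrows <- rbind(vrows, r[keep, , drop = FALSE])
        }
      }
    }
    # occasional artifactual call the filter must remove
    if (has_b && stats::runif(1) < cfg$p_artifact_call) {
      art_gene <- sample(names(.GENE_P), 1)
      art <- data.frame(
        patient_id = pid, timepoint = "baseline", gene = art_gene,
        protein_change = "p.=", consequence = "silent",
        classification = "vus", vaf_pct = stats::runif(1, 0.1, 2),
        mut_copies_per_ml = stats::runif(1, 1, 20),
        total_copies_per_ml = 2000, coverage = 15000L,
        fwd_fraction = stats::runif(1, 0.35, 0.65),
        stringsAsFactors = FALSE)
      art$total_copies_per_ml <- max(art$total_copies_per_ml,
                                     art$mut_copies_per_ml)
      vrows <- rbind(vrows, art)
    }
    variants[[i]] <- vrows

    ## --- clinical covariates
    clinical[[i]] <- data.frame(
      patient_id = pid,
      pfs_months = pfs, event = event,
      age_years = round(stats::rnorm(1, 57, 11)),
      ecog = sample(0:2, 1, prob = c(0.45, 0.45, 0.10)),
      n_sites = sample(0:4, 1, prob = c(0.04, 0.25, 0.26, 0.25, 0.20)),
      visceral = stats::runif(1) < 0.74,
      prior_ct_lines = sample(0:3, 1, prob = c(0.43, 0.30, 0.17, 0.10)),
      prior_et_lines = sample(0:3, 1, prob = c(0.04, 0.28, 0.38, 0.30)),
      nsai_sensitive = stats::runif(1) < 0.70,
      prior_cdk46 = stats::runif(1) < 0.26,
      stringsAsFactors = FALSE)

    truth[[i]] <- data.frame(
      patient_id = pid, latent_benefit = benefit[i],
      response_effect = effect[i], median_pfs_true = med,
      hazard_true = log(2) / med,
      pfs_uncensored = t_event, event = event,
      ctdna_detected_true = detected,
      stringsAsFactors = FALSE)
  }

  out <- list(
    lesions = do.call(rbind, lesions),
    scans = do.call(rbind, scans),
    variants = if (any(!vapply(variants, is.null, logical(1))))
      do.call(rbind, variants[!vapply(variants, is.null, logical(1))])
      else .empty_variants(),
    clinical = do.call(rbind, clinical),
    samples = do.call(rbind, samples[!vapply(samples, is.null, logical(1))]),
    ground_truth = do.call(rbind, truth),
    config = cfg, seed = as.integer(seed))
  for (nm in c("lesions", "scans", "variants", "clinical", "samples",
               "ground_truth"))
    rownames(out[[nm]]) <- NULL
  class(out) <- "synthetic_cohort"
  out
}

.empty_variants <- function() data.frame(
  patient_id = character(), timepoint = character(), gene = character(),
  protein_change = character(), consequence = character(),
  classification = character(), vaf_pct = numeric(),
  mut_copies_per_ml = numeric(), total_copies_per_ml = numeric(),
  coverage = integer(), fwd_fraction = numeric(),
  stringsAsFactors = FALSE)

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (seed %d)\n",
              nrow(x$clinical), x$seed))
  cat(sprintf("  latent benefit: %d / %d\n",
              sum(x$ground_truth$latent_benefit), nrow(x$ground_truth)))
  cat(sprintf("  lesions: %d rows; variants: %d rows; samples: %d\n",
              nrow(x$lesions), nrow(x$variants), nrow(x$samples)))
  invisible(x)
}

#' Run the full pipeline on a synthetic cohort and compare with truth
#'
#' Classifies every patient's PET response, derives ctDNA statuses,
#' estimates the responder-vs-non-responder and latent-benefit hazard
#' ratios by univariate Cox regression, and reports them next to the
#' generating values, together with detection rates and the CDR
#' distribution by latent group.
#'
#' @param cohort a \code{\link{simulate_cohort}} result.
#' @param cutoff_pct SUVmax cut-off used for the PET responder contrast.
#' @return object of class \code{recovery_report}: list with
#'   \code{hr_true} (non-benefit vs benefit hazard ratio),
#'   \code{hr_benefit_est} (Cox estimate on the latent groups),
#'   \code{hr_responder_est} (Cox estimate on the pipeline's PET call),
#'   \code{detection} (configured vs observed rates), \code{cdr_summary},
#'   and the intermediate tables.
#' @export
recover_parameters <- function(cohort, cutoff_pct = 15) {
  if (!inherits(cohort, "synthetic_cohort"))
    .fail("'cohort' must come from simulate_cohort()")
  pet <- classify_pet_cohort(cohort$lesions, cohort$scans,
                             cutoffs = cutoff_pct)
  ct <- ctdna_status(cohort$variants, cohort$samples)
  gt <- cohort$ground_truth
  cl <- cohort$clinical

  m <- merge(cl, gt[, c("patient_id", "latent_benefit")], by = "patient_id")
  m <- merge(m, pet[, c("patient_id", "responder")], by = "patient_id",
             all.x = TRUE)
  m <- merge(m, ct[, c("patient_id", "detected_baseline", "detected_d14",
                       "cdr")], by = "patient_id", all.x = TRUE)

  hr_true <- cohort$config$median_pfs_benefit /
    cohort$config$median_pfs_nonbenefit   # hazard of non-benefit vs benefit
  cox_b <- cox_univariate(m$pfs_months, m$event, !m$latent_benefit,
                          label = "no latent benefit")
  ok <- !is.na(m$responder)
  cox_r <- if (sum(ok) > 2 && length(unique(m$responder[ok])) == 2)
    cox_univariate(m$pfs_months[ok], m$event[ok], !m$responder[ok],
                   label = sprintf("PET non-response (%g%%)", cutoff_pct))
    else NULL

  det_b <- detection_rate(ct, "baseline")
  det_d <- detection_rate(ct, "d14")
  cdr_by <- split(m$cdr, m$latent_benefit)

  structure(list(
    hr_true = hr_true,
    hr_benefit_est = cox_b$hr, hr_benefit_ci = cox_b$hr_ci95,
    hr_responder_est = if (is.null(cox_r)) NA_real_ else cox_r$hr,
    detection = list(
      configured_baseline = cohort$config$ctdna_p_detect_baseline,
      observed_baseline = det_b, observed_d14 = det_d),
    cdr_summary = lapply(cdr_by, function(v)
      stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)),
    pet = pet, ctdna = ct, merged = m),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery on synthetic cohort\n")
  cat(sprintf("  hazard ratio (non-benefit vs benefit): true %.3f, Cox %.3f (95%% CI %.3f-%.3f)\n",
              x$hr_true, x$hr_benefit_est, x$hr_benefit_ci[1],
              x$hr_benefit_ci[2]))
  if (!is.na(x$hr_responder_est))
    cat(sprintf("  hazard ratio via PET non-response call: %.3f\n",
                x$hr_responder_est))
  d <- x$detection
  cat(sprintf("  ctDNA detection: baseline %d/%d (%.1f%%; configured %.1f%%), d14 %d/%d (%.1f%%)\n",
              d$observed_baseline$k, d$observed_baseline$n,
              d$observed_baseline$pct, 100 * d$configured_baseline,
              d$observed_d14$k, d$observed_d14$n, d$observed_d14$pct))
  invisible(x)
}
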