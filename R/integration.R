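# Combination of early PET metabolic response and D14 ctDNA detection, and
# predictive-value summaries for rapid progression.

#' Cross-classify patients by PET response and D14 ctDNA detection
#'
#' @param patient_id patient identifiers (unique).
#' @param pet_responder logical (or NA) metabolic-responder flags.
#' @param ctdna_detected_d14 logical (or NA) D14 detection flags.
#' @return data frame with a \code{group} factor:
#'   \code{R_and_ND}, \code{R_and_D}, \code{NR_and_ND}, \code{NR_and_D}, or
#'   \code{incomplete} when either component is missing.
#' @export
combine_biomarkers <- function(patient_id, pet_responder, ctdna_detected_d14) {
  if (anyDuplicated(patient_id))
    .fail("duplicate patient_id in combined table")
  if (length(pet_responder) != length(patient_id) ||
      length(ctdna_detected_d14) != length(patient_id))
    .fail("inputs must be aligned per patient")
  grp <- ifelse(
    is.na(pet_responder) | is.na(ctdna_detected_d14), "incomplete",
    paste0(ifelse(pet_responder, "R", "NR"), "_and_",
           ifelse(ctdna_detected_d14, "D", "ND")))
  data.frame(
    patient_id = patient_id,
    pet_responder = pet_responder,
    ctdna_detected_d14 = ctdna_detected_d14,
    group = factor(grp, levels = c("R_and_ND", "R_and_D", "NR_and_ND",
                                   "NR_and_D", "incomplete")),
    stringsAsFactors = FALSE)
}

#' Negative predictive value of an unfavorable early biomarker for rapid
#' progression
#'
#' Here "NPV" is used operationally as the probability of rapid progression
#' (progression or death before \code{horizon_months}) given an unfavorable
#' early test -- the share of test-unfavorable patients whose treatment
#' indeed fails early. Patients censored before the horizon without an
#' event have unknown 3-month status and are excluded from both numerator
#' and denominator (reported in \code{n_excluded}). The full 2x2 table of
#' test status against early progression is attached so textbook
#' sensitivity/specificity/PPV are derivable.
#'
#' @param unfavorable logical per patient: \code{TRUE} = test unfavorable
#'   (e.g. metabolic non-response, ctDNA detected); NA drops the patient.
#' @param pfs_months,event progression-free survival and event indicator
#'   (1 = progression/death observed).
#' @param horizon_months rapid-progression horizon (3 months by default).
#' @param test_name label carried into the summary.
#' @return object of class \code{predictive_summary}: list with
#'   \code{k_progressed}, \code{n_unfavorable}, \code{npv_pct} (one decimal,
#'   half away from zero), \code{n_excluded}, \code{table} and
#'   \code{test_name}.
#' @export
#' @examples
#' # 14 of 22 non-responders progress within 3 months
#' npv_early_progression(rep(TRUE, 22), c(rep(1, 14), rep(6, 8)),
#'                       rep(1, 22))
npv_early_progression <- function(unfavorable, pfs_months, event,
                                  horizon_months = 3,
                                  test_name = "unfavorable biomarker") {
  n0 <- length(unfavorable)
  if (length(pfs_months) != n0 || length(event) != n0)
    .fail("inputs must be aligned per patient")
  event <- as.logical(event)

  # 3-month status: TRUE progressed early, FALSE did not, NA unknowable
  early <- ifelse(pfs_months < horizon_months & event, TRUE,
                  ifelse(pfs_months >= horizon_months, FALSE, NA))
  known <- !is.na(unfavorable) & !is.na(early)
  n_excluded <- sum(!is.na(unfavorable) & is.na(early))

  u <- unfavorable[known]
  e <- early[known]
  n <- sum(u)
  k <- sum(u & e)
  npv <- if (n == 0L) NA_real_ else round_half_up(100 * k / n, 1)

  tab <- table(test = factor(ifelse(u, "unfavorable", "favorable"),
                             levels = c("unfavorable", "favorable")),
               progression = factor(ifelse(e, "early", "later"),
                                    levels = c("early", "later")))
  structure(list(test_name = test_name, k_progressed = k,
                 n_unfavorable = n, npv_pct = npv,
                 n_excluded = n_excluded, horizon_months = horizon_months,
                 table = tab),
            class = "predictive_summary")
}

#' @export
print.predictive_summary <- function(x, ...) {
  cat(sprintf("%s: %d / %d unfavorable patients progressed within %g months",
              x$test_name, x$k_progressed, x$n_unfavorable,
              x$horizon_months))
  cat(sprintf("  (NPV %.1f%%)\n", x$npv_pct))
  if (x$n_excluded > 0)
    cat(sprintf("  %d patient(s) censored before the horizon excluded\n",
                x$n_excluded))
  invisible(x)
}
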