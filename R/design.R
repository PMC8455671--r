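# Trial-design arithmetic: hazard ratio implied by exponential survival
# fractions at a common horizon, and the Schoenfeld required-event count
# for a log-rank test.

#' Hazard ratio implied by two exponential survival fractions
#'
#' Under exponential survival, S(t) = exp(-h t), so the hazard ratio
#' between arms with survival fractions s_experimental and s_control at a
#' common horizon is ln(s_experimental) / ln(s_control); the horizon
#' cancels and is accepted only for interface symmetry.
#'
#' @param s_control,s_experimental survival probabilities at the horizon,
#'   strictly inside (0, 1).
#' @param horizon_months unused under the exponential assumption (kept so
#'   callers can state the horizon explicitly).
#' @return hazard ratio (experimental vs control).
#' @export
#' @examples
#' exponential_hr(0.37, 0.70)  # about 0.36
exponential_hr <- function(s_control, s_experimental, horizon_months = NULL) {
  .assert_prob(s_control, "s_control")
  .assert_prob(s_experimental, "s_experimental")
  log(s_experimental) / log(s_control)
}

#' Schoenfeld required number of events for a log-rank test
#'
#' Number of events needed to detect hazard ratio \code{hr} with a
#' two-sided log-rank test:
#' \deqn{d = \lceil (z_{1-\alpha/2} + z_{power})^2 /
#'       (p (1-p) \, \ln^2 hr) \rceil}
#' where p is the fraction of patients allocated to (or expected in) one
#' arm. Symmetric in hr vs 1/hr.
#'
#' @param hr design hazard ratio (positive, not 1).
#' @param alpha_two_sided two-sided significance level.
#' @param power target power.
#' @param allocation_fraction expected fraction of patients in one arm
#'   (0.5 for balanced randomization; for a biomarker-defined split, the
#'   expected biomarker-positive fraction).
#' @return integer number of required events.
#' @export
#' @examples
#' schoenfeld_events(0.36, 0.05, 0.90, 0.59)  # 42
schoenfeld_events <- function(hr, alpha_two_sided = 0.05, power = 0.90,
                              allocation_fraction = 0.5) {
  if (!is.numeric(hr) || length(hr) != 1L || is.na(hr) || hr <= 0)
    .fail("'hr' must be a single positive number")
  if (hr == 1)
    .fail("'hr' = 1 requires infinitely many events")
  .assert_prob(alpha_two_sided, "alpha_two_sided")
  .assert_prob(power, "power")
  .assert_prob(allocation_fraction, "allocation_fraction")
  z <- stats::qnorm(1 - alpha_two_sided / 2) + stats::qnorm(power)
  p <- allocation_fraction
  as.integer(ceiling(z^2 / (p * (1 - p) * log(hr)^2)))
}
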