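# Outcome analysis layer: Kaplan-Meier medians, log-rank tests and
# univariate Cox hazard ratios for biomarker groups and clinical
# covariates. Thin, convention-pinning wrappers around the survival
# package (Efron ties, Wald CIs on the log hazard ratio).

#' Kaplan-Meier median survival
#'
#' Product-limit estimate; the median is the earliest time at which the
#' survival curve falls to 0.5 or below, \code{NA} when the curve never
#' reaches 0.5.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event observed, 0 = censored).
#' @return median survival time, or \code{NA}.
#' @export
#' @examples
#' km_median(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 1))  # 4
km_median <- function(times, events) {
  if (any(times < 0, na.rm = TRUE)) .fail("negative survival times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  hit <- fit$surv <= 0.5 + .Machine$double.eps^0.5
  if (!any(hit)) return(NA_real_)
  min(fit$time[hit])
}

#' Log-rank test between survival groups
#'
#' @param times,events as in \code{\link{km_median}}.
#' @param groups group labels (2 or more non-empty groups).
#' @return list with \code{statistic} (chi-square), \code{df}, \code{p}.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(droplevels(g)) < 2L)
    .fail("log-rank test needs at least two non-empty groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(fit$n) - 1L
  list(statistic = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards comparison
#'
#' Fits a single-covariate Cox model (Efron ties) and reports the hazard
#' ratio with a Wald 95\% confidence interval, alongside the log-rank p
#' and per-group Kaplan-Meier medians when the covariate is categorical
#' or logical. Monotone-likelihood fits (complete separation) and
#' non-convergence are flagged rather than reported as estimates.
#'
#' @param times,events as in \code{\link{km_median}}.
#' @param covariate numeric, logical or factor covariate (non-constant).
#' @param label covariate name carried into the result.
#' @param conf_level confidence level for the Wald interval.
#' @return object of class \code{group_comparison}: list with \code{hr},
#'   \code{hr_ci95} (length-2), \code{p_wald}, \code{logrank_p} and
#'   \code{median_pfs} (per group; categorical covariates only),
#'   \code{n}, \code{n_events}, \code{flag} (\code{NA} or a reason the
#'   estimate is unreliable).
#' @export
cox_univariate <- function(times, events, covariate, label = "covariate",
                           conf_level = 0.95) {
  keep <- !is.na(times) & !is.na(events) & !is.na(covariate)
  times <- times[keep]; events <- events[keep]
  covariate <- covariate[keep]
  if (length(unique(covariate)) < 2L)
    .fail("covariate is constant; hazard ratio undefined")

  categorical <- is.logical(covariate) || is.factor(covariate) ||
    is.character(covariate)
  x <- if (categorical) factor(covariate) else covariate

  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "efron"),
    warning = function(w) structure(list(msg = conditionMessage(w)),
                                    class = "cox_flagged"),
    error = function(e) structure(list(msg = conditionMessage(e)),
                                  class = "cox_flagged"))

  flag <- NA_character_
  hr <- ci <- p_wald <- NA_real_
  if (inherits(fit, "cox_flagged")) {
    flag <- fit$msg
    ci <- c(NA_real_, NA_real_)
  } else {
    beta <- fit$coefficients[1L]
    se <- sqrt(fit$var[1L, 1L])
    if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) {
      flag <- "monotone likelihood / complete separation"
      ci <- c(NA_real_, NA_real_)
    } else {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      hr <- exp(beta)
      ci <- exp(beta + c(-1, 1) * z * se)
      p_wald <- 2 * stats::pnorm(-abs(beta / se))
    }
  }

  medians <- NULL
  lr_p <- NA_real_
  if (categorical) {
    medians <- vapply(split(seq_along(times), x), function(i)
      km_median(times[i], events[i]), numeric(1))
    lr_p <- logrank_test(times, events, x)$p
  }

  structure(list(label = label, hr = unname(hr), hr_ci95 = unname(ci),
                 p_wald = unname(p_wald), logrank_p = lr_p,
                 median_pfs = medians, n = length(times),
                 n_events = sum(events), flag = flag),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!is.na(x$flag)) {
    cat(sprintf("%s: estimate flagged (%s); n = %d\n", x$label, x$flag, x$n))
    return(invisible(x))
  }
  cat(sprintf("%s: HR %.2f (95%% CI %.2f-%.2f), Wald p = %.3g",
              x$label, x$hr, x$hr_ci95[1], x$hr_ci95[2], x$p_wald))
  if (!is.na(x$logrank_p))
    cat(sprintf(", log-rank p = %.3g", x$logrank_p))
  cat(sprintf(" [n = %d, %d events]\n", x$n, x$n_events))
  if (!is.null(x$median_pfs)) {
    cat("  median PFS by group:",
        paste(sprintf("%s = %s", names(x$median_pfs),
                      ifelse(is.na(x$median_pfs), "not reached",
                             sprintf("%.1f", x$median_pfs))),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Univariate forest table over a set of covariates
#'
#' One univariate Cox comparison per covariate, with no multiplicity
#' adjustment (each row is a separate hypothesis, as in an exploratory
#' forest plot). Per-covariate failures are carried as flagged rows.
#'
#' @param data data frame containing the survival columns and covariates.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col survival column names.
#' @return data frame: one row per covariate with \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{p_wald}, \code{logrank_p}, \code{n},
#'   \code{n_events}, \code{flag}.
#' @export
forest_univariate <- function(data, covariates, time_col = "pfs_months",
                              event_col = "event") {
  if (length(covariates) == 0L)
    return(data.frame(covariate = character(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_wald = numeric(), logrank_p = numeric(),
                      n = integer(), n_events = integer(),
                      flag = character(), stringsAsFactors = FALSE))
  rows <- lapply(covariates, function(cv) {
    res <- tryCatch(
      cox_univariate(data[[time_col]], data[[event_col]], data[[cv]],
                     label = cv),
      error = function(e) list(label = cv, hr = NA_real_,
                               hr_ci95 = c(NA_real_, NA_real_),
                               p_wald = NA_real_, logrank_p = NA_real_,
                               n = NA_integer_, n_events = NA_integer_,
                               flag = conditionMessage(e)))
    data.frame(covariate = cv, hr = res$hr, ci_low = res$hr_ci95[1],
               ci_high = res$hr_ci95[2], p_wald = res$p_wald,
               logrank_p = res$logrank_p, n = res$n,
               n_events = res$n_events, flag = res$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
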