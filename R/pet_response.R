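# Patient-level metabolic response from lesion-level FDG-PET tables.
#
# Two patient-based classifications are implemented:
#   * the consistent ("dominance") method: four classes driven by whether
#     all, a load-weighted majority, a minority, or none of the lesions
#     show an SUVmax reduction beyond a cut-off, with any progression event
#     (new FDG-avid lesion or SUVmax increase) forcing class 4;
#   * PERCIST: SUVpeak of the hottest of up to 10 target lesions
#     (at most 2 per organ), metabolic response if it drops by more
#     than 30%.

#' Lesion evaluability against reference-tissue uptake
#'
#' A lesion is evaluable when its SUVmax is at least 1.5-fold the liver
#' reference uptake (SUVmean + 2 SD in a 3 cm right-lobe ROI). When the
#' liver is abnormal the blood-pool reference applies instead: uptake must
#' exceed 2.0 x (SUVmean + 2 SD) of a 1 cm ROI in the descending thoracic
#' aorta. The liver branch is inclusive (">= threshold"), the blood-pool
#' branch strict (">"), mirroring the wording of each rule.
#'
#' @param suvmax numeric vector of lesion SUVmax values.
#' @param ref reference uptake: a list or one-row data frame with
#'   \code{liver_suvmean}, \code{liver_suvsd} and, when
#'   \code{liver_abnormal} is \code{TRUE}, \code{bloodpool_suvmean},
#'   \code{bloodpool_suvsd}.
#' @return logical vector, one element per lesion.
#' @export
#' @examples
#' ref <- list(liver_suvmean = 2, liver_suvsd = 0.3, liver_abnormal = FALSE)
#' lesion_evaluable(c(4.0, 3.9, 3.8), ref)
lesion_evaluable <- function(suvmax, ref) {
  if (any(is.na(suvmax)) || any(suvmax < 0))
    .fail("'suvmax' must be non-negative and non-missing")
  abnormal <- isTRUE(as.logical(ref$liver_abnormal))
  if (abnormal) {
    if (is.null(ref$bloodpool_suvmean) || is.null(ref$bloodpool_suvsd) ||
        is.na(ref$bloodpool_suvmean) || is.na(ref$bloodpool_suvsd))
      .fail("liver is abnormal but blood-pool reference statistics are missing")
    suvmax > 2.0 * (ref$bloodpool_suvmean + 2 * ref$bloodpool_suvsd) + 1e-9
  } else {
    if (is.null(ref$liver_suvmean) || is.null(ref$liver_suvsd) ||
        is.na(ref$liver_suvmean) || is.na(ref$liver_suvsd))
      .fail("liver reference statistics are missing")
    suvmax >= 1.5 * (ref$liver_suvmean + 2 * ref$liver_suvsd) - 1e-9
  }
}

#' Quality control of a baseline / early-scan pair
#'
#' Advisory acquisition checks between the two scans of a pair. Findings do
#' not invalidate a pair; they are reported as machine-readable codes:
#' \describe{
#'   \item{activity_diff}{injected activity differs by more than 25\% of the
#'     baseline activity}
#'   \item{uptake_window_baseline / uptake_window_followup}{uptake time
#'     outside 60--70 min}
#'   \item{uptake_time_diff}{uptake times differ by more than 10 min}
#'   \item{scanner_mismatch}{scans acquired on different machines}
#'   \item{baseline_too_early}{baseline scan more than 7 days before
#'     treatment start}
#'   \item{glucose_high_baseline / glucose_high_followup}{blood glucose at or
#'     above 200 mg/dL}
#' }
#'
#' @param baseline,followup scan metadata: lists or one-row data frames with
#'   \code{injected_activity_mbq}, \code{uptake_time_min},
#'   \code{glucose_mg_dl}, \code{scanner_id},
#'   \code{days_from_treatment_start}.
#' @return data frame with columns \code{code} and \code{message}; zero rows
#'   means the pair passes all checks.
#' @export
qc_scan_pair <- function(baseline, followup) {
  findings <- list()
  flag <- function(code, msg) findings[[length(findings) + 1L]] <<-
    data.frame(code = code, message = msg, stringsAsFactors = FALSE)

  a0 <- baseline$injected_activity_mbq
  a1 <- followup$injected_activity_mbq
  if (!is.na(a0) && !is.na(a1)) {
    rel <- abs(a1 - a0) / a0 * 100
    if (rel > 25)
      flag("activity_diff",
           sprintf("injected activity differs by %.1f%% (> 25%% of baseline)", rel))
  }

  u0 <- baseline$uptake_time_min
  u1 <- followup$uptake_time_min
  if (!is.na(u0) && (u0 < 60 || u0 > 70))
    flag("uptake_window_baseline",
         sprintf("baseline uptake time %.0f min outside 60-70 min", u0))
  if (!is.na(u1) && (u1 < 60 || u1 > 70))
    flag("uptake_window_followup",
         sprintf("follow-up uptake time %.0f min outside 60-70 min", u1))
  if (!is.na(u0) && !is.na(u1) && abs(u1 - u0) > 10)
    flag("uptake_time_diff",
         sprintf("uptake times differ by %.0f min (> 10 min)", abs(u1 - u0)))

  if (!is.na(baseline$scanner_id) && !is.na(followup$scanner_id) &&
      baseline$scanner_id != followup$scanner_id)
    flag("scanner_mismatch", "baseline and follow-up acquired on different scanners")

  d0 <- baseline$days_from_treatment_start
  if (!is.na(d0) && d0 < -7)
    flag("baseline_too_early",
         sprintf("baseline scan %d days before treatment start (> 7)", -as.integer(d0)))

  if (!is.na(baseline$glucose_mg_dl) && baseline$glucose_mg_dl >= 200)
    flag("glucose_high_baseline",
         sprintf("baseline glucose %.0f mg/dL >= 200", baseline$glucose_mg_dl))
  if (!is.na(followup$glucose_mg_dl) && followup$glucose_mg_dl >= 200)
    flag("glucose_high_followup",
         sprintf("follow-up glucose %.0f mg/dL >= 200", followup$glucose_mg_dl))

  if (length(findings) == 0L)
    return(data.frame(code = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Signed percent change of a lesion SUV between two timepoints
#'
#' @param baseline_suv,followup_suv numeric vectors (recycled pairwise);
#'   baseline values must be strictly positive.
#' @return numeric vector: \code{100 * (followup - baseline) / baseline}.
#' @export
#' @examples
#' lesion_delta_pct(10, 6.9)   # -31
lesion_delta_pct <- function(baseline_suv, followup_suv) {
  if (any(is.na(baseline_suv)) || any(baseline_suv <= 0))
    .fail("baseline SUV must be strictly positive (percent change undefined at 0)")
  100 * (followup_suv - baseline_suv) / baseline_suv
}

#' Consistent ("dominance") four-class metabolic response
#'
#' Classifies a patient from matched baseline and follow-up lesions. A
#' lesion responds when its SUVmax reduction is strictly greater than
#' \code{cutoff_pct}. Classes:
#' \describe{
#'   \item{1}{all lesions respond and there is no progression event
#'     (responder)}
#'   \item{2}{mixed response with the load-weighted majority of disease
#'     responding (share > 0.5)}
#'   \item{3}{mixed response with the majority not responding (share <= 0.5)}
#'   \item{4}{progression: a new FDG-avid lesion, any SUVmax increase in a
#'     known lesion, or no responding lesion at all}
#' }
#' Load weights are baseline MATV by default, falling back to baseline
#' SUVmax when any MATV is missing, and to unweighted lesion counts when
#' all weights are zero.
#'
#' @param baseline,followup lesion data frames with columns
#'   \code{lesion_id}, \code{suvmax}, optionally \code{matv_cm3}; the
#'   follow-up table may carry \code{is_new} (logical or 0/1). Matching is
#'   by \code{lesion_id}.
#' @param cutoff_pct positive SUVmax-reduction threshold in percent
#'   (25 by default; 15 is the common sensitivity cut-off).
#' @param load_weight \code{"matv"} (default) or \code{"baseline_suvmax"}:
#'   the baseline quantity used to weight lesions when splitting mixed
#'   responses into classes 2 and 3.
#' @return an object of class \code{consist_result}: a list with
#'   \code{consist_class} (integer 1--4), \code{responder} (logical, class 1
#'   only), \code{cutoff_pct}, \code{per_lesion_delta_pct} (named numeric),
#'   \code{n_new_lesions}, \code{load_share_responding}, and
#'   \code{weighting_used}.
#' @export
#' @examples
#' b <- data.frame(lesion_id = c("L1", "L2"), suvmax = c(10, 8),
#'                 matv_cm3 = c(80, 20))
#' f <- data.frame(lesion_id = c("L1", "L2"), suvmax = c(7, 7.2),
#'                 is_new = c(FALSE, FALSE))
#' classify_consist(b, f, cutoff_pct = 25)
classify_consist <- function(baseline, followup, cutoff_pct = 25,
                             load_weight = c("matv", "baseline_suvmax")) {
  load_weight <- match.arg(load_weight)
  if (!is.numeric(cutoff_pct) || length(cutoff_pct) != 1L || cutoff_pct <= 0)
    .fail("'cutoff_pct' must be a single positive percentage")

  is_new <- if ("is_new" %in% names(followup))
    as.logical(followup$is_new) else rep(FALSE, nrow(followup))
  is_new[is.na(is_new)] <- FALSE
  n_new <- sum(is_new)

  fu <- followup[!is_new, , drop = FALSE]
  if (nrow(baseline) == 0L || nrow(fu) == 0L)
    .fail("no matched lesions between baseline and follow-up")
  matched <- intersect(baseline$lesion_id, fu$lesion_id)
  stray <- setdiff(fu$lesion_id, baseline$lesion_id)
  if (length(stray) > 0L)
    .fail("follow-up lesions not flagged as new and absent at baseline: ",
          paste(stray, collapse = ", "))
  if (length(matched) == 0L)
    .fail("no matched lesions between baseline and follow-up")

  b <- baseline[match(matched, baseline$lesion_id), , drop = FALSE]
  f <- fu[match(matched, fu$lesion_id), , drop = FALSE]
  delta <- lesion_delta_pct(b$suvmax, f$suvmax)
  names(delta) <- matched

  responds <- delta < -cutoff_pct          # strictly more than cutoff reduction
  increased <- delta > 0

  # baseline load weights for the mixed-response split
  weighting <- "unweighted"
  w <- rep(1, length(matched))
  if (load_weight == "matv" && "matv_cm3" %in% names(b) &&
      !anyNA(b$matv_cm3)) {
    w <- b$matv_cm3
    weighting <- "matv"
  } else if (!anyNA(b$suvmax)) {
    w <- b$suvmax
    weighting <- "baseline_suvmax"
  }
  if (sum(w) <= 0) {                        # degenerate weights: plain counts
    w <- rep(1, length(matched))
    weighting <- "unweighted"
  }
  share <- sum(w[responds]) / sum(w)

  cls <- if (n_new > 0L || any(increased) || !any(responds)) {
    4L
  } else if (all(responds)) {
    1L
  } else if (share > 0.5) {
    2L
  } else {
    3L
  }

  structure(list(
    consist_class = cls,
    responder = cls == 1L,
    cutoff_pct = cutoff_pct,
    per_lesion_delta_pct = delta,
    n_new_lesions = n_new,
    load_share_responding = share,
    weighting_used = weighting
  ), class = "consist_result")
}

#' @export
print.consist_result <- function(x, ...) {
  cat(sprintf("Consistent metabolic response (cut-off %g%% SUVmax reduction)\n",
              x$cutoff_pct))
  cat(sprintf("  class %d  (%s)\n", x$consist_class,
              if (x$responder) "responder" else "non-responder"))
  cat(sprintf("  lesions: %d matched, %d new; responding load share %.2f (%s weights)\n",
              length(x$per_lesion_delta_pct), x$n_new_lesions,
              x$load_share_responding, x$weighting_used))
  invisible(x)
}

#' Select PERCIST target lesions at baseline
#'
#' Candidates are baseline lesions with diameter >= 1.5 cm and evaluable
#' uptake (\code{\link{lesion_evaluable}}). Within each organ at most the 2
#' hottest by SUVpeak are kept, then at most 10 overall; ties are broken by
#' lexicographic \code{lesion_id} so selection is deterministic under input
#' permutation.
#'
#' @param lesions baseline lesion data frame with \code{lesion_id},
#'   \code{organ}, \code{suvmax}, \code{suvpeak}, \code{diameter_cm}.
#' @param ref reference uptake (see \code{\link{lesion_evaluable}}).
#' @return character vector of selected \code{lesion_id}s (possibly empty:
#'   the patient is then PERCIST-inevaluable).
#' @export
select_percist_targets <- function(lesions, ref) {
  if (nrow(lesions) == 0L) return(character())
  ok <- !is.na(lesions$diameter_cm) & lesions$diameter_cm >= 1.5 &
    !is.na(lesions$suvpeak) &
    lesion_evaluable(lesions$suvmax, ref)
  cand <- lesions[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(character())
  # deterministic: hottest SUVpeak first, ties by lesion_id
  cand <- cand[order(-cand$suvpeak, cand$lesion_id), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(cand)), cand$organ), utils::head, 2L))
  cand <- cand[sort(keep), , drop = FALSE]    # preserve hotness order
  utils::head(cand$lesion_id, 10L)
}

#' PERCIST metabolic response of a scan pair
#'
#' The hottest target SUVpeak at baseline is compared with the hottest
#' SUVpeak among the same targets at follow-up (lesion identity may differ:
#' the hottest lesion can change under treatment). Metabolic response (MR)
#' requires a decrease of strictly more than 30\%; otherwise metabolic
#' non-response (MNR).
#'
#' @param baseline,followup lesion data frames carrying \code{lesion_id} and
#'   \code{suvpeak}.
#' @param targets character vector of target lesion ids (from
#'   \code{\link{select_percist_targets}}).
#' @return an object of class \code{percist_result}: list with
#'   \code{status} ("MR"/"MNR", or NA if inevaluable),
#'   \code{target_lesion_ids}, \code{hottest_delta_pct}.
#' @export
classify_percist <- function(baseline, followup, targets) {
  if (length(targets) == 0L)
    .fail("no PERCIST target lesions supplied")
  b <- baseline[baseline$lesion_id %in% targets, , drop = FALSE]
  f <- followup[followup$lesion_id %in% targets, , drop = FALSE]
  if (nrow(b) == 0L || all(is.na(b$suvpeak)))
    .fail("targets have no baseline SUVpeak")
  if (nrow(f) == 0L || all(is.na(f$suvpeak))) {
    return(structure(list(status = NA_character_,
                          target_lesion_ids = targets,
                          hottest_delta_pct = NA_real_),
                     class = "percist_result"))
  }
  hot0 <- max(b$suvpeak, na.rm = TRUE)
  hot1 <- max(f$suvpeak, na.rm = TRUE)
  delta <- lesion_delta_pct(hot0, hot1)
  structure(list(
    status = if (delta < -30) "MR" else "MNR",
    target_lesion_ids = targets,
    hottest_delta_pct = delta
  ), class = "percist_result")
}

#' @export
print.percist_result <- function(x, ...) {
  cat(sprintf("PERCIST: %s (hottest SUVpeak change %.1f%%; %d targets)\n",
              if (is.na(x$status)) "inevaluable" else x$status,
              x$hottest_delta_pct, length(x$target_lesion_ids)))
  invisible(x)
}

#' Baseline disease burden
#'
#' Total metabolically active tumor volume and lesion count, with the
#' prognostic dichotomies MATV > 100 cm3 and more than 7 lesions.
#'
#' @param lesions baseline lesion data frame; \code{matv_cm3} may contain
#'   missing values (the total is over available values and flagged).
#' @param matv_cutoff_cm3,lesion_cutoff dichotomy thresholds (100 cm3 and 7
#'   lesions by default).
#' @return list with \code{matv_total_cm3}, \code{n_lesions},
#'   \code{high_matv}, \code{high_lesion_count}, \code{matv_incomplete}.
#' @export
disease_burden <- function(lesions, matv_cutoff_cm3 = 100, lesion_cutoff = 7) {
  if (nrow(lesions) == 0L)
    return(list(matv_total_cm3 = 0, n_lesions = 0L,
                high_matv = FALSE, high_lesion_count = FALSE,
                matv_incomplete = FALSE))
  matv <- if ("matv_cm3" %in% names(lesions)) lesions$matv_cm3 else
    rep(NA_real_, nrow(lesions))
  list(
    matv_total_cm3 = sum(matv, na.rm = TRUE),
    n_lesions = nrow(lesions),
    high_matv = sum(matv, na.rm = TRUE) > matv_cutoff_cm3,
    high_lesion_count = nrow(lesions) > lesion_cutoff,
    matv_incomplete = anyNA(matv)
  )
}

#' Cohen's kappa for two binary ratings
#'
#' Chance-corrected agreement (po - pe) / (1 - pe) between two raters,
#' e.g. metabolic response calls at two early timepoints.
#'
#' @param labels_a,labels_b vectors of equal length, coercible to factors.
#' @return kappa in [-1, 1]; \code{NA} when expected agreement is 1
#'   (both ratings constant).
#' @export
#' @examples
#' cohen_kappa(rep(c(1, 0), c(25, 25)), rep(c(1, 0, 1, 0), c(20, 5, 5, 20)))
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    .fail("rating vectors must have equal length")
  if (length(labels_a) == 0L)
    .fail("rating vectors must be non-empty")
  lev <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Patient-level PET response over a cohort
#'
#' Runs evaluability filtering, QC, consistent classification at one or
#' more cut-offs, PERCIST, and disease burden for every patient in
#' lesion/scan tables (see \code{\link{read_lesions}} for the table
#' layouts).
#'
#' @param lesions lesion table: one row per patient x timepoint x lesion.
#' @param scans scan table: one row per patient x timepoint with acquisition
#'   metadata and reference uptake statistics.
#' @param cutoffs numeric vector of SUVmax-reduction cut-offs (percent).
#' @param load_weight passed to \code{\link{classify_consist}}.
#' @param followup_timepoint which follow-up scan to classify against
#'   (default \code{"d14"}).
#' @return data frame with one row per patient x cut-off: consist class,
#'   responder flag, PERCIST status, burden summaries and QC flags. Patients
#'   without an analyzable pair (no evaluable matched lesions or missing
#'   scans) get NA classifications.
#' @export
classify_pet_cohort <- function(lesions, scans, cutoffs = c(25, 15),
                                load_weight = "matv",
                                followup_timepoint = "d14") {
  patients <- unique(lesions$patient_id)
  les_split <- split(lesions, factor(lesions$patient_id, levels = patients))
  scn_split <- split(scans, factor(scans$patient_id, levels = patients))
  rows <- lapply(patients, function(pid) {
    les <- les_split[[pid]]
    scn <- scn_split[[pid]]
    if (is.null(scn)) scn <- scans[0, , drop = FALSE]
    b_les <- les[les$timepoint == "baseline", , drop = FALSE]
    f_les <- les[les$timepoint == followup_timepoint, , drop = FALSE]
    b_scn <- scn[scn$timepoint == "baseline", , drop = FALSE]
    f_scn <- scn[scn$timepoint == followup_timepoint, , drop = FALSE]

    burden <- disease_burden(b_les)
    na_row <- function(cut) data.frame(
      patient_id = pid, cutoff_pct = cut,
      consist_class = NA_integer_, responder = NA,
      percist_status = NA_character_, hottest_delta_pct = NA_real_,
      matv_total_cm3 = burden$matv_total_cm3, n_lesions = burden$n_lesions,
      high_matv = burden$high_matv,
      high_lesion_count = burden$high_lesion_count,
      qc_flags = NA_character_, stringsAsFactors = FALSE)

    if (nrow(b_scn) == 0L || nrow(f_scn) == 0L || nrow(b_les) == 0L ||
        nrow(f_les) == 0L)
      return(do.call(rbind, lapply(cutoffs, na_row)))

    ref <- as.list(b_scn[1L, ])
    qc <- qc_scan_pair(as.list(b_scn[1L, ]), as.list(f_scn[1L, ]))
    qc_str <- if (nrow(qc)) paste(qc$code, collapse = ",") else ""

    b_eval <- b_les[lesion_evaluable(b_les$suvmax, ref), , drop = FALSE]
    is_new <- if ("is_new" %in% names(f_les)) as.logical(f_les$is_new) else
      rep(FALSE, nrow(f_les))
    is_new[is.na(is_new)] <- FALSE
    f_use <- f_les[is_new | f_les$lesion_id %in% b_eval$lesion_id, ,
                   drop = FALSE]
    matched <- intersect(b_eval$lesion_id, f_use$lesion_id)
    if (nrow(b_eval) == 0L || length(matched) == 0L) {
      out <- do.call(rbind, lapply(cutoffs, na_row))
      out$qc_flags <- qc_str
      return(out)
    }

    targets <- select_percist_targets(b_eval, ref)
    percist <- if (length(targets)) classify_percist(b_eval, f_use, targets)
      else list(status = NA_character_, hottest_delta_pct = NA_real_)

    do.call(rbind, lapply(cutoffs, function(cut) {
      cr <- classify_consist(b_eval, f_use, cutoff_pct = cut,
                             load_weight = load_weight)
      data.frame(
        patient_id = pid, cutoff_pct = cut,
        consist_class = cr$consist_class, responder = cr$responder,
        percist_status = percist$status,
        hottest_delta_pct = percist$hottest_delta_pct,
        matv_total_cm3 = burden$matv_total_cm3,
        n_lesions = burden$n_lesions,
        high_matv = burden$high_matv,
        high_lesion_count = burden$high_lesion_count,
        qc_flags = qc_str, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
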