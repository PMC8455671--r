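# Plasma ctDNA detection and longitudinal dynamics from variant-level calls.
#
# Candidate somatic variants from targeted panel sequencing are filtered on
# coverage, strand balance and consequence; a patient-timepoint is
# "detected" when at least one retained variant carries mutated copies.
# Dynamics are summarised by the circulating DNA ratio (CDR): total mutated
# copies/ml at day 14 over baseline, pooled across all mutations of a
# patient.

.VALID_CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice",
                         "silent", "intronic")
.CODING_CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice")

#' Default gene vocabulary of the ctDNA panel
#'
#' The genes named in the package's analyses; the full panel is wider and
#' the vocabulary is open (any symbol can be supplied to
#' \code{\link{gene_prevalence}} via \code{genes}).
#' @export
default_ctdna_genes <- function() {
  c("ESR1", "PIK3CA", "TP53", "AKT1", "PTEN", "ERBB2", "FGFR1")
}

#' Filter candidate somatic variants
#'
#' Retains calls with coverage strictly greater than 100, a forward-read
#' fraction within [0.10, 0.90] (strand balance), and a protein-coding
#' consequence (missense, nonsense, frameshift or splice); silent and
#' intronic changes are excluded. Each removed call is annotated with the
#' first failing rule. The filter is idempotent and order-preserving.
#'
#' @param variants variant data frame with at least \code{coverage},
#'   \code{fwd_fraction}, \code{consequence} (see
#'   \code{\link{read_variants}}).
#' @return the retained subset, with the removed calls (plus a
#'   \code{removal_reason} column) attached as attribute \code{"removed"}.
#' @export
filter_variants <- function(variants) {
  cons <- as.character(variants$consequence)
  bad <- !(cons %in% .VALID_CONSEQUENCES)
  if (any(bad))
    .fail("unknown consequence value(s): ",
          paste(unique(cons[bad]), collapse = ", "))

  reason <- rep(NA_character_, nrow(variants))
  fail_cov <- is.na(variants$coverage) | variants$coverage <= 100
  fail_strand <- is.na(variants$fwd_fraction) |
    variants$fwd_fraction < 0.10 | variants$fwd_fraction > 0.90
  fail_cons <- !(cons %in% .CODING_CONSEQUENCES)
  reason[fail_cons] <- "non_coding_consequence"
  reason[fail_strand] <- "strand_imbalance"
  reason[fail_cov] <- "low_coverage"          # first rule wins

  keep <- is.na(reason)
  removed <- variants[!keep, , drop = FALSE]
  if (nrow(removed)) removed$removal_reason <- reason[!keep]
  out <- variants[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' ctDNA detection call at one patient-timepoint
#'
#' @param calls filtered variant calls for one patient and timepoint (zero
#'   rows allowed).
#' @param sample_present was a plasma sample collected and sequenced at this
#'   timepoint?
#' @return \code{TRUE} if at least one retained call has
#'   \code{mut_copies_per_ml > 0}, \code{FALSE} if the sample exists but no
#'   such call does, \code{NA} if no sample was collected.
#' @export
ctdna_detect <- function(calls, sample_present = TRUE) {
  if (!isTRUE(sample_present)) return(NA)
  nrow(calls) > 0L && any(calls$mut_copies_per_ml > 0, na.rm = TRUE)
}

#' Circulating DNA ratio (CDR)
#'
#' Ratio of total mutated copies/ml at day 14 to baseline, pooled over all
#' retained mutations of a patient. Mutations undetected at D14 contribute
#' zero to the numerator; mutations first seen at D14 add to the numerator.
#' Defined only when ctDNA was detected at baseline (baseline sum > 0) and
#' a D14 sample exists.
#'
#' @param baseline_copies,d14_copies numeric vectors of mutated copies/ml
#'   (per mutation; need not align, sums are compared).
#' @param d14_sample_present logical; \code{FALSE} yields \code{NA}.
#' @return CDR as a non-negative number, or \code{NA} when undefined.
#' @export
#' @examples
#' compute_cdr(c(30, 70), c(5, 5))  # 0.10
compute_cdr <- function(baseline_copies, d14_copies,
                        d14_sample_present = TRUE) {
  if (!isTRUE(d14_sample_present)) return(NA_real_)
  b <- sum(baseline_copies, na.rm = TRUE)
  if (!is.finite(b) || b <= 0) return(NA_real_)
  sum(d14_copies, na.rm = TRUE) / b
}

#' Per-patient ctDNA status table
#'
#' Filters the variant table, makes a detection call per patient and
#' timepoint, and computes per-patient dynamics (CDR, maximum VAF,
#' mutation counts).
#'
#' @param variants variant table (see \code{\link{read_variants}}); may be
#'   pre-filtered or raw (the filter is idempotent).
#' @param samples data frame with \code{patient_id}, \code{timepoint}
#'   listing the plasma samples actually collected; timepoints absent for a
#'   patient yield \code{NA} status. If \code{NULL}, every patient in
#'   \code{variants} is assumed sampled at baseline and d14.
#' @param pathogenic_only if \code{TRUE}, only calls with
#'   \code{classification == "pathogenic"} count towards detection (variants
#'   of unknown significance are ignored).
#' @return data frame, one row per patient: \code{detected_baseline},
#'   \code{detected_d14} (logical or NA), \code{cdr}, \code{max_vaf_baseline},
#'   \code{max_vaf_d14}, \code{n_mut_baseline}, \code{n_mut_d14}.
#' @export
ctdna_status <- function(variants, samples = NULL, pathogenic_only = FALSE) {
  v <- filter_variants(variants)
  if (pathogenic_only)
    v <- v[v$classification == "pathogenic", , drop = FALSE]
  v <- v[v$mut_copies_per_ml > 0, , drop = FALSE]

  if (is.null(samples)) {
    pid <- unique(variants$patient_id)
    samples <- data.frame(
      patient_id = rep(pid, each = 2L),
      timepoint = rep(c("baseline", "d14"), length(pid)),
      stringsAsFactors = FALSE)
  }
  patients <- unique(samples$patient_id)

  has_sample <- function(pid, tp)
    any(samples$patient_id == pid & samples$timepoint == tp)
  calls_at <- function(pid, tp)
    v[v$patient_id == pid & v$timepoint == tp, , drop = FALSE]

  rows <- lapply(patients, function(pid) {
    b <- calls_at(pid, "baseline")
    d <- calls_at(pid, "d14")
    sb <- has_sample(pid, "baseline")
    sd14 <- has_sample(pid, "d14")
    det_b <- ctdna_detect(b, sb)
    det_d <- ctdna_detect(d, sd14)
    cdr <- if (isTRUE(det_b) && sd14)
      compute_cdr(b$mut_copies_per_ml, d$mut_copies_per_ml) else NA_real_
    data.frame(
      patient_id = pid,
      detected_baseline = det_b,
      detected_d14 = det_d,
      cdr = cdr,
      max_vaf_baseline = if (nrow(b)) max(b$vaf_pct) else
        if (sb) 0 else NA_real_,
      max_vaf_d14 = if (nrow(d)) max(d$vaf_pct) else
        if (sd14) 0 else NA_real_,
      n_mut_baseline = nrow(b),
      n_mut_d14 = nrow(d),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection rate at a timepoint
#'
#' @param statuses ctDNA status table (\code{\link{ctdna_status}}).
#' @param timepoint \code{"baseline"} or \code{"d14"}.
#' @return list with \code{k} detected, \code{n} patients with a sample, and
#'   \code{pct} = 100 k / n rounded to one decimal (half away from zero);
#'   all \code{NA} when n = 0.
#' @export
detection_rate <- function(statuses, timepoint = c("baseline", "d14")) {
  timepoint <- match.arg(timepoint)
  col <- paste0("detected_", timepoint)
  x <- statuses[[col]]
  n <- sum(!is.na(x))
  if (n == 0L) return(list(k = NA_integer_, n = 0L, pct = NA_real_))
  k <- sum(x, na.rm = TRUE)
  list(k = k, n = n, pct = round_half_up(100 * k / n, 1))
}

#' Prevalence of mutations in one gene at a timepoint
#'
#' Share of sampled patients carrying at least one retained mutation in the
#' gene.
#'
#' @param variants variant table (filtered internally).
#' @param gene gene symbol; must belong to \code{genes}.
#' @param timepoint timepoint to evaluate.
#' @param samples sample-collection table as in \code{\link{ctdna_status}};
#'   if \code{NULL}, all patients in \code{variants} are assumed sampled.
#' @param genes allowed gene vocabulary
#'   (default \code{\link{default_ctdna_genes}}).
#' @return list with \code{k}, \code{n}, \code{pct} as in
#'   \code{\link{detection_rate}}.
#' @export
gene_prevalence <- function(variants, gene, timepoint = "baseline",
                            samples = NULL,
                            genes = default_ctdna_genes()) {
  if (!gene %in% genes)
    .fail("unknown gene symbol '", gene, "' (extend 'genes' to allow it)")
  v <- filter_variants(variants)
  v <- v[v$timepoint == timepoint & v$mut_copies_per_ml > 0, , drop = FALSE]
  if (is.null(samples)) {
    pts <- unique(variants$patient_id)
  } else {
    pts <- unique(samples$patient_id[samples$timepoint == timepoint])
  }
  n <- length(pts)
  if (n == 0L) return(list(k = NA_integer_, n = 0L, pct = NA_real_))
  k <- length(unique(v$patient_id[v$gene == gene & v$patient_id %in% pts]))
  list(k = k, n = n, pct = round_half_up(100 * k / n, 1))
}

#' Dichotomize values at their median
#'
#' Median uses the midpoint-of-middle-two convention for even n; values at
#' or below the median are labelled \code{"low"} (the favorable side for
#' CDR), above it \code{"high"}. \code{NA}s keep an \code{NA} label.
#'
#' @param values numeric vector (at least one non-missing value).
#' @return list with \code{median} and \code{labels} (character vector
#'   aligned with \code{values}).
#' @export
#' @examples
#' dichotomize_at_median(c(0.02, 0.061, 0.9))
dichotomize_at_median <- function(values) {
  if (all(is.na(values))) .fail("all values are missing")
  med <- stats::median(values, na.rm = TRUE)
  labels <- ifelse(is.na(values), NA_character_,
                   ifelse(values <= med, "low", "high"))
  list(median = med, labels = labels)
}

#' VAF stratum of a patient's maximal variant allele frequency
#'
#' Default strata follow the three-level split used for outcome analysis:
#' not detected (VAF 0), detected below 20\%, and VAF >= 20\%. Detected
#' mutations with VAF below 10\% fall in the middle stratum. Strata edges
#' are configurable through \code{edges}: stratum 0 is VAF == 0, stratum k
#' (k >= 1) is [edges[k-1], edges[k]) with the last edge opening the top
#' stratum.
#'
#' @param max_vaf_pct numeric vector of per-patient maximal VAF (0 = not
#'   detected).
#' @param edges strictly increasing positive breakpoints; default 20 gives
#'   the three default strata.
#' @return integer vector of strata (0-based ordinal).
#' @export
#' @examples
#' vaf_stratum(c(0, 12, 20, 35))  # 0 1 2 2
vaf_stratum <- function(max_vaf_pct, edges = 20) {
  if (any(max_vaf_pct < 0, na.rm = TRUE))
    .fail("VAF cannot be negative")
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0))
    .fail("'edges' must be strictly increasing and positive")
  out <- rep(NA_integer_, length(max_vaf_pct))
  known <- !is.na(max_vaf_pct)
  out[known] <- 1L + findInterval(max_vaf_pct[known], edges)
  out[known & max_vaf_pct == 0] <- 0L
  out
}

#' Normalize a longitudinal trajectory to its baseline value
#'
#' @param values named numeric vector of measurements; one name must be
#'   \code{"baseline"}.
#' @return vector of the same shape divided by the baseline value (baseline
#'   maps to 1); all-\code{NA} when baseline is zero or missing.
#' @export
#' @examples
#' normalize_to_baseline(c(baseline = 20, d14 = 5, progression = 40))
normalize_to_baseline <- function(values) {
  if (!"baseline" %in% names(values))
    .fail("trajectory must contain a 'baseline' element")
  b <- values[["baseline"]]
  if (is.na(b) || b <= 0) {
    values[] <- NA_real_
    return(values)
  }
  values / b
}
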