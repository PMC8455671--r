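# Tab-delimited table readers/writers. TSV is the canonical interchange
# format: one row per lesion x timepoint, per scan, per variant call, per
# patient. Readers validate required columns and coerce 0/1 flags to
# logical; empty fields are missing values.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .fail(what, " is missing required column(s): ",
          paste(missing, collapse = ", "))
  invisible(df)
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  as.logical(as.integer(x))
}

#' Read a lesion-level PET table
#'
#' Columns: \code{patient_id}, \code{timepoint} (baseline/d14/d28/
#' progression), \code{lesion_id}, \code{organ}, \code{suvmax},
#' \code{suvpeak}, \code{diameter_cm}, \code{matv_cm3}, \code{is_new} (0/1).
#'
#' @param path TSV file path.
#' @return validated data frame.
#' @export
read_lesions <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "timepoint", "lesion_id", "organ",
                      "suvmax"), "lesion table")
  if (!"is_new" %in% names(df)) df$is_new <- FALSE
  df$is_new <- .as_flag(df$is_new)
  df$is_new[is.na(df$is_new)] <- FALSE
  if (any(df$is_new & df$timepoint == "baseline"))
    .fail("lesion table flags new lesions at baseline")
  bad <- !is.na(df$suvpeak) & !is.na(df$suvmax) & df$suvpeak > df$suvmax +
    1e-8
  if (any(bad))
    .fail("lesion table has suvpeak > suvmax for lesion(s): ",
          paste(utils::head(df$lesion_id[bad]), collapse = ", "))
  df
}

#' Read a scan-level metadata table
#'
#' Columns: \code{patient_id}, \code{timepoint},
#' \code{injected_activity_mbq}, \code{uptake_time_min},
#' \code{glucose_mg_dl}, \code{scanner_id},
#' \code{days_from_treatment_start}, \code{liver_suvmean},
#' \code{liver_suvsd}, \code{bloodpool_suvmean}, \code{bloodpool_suvsd},
#' \code{liver_abnormal} (0/1).
#'
#' @param path TSV file path.
#' @return validated data frame.
#' @export
read_scans <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "timepoint", "injected_activity_mbq",
                      "uptake_time_min", "glucose_mg_dl", "scanner_id",
                      "days_from_treatment_start", "liver_suvmean",
                      "liver_suvsd", "liver_abnormal"), "scan table")
  df$liver_abnormal <- .as_flag(df$liver_abnormal)
  if (any(df$injected_activity_mbq <= 0, na.rm = TRUE))
    .fail("scan table has non-positive injected activity")
  df
}

#' Read a variant-level ctDNA table
#'
#' Columns: \code{patient_id}, \code{timepoint}, \code{gene},
#' \code{protein_change}, \code{consequence}, \code{classification},
#' \code{vaf_pct}, \code{mut_copies_per_ml}, \code{total_copies_per_ml},
#' \code{coverage}, \code{fwd_fraction}.
#'
#' @param path TSV file path.
#' @return validated data frame.
#' @export
read_variants <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "timepoint", "gene", "consequence",
                      "vaf_pct", "mut_copies_per_ml", "coverage",
                      "fwd_fraction"), "variant table")
  if (any(df$vaf_pct < 0 | df$vaf_pct > 100, na.rm = TRUE))
    .fail("variant table has VAF outside [0, 100]")
  if ("total_copies_per_ml" %in% names(df) &&
      any(df$mut_copies_per_ml > df$total_copies_per_ml + 1e-8,
          na.rm = TRUE))
    .fail("variant table has mutated copies exceeding total copies")
  df
}

#' Read a clinical outcome table
#'
#' Requires \code{patient_id}, \code{pfs_months}, \code{event}; any further
#' columns are carried through as covariates.
#'
#' @param path TSV file path.
#' @return validated data frame.
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "pfs_months", "event"),
                "clinical table")
  if (any(df$pfs_months < 0, na.rm = TRUE))
    .fail("clinical table has negative PFS")
  df
}

#' Read a plasma sample-collection table
#'
#' Columns \code{patient_id}, \code{timepoint}: one row per plasma sample
#' actually collected (distinguishes "sample sequenced, nothing detected"
#' from "no sample").
#'
#' @param path TSV file path.
#' @return validated data frame.
#' @export
read_samples <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "timepoint"), "sample table")
  df
}

#' Write a (simulated or assembled) cohort to TSV files
#'
#' Writes \code{lesions.tsv}, \code{scans.tsv}, \code{variants.tsv},
#' \code{clinical.tsv}, \code{samples.tsv} and, when present,
#' \code{ground_truth.tsv} into \code{dir}.
#'
#' @param cohort list of data frames as returned by
#'   \code{\link{simulate_cohort}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  parts <- c("lesions", "scans", "variants", "clinical", "samples",
             "ground_truth")
  paths <- character(0)
  for (p in parts) {
    if (is.null(cohort[[p]])) next
    path <- file.path(dir, paste0(p, ".tsv"))
    utils::write.table(cohort[[p]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}
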