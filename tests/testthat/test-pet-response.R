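test_that("lesion evaluability applies the liver and blood-pool branches", {
  ref <- normal_ref(2.0, 0.3)          # liver threshold 1.5*(2+0.6) = 3.9
  expect_true(lesion_evaluable(4.0, ref))
  expect_true(lesion_evaluable(3.9, ref))     # inclusive "at least"
  expect_false(lesion_evaluable(3.89, ref))

  bp <- abnormal_liver_ref(1.5, 0.2)   # blood-pool threshold 2*(1.5+0.4) = 3.8
  expect_false(lesion_evaluable(3.8, bp))     # strict ">"
  expect_true(lesion_evaluable(3.81, bp))

  expect_error(lesion_evaluable(5, list(liver_suvmean = NA_real_,
                                        liver_suvsd = NA_real_,
                                        liver_abnormal = FALSE)),
               "liver reference")
  expect_error(lesion_evaluable(5, list(liver_abnormal = TRUE)),
               "blood-pool")
})

test_that("scan-pair QC flags each acquisition rule and only those", {
  b <- compliant_scan()
  f <- compliant_scan("d14", days = 14)
  expect_identical(nrow(qc_scan_pair(b, f)), 0L)

  # 300 -> 370 MBq is 23.3% (no flag); 300 -> 380 exceeds 25%
  f2 <- compliant_scan("d14", activity = 370, days = 14)
  expect_identical(nrow(qc_scan_pair(b, f2)), 0L)
  f3 <- compliant_scan("d14", activity = 380, days = 14)
  expect_identical(qc_scan_pair(b, f3)$code, "activity_diff")

  # uptake 60 vs 72: outside window AND >10 min apart
  b4 <- compliant_scan(uptake = 60)
  f4 <- compliant_scan("d14", uptake = 72, days = 14)
  qc <- qc_scan_pair(b4, f4)
  expect_setequal(qc$code, c("uptake_window_followup", "uptake_time_diff"))

  qc <- qc_scan_pair(compliant_scan(scanner = "A", days = -10, glucose = 200),
                     compliant_scan("d14", scanner = "B", days = 14,
                                    glucose = 210))
  expect_setequal(qc$code, c("scanner_mismatch", "baseline_too_early",
                             "glucose_high_baseline",
                             "glucose_high_followup"))
})

test_that("lesion percent change is signed and rejects zero baseline", {
  expect_equal(lesion_delta_pct(10, 6.9), -31)
  expect_equal(lesion_delta_pct(10, 10), 0)
  expect_equal(lesion_delta_pct(4, 5), 25)
  expect_equal(lesion_delta_pct(c(10, 4), c(6.9, 5)), c(-31, 25))
  expect_error(lesion_delta_pct(0, 5), "strictly positive")
})

test_that("consistent classification covers the four classes", {
  p <- lesions_from_deltas(c(-30, -40))
  r <- classify_consist(p$baseline, p$followup, cutoff_pct = 25)
  expect_identical(r$consist_class, 1L)
  expect_true(r$responder)
  expect_equal(unname(r$per_lesion_delta_pct), c(-30, -40))

  # mixed response, majority of load (MATV 80 vs 20) responds -> class 2
  p <- lesions_from_deltas(c(-30, -10), matv = c(80, 20))
  r <- classify_consist(p$baseline, p$followup, cutoff_pct = 25)
  expect_identical(r$consist_class, 2L)
  expect_false(r$responder)
  expect_identical(r$weighting_used, "matv")

  # minority of load responds -> class 3
  p <- lesions_from_deltas(c(-30, -10), matv = c(20, 80))
  expect_identical(classify_consist(p$baseline, p$followup, 25)$consist_class,
                   3L)

  # a new FDG-avid lesion forces class 4 even with responding lesions
  p <- lesions_from_deltas(c(-30, -10), new_lesion = TRUE)
  r <- classify_consist(p$baseline, p$followup, cutoff_pct = 25)
  expect_identical(r$consist_class, 4L)
  expect_identical(r$n_new_lesions, 1L)

  # any SUVmax increase is a progression event
  p <- lesions_from_deltas(c(-40, 5))
  expect_identical(classify_consist(p$baseline, p$followup, 25)$consist_class,
                   4L)

  # same deltas, different cut-off: responder at 15, class 4 at 25
  p <- lesions_from_deltas(c(-20, -18))
  expect_identical(classify_consist(p$baseline, p$followup, 15)$consist_class,
                   1L)
  expect_identical(classify_consist(p$baseline, p$followup, 25)$consist_class,
                   4L)

  # boundary: a reduction of exactly the cut-off is non-responding
  p <- lesions_from_deltas(c(-25, -25))
  expect_identical(classify_consist(p$baseline, p$followup, 25)$consist_class,
                   4L)
})

test_that("consistent classification weight fallbacks and errors behave", {
  # missing MATV -> baseline SUVmax weights
  p <- lesions_from_deltas(c(-30, -10))
  p$baseline$suvmax <- c(10, 2)        # hot lesion responds
  p$followup$suvmax <- c(7, 1.8)
  r <- classify_consist(p$baseline, p$followup, 25)
  expect_identical(r$weighting_used, "baseline_suvmax")
  expect_identical(r$consist_class, 2L)

  # all-zero MATV -> unweighted counts (share 0.5 -> class 3)
  p <- lesions_from_deltas(c(-30, -10), matv = c(0, 0))
  r <- classify_consist(p$baseline, p$followup, 25)
  expect_identical(r$weighting_used, "unweighted")
  expect_identical(r$consist_class, 3L)

  expect_error(classify_consist(p$baseline[0, ], p$followup, 25),
               "no matched lesions")
  # a non-new follow-up lesion missing from baseline is a data error
  bad <- p$followup
  bad$lesion_id[2] <- "LX"
  expect_error(classify_consist(p$baseline, bad, 25), "absent at baseline")
})

test_that("classification is invariant to lesion order and SUV rescaling", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:5, 1)
    deltas <- round(runif(n, -60, 30), 1)
    p <- lesions_from_deltas(deltas, matv = runif(n, 5, 100),
                             new_lesion = runif(1) < 0.3)
    base <- classify_consist(p$baseline, p$followup, 25)$consist_class

    perm <- sample(nrow(p$followup))
    shuffled <- classify_consist(p$baseline[sample(n), , drop = FALSE],
                                 p$followup[perm, , drop = FALSE], 25)
    expect_identical(shuffled$consist_class, base)

    k <- runif(1, 0.2, 5)
    b2 <- p$baseline; f2 <- p$followup
    b2$suvmax <- b2$suvmax * k; f2$suvmax <- f2$suvmax * k
    expect_identical(classify_consist(b2, f2, 25)$consist_class, base)
  }
})

test_that("responder status is monotone in the cut-off", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(1:5, 1)
    p <- lesions_from_deltas(round(runif(n, -60, 10), 1),
                             matv = runif(n, 5, 100))
    r25 <- classify_consist(p$baseline, p$followup, 25)$responder
    r15 <- classify_consist(p$baseline, p$followup, 15)$responder
    if (r25) expect_true(r15)
  }
})

test_that("PERCIST target selection enforces size, organ and count limits", {
  ref <- normal_ref()
  les <- data.frame(
    lesion_id = c("A", "B", "C"), organ = "liver",
    suvmax = c(9, 7, 6), suvpeak = c(8, 6, 5),
    diameter_cm = c(2, 2, 2), stringsAsFactors = FALSE)
  expect_identical(select_percist_targets(les, ref), c("A", "B"))

  les$diameter_cm <- c(2, 1.4, 2)      # size rule excludes B
  expect_identical(select_percist_targets(les, ref), c("A", "C"))

  # 12 candidates over 8 organs -> the 10 hottest
  set.seed(5)
  big <- data.frame(
    lesion_id = sprintf("L%02d", 1:12),
    organ = c(rep("liver", 2), rep("lung", 2), rep("bone", 2),
              rep("node", 2), "other", "skin", "adrenal", "spleen"),
    suvmax = 20, suvpeak = seq(19, 8, length.out = 12),
    diameter_cm = 2, stringsAsFactors = FALSE)
  got <- select_percist_targets(big, ref)
  expect_length(got, 10)
  expect_identical(got, sprintf("L%02d", 1:10))

  expect_identical(select_percist_targets(les[0, ], ref), character())
})

test_that("PERCIST selection is deterministic and never over-selects", {
  ref <- normal_ref()
  set.seed(13)
  for (i in 1:30) {
    n <- sample(1:20, 1)
    les <- data.frame(
      lesion_id = sprintf("L%02d", sample(n)),
      organ = sample(c("liver", "lung", "bone", "node", "other"), n,
                     replace = TRUE),
      suvmax = runif(n, 4, 15), stringsAsFactors = FALSE)
    les$suvpeak <- les$suvmax * 0.9
    les$diameter_cm <- runif(n, 0.8, 4)
    got <- select_percist_targets(les, ref)
    expect_lte(length(got), 10)
    organs <- les$organ[match(got, les$lesion_id)]
    if (length(got)) expect_lte(max(table(organs)), 2)
    perm <- select_percist_targets(les[sample(n), , drop = FALSE], ref)
    expect_identical(got, perm)
  }
})

test_that("PERCIST response uses the hottest SUVpeak with a strict -30% rule", {
  mk <- function(peak0, peak1) list(
    b = data.frame(lesion_id = "A", suvpeak = peak0,
                   stringsAsFactors = FALSE),
    f = data.frame(lesion_id = "A", suvpeak = peak1,
                   stringsAsFactors = FALSE))
  p <- mk(10, 6.9)
  expect_identical(classify_percist(p$b, p$f, "A")$status, "MR")
  expect_identical(classify_percist(mk(10, 7)$b, mk(10, 7)$f, "A")$status,
                   "MNR")                       # exactly -30% is not MR
  expect_identical(classify_percist(mk(10, 12)$b, mk(10, 12)$f, "A")$status,
                   "MNR")

  # hottest lesion may change identity between timepoints
  b <- data.frame(lesion_id = c("A", "B"), suvpeak = c(10, 8))
  f <- data.frame(lesion_id = c("A", "B"), suvpeak = c(2, 6.9))
  r <- classify_percist(b, f, c("A", "B"))
  expect_identical(r$status, "MR")
  expect_equal(r$hottest_delta_pct, -31)

  # all follow-up SUVpeak missing -> inevaluable, not an error
  f$suvpeak <- NA_real_
  expect_true(is.na(classify_percist(b, f, c("A", "B"))$status))
  expect_error(classify_percist(b, f, character()), "no PERCIST target")
})

test_that("disease burden sums MATV and applies the printed dichotomies", {
  les <- data.frame(lesion_id = c("A", "B"), matv_cm3 = c(60, 50))
  b <- disease_burden(les)
  expect_equal(b$matv_total_cm3, 110)
  expect_true(b$high_matv)
  expect_identical(b$n_lesions, 2L)

  les7 <- data.frame(lesion_id = sprintf("L%d", 1:7), matv_cm3 = rep(1, 7))
  expect_false(disease_burden(les7)$high_lesion_count)
  les8 <- data.frame(lesion_id = sprintf("L%d", 1:8), matv_cm3 = rep(1, 8))
  expect_true(disease_burden(les8)$high_lesion_count)

  empty <- disease_burden(les[0, ])
  expect_equal(empty$matv_total_cm3, 0)
  expect_identical(empty$n_lesions, 0L)

  les$matv_cm3[2] <- NA
  b <- disease_burden(les)
  expect_equal(b$matv_total_cm3, 60)
  expect_true(b$matv_incomplete)
})

test_that("Cohen's kappa matches hand computation and a reference", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # fully balanced 2x2 table {25, 25, 25, 25}: po = pe = 0.5 -> kappa 0
  expect_equal(cohen_kappa(rep(c(1, 1, 0, 0), c(25, 25, 25, 25)),
                           rep(c(1, 0, 1, 0), c(25, 25, 25, 25))), 0)
  # 2x2 table {20, 5, 5, 20}: po = 0.8, pe = 0.5, kappa = 0.6
  a <- rep(c(1, 1, 0, 0), c(20, 5, 5, 20))
  b <- rep(c(1, 0, 1, 0), c(20, 5, 5, 20))
  expect_equal(cohen_kappa(a, b), 0.6)
  expect_true(is.na(cohen_kappa(rep(1, 5), rep(1, 5))))  # pe = 1
  expect_error(cohen_kappa(1:3, 1:4), "equal length")

  skip_if_not_installed("e1071")
  set.seed(99)
  for (i in 1:10) {
    x <- sample(0:1, 60, replace = TRUE)
    y <- ifelse(runif(60) < 0.7, x, sample(0:1, 60, replace = TRUE))
    expect_equal(cohen_kappa(x, y),
                 e1071::classAgreement(table(x, y))$kappa)
  }
})

test_that("cohort-level PET classification assembles per-patient rows", {
  cfg <- cohort_config(n_patients = 12)
  co <- simulate_cohort(cfg, seed = 3)
  pet <- classify_pet_cohort(co$lesions, co$scans, cutoffs = c(25, 15))
  expect_identical(nrow(pet), 24L)
  expect_setequal(unique(pet$cutoff_pct), c(25, 15))
  done <- !is.na(pet$consist_class)
  expect_true(all(pet$consist_class[done] %in% 1:4))
  expect_identical(pet$responder[done], pet$consist_class[done] == 1L)
  # burden fields constant within patient
  for (pid in unique(pet$patient_id))
    expect_identical(length(unique(pet$matv_total_cm3[pet$patient_id == pid])),
                     1L)
})
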