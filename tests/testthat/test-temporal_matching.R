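test_that("unified dates are the deduplicated per-patient union", {
  cl <- tibble::tibble(patient_id = "P1", date = as.Date("2015-01-01"))
  mri <- tibble::tibble(patient_id = "P1",
                        date = as.Date(c("2015-01-10", "2015-01-01")))
  u <- unify_dates(cl, mri)
  expect_equal(u$date, as.Date(c("2015-01-01", "2015-01-10")))
  u2 <- unify_dates(cl, mri[0, ])
  expect_equal(u2$date, as.Date("2015-01-01"))
})

test_that("nearest fill honours the 15-day boundary and earlier-wins ties", {
  target <- as.Date("2015-06-01")
  inside <- tibble::tibble(date = target + 14, value = 7)
  expect_equal(nearest_fill(inside, target), 7)
  at_edge <- tibble::tibble(date = target + 15, value = 8)
  expect_equal(nearest_fill(at_edge, target), 8)
  outside <- tibble::tibble(date = target - 16, value = 9)
  expect_true(is.na(nearest_fill(outside, target)))
  tie <- tibble::tibble(date = target + c(-10, 10), value = c(3, 5))
  expect_equal(nearest_fill(tie, target), 3)
})

test_that("directional fills copy values the right way and are idempotent", {
  dates <- as.Date("2015-01-01") + c(0, 30, 60, 90)
  lesion <- tibble::tibble(date = dates, value = c(2.0, NA, NA, 3.1))
  f1 <- forward_fill_lesions(lesion)
  expect_equal(f1$value, c(2.0, 2.0, 2.0, 3.1))
  expect_equal(f1$provenance,
               c("measured", "forward_filled", "forward_filled", "measured"))
  expect_equal(forward_fill_lesions(f1), f1)
  no_back <- forward_fill_lesions(
    tibble::tibble(date = dates[1:2], value = c(NA, 1.0))
  )
  expect_true(is.na(no_back$value[1]))

  par <- tibble::tibble(date = dates[1:3], value = c(NA, NA, 980))
  b1 <- backward_fill_parenchyma(par)
  expect_equal(b1$value, c(980, 980, 980))
  expect_equal(b1$provenance,
               c("backward_filled", "backward_filled", "measured"))
  expect_equal(backward_fill_parenchyma(b1), b1)
  no_fwd <- backward_fill_parenchyma(
    tibble::tibble(date = dates[1:2], value = c(1000, NA))
  )
  expect_true(is.na(no_fwd$value[2]))
})

test_that("clinical fill uses the 9-month window with nearest-wins", {
  base <- as.Date("2015-06-01")
  series <- tibble::tibble(
    date = c(base - 8 * 30, base, base + 5 * 30),
    value = c(2.0, NA, 3.0)
  )
  # 3 months before beats 5 months after
  series2 <- tibble::tibble(date = c(base - 91, base, base + 152),
                            value = c(2.0, NA, 3.0))
  out2 <- fill_clinical(series2)
  expect_equal(out2$value[out2$date == base], 2.0)
  # beyond 9 months stays missing
  far <- tibble::tibble(date = c(base, base + 305), value = c(NA, 3.0))
  expect_true(is.na(fill_clinical(far)$value[1]))
})

test_that("match_cohort reproduces the hand-derived provenance fixture", {
  tabs <- fixture_cohort()
  matched <- match_cohort(tabs$clinical, tabs$brain_mri, tabs$cord_mri)
  expected <- fixture_expected()
  got <- dplyr::inner_join(
    expected[c("patient_id", "date", "measure")], matched,
    by = c("patient_id", "date", "measure")
  )
  expect_equal(nrow(got), nrow(expected))
  expect_equal(got$value, expected$value)
  expect_equal(got$provenance, expected$provenance)
})

test_that("a perfectly aligned cohort is matched with pure measurements", {
  cfg <- small_config(n_patients = 3, seed = 15, date_jitter_days = 0,
                      mri_interval_months = 6, cord_scan_availability = 1)
  cohort <- generate_cohort(cfg)
  matched <- match_cohort(cohort$clinical, cohort$brain_mri, cohort$cord_mri)
  mri_rows <- matched[matched$measure %in% c("juxtacortical", "mucca",
                                             "p_cereb", "high_cervical"), ]
  expect_true(all(mri_rows$provenance == "measured"))
})

test_that("matching is insensitive to input row order", {
  tabs <- fixture_cohort()
  ref <- match_cohort(tabs$clinical, tabs$brain_mri, tabs$cord_mri)
  set.seed(16)
  shuf <- match_cohort(
    tabs$clinical[sample(nrow(tabs$clinical)), ],
    tabs$brain_mri[sample(nrow(tabs$brain_mri)), ],
    tabs$cord_mri[sample(nrow(tabs$cord_mri)), ]
  )
  expect_equal(as.data.frame(ref), as.data.frame(shuf))
})

test_that("no value is invented: every fill copies a measurement", {
  cohort <- generate_cohort(small_config(n_patients = 5, seed = 17,
                                         cord_scan_availability = 0.6))
  matched <- match_cohort(cohort$clinical, cohort$brain_mri, cohort$cord_mri,
                          calibrate = FALSE)
  sources <- list(
    juxtacortical = cohort$brain_mri, p_cereb = cohort$brain_mri,
    high_cervical = cohort$cord_mri, mucca = cohort$cord_mri,
    edss = cohort$clinical
  )
  for (m in names(sources)) {
    rows <- matched[matched$measure == m & !is.na(matched$value), ]
    src <- sources[[m]]
    for (pid in unique(rows$patient_id)) {
      vals <- rows$value[rows$patient_id == pid]
      pool <- src[[m]][src$patient_id == pid]
      expect_true(all(vals %in% pool), label = paste("measure", m))
    }
  }
})

test_that("every non-missing value carries exactly one provenance flag", {
  tabs <- fixture_cohort()
  matched <- match_cohort(tabs$clinical, tabs$brain_mri, tabs$cord_mri)
  expect_true(all(matched$provenance %in% PROVENANCE_LEVELS))
  expect_true(all(is.na(matched$value) == (matched$provenance == "missing")))
})

test_that("calibrated mucca enters matching only where no cord scan exists", {
  tabs <- fixture_cohort()
  # brain-derived mucca present everywhere; P1 cord scan on 2015-12-01
  tabs$brain_mri$mucca_brain_t1 <- 1.06 * 70 - 4
  # add extra patients' pairs so the quadratic fit is anchored
  extra_b <- dplyr::bind_rows(lapply(1:4, function(i) {
    fixture_brain_row("P9", sprintf("2015-0%d-01", i), juxta = 0.1,
                      p_cereb = 1000,
                      mucca_brain_t1 = 1.06 * (60 + 5 * i) - 4)
  }))
  extra_c <- dplyr::bind_rows(lapply(1:4, function(i) {
    fixture_cord_row("P9", sprintf("2015-0%d-01", i), mucca = 60 + 5 * i)
  }))
  tabs$brain_mri <- dplyr::bind_rows(tabs$brain_mri, extra_b)
  tabs$cord_mri <- dplyr::bind_rows(tabs$cord_mri, extra_c)
  matched <- match_cohort(tabs$clinical, tabs$brain_mri, tabs$cord_mri)
  cal <- attr(matched, "mucca_calibration")
  expect_s3_class(cal, "mucca_calibration")
  # P2 had no cord scan at all: its mucca now comes from calibrated brain T1
  p2 <- matched[matched$patient_id == "P2" & matched$measure == "mucca", ]
  expect_true(all(!is.na(p2$value)))
  expect_equal(p2$value, rep(70, nrow(p2)), tolerance = 0.05)
})
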