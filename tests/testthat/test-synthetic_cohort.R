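test_that("cohort counts and phenotype split match the configuration", {
  cohort <- generate_cohort(cohort_config(n_patients = 78,
                                          frac_progressing = 0.5, seed = 7))
  expect_length(unique(cohort$clinical$patient_id), 78)
  expect_equal(sum(cohort$truth$patients$progressing), 39)
  expect_equal(sum(!cohort$truth$patients$progressing), 39)
  validate_cohort(cohort)
})

test_that("null generative process yields constant records", {
  cfg <- cohort_config(
    n_patients = 1, frac_progressing = 0,
    lesion_rate_per_year = c(cord = 0, infra = 0, cereb = 0),
    parenchyma_decline_per_year = c(cord = 0, infra = 0, cereb = 0),
    parenchyma_noise_frac = 0, edss_noise_sd = 0, seed = 3
  )
  cohort <- generate_cohort(cfg)
  lesions <- unlist(cohort$brain_mri[, c(
    "juxtacortical", "deep_white_matter", "periventricular",
    "medulla", "pons", "midbrain", "cerebellum"
  )])
  expect_true(all(lesions == 0))
  expect_true(all(unlist(cohort$cord_mri[, c("high_cervical", "low_cervical")]) == 0))
  expect_equal(length(unique(cohort$brain_mri$p_cereb)), 1)
  expect_equal(length(unique(cohort$cord_mri$mucca)), 1)
  expect_equal(length(unique(cohort$clinical$edss)), 1)
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$brain_mri, b$brain_mri)
  expect_identical(a$cord_mri, b$cord_mri)
  expect_identical(a$truth$patients, b$truth$patients)
})

test_that("generated tables round-trip through write and read", {
  cohort <- generate_cohort(small_config(n_patients = 4, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  for (tab in c("clinical", "brain_mri", "cord_mri")) {
    ord <- order(cohort[[tab]]$patient_id, cohort[[tab]]$date)
    expect_equal(as.data.frame(back[[tab]]),
                 as.data.frame(cohort[[tab]][ord, ]),
                 ignore_attr = TRUE)
  }
})

poisson_test_params <- function(cfg, rate, decline = 0, p0_cereb = 1000,
                                followup = 5) {
  list(
    config = cfg, patient_id = "T1", progressing = FALSE,
    followup_years = followup, age0 = 40, disease_duration_years = 0,
    start_date = as.Date("2012-01-01"), onset_years = NA_real_,
    lesion_rate = c(cord = rate, infra = 0, cereb = 0),
    lesion_size_mean = c(cord = 0.06, infra = 0.12, cereb = 0.35),
    parenchyma_decline = c(cord = decline, infra = decline, cereb = decline),
    p0 = c(cereb = p0_cereb, infra = 150, cord = 70),
    subcompartment_shares = list(
      cord = c(high_cervical = 0.6, low_cervical = 0.4),
      infra = c(medulla = 0.25, pons = 0.25, midbrain = 0.25,
                cerebellum = 0.25),
      cereb = c(juxtacortical = 0.3, deep_white_matter = 0.4,
                periventricular = 0.3)
    ),
    visual_base = 0
  )
}

test_that("lesion event counts follow the configured Poisson process", {
  cfg <- cohort_config(rrms_activity_multiplier = 1, date_jitter_days = 0,
                       parenchyma_noise_frac = 0)
  set.seed(101)
  total <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    traj <- generate_patient_trajectory(poisson_test_params(cfg, rate = 2))
    ev <- traj$lesion_events
    total <- total + sum(ev$compartment == "cord" & ev$time > 0)
  }
  # 200 repetitions of Poisson(2 events/yr * 5 yr): total ~ Poisson(2000).
  ci <- qpois(c(0.005, 0.995), n_rep * 2 * 5)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
})

test_that("parenchymal decline follows the closed-form geometric decay", {
  cfg <- cohort_config(rrms_activity_multiplier = 1, date_jitter_days = 0,
                       parenchyma_noise_frac = 0)
  set.seed(5)
  traj <- generate_patient_trajectory(
    poisson_test_params(cfg, rate = 0, decline = 0.01, followup = 10)
  )
  last <- nrow(traj$brain_mri)
  t_years <- as.numeric(traj$brain_mri$date[last] - as.Date("2012-01-01")) /
    365.25
  expect_equal(traj$brain_mri$p_cereb[last], 1000 * (1 - 0.01)^t_years,
               tolerance = 1e-10)
})

test_that("zero-noise EDSS is nondecreasing when only cord lesions grow", {
  cfg <- cohort_config(
    n_patients = 1, frac_progressing = 0, edss_noise_sd = 0,
    lesion_rate_per_year = c(cord = 1.5, infra = 0, cereb = 0),
    parenchyma_decline_per_year = c(cord = 0, infra = 0, cereb = 0),
    parenchyma_noise_frac = 0, rrms_activity_multiplier = 1, seed = 8
  )
  cohort <- generate_cohort(cfg)
  expect_true(all(diff(cohort$clinical$edss) >= 0))
})

test_that("EDSS is an exact affine function of the planted percentile signal", {
  cfg <- small_config(n_patients = 6, seed = 2, edss_noise_sd = 0,
                      quantize_edss = FALSE)
  cohort <- generate_cohort(cfg)
  lat <- merge(cohort$truth$latent,
               cohort$clinical[, c("patient_id", "date", "edss", "age0")],
               by = c("patient_id", "date"))
  fit <- stats::lm(edss ~ sig_cord + sig_infra + sig_cereb + age0, data = lat)
  expect_lt(max(abs(stats::residuals(fit))), 1e-8)
  co <- coef(fit)
  expect_equal(unname(co["sig_cord"] / co["sig_cereb"]), 3.8,
               tolerance = 1e-6)
  expect_equal(unname(co["sig_infra"] / co["sig_cereb"]), 2.5,
               tolerance = 1e-6)
})

test_that("cord-scan thinning follows the availability fraction", {
  cohort <- generate_cohort(small_config(n_patients = 10, seed = 4,
                                         cord_scan_availability = 1))
  n_total <- nrow(cohort$cord_mri)
  cfg_half <- small_config(n_patients = 10, cord_scan_availability = 0.5)
  kept <- numeric(30)
  set.seed(77)
  for (r in seq_len(30)) {
    thinned <- inject_missingness(cohort, cfg_half)
    kept[r] <- nrow(thinned$cord_mri)
  }
  # Keep-at-least-one guard nudges the mean only by ~n_patients * 2^-n_rows.
  expect_gt(mean(kept) / n_total, 0.42)
  expect_lt(mean(kept) / n_total, 0.58)
  per_patient <- table(inject_missingness(cohort, cfg_half)$cord_mri$patient_id)
  expect_length(per_patient, 10) # no patient loses every cord scan
})

test_that("degenerate missingness configurations are rejected or inert", {
  cohort <- generate_cohort(small_config(n_patients = 3, seed = 5,
                                         cord_scan_availability = 1))
  same <- inject_missingness(cohort, small_config(cord_scan_availability = 1))
  expect_identical(same$cord_mri, cohort$cord_mri)
  expect_error(
    inject_missingness(cohort, small_config(cord_scan_availability = 0)),
    "cord_scan_availability"
  )
})

test_that("invalid configuration fields are rejected with named messages", {
  expect_error(cohort_config(frac_progressing = 1.5), "frac_progressing")
  expect_error(cohort_config(n_patients = -2), "n_patients")
  expect_error(cohort_config(lesion_rate_per_year = c(cord = -1, infra = 1,
                                                      cereb = 1)),
               "lesion_rate_per_year")
  expect_error(cohort_config(true_weights = c(a = 1, b = 2, c = 3)),
               "true_weights")
  expect_error(cohort_config(followup_years_range = c(8, 5)),
               "followup_years_range")
})

test_that("truth sidecar serializes to JSON and back", {
  cohort <- generate_cohort(small_config(n_patients = 3, seed = 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(cohort$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$true_weights$cord, 3.8)
  expect_length(back$patients, 3)
  expect_equal(back$patients[[1]]$patient_id, "P001")
})
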