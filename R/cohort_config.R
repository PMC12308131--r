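#' Configuration of a synthetic longitudinal MS cohort
#'
#' Bundles and validates every generative parameter of the synthetic-cohort
#' module. Defaults emulate the modelling cohort the analysis was designed
#' for: 78 patients, half of whom transition from relapsing-remitting to
#' secondary progressive MS, followed for at least five years with clinical
#' visits roughly twice a year and annual MRI, with cervical cord imaging
#' available at most but not all imaging time points.
#'
#' Per-compartment vectors must be named with `cord`, `infra` and `cereb`.
#' Lesion accrual is a homogeneous Poisson process per compartment with
#' lognormal per-lesion volumes; parenchymal measures decline geometrically;
#' EDSS is an affine function of the weighted compartmental LPF percentile
#' signal plus age, observation noise, grid quantization and clipping.
#'
#' @param n_patients Number of patients.
#' @param frac_progressing Fraction of patients transitioning to SPMS.
#' @param followup_years_range Length-2 range (years) of per-patient
#'   follow-up, drawn uniformly.
#' @param clinical_visit_interval_months Spacing of clinical visits.
#' @param mri_interval_months Spacing of MRI sessions.
#' @param cord_scan_availability Probability that an MRI time point includes
#'   a cord scan; the remainder are removed by [inject_missingness()].
#' @param lesion_rate_per_year Named per-compartment Poisson rates
#'   (new lesions / year).
#' @param lesion_size_mean_ml Named per-compartment mean volume (ml) of a
#'   new lesion.
#' @param parenchyma_decline_per_year Named per-compartment fractional
#'   decline per year of the parenchymal measure (volume for cereb/infra,
#'   mucca mm2 for cord).
#' @param true_weights Named per-compartment nonnegative weights linking the
#'   latent LPF percentile signal to EDSS (cord > infra > cereb by default,
#'   at the 3.8 / 2.5 / 1 ratios used for the trajectory visualization).
#' @param edss_noise_sd SD of Gaussian EDSS observation noise (EDSS units).
#' @param date_jitter_days Uniform jitter (+/- days) applied independently
#'   to clinical and MRI schedule dates, so the two streams misalign.
#' @param n_scanners Number of scanner identities assigned to MRI rows.
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   cohort byte-for-byte.
#' @param progression_rate_multiplier Multiplier on cord and infratentorial
#'   lesion rates after SPMS onset in progressing patients.
#' @param rrms_activity_multiplier Multiplier on lesion rates during the
#'   observed relapsing-remitting phase (the whole follow-up of
#'   non-progressing patients, the pre-onset span of progressing ones):
#'   cohorts followed on therapy accrue new lesions well below their
#'   historical rate.
#' @param baseline_load_multiplier Multiplier on lesion rates during the
#'   pre-baseline disease-duration era: patients enter the study carrying
#'   the load of their early, more active (often untreated) disease, while
#'   under-observation accrual runs at the face-value rate.
#' @param progression_atrophy_multiplier Multiplier on parenchymal decline
#'   after SPMS onset in progressing patients (reserve depletion).
#' @param relapse_rate_per_year Relapse flag rate; progressing patients
#'   relapse only before their SPMS onset (progression is relapse-free).
#' @param parenchyma_noise_frac Multiplicative measurement noise SD on
#'   observed parenchymal values (fraction of the true value).
#' @param lesion_size_sdlog Lognormal sdlog of per-lesion volumes.
#' @param baseline_age_range Length-2 range (years) of age at first visit.
#' @param disease_duration_mean_years Mean pre-baseline disease duration;
#'   sets the lesion load already present at the first visit.
#' @param edss_link `"lpf"` (default) drives the latent disability signal
#'   with weighted LPF percentiles; `"pv"` drives it with weighted
#'   parenchymal-loss percentiles (100 - parenchymal percentile), to probe
#'   model-ranking behaviour under a competing generative mechanism.
#' @param quantize_edss Snap generated EDSS to the valid grid (disable to
#'   study the continuous latent signal).
#' @param edss_span EDSS units spanned by the weighted percentile signal as
#'   it runs from 0 to 100.
#' @param age_coef_per_year Latent EDSS increment per year of baseline age.
#' @param edss_intercept Latent EDSS intercept.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 78,
                          frac_progressing = 0.5,
                          followup_years_range = c(5, 10),
                          clinical_visit_interval_months = 6,
                          mri_interval_months = 12,
                          cord_scan_availability = 0.8,
                          lesion_rate_per_year = c(cord = 0.15, infra = 0.25, cereb = 0.8),
                          lesion_size_mean_ml = c(cord = 0.06, infra = 0.12, cereb = 0.35),
                          parenchyma_decline_per_year = c(cord = 0.004, infra = 0.003, cereb = 0.003),
                          true_weights = c(cord = 3.8, infra = 2.5, cereb = 1),
                          edss_noise_sd = 0.35,
                          date_jitter_days = 10L,
                          n_scanners = 3L,
                          seed = 1L,
                          progression_rate_multiplier = 8,
                          baseline_load_multiplier = 2,
                          rrms_activity_multiplier = 0.2,
                          progression_atrophy_multiplier = 2,
                          relapse_rate_per_year = 0.3,
                          parenchyma_noise_frac = 0.002,
                          lesion_size_sdlog = 0.6,
                          baseline_age_range = c(25, 55),
                          disease_duration_mean_years = 4,
                          edss_link = c("lpf", "pv"),
                          quantize_edss = TRUE,
                          edss_span = 6.5,
                          age_coef_per_year = 0.02,
                          edss_intercept = -1.2) {
  edss_link <- match.arg(edss_link)
  cfg <- list(
    n_patients = n_patients, frac_progressing = frac_progressing,
    followup_years_range = followup_years_range,
    clinical_visit_interval_months = clinical_visit_interval_months,
    mri_interval_months = mri_interval_months,
    cord_scan_availability = cord_scan_availability,
    lesion_rate_per_year = lesion_rate_per_year,
    lesion_size_mean_ml = lesion_size_mean_ml,
    parenchyma_decline_per_year = parenchyma_decline_per_year,
    true_weights = true_weights,
    edss_noise_sd = edss_noise_sd,
    date_jitter_days = as.integer(date_jitter_days),
    n_scanners = as.integer(n_scanners),
    seed = as.integer(seed),
    progression_rate_multiplier = progression_rate_multiplier,
    baseline_load_multiplier = baseline_load_multiplier,
    rrms_activity_multiplier = rrms_activity_multiplier,
    progression_atrophy_multiplier = progression_atrophy_multiplier,
    relapse_rate_per_year = relapse_rate_per_year,
    parenchyma_noise_frac = parenchyma_noise_frac,
    lesion_size_sdlog = lesion_size_sdlog,
    baseline_age_range = baseline_age_range,
    disease_duration_mean_years = disease_duration_mean_years,
    edss_link = edss_link,
    quantize_edss = isTRUE(quantize_edss),
    edss_span = edss_span,
    age_coef_per_year = age_coef_per_year,
    edss_intercept = edss_intercept
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("cohort_config: field '", field, "' ", msg, call. = FALSE)
  }
  scalar_pos <- function(field, allow_zero = FALSE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        (if (allow_zero) v < 0 else v <= 0)) {
      fail(field, if (allow_zero) "must be a nonnegative number"
           else "must be a positive number")
    }
  }
  comp_vec <- function(field, allow_zero = TRUE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 3 ||
        !setequal(names(v), COMPARTMENTS) || anyNA(v)) {
      fail(field, "must be a numeric vector named cord, infra, cereb")
    }
    if (any(if (allow_zero) v < 0 else v <= 0)) {
      fail(field, if (allow_zero) "must be nonnegative" else "must be positive")
    }
  }
  scalar_pos("n_patients")
  if (cfg$n_patients != round(cfg$n_patients)) fail("n_patients", "must be an integer")
  if (!is.numeric(cfg$frac_progressing) || length(cfg$frac_progressing) != 1 ||
      is.na(cfg$frac_progressing) ||
      cfg$frac_progressing < 0 || cfg$frac_progressing > 1) {
    fail("frac_progressing", "must be in [0, 1]")
  }
  fr <- cfg$followup_years_range
  if (!is.numeric(fr) || length(fr) != 2 || anyNA(fr) || any(fr <= 0) ||
      fr[1] > fr[2]) {
    fail("followup_years_range", "must be an increasing pair of positive years")
  }
  scalar_pos("clinical_visit_interval_months")
  scalar_pos("mri_interval_months")
  if (!is.numeric(cfg$cord_scan_availability) ||
      length(cfg$cord_scan_availability) != 1 ||
      is.na(cfg$cord_scan_availability) ||
      cfg$cord_scan_availability < 0 || cfg$cord_scan_availability > 1) {
    fail("cord_scan_availability", "must be in [0, 1]")
  }
  comp_vec("lesion_rate_per_year")
  comp_vec("lesion_size_mean_ml", allow_zero = FALSE)
  comp_vec("parenchyma_decline_per_year")
  comp_vec("true_weights")
  scalar_pos("edss_noise_sd", allow_zero = TRUE)
  scalar_pos("date_jitter_days", allow_zero = TRUE)
  scalar_pos("n_scanners")
  scalar_pos("progression_rate_multiplier")
  scalar_pos("baseline_load_multiplier")
  scalar_pos("rrms_activity_multiplier")
  scalar_pos("progression_atrophy_multiplier")
  scalar_pos("relapse_rate_per_year", allow_zero = TRUE)
  scalar_pos("parenchyma_noise_frac", allow_zero = TRUE)
  scalar_pos("lesion_size_sdlog", allow_zero = TRUE)
  ar <- cfg$baseline_age_range
  if (!is.numeric(ar) || length(ar) != 2 || anyNA(ar) || any(ar <= 0) ||
      ar[1] > ar[2]) {
    fail("baseline_age_range", "must be an increasing pair of positive years")
  }
  scalar_pos("disease_duration_mean_years", allow_zero = TRUE)
  scalar_pos("edss_span")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients (%.0f%% progressing), follow-up %g-%g years\n",
              x$n_patients, 100 * x$frac_progressing,
              x$followup_years_range[1], x$followup_years_range[2]))
  cat(sprintf("  visits every %g mo, MRI every %g mo, cord availability %.2f\n",
              x$clinical_visit_interval_months, x$mri_interval_months,
              x$cord_scan_availability))
  cat(sprintf("  true weights cord/infra/cereb = %g / %g / %g, link = %s\n",
              x$true_weights[["cord"]], x$true_weights[["infra"]],
              x$true_weights[["cereb"]], x$edss_link))
  cat(sprintf("  edss noise sd %g, quantize %s, seed %d\n",
              x$edss_noise_sd, x$quantize_edss, x$seed))
  invisible(x)
}
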