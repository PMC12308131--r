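#' Run the full LPF analysis pipeline
#'
#' Convenience wrapper chaining the stages: simulate (or accept) a cohort,
#' match clinical and MRI streams, build the percentile feature table,
#' classify phenotypes, fit and compare the EDSS-decoding models under
#' leave-one-patient-out cross-validation, and summarize the LPF model's
#' compartmental coefficients.
#'
#' @param cohort A [cohort_config()] (a cohort is generated), an
#'   [lpf_cohort][generate_cohort()], or a list of tables with `clinical`,
#'   `brain_mri`, `cord_mri`.
#' @param models Models to fit and rank (default all four).
#' @param intercept Include an intercept in every model.
#' @return List with `cohort`, `matched`, `features`, `phenotypes`,
#'   `comparison` (from [compare_models()]) and `lpf_coefficients` (from
#'   [summarize_coefficients()], `NULL` when the LPF model is not fitted).
#' @examples
#' \donttest{
#' res <- run_lpf_pipeline(cohort_config(n_patients = 10, seed = 42))
#' res$comparison$evaluation
#' }
#' @export
run_lpf_pipeline <- function(cohort, models = MODEL_NAMES, intercept = TRUE) {
  if (inherits(cohort, "cohort_config")) {
    cohort <- generate_cohort(cohort)
  }
  validate_cohort(cohort)
  matched <- match_cohort(cohort$clinical, cohort$brain_mri, cohort$cord_mri)
  features <- build_feature_table(matched, cohort$clinical)
  phenotypes <- classify_spms(cohort$clinical)
  comparison <- compare_models(features, models = models,
                               intercept = intercept)
  lpf_coefficients <- if ("LPF" %in% names(comparison$fits)) {
    summarize_coefficients(comparison$fits$LPF$coefficients, "LPF")
  } else {
    NULL
  }
  list(cohort = cohort, matched = matched, features = features,
       phenotypes = phenotypes, comparison = comparison,
       lpf_coefficients = lpf_coefficients)
}
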