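# Compartmental aggregation, mucca calibration, percentile transform and the
# lesion parenchymal fraction itself: LPF = regional T2 lesion volume /
# regional parenchymal volume, per compartment (cervical cord,
# infratentorial, cerebral hemispheres). The cord parenchymal measure is the
# mean upper cervical cord cross-sectional area (mucca, mm2); the cord LPF
# (ml / mm2) is left unnormalized because only percentiles enter the models.

#' Aggregate lesion subcompartments into the three model compartments
#'
#' `L_cord = high_cervical + low_cervical`;
#' `L_infra = medulla + pons + midbrain + cerebellum`;
#' `L_cereb = juxtacortical + deep_white_matter + periventricular`.
#' Parenchymal measures are taken from `p_cereb`, `p_infra` and `mucca`.
#' Missing cord fields leave the cord components missing, not zero.
#'
#' @param record A one-row (or multi-row) data frame with subcompartment
#'   lesion columns and optionally `p_cereb`, `p_infra`, `mucca`.
#' @return Tibble with `l_cord`, `l_infra`, `l_cereb`, `p_cord`, `p_infra`,
#'   `p_cereb`, one row per input row.
#' @export
aggregate_subcompartments <- function(record) {
  sum_cols <- function(cols) {
    present <- intersect(cols, names(record))
    if (length(present) == 0) {
      return(rep(NA_real_, nrow(record)))
    }
    m <- as.matrix(record[, present, drop = FALSE])
    if (length(present) < length(cols)) {
      rep(NA_real_, nrow(record)) # incomplete subcompartment set
    } else {
      rowSums(m) # NA if any subcompartment missing
    }
  }
  get_col <- function(col) {
    if (col %in% names(record)) record[[col]] else rep(NA_real_, nrow(record))
  }
  tibble::tibble(
    l_cord = sum_cols(CORD_SUBCOMPARTMENTS),
    l_infra = sum_cols(INFRA_SUBCOMPARTMENTS),
    l_cereb = sum_cols(CEREB_SUBCOMPARTMENTS),
    p_cord = get_col("mucca"),
    p_infra = get_col("p_infra"),
    p_cereb = get_col("p_cereb")
  )
}

#' Pair brain-T1 and cord-MRI mucca measurements
#'
#' Collects, per patient, time points at which both a brain-T1-derived mucca
#' estimate and a cord-MRI mucca measurement exist within `window_days` of
#' each other; these pairs anchor the quadratic calibration.
#'
#' @param brain_mri Brain MRI table with `mucca_brain_t1`.
#' @param cord_mri Cord MRI table with `mucca`.
#' @param window_days Maximum day gap between the paired scans.
#' @return Tibble with `brain_t1` and `cord` columns.
#' @export
mucca_pairs <- function(brain_mri, cord_mri, window_days = 15) {
  if (!"mucca_brain_t1" %in% names(brain_mri)) {
    return(tibble::tibble(brain_t1 = numeric(), cord = numeric()))
  }
  b <- brain_mri[!is.na(brain_mri$mucca_brain_t1), ]
  cc <- cord_mri[!is.na(cord_mri$mucca), ]
  if (nrow(b) == 0 || nrow(cc) == 0) {
    return(tibble::tibble(brain_t1 = numeric(), cord = numeric()))
  }
  out <- vector("list", nrow(b))
  for (j in seq_len(nrow(b))) {
    same <- cc$patient_id == b$patient_id[j]
    if (!any(same)) next
    gap <- abs(as.numeric(cc$date[same] - b$date[j]))
    if (min(gap) <= window_days) {
      k <- which(same)[which.min(gap)]
      out[[j]] <- tibble::tibble(brain_t1 = b$mucca_brain_t1[j],
                                 cord = cc$mucca[k])
    }
  }
  dplyr::bind_rows(out)
}

#' Fit the quadratic mucca calibration
#'
#' Least-squares quadratic map from brain-T1-derived mucca to cord-MRI
#' mucca: `cord ~ c0 + c1 * brain + c2 * brain^2`, fitted on time points
#' with both measurements.
#'
#' @param pairs Data frame with columns `brain_t1` and `cord` (at least 3
#'   pairs with distinct brain values).
#' @return A `mucca_calibration` list: `c0`, `c1`, `c2`, `n_pairs`,
#'   `residual_sd`, `degree`.
#' @export
fit_mucca_calibration <- function(pairs) {
  pairs <- pairs[stats::complete.cases(pairs[c("brain_t1", "cord")]), ]
  if (nrow(pairs) < 3 || length(unique(pairs$brain_t1)) < 3) {
    stop("mucca calibration needs >= 3 pairs with distinct brain values; ",
         "use calibrate_mucca() for the linear/identity fallback chain",
         call. = FALSE)
  }
  fit <- stats::lm(cord ~ brain_t1 + I(brain_t1^2), data = pairs)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("mucca calibration design is rank deficient; ",
         "use calibrate_mucca() for the linear/identity fallback chain",
         call. = FALSE)
  }
  structure(
    list(c0 = unname(co[1]), c1 = unname(co[2]), c2 = unname(co[3]),
         n_pairs = nrow(pairs),
         residual_sd = stats::sigma(fit), degree = 2L),
    class = "mucca_calibration"
  )
}

#' Fit a mucca calibration with graceful degradation
#'
#' Quadratic when at least three distinct pairs exist, otherwise linear
#' (two distinct pairs), otherwise the identity map; each fallback is
#' announced with a message.
#'
#' @inheritParams fit_mucca_calibration
#' @return A `mucca_calibration` object; `degree` records which map was
#'   fitted (2, 1 or 0).
#' @export
calibrate_mucca <- function(pairs) {
  pairs <- pairs[stats::complete.cases(pairs[c("brain_t1", "cord")]), ]
  n_distinct <- length(unique(pairs$brain_t1))
  if (nrow(pairs) >= 3 && n_distinct >= 3) {
    return(tryCatch(fit_mucca_calibration(pairs), error = function(e) {
      message("quadratic mucca calibration failed (", conditionMessage(e),
              "); falling back to linear")
      linear_mucca(pairs)
    }))
  }
  if (nrow(pairs) >= 2 && n_distinct >= 2) {
    message("fewer than 3 distinct mucca pairs; fitting linear calibration")
    return(linear_mucca(pairs))
  }
  message("insufficient mucca pairs; using identity calibration")
  structure(list(c0 = 0, c1 = 1, c2 = 0, n_pairs = nrow(pairs),
                 residual_sd = NA_real_, degree = 0L),
            class = "mucca_calibration")
}

linear_mucca <- function(pairs) {
  fit <- stats::lm(cord ~ brain_t1, data = pairs)
  co <- stats::coef(fit)
  structure(
    list(c0 = unname(co[1]), c1 = unname(co[2]), c2 = 0,
         n_pairs = nrow(pairs),
         residual_sd = stats::sigma(fit), degree = 1L),
    class = "mucca_calibration"
  )
}

#' Apply a mucca calibration to brain-T1 mucca estimates
#'
#' Returns `c0 + c1 * b + c2 * b^2`. Nonpositive results are invalid
#' measurements: they are returned as `NA` with a warning, mirroring the
#' quality-control discard of implausible values.
#'
#' @param calibration A `mucca_calibration`.
#' @param brain_t1_mucca Numeric vector of brain-derived mucca estimates.
#' @return Calibrated mucca in mm2 (`NA` where invalid).
#' @export
apply_mucca_calibration <- function(calibration, brain_t1_mucca) {
  stopifnot(inherits(calibration, "mucca_calibration"))
  b <- brain_t1_mucca
  val <- calibration$c0 + calibration$c1 * b + calibration$c2 * b^2
  invalid <- !is.na(val) & val <= 0
  if (any(invalid)) {
    warning(sum(invalid), " calibrated mucca value(s) were nonpositive and ",
            "flagged invalid", call. = FALSE)
    val[invalid] <- NA_real_
  }
  val
}

#' Lesion parenchymal fraction
#'
#' `LPF = L / P`: regional lesion volume over the regional parenchymal
#' measure. Dimensionless within the brain compartments; the cord value
#' (ml / mm2) is an internally consistent index.
#'
#' @param L Lesion volume (ml), nonnegative; `NA` propagates.
#' @param P Parenchymal measure, strictly positive.
#' @return `L / P`.
#' @export
compute_lpf <- function(L, P) {
  if (any(!is.na(P) & P <= 0)) {
    stop("parenchymal measure must be positive", call. = FALSE)
  }
  if (any(!is.na(L) & L < 0)) {
    stop("lesion volume must be nonnegative", call. = FALSE)
  }
  L / P
}

#' Percentile transform with respect to the study sample
#'
#' Hazen percentile rank, `100 * (r - 0.5) / n`, with midranks for ties,
#' computed over the non-missing values of the pooled study sample (all
#' patients, all time points). Symmetric (mean 50) and tie-stable; any
#' strictly monotone transform of the input leaves the output unchanged.
#' Missing in, missing out.
#'
#' @param values Numeric vector (at least 2 non-missing values).
#' @param method Percentile method; only `"hazen"` is implemented.
#' @return Percentiles in \[0, 100\], `NA` preserved.
#' @export
to_percentiles <- function(values, method = c("hazen")) {
  method <- match.arg(method)
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0) {
    stop("all values are missing; cannot compute percentiles", call. = FALSE)
  }
  if (n < 2) {
    stop("need at least 2 non-missing values for percentiles", call. = FALSE)
  }
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- 100 * (r - 0.5) / n
  out
}

#' Build the per-time-point modelling feature table
#'
#' From a matched cohort, aggregates lesion subcompartments into the three
#' compartments, computes raw LPF per compartment, percentile-transforms
#' lesion volumes, parenchymal measures and LPF against the pooled study
#' sample (all patients and time points), and attaches EDSS and baseline
#' age. Rows missing any required feature (EDSS, the nine percentile
#' features, age) are excluded and counted.
#'
#' @param matched Long matched table from [match_cohort()].
#' @param clinical The clinical table (source of `age0`).
#' @return Tibble with one row per complete time point: `patient_id`,
#'   `date`, `age_years`, `age0`, `edss`, raw `l_*`, `p_*`, `lpf_*` and
#'   percentile `l_pct_*`, `p_pct_*`, `lpf_pct_*` columns. Attribute
#'   `exclusions` records the number of incomplete rows and patients lost.
#' @export
build_feature_table <- function(matched, clinical) {
  wide <- matched_to_wide(matched)
  agg <- aggregate_subcompartments(wide)
  for (col in names(agg)) wide[[col]] <- agg[[col]]

  # Nonpositive parenchymal values are invalid measurements, not usable
  # denominators.
  for (pc in c("p_cord", "p_infra", "p_cereb")) {
    bad <- !is.na(wide[[pc]]) & wide[[pc]] <= 0
    if (any(bad)) wide[[pc]][bad] <- NA_real_
  }
  for (k in COMPARTMENTS) {
    wide[[paste0("lpf_", k)]] <- compute_lpf(wide[[paste0("l_", k)]],
                                             wide[[paste0("p_", k)]])
  }

  pct_safe <- function(v) {
    if (sum(!is.na(v)) < 2) rep(NA_real_, length(v)) else to_percentiles(v)
  }
  for (k in COMPARTMENTS) {
    wide[[paste0("l_pct_", k)]] <- pct_safe(wide[[paste0("l_", k)]])
    wide[[paste0("p_pct_", k)]] <- pct_safe(wide[[paste0("p_", k)]])
    wide[[paste0("lpf_pct_", k)]] <- pct_safe(wide[[paste0("lpf_", k)]])
  }

  # Age: baseline age at the first clinical visit, advanced to each matched
  # date; age0 is the age at the patient's earliest matched time point.
  base <- clinical[order(clinical$patient_id, clinical$date), ]
  base <- base[!duplicated(base$patient_id),
               c("patient_id", "date", "age0")]
  names(base) <- c("patient_id", "first_clinical_date", "age_first_clinical")
  wide <- dplyr::left_join(wide, base, by = "patient_id")
  wide$age_years <- wide$age_first_clinical +
    as.numeric(wide$date - wide$first_clinical_date) / 365.25
  first_matched <- tapply(wide$age_years, wide$patient_id, min)
  wide$age0 <- unname(first_matched[wide$patient_id])

  required <- c("edss", "age0",
                paste0("l_pct_", COMPARTMENTS),
                paste0("p_pct_", COMPARTMENTS),
                paste0("lpf_pct_", COMPARTMENTS))
  complete <- stats::complete.cases(wide[required])
  excluded <- wide[!complete, ]
  out <- wide[complete, c("patient_id", "date", "age_years", "age0", "edss",
                          paste0("l_", COMPARTMENTS),
                          paste0("p_", COMPARTMENTS),
                          paste0("lpf_", COMPARTMENTS),
                          paste0("l_pct_", COMPARTMENTS),
                          paste0("p_pct_", COMPARTMENTS),
                          paste0("lpf_pct_", COMPARTMENTS))]
  attr(out, "exclusions") <- list(
    n_rows_excluded = sum(!complete),
    n_rows_kept = sum(complete),
    patients_without_rows = setdiff(unique(wide$patient_id),
                                    unique(out$patient_id)),
    missing_by_field = colSums(is.na(excluded[required]))
  )
  out
}
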