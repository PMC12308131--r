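# Merging clinical and MRI visit streams onto unified per-patient time
# points. Stages, applied strictly in order, each seeing the previous
# stage's output once:
#   1. union of clinical and MRI dates per patient;
#   2. MRI measures copied from the nearest measurement within +/- 15 days
#      (boundary inclusive at 15 days; equidistant ties resolve to the
#      earlier measurement);
#   3. lesion volumes forward-filled (lesions, once formed, are treated as
#      permanent) and parenchymal measures back-filled (adult parenchyma
#      does not regrow);
#   4. clinical scores copied from the nearest visit within 9 months
#      (274 days) either side.
# Every filled value is a copy of a measured value of the same patient and
# measure; no interpolation is ever performed.

# Index of nearest measurement within `window` days; ties go to the earlier
# date. `meas_days` must be sorted increasing and unique.
nearest_within_idx <- function(target_days, meas_days, window) {
  n_t <- length(target_days)
  n_m <- length(meas_days)
  if (n_m == 0) {
    return(rep(NA_integer_, n_t))
  }
  pos <- findInterval(target_days, meas_days)
  d_left <- rep(Inf, n_t)
  has_left <- pos >= 1
  d_left[has_left] <- target_days[has_left] - meas_days[pos[has_left]]
  d_right <- rep(Inf, n_t)
  has_right <- pos < n_m
  d_right[has_right] <- meas_days[pos[has_right] + 1L] - target_days[has_right]
  use_left <- d_left <= d_right # tie -> earlier measurement
  idx <- ifelse(use_left, pos, pos + 1L)
  dist <- pmin(d_left, d_right)
  idx[!is.finite(dist) | dist > window] <- NA_integer_
  as.integer(idx)
}

locf_vec <- function(v) {
  src <- cummax(ifelse(!is.na(v), seq_along(v), 0L))
  fill <- src > 0L & is.na(v)
  v[fill] <- v[src[fill]]
  list(values = v, filled = fill)
}

nocb_vec <- function(v) {
  r <- locf_vec(rev(v))
  list(values = rev(r$values), filled = rev(r$filled))
}

#' Unified candidate dates per patient
#'
#' The per-patient union of clinical and MRI visit dates, deduplicated and
#' ascending.
#'
#' @param clinical Clinical visit table (needs `patient_id`, `date`).
#' @param ... Further tables with `patient_id` and `date` columns (brain
#'   and/or cord MRI); may be empty.
#' @return Tibble with `patient_id`, `date`, sorted by both.
#' @export
unify_dates <- function(clinical, ...) {
  tabs <- c(list(clinical), list(...))
  all <- dplyr::bind_rows(lapply(tabs, function(tb) {
    tibble::tibble(patient_id = tb$patient_id, date = tb$date)
  }))
  out <- dplyr::distinct(all)
  out[order(out$patient_id, out$date), ]
}

#' Fill from the nearest measurement within a day window
#'
#' For each target date, returns the value of the nearest dated measurement
#' within `window_days` days before or after (boundary inclusive);
#' equidistant ties resolve to the earlier measurement; beyond the window
#' the result is `NA`.
#'
#' @param series Tibble with `date` (Date) and `value` columns; rows with
#'   `NA` value are ignored.
#' @param target_date Date vector of dates to fill.
#' @param window_days Window half-width in days (default 15).
#' @return Numeric vector of values aligned with `target_date`.
#' @export
nearest_fill <- function(series, target_date, window_days = 15) {
  series <- series[!is.na(series$value), ]
  series <- series[order(series$date), ]
  series <- series[!duplicated(series$date), ]
  idx <- nearest_within_idx(as.numeric(target_date),
                            as.numeric(series$date), window_days)
  out <- rep(NA_real_, length(target_date))
  ok <- !is.na(idx)
  out[ok] <- series$value[idx[ok]]
  out
}

fill_series_frame <- function(series, filler, flag) {
  stopifnot(all(c("date", "value") %in% names(series)))
  ord <- order(series$date)
  v <- series$value[ord]
  prov <- if ("provenance" %in% names(series)) {
    series$provenance[ord]
  } else {
    ifelse(is.na(v), "missing", "measured")
  }
  r <- filler(v)
  prov[r$filled] <- flag
  out <- series[ord, ]
  out$value <- r$values
  out$provenance <- prov
  out
}

#' Forward-fill a lesion-volume series
#'
#' Gaps after the first measurement carry the last observed value forward
#' (lesions, once formed, are treated as permanent); nothing is filled
#' before the first measurement. Idempotent.
#'
#' @param series Tibble with `date`, `value` and optionally `provenance`.
#' @return The series date-sorted, with filled values and a `provenance`
#'   column (`forward_filled` where filling occurred).
#' @export
forward_fill_lesions <- function(series) {
  fill_series_frame(series, locf_vec, "forward_filled")
}

#' Back-fill a parenchymal series
#'
#' Gaps before a measurement carry the next observed value backwards (adult
#' parenchyma does not regrow); nothing is filled after the last
#' measurement. Idempotent.
#'
#' @inheritParams forward_fill_lesions
#' @return The series date-sorted, with filled values and a `provenance`
#'   column (`backward_filled` where filling occurred).
#' @export
backward_fill_parenchyma <- function(series) {
  fill_series_frame(series, nocb_vec, "backward_filled")
}

#' Fill clinical scores from the nearest visit within nine months
#'
#' Missing clinical values are copied from the nearest visit within
#' `max_days` (default 274 days, i.e. nine months) before or after; nearest
#' wins, equidistant ties resolve to the earlier visit.
#'
#' @inheritParams forward_fill_lesions
#' @param max_days Window half-width in days.
#' @return The series date-sorted, with filled values and a `provenance`
#'   column (`clinical_filled_9m` where filling occurred).
#' @export
fill_clinical <- function(series, max_days = CLINICAL_FILL_WINDOW_DAYS) {
  ord <- order(series$date)
  out <- series[ord, ]
  v <- out$value
  prov <- if ("provenance" %in% names(out)) {
    out$provenance
  } else {
    ifelse(is.na(v), "missing", "measured")
  }
  have <- which(!is.na(v))
  need <- which(is.na(v))
  if (length(have) && length(need)) {
    idx <- nearest_within_idx(as.numeric(out$date[need]),
                              as.numeric(out$date[have]), max_days)
    ok <- !is.na(idx)
    v[need[ok]] <- v[have[idx[ok]]]
    prov[need[ok]] <- "clinical_filled_9m"
  }
  out$value <- v
  out$provenance <- prov
  out
}

#' Match clinical and MRI streams onto unified time points
#'
#' Applies, in order: date unification, the +/- 15-day nearest fill for MRI
#' measures, forward filling of lesion volumes plus back filling of
#' parenchymal measures, and the 9-month nearest fill for clinical scores.
#' Each non-missing value carries exactly one provenance flag recording the
#' stage that produced it.
#'
#' When the brain table carries `mucca_brain_t1` and `calibrate = TRUE`, a
#' quadratic mucca calibration is fitted from time points with both brain
#' and cord MRI (see [calibrate_mucca()]) and calibrated mucca values are
#' inserted, as measurements, at brain MRI dates with no cord scan within
#' the window; nonpositive calibrated values are discarded.
#'
#' @param clinical,brain_mri,cord_mri Validated cohort tables.
#' @param window_days MRI nearest-fill window (days).
#' @param clinical_window_days Clinical fill window (days; 274 = 9 months).
#' @param calibrate Fit and apply the brain-T1 mucca calibration.
#' @return A long tibble `patient_id, date, measure, value, provenance`
#'   covering every unified date and measure. Attributes: `fill_counts`
#'   (provenance tally per measure group) and `mucca_calibration` (the
#'   fitted calibration, or `NULL`).
#' @export
match_cohort <- function(clinical, brain_mri, cord_mri,
                         window_days = 15,
                         clinical_window_days = CLINICAL_FILL_WINDOW_DAYS,
                         calibrate = TRUE) {
  if (inherits(clinical, "lpf_cohort")) {
    cohort <- clinical
    clinical <- cohort$clinical
    brain_mri <- cohort$brain_mri
    cord_mri <- cohort$cord_mri
  }

  meas <- list()
  grab <- function(tb, cols) {
    for (m in intersect(cols, names(tb))) {
      rows <- !is.na(tb[[m]])
      meas[[m]] <<- tibble::tibble(
        patient_id = tb$patient_id[rows],
        date = tb$date[rows],
        value = tb[[m]][rows]
      )
    }
  }
  grab(brain_mri, c(CEREB_SUBCOMPARTMENTS, INFRA_SUBCOMPARTMENTS,
                    "p_cereb", "p_infra"))
  grab(cord_mri, c(CORD_SUBCOMPARTMENTS, "mucca"))
  grab(clinical, CLINICAL_MEASURES)

  calibration <- NULL
  if (calibrate && "mucca_brain_t1" %in% names(brain_mri) &&
      any(!is.na(brain_mri$mucca_brain_t1))) {
    pairs <- mucca_pairs(brain_mri, cord_mri, window_days = window_days)
    if (nrow(pairs) >= 2) {
      calibration <- calibrate_mucca(pairs)
      extra <- calibrated_mucca_rows(brain_mri, meas[["mucca"]],
                                     calibration, window_days)
      if (!is.null(extra) && nrow(extra)) {
        meas[["mucca"]] <- dplyr::bind_rows(meas[["mucca"]], extra)
      }
    }
  }

  # Deterministic, input-order-insensitive patient and date ordering.
  patients <- sort(unique(c(clinical$patient_id, brain_mri$patient_id,
                            cord_mri$patient_id)))
  meas_split <- lapply(meas, function(tb) {
    tb <- tb[order(tb$patient_id, tb$date), ]
    tb <- tb[!duplicated(tb[c("patient_id", "date")]), ]
    split(tb[c("date", "value")], factor(tb$patient_id, levels = patients))
  })
  date_union <- unify_dates(clinical, brain_mri, cord_mri)
  dates_split <- split(date_union$date,
                       factor(date_union$patient_id, levels = patients))

  mri_measures <- intersect(names(meas), MRI_MEASURES)
  clin_measures <- intersect(names(meas), CLINICAL_MEASURES)
  lesion_set <- intersect(mri_measures, LESION_SUBCOMPARTMENTS)
  parenchyma_set <- intersect(mri_measures, unname(PARENCHYMA_MEASURES))

  out <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    pid <- patients[i]
    dates <- dates_split[[i]]
    nd <- length(dates)
    if (nd == 0) next
    td <- as.numeric(dates)
    vals <- list()
    provs <- list()
    for (m in c(mri_measures, clin_measures)) {
      s <- meas_split[[m]][[i]]
      md <- as.numeric(s$date)
      mv <- s$value
      v <- rep(NA_real_, nd)
      prov <- rep("missing", nd)
      if (length(md)) {
        if (m %in% mri_measures) {
          idx <- nearest_within_idx(td, md, window_days)
          ok <- !is.na(idx)
          v[ok] <- mv[idx[ok]]
          dist <- abs(td[ok] - md[idx[ok]])
          prov[ok] <- ifelse(dist == 0, "measured", "nearest_15d")
          if (m %in% lesion_set) {
            r <- locf_vec(v)
          } else {
            r <- nocb_vec(v)
          }
          v <- r$values
          prov[r$filled] <- if (m %in% lesion_set) "forward_filled" else "backward_filled"
        } else {
          idx <- nearest_within_idx(td, md, clinical_window_days)
          ok <- !is.na(idx)
          v[ok] <- mv[idx[ok]]
          dist <- abs(td[ok] - md[idx[ok]])
          prov[ok] <- ifelse(dist == 0, "measured", "clinical_filled_9m")
        }
      }
      vals[[m]] <- v
      provs[[m]] <- prov
    }
    nm <- length(vals)
    out[[i]] <- tibble::tibble(
      patient_id = pid,
      date = rep(dates, nm),
      measure = rep(names(vals), each = nd),
      value = unlist(vals, use.names = FALSE),
      provenance = unlist(provs, use.names = FALSE)
    )
  }
  matched <- dplyr::bind_rows(out)
  matched <- matched[order(matched$patient_id, matched$date,
                           matched$measure), ]
  counts <- table(
    group = ifelse(matched$measure %in% lesion_set, "lesion",
                   ifelse(matched$measure %in% parenchyma_set, "parenchyma",
                          "clinical")),
    provenance = matched$provenance
  )
  attr(matched, "fill_counts") <- counts
  attr(matched, "mucca_calibration") <- calibration
  matched
}

# Calibrated mucca pseudo-measurements at brain MRI dates lacking a cord
# scan within the matching window.
calibrated_mucca_rows <- function(brain_mri, cord_mucca, calibration,
                                  window_days) {
  cand <- brain_mri[!is.na(brain_mri$mucca_brain_t1),
                    c("patient_id", "date", "mucca_brain_t1")]
  if (nrow(cand) == 0) {
    return(NULL)
  }
  keep <- rep(TRUE, nrow(cand))
  if (!is.null(cord_mucca) && nrow(cord_mucca)) {
    for (j in seq_len(nrow(cand))) {
      near <- cord_mucca$patient_id == cand$patient_id[j] &
        abs(as.numeric(cord_mucca$date - cand$date[j])) <= window_days
      if (any(near)) keep[j] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(NULL)
  }
  val <- apply_mucca_calibration(calibration, cand$mucca_brain_t1)
  tibble::tibble(patient_id = cand$patient_id, date = cand$date,
                 value = val)[!is.na(val), ]
}

#' Pivot a matched long table to one row per time point
#'
#' @param matched Result of [match_cohort()].
#' @param provenance Also emit `prov_<measure>` columns.
#' @return Wide tibble with one row per (patient_id, date).
#' @export
matched_to_wide <- function(matched, provenance = FALSE) {
  wide <- tidyr::pivot_wider(matched[c("patient_id", "date", "measure", "value")],
                             names_from = "measure", values_from = "value")
  if (provenance) {
    pw <- tidyr::pivot_wider(
      matched[c("patient_id", "date", "measure", "provenance")],
      names_from = "measure", values_from = "provenance",
      names_prefix = "prov_"
    )
    wide <- dplyr::left_join(wide, pw, by = c("patient_id", "date"))
  }
  wide[order(wide$patient_id, wide$date), ]
}
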