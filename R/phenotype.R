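# Retrospective SPMS classification from clinical series: relapse-free,
# sustained disability progression. Two pathways:
#   (a) EDSS pathway (the majority pathway of standardized SPMS
#       definitions): a relapse-free new-maximum EDSS that exceeds 4 and
#       exceeds the baseline EDSS by the conventional step (1.0 when
#       baseline < 6, else 0.5), confirmed at the next visit at least
#       `confirm_days` later;
#   (b) FSS pathway: any functional system score rising, relapse-free and
#       confirmed, by at least two steps over its baseline.
# Progression events are *new running-maximum* visits, so the relapse veto
# is total: a relapse attributed to every strict-increase visit suppresses
# every event.

#' Is a disability increase free of relapse activity?
#'
#' `TRUE` iff no relapse falls within the attribution window around the
#' increase: `days_before` days before through `days_after` days after.
#'
#' @param increase_date Date of the disability increase.
#' @param relapse_dates Dates of relapses (may be empty).
#' @param days_before,days_after Attribution window half-widths (days).
#' @return Logical.
#' @export
relapse_free <- function(increase_date, relapse_dates,
                         days_before = 90, days_after = 30) {
  if (length(relapse_dates) == 0) {
    return(TRUE)
  }
  !any(relapse_dates >= increase_date - days_before &
         relapse_dates <= increase_date + days_after)
}

#' Classify progressing (RRMS to SPMS) versus non-progressing patients
#'
#' Applies the relapse-free sustained-progression rules (see the module
#' description above) to each patient's clinical series and dates the onset
#' of progression as the first increase in EDSS or any FSS in the absence
#' of relapse.
#'
#' @param clinical Clinical table (`patient_id`, `date`, `edss`, `fss_*`,
#'   `relapse`); a single patient or a whole cohort.
#' @param edss_step EDSS increase required over baseline; default follows
#'   convention: 1.0 when baseline EDSS < 6, else 0.5.
#' @param edss_threshold The EDSS pathway requires the confirmed EDSS to
#'   exceed this value (default 4).
#' @param fss_step FSS increase (steps) required over baseline (default 2).
#' @param fss_min_level The FSS pathway requires the confirmed score to
#'   reach this level (default 3): a two-step change landing in the mild
#'   range (0-2) is within the measurement variability of low scores and
#'   does not mark progressive worsening.
#' @param confirm_days Minimum days to the confirming visit (default 90,
#'   i.e. 3-month confirmation).
#' @param relapse_before,relapse_after Relapse attribution window (days)
#'   passed to [relapse_free()].
#' @return Tibble with one row per patient: `patient_id`, `progressing`,
#'   `onset_date`, `pathway` (`edss_gt4`, `fss_two_step` or `none`).
#' @export
classify_spms <- function(clinical, edss_step = NULL, edss_threshold = 4,
                          fss_step = 2, fss_min_level = 3,
                          confirm_days = 90,
                          relapse_before = 90, relapse_after = 30) {
  if (inherits(clinical, "lpf_cohort")) clinical <- clinical$clinical
  split_rows <- split(seq_len(nrow(clinical)), clinical$patient_id)
  out <- lapply(names(split_rows), function(pid) {
    classify_one(clinical[split_rows[[pid]], ], pid, edss_step,
                 edss_threshold, fss_step, fss_min_level, confirm_days,
                 relapse_before, relapse_after)
  })
  dplyr::bind_rows(out)
}

classify_one <- function(visits, pid, edss_step, edss_threshold, fss_step,
                         fss_min_level, confirm_days, relapse_before,
                         relapse_after) {
  visits <- visits[order(visits$date), ]
  relapse_dates <- visits$date[!is.na(visits$relapse) & visits$relapse]
  ok_edss <- !is.na(visits$edss)
  if (sum(ok_edss) < 2) {
    stop("patient ", pid, ": need at least 2 visits with EDSS", call. = FALSE)
  }
  rl_free <- function(d) {
    relapse_free(d, relapse_dates, relapse_before, relapse_after)
  }

  # Confirmed relapse-free new-maximum events on a score series.
  confirmed_event <- function(dates, values, needed, also_above = -Inf) {
    run_max <- cummax(c(-Inf, values))[seq_along(values)]
    for (i in seq_along(values)[-1]) {
      v <- values[i]
      if (v <= run_max[i] || v < needed || v <= also_above) next
      if (!rl_free(dates[i])) next
      later <- which(dates >= dates[i] + confirm_days)
      if (length(later) == 0) next
      j <- later[1]
      if (values[j] >= needed && values[j] > also_above) {
        return(i)
      }
    }
    NA_integer_
  }

  ed <- visits$edss[ok_edss]
  ed_dates <- visits$date[ok_edss]
  baseline <- ed[1]
  step <- edss_step %||% (if (baseline < 6) 1.0 else 0.5)
  edss_event <- confirmed_event(ed_dates, ed, needed = baseline + step,
                                also_above = edss_threshold)

  fss_event <- NA_integer_
  fss_event_date <- as.Date(NA)
  for (col in intersect(FSS_COLUMNS, names(visits))) {
    ok <- !is.na(visits[[col]])
    if (sum(ok) < 2) next
    fv <- visits[[col]][ok]
    fd <- visits$date[ok]
    ev <- confirmed_event(fd, fv,
                          needed = max(fv[1] + fss_step, fss_min_level))
    if (!is.na(ev) && (is.na(fss_event) || fd[ev] < fss_event_date)) {
      fss_event <- ev
      fss_event_date <- fd[ev]
    }
  }

  progressing <- !is.na(edss_event) || !is.na(fss_event)
  pathway <- if (!is.na(edss_event)) {
    "edss_gt4"
  } else if (!is.na(fss_event)) {
    "fss_two_step"
  } else {
    "none"
  }

  onset <- as.Date(NA)
  if (progressing) {
    onset <- first_relapse_free_increase(visits, rl_free)
    if (is.na(onset)) {
      onset <- if (!is.na(edss_event)) ed_dates[edss_event] else fss_event_date
    }
  }
  tibble::tibble(patient_id = pid, progressing = progressing,
                 onset_date = onset, pathway = pathway)
}

# Date of the first increase in EDSS or any FSS, in the absence of relapse.
first_relapse_free_increase <- function(visits, rl_free) {
  score_cols <- c("edss", intersect(FSS_COLUMNS, names(visits)))
  candidates <- as.Date(character())
  for (col in score_cols) {
    ok <- !is.na(visits[[col]])
    if (sum(ok) < 2) next
    v <- visits[[col]][ok]
    d <- visits$date[ok]
    up <- which(diff(v) > 0) + 1L
    for (i in up) {
      if (rl_free(d[i])) {
        candidates <- c(candidates, d[i])
        break
      }
    }
  }
  if (length(candidates)) min(candidates) else as.Date(NA)
}
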