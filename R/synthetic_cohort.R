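#' Generate a synthetic longitudinal MS cohort
#'
#' Simulates clinical and MRI visit tables with the statistical structure the
#' LPF analysis assumes: per-patient visit schedules with jittered dates,
#' punctate (stepwise, permanent) lesion accrual per subcompartment,
#' geometrically declining parenchymal measures, EDSS/FSS trajectories driven
#' by a latent weighted compartmental signal, progressing versus
#' non-progressing phenotypes, and missing cervical cord scans.
#'
#' The latent disability signal at each clinical visit is
#' `intercept + K * age0 + edss_span * sum(w_k * sig_k) / (100 * sum(w_k))`,
#' where `sig_k` is the percentile (within the generated cohort, pooled over
#' all patients and visits) of the true compartmental LPF (`edss_link =
#' "lpf"`) or of parenchymal loss (`edss_link = "pv"`). Observed EDSS adds
#' Gaussian noise, clips to \[0, 10\] and snaps to the EDSS grid. Functional
#' system scores are assigned from the compartment shares of the latent
#' signal: pyramidal/sensory/bowel-bladder follow the cord term,
#' brainstem/cerebellar the infratentorial term, mental the cerebral term;
#' the visual score has no MRI correlate and is a stable per-patient value.
#'
#' @param config A [cohort_config()].
#' @return An object of class `lpf_cohort`: a list with tibbles `clinical`,
#'   `brain_mri`, `cord_mri` (the on-disk schema of [write_cohort()]) and
#'   `truth`, a `cohort_truth` list holding per-patient phenotype labels and
#'   onset dates, the per-visit latent signal, and the generative link.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 4, seed = 1))
#' names(cohort)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config object", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_patients
  n_prog <- round(n * config$frac_progressing)
  progressing <- rep(c(TRUE, FALSE), c(n_prog, n - n_prog))
  ids <- sprintf("P%03d", seq_len(n))

  pats <- vector("list", n)
  for (i in seq_len(n)) {
    params <- draw_patient_params(config, ids[i], progressing[i])
    pats[[i]] <- generate_patient_trajectory(params)
  }

  clinical <- dplyr::bind_rows(lapply(pats, `[[`, "clinical"))
  brain_mri <- dplyr::bind_rows(lapply(pats, `[[`, "brain_mri"))
  cord_mri <- dplyr::bind_rows(lapply(pats, `[[`, "cord_mri"))
  latent <- dplyr::bind_rows(lapply(pats, `[[`, "latent"))

  # Pooled percentile signal over all patients and clinical visits.
  sig <- latent_signal(latent, config$edss_link)
  w <- config$true_weights
  wsum <- sum(w)
  contrib <- config$edss_span *
    (w[["cord"]] * sig$cord + w[["infra"]] * sig$infra +
       w[["cereb"]] * sig$cereb) / (100 * wsum)
  edss_latent <- config$edss_intercept +
    config$age_coef_per_year * latent$age0 + contrib

  noise <- if (config$edss_noise_sd > 0) {
    stats::rnorm(length(edss_latent), 0, config$edss_noise_sd)
  } else {
    0
  }
  edss_obs <- pmin(pmax(edss_latent + noise, 0), 10)
  if (config$quantize_edss) edss_obs <- snap_edss(edss_obs)

  fss <- assign_fss(edss_obs, sig, w, latent$visual_base)
  clinical$edss <- edss_obs
  for (col in FSS_COLUMNS) clinical[[col]] <- fss[[col]]
  clinical$ambulation_affected <- edss_obs >= 4.5
  clinical <- clinical[, c("patient_id", "date", "age0", "edss", FSS_COLUMNS,
                           "ambulation_affected", "relapse")]

  tables <- list(clinical = clinical, brain_mri = brain_mri,
                 cord_mri = cord_mri)
  if (config$cord_scan_availability < 1) {
    tables <- inject_missingness(tables, config)
  }

  truth <- structure(
    list(
      patients = dplyr::bind_rows(lapply(pats, `[[`, "truth")),
      latent = tibble::tibble(
        patient_id = latent$patient_id,
        date = latent$date,
        edss_latent = edss_latent,
        sig_cord = sig$cord,
        sig_infra = sig$infra,
        sig_cereb = sig$cereb
      ),
      true_weights = w,
      edss_link = config$edss_link,
      coef_per_percentile = config$edss_span * w / (100 * wsum),
      age_coef_per_year = config$age_coef_per_year,
      edss_intercept = config$edss_intercept
    ),
    class = "cohort_truth"
  )

  structure(
    list(clinical = tables$clinical, brain_mri = tables$brain_mri,
         cord_mri = tables$cord_mri, truth = truth, config = config),
    class = "lpf_cohort"
  )
}

# Percentile signal per compartment, pooled over all patients and visits.
latent_signal <- function(latent, edss_link) {
  one <- function(k) {
    if (edss_link == "lpf") {
      vals <- latent[[paste0("lpf_", k)]]
    } else {
      vals <- latent[[paste0("p_true_", k)]]
    }
    if (length(vals) < 2 || all(vals == vals[1])) {
      pct <- rep(50, length(vals))
    } else {
      pct <- to_percentiles(vals)
    }
    if (edss_link == "pv") 100 - pct else pct
  }
  list(cord = one("cord"), infra = one("infra"), cereb = one("cereb"))
}

# Deterministic FSS assignment from quantized EDSS and compartment shares.
assign_fss <- function(edss, sig, w, visual_base) {
  denom <- w[["cord"]] * sig$cord + w[["infra"]] * sig$infra +
    w[["cereb"]] * sig$cereb
  share <- function(k) {
    s <- ifelse(denom > 0, w[[k]] * sig[[k]] / denom, 0)
    s
  }
  s_cord <- share("cord")
  s_infra <- share("infra")
  s_cereb <- share("cereb")
  # The leading system of the dominant compartment tracks disability nearly
  # one-to-one (an EDSS built on a single functional system needs that
  # system's score close to the EDSS level); secondary systems lag.
  list(
    fss_pyramidal = pmin(FSS_MAX[["fss_pyramidal"]], round(edss * s_cord * 1.7)),
    fss_sensory = pmin(FSS_MAX[["fss_sensory"]], round(edss * s_cord * 1.2)),
    fss_bowel_bladder = pmin(FSS_MAX[["fss_bowel_bladder"]], round(edss * s_cord * 0.8)),
    fss_cerebellar = pmin(FSS_MAX[["fss_cerebellar"]], round(edss * s_infra * 1.7)),
    fss_brainstem = pmin(FSS_MAX[["fss_brainstem"]], round(edss * s_infra * 1.2)),
    fss_mental = pmin(FSS_MAX[["fss_mental"]], round(edss * s_cereb * 1.4)),
    fss_visual = pmin(FSS_MAX[["fss_visual"]], visual_base)
  )
}

# Draw per-patient generative parameters from the cohort config.
draw_patient_params <- function(config, patient_id, progressing) {
  fr <- config$followup_years_range
  followup_years <- stats::runif(1, fr[1], fr[2])
  age0 <- stats::runif(1, config$baseline_age_range[1],
                       config$baseline_age_range[2])
  duration <- stats::rgamma(1, shape = 3,
                            scale = config$disease_duration_mean_years / 3)
  window_start <- as.Date("2011-01-01")
  window_end <- as.Date("2019-12-31")
  slack <- max(1, as.numeric(window_end - window_start) -
                 followup_years * 365.25)
  start_date <- window_start + round(stats::runif(1, 0, slack))
  onset_years <- if (progressing) {
    stats::runif(1, 0.2, 0.5) * followup_years
  } else {
    NA_real_
  }
  decline_mult <- stats::runif(1, 0.6, 1.4)
  shares <- lapply(SUBCOMPARTMENTS_OF, function(subs) {
    g <- stats::rgamma(length(subs), shape = 2)
    stats::setNames(g / sum(g), subs)
  })
  p0 <- c(
    cereb = max(800, stats::rnorm(1, 1150, 60)),
    infra = max(100, stats::rnorm(1, 160, 10)),
    cord = max(50, stats::rnorm(1, 72, 6))
  )
  visual_base <- sample(0:2, 1, prob = c(0.7, 0.2, 0.1))
  list(
    config = config,
    patient_id = patient_id,
    progressing = progressing,
    followup_years = followup_years,
    age0 = age0,
    disease_duration_years = duration,
    start_date = start_date,
    onset_years = onset_years,
    lesion_rate = config$lesion_rate_per_year,
    lesion_size_mean = config$lesion_size_mean_ml,
    parenchyma_decline = config$parenchyma_decline_per_year * decline_mult,
    p0 = p0,
    subcompartment_shares = shares,
    visual_base = visual_base
  )
}

#' Generate one patient's visit and MRI records
#'
#' Draws, from the current RNG stream, the clinical and MRI schedules, the
#' compartmental lesion event process, the parenchymal decline curves and the
#' observed MRI records for a single patient. Lesion volumes are
#' nondecreasing step functions of scan date (new-lesion events only add
#' volume); parenchymal series are nonincreasing up to the configured
#' measurement noise. EDSS/FSS columns are left empty: they are filled at
#' cohort level by [generate_cohort()], which needs the pooled percentile
#' signal.
#'
#' @param params A per-patient parameter list as built internally by
#'   [generate_cohort()]; the elements used here are `config`, `patient_id`,
#'   `progressing`, `followup_years`, `age0`, `disease_duration_years`,
#'   `start_date`, `onset_years`, `lesion_rate`, `lesion_size_mean`,
#'   `parenchyma_decline`, `p0`, `subcompartment_shares` and `visual_base`.
#' @return A list with `clinical` (skeleton rows), `brain_mri`, `cord_mri`,
#'   `latent` (true per-visit LPF and parenchymal values), `lesion_events`
#'   (tibble of compartment, time in years, volume) and `truth` (one-row
#'   patient summary).
#' @export
generate_patient_trajectory <- function(params) {
  cfg <- params$config
  fy <- params$followup_years
  jit <- cfg$date_jitter_days

  jitter_days <- function(nn) {
    if (jit > 0) round(stats::runif(nn, -jit, jit)) else rep(0, nn)
  }
  clin_t <- seq(0, fy, by = cfg$clinical_visit_interval_months / 12)
  mri_t <- seq(0, fy, by = cfg$mri_interval_months / 12)
  clin_dates <- sort(unique(params$start_date + round(clin_t * 365.25) +
                              jitter_days(length(clin_t))))
  mri_dates <- sort(unique(params$start_date + round(mri_t * 365.25) +
                             jitter_days(length(mri_t))))
  t_clin <- as.numeric(clin_dates - params$start_date) / 365.25
  t_mri <- as.numeric(mri_dates - params$start_date) / 365.25

  onset <- if (params$progressing) params$onset_years else Inf

  # Lesion events: pre-baseline load plus a (piecewise-homogeneous) Poisson
  # process during follow-up; rates for cord and infratentorium jump at SPMS
  # onset in progressing patients.
  draw_events <- function(k) {
    rate <- params$lesion_rate[[k]]
    mult <- if (k %in% c("cord", "infra")) cfg$progression_rate_multiplier else 1
    rln <- function(nn) {
      mu <- log(params$lesion_size_mean[[k]]) - cfg$lesion_size_sdlog^2 / 2
      stats::rlnorm(nn, meanlog = mu, sdlog = cfg$lesion_size_sdlog)
    }
    n0 <- stats::rpois(1, rate * cfg$baseline_load_multiplier *
                         params$disease_duration_years)
    pre <- if (n0 > 0) {
      # Pre-baseline disease-duration load; predates every visit (visit
      # dates can fall slightly before t = 0 through date jitter).
      tibble::tibble(time = rep(-params$disease_duration_years, n0),
                     volume = rln(n0))
    } else {
      tibble::tibble(time = numeric(), volume = numeric())
    }
    seg <- function(r, t_from, t_to) {
      span <- max(0, t_to - t_from)
      nn <- if (r * span > 0) stats::rpois(1, r * span) else 0L
      if (nn > 0) {
        tibble::tibble(time = sort(stats::runif(nn, t_from, t_to)),
                       volume = rln(nn))
      } else {
        tibble::tibble(time = numeric(), volume = numeric())
      }
    }
    ev <- dplyr::bind_rows(
      pre,
      seg(rate * cfg$rrms_activity_multiplier, 0, min(onset, fy)),
      if (is.finite(onset) && onset < fy) seg(rate * mult, onset, fy)
    )
    ev$compartment <- k
    ev[order(ev$time), c("compartment", "time", "volume")]
  }
  events <- lapply(stats::setNames(COMPARTMENTS, COMPARTMENTS), draw_events)

  cum_lesion <- function(k, tt) {
    ev <- events[[k]]
    vapply(tt, function(t1) sum(ev$volume[ev$time <= t1]), numeric(1))
  }

  # True parenchymal value: geometric decline, accelerated after onset.
  p_true <- function(k, tt) {
    r <- params$parenchyma_decline[[k]]
    am <- if (params$progressing) cfg$progression_atrophy_multiplier else 1
    r2 <- min(r * am, 0.5)
    t_pre <- pmin(tt, onset)
    t_post <- pmax(0, tt - onset)
    t_post[!is.finite(t_post)] <- 0
    params$p0[[k]] * exp(t_pre * log(1 - r) + t_post * log(1 - r2))
  }
  observe <- function(x) {
    if (cfg$parenchyma_noise_frac > 0) {
      x * (1 + stats::rnorm(length(x), 0, cfg$parenchyma_noise_frac))
    } else {
      x
    }
  }

  scanner <- sample(sprintf("SC%02d", seq_len(cfg$n_scanners)),
                    length(mri_dates), replace = TRUE)

  sub_values <- function(k) {
    tot <- cum_lesion(k, t_mri)
    sh <- params$subcompartment_shares[[k]]
    out <- lapply(names(sh), function(s) tot * sh[[s]])
    stats::setNames(out, names(sh))
  }
  cereb_sub <- sub_values("cereb")
  infra_sub <- sub_values("infra")
  cord_sub <- sub_values("cord")

  mucca_true <- p_true("cord", t_mri)
  brain_mri <- tibble::tibble(
    patient_id = params$patient_id,
    date = mri_dates,
    scanner_id = scanner,
    !!!cereb_sub, !!!infra_sub,
    p_cereb = observe(p_true("cereb", t_mri)),
    p_infra = observe(p_true("infra", t_mri)),
    mucca_brain_t1 = 1.06 * mucca_true - 4 + stats::rnorm(length(t_mri), 0, 0.8)
  )
  cord_mri <- tibble::tibble(
    patient_id = params$patient_id,
    date = mri_dates,
    scanner_id = scanner,
    !!!cord_sub,
    mucca = observe(mucca_true)
  )

  # Relapse flags: progressing patients relapse only before onset.
  relapse_until <- if (params$progressing) min(onset, fy) else fy
  n_rel <- stats::rpois(1, cfg$relapse_rate_per_year * relapse_until)
  relapse <- rep(FALSE, length(clin_dates))
  if (n_rel > 0) {
    rel_t <- stats::runif(n_rel, 0, relapse_until)
    idx <- vapply(rel_t, function(rt) which.min(abs(t_clin - rt)), integer(1))
    relapse[unique(idx)] <- TRUE
  }

  clinical <- tibble::tibble(
    patient_id = params$patient_id,
    date = clin_dates,
    age0 = round(params$age0, 1),
    edss = NA_real_,
    relapse = relapse
  )

  l_clin <- lapply(stats::setNames(COMPARTMENTS, COMPARTMENTS),
                   function(k) cum_lesion(k, t_clin))
  latent <- tibble::tibble(
    patient_id = params$patient_id,
    date = clin_dates,
    age0 = round(params$age0, 1),
    visual_base = params$visual_base,
    lpf_cord = l_clin$cord / p_true("cord", t_clin),
    lpf_infra = l_clin$infra / p_true("infra", t_clin),
    lpf_cereb = l_clin$cereb / p_true("cereb", t_clin),
    p_true_cord = p_true("cord", t_clin),
    p_true_infra = p_true("infra", t_clin),
    p_true_cereb = p_true("cereb", t_clin)
  )

  truth <- tibble::tibble(
    patient_id = params$patient_id,
    progressing = params$progressing,
    onset_date = if (params$progressing) {
      params$start_date + round(params$onset_years * 365.25)
    } else {
      as.Date(NA)
    },
    age0 = round(params$age0, 1),
    start_date = params$start_date,
    followup_years = fy
  )

  list(clinical = clinical, brain_mri = brain_mri, cord_mri = cord_mri,
       latent = latent, lesion_events = dplyr::bind_rows(events),
       truth = truth)
}

#' Remove cervical cord scans to emulate incomplete cord imaging
#'
#' Drops each cord MRI row independently with probability
#' `1 - cord_scan_availability`, but never removes the last remaining cord
#' row of a patient (a patient with no cord scan at all could contribute
#' nothing to mucca calibration or cord LPF).
#'
#' @param tables List with elements `clinical`, `brain_mri`, `cord_mri`.
#' @param config A [cohort_config()]; `cord_scan_availability` must be
#'   strictly positive.
#' @return The list of tables with thinned `cord_mri`.
#' @export
inject_missingness <- function(tables, config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config object", call. = FALSE)
  }
  if (config$cord_scan_availability <= 0) {
    stop("cohort_config: field 'cord_scan_availability' is 0: no cord ",
         "measurements would remain to anchor mucca calibration",
         call. = FALSE)
  }
  if (config$cord_scan_availability >= 1) {
    return(tables)
  }
  cord <- tables$cord_mri
  if (nrow(cord) == 0) {
    return(tables)
  }
  keep <- stats::runif(nrow(cord)) < config$cord_scan_availability
  for (pid in unique(cord$patient_id)) {
    idx <- which(cord$patient_id == pid)
    if (!any(keep[idx])) {
      keep[idx[sample.int(length(idx), 1)]] <- TRUE
    }
  }
  tables$cord_mri <- cord[keep, , drop = FALSE]
  tables
}

#' Write the generative truth of a synthetic cohort as JSON
#'
#' @param truth The `truth` element of an [generate_cohort()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "cohort_truth"))
  out <- list(
    true_weights = as.list(truth$true_weights),
    edss_link = truth$edss_link,
    coef_per_percentile = as.list(truth$coef_per_percentile),
    age_coef_per_year = truth$age_coef_per_year,
    edss_intercept = truth$edss_intercept,
    patients = lapply(seq_len(nrow(truth$patients)), function(i) {
      p <- truth$patients[i, ]
      list(
        patient_id = p$patient_id,
        progressing = p$progressing,
        onset_date = if (is.na(p$onset_date)) NULL else format(p$onset_date),
        age0 = p$age0,
        start_date = format(p$start_date),
        followup_years = p$followup_years
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.lpf_cohort <- function(x, ...) {
  cat("<lpf_cohort>\n")
  cat(sprintf("  %d patients, %d clinical visits, %d brain MRI, %d cord MRI\n",
              length(unique(x$clinical$patient_id)), nrow(x$clinical),
              nrow(x$brain_mri), nrow(x$cord_mri)))
  cat(sprintf("  %d progressing in truth, link = %s\n",
              sum(x$truth$patients$progressing), x$truth$edss_link))
  invisible(x)
}
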