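# Four-panel per-patient disease-course figure. Shared x-axis is patient
# age; bottom-to-top: stacked lesion-volume bars at true MRI dates (split
# y-axis), parenchymal percentile lines, stacked compartment-weighted LPF
# percentiles with grey no-data regions, and the EDSS trajectory with
# functional-system colour wheels. Colour families follow the topographical
# compartments: cord reds, infratentorial yellows, cerebral greens; the
# visual system, with no MRI correlate, is grey.

VIZ_COLOURS <- list(
  cord = c(high_cervical = "#67000d", low_cervical = "#cb181d"),
  infra = c(medulla = "#7f2704", pons = "#d94801", midbrain = "#fd8d3c",
            cerebellum = "#fdbe85"),
  cereb = c(juxtacortical = "#00441b", deep_white_matter = "#238b45",
            periventricular = "#74c476"),
  compartment = c(cord = "#cb181d", infra = "#fd8d3c", cereb = "#238b45"),
  top_line = "#2166ac",
  no_data = "#bdbdbd",
  fss = c(fss_pyramidal = "#67000d", fss_sensory = "#cb181d",
          fss_bowel_bladder = "#fb6a4a", fss_brainstem = "#d94801",
          fss_cerebellar = "#fd8d3c", fss_mental = "#238b45",
          fss_visual = "#969696")
)

#' Visualization configuration
#'
#' @param weights Named compartment weights applied to the LPF percentile
#'   stack; the defaults (cereb 1, infra 2.5, cord 3.8) are the relative
#'   compartment coefficients of the LPF decoding model.
#' @param lesion_axis_split Lesion-volume (ml) value at which the bottom
#'   panel's y-axis splits; the lower half covers 0 to this value.
#' @param lesion_axis_max Upper limit (ml) of the lesion axis.
#' @param width,height,res Raster device size (inches) and resolution.
#' @return A `viz_config` list.
#' @export
viz_config <- function(weights = c(cord = 3.8, infra = 2.5, cereb = 1),
                       lesion_axis_split = 2, lesion_axis_max = 14,
                       width = 7.5, height = 9.5, res = 110) {
  if (!setequal(names(weights), COMPARTMENTS) || any(weights < 0)) {
    stop("weights must be nonnegative and named cord, infra, cereb",
         call. = FALSE)
  }
  if (lesion_axis_split >= lesion_axis_max) {
    stop("lesion_axis_split must be below lesion_axis_max", call. = FALSE)
  }
  structure(list(weights = weights, lesion_axis_split = lesion_axis_split,
                 lesion_axis_max = lesion_axis_max, width = width,
                 height = height, res = res, colours = VIZ_COLOURS),
            class = "viz_config")
}

#' Compartment-weighted cumulative LPF stack
#'
#' The top line is the weighted sum of the compartmental LPF percentiles,
#' `sum_k w_k * LPFpct_k`, per date; the bands are the per-compartment
#' contributions `w_k * LPFpct_k`, optionally subdivided by subcompartment
#' lesion-volume shares. Band heights sum exactly to the top line at every
#' date.
#'
#' @param lpf_pct Tibble with `date` and `cord`, `infra`, `cereb`
#'   percentile columns (`NA` marks no data).
#' @param weights Named compartment weights.
#' @param sub_shares Optional tibble with `date` plus one share column per
#'   lesion subcompartment (shares within each compartment summing to 1).
#' @return List with `top` (tibble `date`, `value`) and `bands` (tibble
#'   `date`, `compartment`, `band`, `height`).
#' @export
cumulative_weighted_lpf <- function(lpf_pct,
                                    weights = c(cord = 3.8, infra = 2.5,
                                                cereb = 1),
                                    sub_shares = NULL) {
  stopifnot(all(c("date", COMPARTMENTS) %in% names(lpf_pct)))
  contr <- lapply(stats::setNames(COMPARTMENTS, COMPARTMENTS),
                  function(k) weights[[k]] * lpf_pct[[k]])
  top <- tibble::tibble(
    date = lpf_pct$date,
    value = contr$cord + contr$infra + contr$cereb
  )
  bands <- list()
  for (k in COMPARTMENTS) {
    subs <- SUBCOMPARTMENTS_OF[[k]]
    if (!is.null(sub_shares) && all(subs %in% names(sub_shares))) {
      sh <- sub_shares[match(lpf_pct$date, sub_shares$date), subs,
                       drop = FALSE]
      sh <- as.matrix(sh)
      tot <- rowSums(sh)
      # Guard: renormalize so the subdivision conserves the band height.
      sh <- sh / ifelse(tot > 0, tot, length(subs))
      sh[tot <= 0 | is.na(tot), ] <- 1 / length(subs)
      for (s in subs) {
        bands[[paste0(k, ".", s)]] <- tibble::tibble(
          date = lpf_pct$date, compartment = k, band = s,
          height = contr[[k]] * sh[, s]
        )
      }
    } else {
      bands[[k]] <- tibble::tibble(date = lpf_pct$date, compartment = k,
                                   band = k, height = contr[[k]])
    }
  }
  list(top = top, bands = dplyr::bind_rows(bands))
}

# Piecewise transform for the split lesion axis: [0, split] maps to the
# lower half of the panel, (split, max] to the upper half.
lesion_axis_transform <- function(v, split, vmax) {
  ifelse(v <= split, 0.5 * v / split,
         0.5 + 0.5 * pmin(v - split, vmax - split) / (vmax - split))
}

draw_fss_wheel <- function(x, y, rx, ry, scores, ambulation) {
  systems <- names(VIZ_COLOURS$fss)
  n <- length(systems)
  for (s in seq_len(n)) {
    sys <- systems[s]
    val <- scores[[sys]]
    if (is.null(val) || is.na(val) || val <= 0) next
    frac <- min(1, val / FSS_MAX[[sys]])
    th <- seq(2 * pi * (s - 1) / n, 2 * pi * s / n, length.out = 12)
    graphics::polygon(c(x, x + rx * frac * sin(th)),
                      c(y, y + ry * frac * cos(th)),
                      col = VIZ_COLOURS$fss[[sys]], border = NA)
  }
  th_all <- seq(0, 2 * pi, length.out = 60)
  graphics::lines(x + rx * sin(th_all), y + ry * cos(th_all),
                  col = "grey40", lwd = 0.5)
  if (isTRUE(ambulation)) {
    th_a <- seq(0, 1.5 * pi, length.out = 45)
    graphics::lines(x + 1.25 * rx * sin(th_a), y + 1.25 * ry * cos(th_a),
                    col = "black", lwd = 2)
  }
}

# Collect everything one patient's figure needs.
patient_panel_data <- function(patient_id, features, matched, clinical,
                               phenotype = NULL) {
  feat <- features[features$patient_id == patient_id, ]
  feat <- feat[order(feat$date), ]
  if (nrow(feat) == 0) {
    stop("patient ", patient_id, " has no matched time points", call. = FALSE)
  }
  m <- matched[matched$patient_id == patient_id, ]
  wide <- matched_to_wide(m, provenance = TRUE)
  cl <- clinical[clinical$patient_id == patient_id, ]
  cl <- cl[order(cl$date), ]

  first_clin <- cl$date[1]
  age_at <- function(d) cl$age0[1] + as.numeric(d - first_clin) / 365.25

  prov_cols <- paste0("prov_", LESION_SUBCOMPARTMENTS)
  prov_cols <- intersect(prov_cols, names(wide))
  measured_mri <- apply(as.matrix(wide[prov_cols]), 1,
                        function(r) any(r == "measured", na.rm = TRUE))

  onset_date <- as.Date(NA)
  if (!is.null(phenotype)) {
    row <- phenotype[phenotype$patient_id == patient_id, ]
    if (nrow(row) == 1 && isTRUE(row$progressing)) onset_date <- row$onset_date
  }
  cord_prov <- if ("prov_high_cervical" %in% names(wide)) {
    wide$prov_high_cervical
  } else {
    rep("missing", nrow(wide))
  }
  list(features = feat, wide = wide, clinical = cl, age_at = age_at,
       measured_mri = measured_mri, onset_date = onset_date,
       first_cord_measured = suppressWarnings(
         min(wide$date[cord_prov == "measured"])
       ))
}

#' Render the four-panel disease-course figure for one patient
#'
#' @param patient_id Patient to render.
#' @param features Feature table from [build_feature_table()].
#' @param matched Matched long table from [match_cohort()].
#' @param clinical Clinical visit table.
#' @param phenotype Optional [classify_spms()] result; when the patient is
#'   progressing, the figure background darkens at the onset date.
#' @param config A [viz_config()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_patient <- function(patient_id, features, matched, clinical,
                           phenotype = NULL, config = viz_config(),
                           path = paste0(patient_id, ".png")) {
  pd <- patient_panel_data(patient_id, features, matched, clinical, phenotype)
  feat <- pd$features
  wide <- pd$wide
  cl <- pd$clinical
  age_at <- pd$age_at

  ages_feat <- age_at(feat$date)
  ages_mri <- age_at(wide$date)
  ages_cl <- age_at(cl$date)
  xlim <- range(c(ages_feat, ages_mri, ages_cl)) + c(-0.3, 0.3)
  onset_age <- if (!is.na(pd$onset_date)) age_at(pd$onset_date) else NA

  grDevices::png(path, width = config$width, height = config$height,
                 units = "in", res = config$res)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::layout(matrix(4:1, ncol = 1), heights = c(1.1, 1, 1, 1))
  # par state is scoped to the png device and dies with it on dev.off()
  graphics::par(mar = c(1.5, 4.2, 0.6, 6.5), mgp = c(2.2, 0.6, 0),
                xaxs = "i")

  shade_background <- function(ymax) {
    if (!is.na(onset_age)) {
      graphics::rect(xlim[1], 0, onset_age, ymax, col = "#deebf7",
                     border = NA)
      graphics::rect(onset_age, 0, xlim[2], ymax, col = "#9ecae1",
                     border = NA)
    } else {
      graphics::rect(xlim[1], 0, xlim[2], ymax, col = "#deebf7",
                     border = NA)
    }
  }

  # --- Bottom panel: stacked lesion bars at true MRI dates, split axis ---
  split <- config$lesion_axis_split
  vmax <- config$lesion_axis_max
  ty <- function(v) lesion_axis_transform(v, split, vmax)
  graphics::plot(NA, xlim = xlim, ylim = c(0, 1.02), xlab = "age (years)",
                 ylab = "lesion volume (ml)", yaxt = "n")
  ticks <- c(0, split / 2, split, (split + vmax) / 2, vmax)
  graphics::axis(2, at = ty(ticks), labels = ticks, las = 1)
  graphics::abline(h = 0.5, lty = 3, col = "grey60")
  bar_w <- diff(xlim) / 90
  bar_dates <- which(pd$measured_mri)
  sub_cols <- unlist(VIZ_COLOURS[c("cord", "infra", "cereb")])
  names(sub_cols) <- sub("^(cord|infra|cereb)\\.", "", names(sub_cols))
  for (i in bar_dates) {
    x0 <- ages_mri[i] - bar_w / 2
    x1 <- ages_mri[i] + bar_w / 2
    base <- 0
    for (s in LESION_SUBCOMPARTMENTS) {
      v <- wide[[s]][i]
      if (is.na(v) || v <= 0) next
      graphics::rect(x0, ty(base), x1, ty(base + v), col = sub_cols[[s]],
                     border = NA)
      base <- base + v
    }
  }
  graphics::legend("topright", inset = c(-0.22, 0), xpd = TRUE, cex = 0.6,
                   fill = sub_cols, legend = names(sub_cols), bty = "n",
                   title = "subcompartment")

  # --- Second panel: parenchymal percentiles ---
  graphics::plot(NA, xlim = xlim, ylim = c(0, 100), xlab = "",
                 ylab = "parenchymal volume (percentile)", las = 1)
  prov_p <- list(cord = "prov_mucca", infra = "prov_p_infra",
                 cereb = "prov_p_cereb")
  for (k in COMPARTMENTS) {
    v <- feat[[paste0("p_pct_", k)]]
    graphics::lines(ages_feat, v, col = VIZ_COLOURS$compartment[[k]],
                    lwd = 2)
    pc <- prov_p[[k]]
    if (pc %in% names(wide)) {
      meas <- wide$date[wide[[pc]] == "measured"]
      idx <- match(meas, feat$date)
      idx <- idx[!is.na(idx)]
      graphics::points(ages_feat[idx], v[idx], pch = 19,
                       col = VIZ_COLOURS$compartment[[k]], cex = 0.8)
    }
  }
  graphics::legend("topright", inset = c(-0.2, 0), xpd = TRUE, cex = 0.7,
                   col = VIZ_COLOURS$compartment, lwd = 2,
                   legend = c("cord (mucca)", "infratentorial", "cerebral"),
                   bty = "n")

  # --- Third panel: stacked weighted LPF ---
  lpf_pct <- tibble::tibble(date = feat$date, cord = feat$lpf_pct_cord,
                            infra = feat$lpf_pct_infra,
                            cereb = feat$lpf_pct_cereb)
  shares <- lesion_share_table(wide)
  stack <- cumulative_weighted_lpf(lpf_pct, config$weights, shares)
  ymax <- max(stack$top$value, 1, na.rm = TRUE) * 1.05
  graphics::plot(NA, xlim = xlim, ylim = c(0, ymax), xlab = "",
                 ylab = "cumulative weighted LPF (percentile)", las = 1)
  if (is.finite(as.numeric(pd$first_cord_measured)) &&
      age_at(pd$first_cord_measured) > xlim[1]) {
    graphics::rect(xlim[1], 0, age_at(pd$first_cord_measured), ymax,
                   col = VIZ_COLOURS$no_data, border = NA)
  }
  band_order <- c(paste0("cord.", CORD_SUBCOMPARTMENTS),
                  paste0("infra.", INFRA_SUBCOMPARTMENTS),
                  paste0("cereb.", CEREB_SUBCOMPARTMENTS))
  cum <- rep(0, nrow(feat))
  for (bn in band_order) {
    parts <- strsplit(bn, ".", fixed = TRUE)[[1]]
    b <- stack$bands[stack$bands$compartment == parts[1] &
                       stack$bands$band == parts[2], ]
    if (nrow(b) == 0) next
    h <- b$height[match(feat$date, b$date)]
    h[is.na(h)] <- 0
    upper <- cum + h
    graphics::polygon(c(ages_feat, rev(ages_feat)), c(cum, rev(upper)),
                      col = sub_cols[[parts[2]]], border = NA)
    cum <- upper
  }
  graphics::lines(ages_feat, stack$top$value, col = VIZ_COLOURS$top_line,
                  lwd = 2.5)

  # --- Top panel: EDSS and FSS wheels ---
  graphics::plot(NA, xlim = xlim, ylim = c(0, 10), xlab = "", ylab = "EDSS",
                 las = 1)
  shade_background(10)
  graphics::lines(ages_cl, cl$edss, col = VIZ_COLOURS$top_line, lwd = 2.5)
  usr <- graphics::par("usr")
  pin <- graphics::par("pin")
  rx <- diff(usr[1:2]) / pin[1] * 0.055
  ry <- diff(usr[3:4]) / pin[2] * 0.055
  for (i in seq_len(nrow(cl))) {
    draw_fss_wheel(ages_cl[i], cl$edss[i], rx, ry,
                   as.list(cl[i, FSS_COLUMNS]),
                   isTRUE(cl$ambulation_affected[i]))
  }
  lab <- if (!is.na(onset_age)) {
    sprintf("%s   RRMS → SPMS at age %.0f", patient_id, onset_age)
  } else {
    sprintf("%s   RRMS (non-progressing)", patient_id)
  }
  graphics::mtext(lab, side = 3, line = -1.2, cex = 0.8)

  invisible(path)
}

# Subcompartment lesion shares within each compartment, per matched date.
lesion_share_table <- function(wide) {
  out <- tibble::tibble(date = wide$date)
  for (k in COMPARTMENTS) {
    subs <- SUBCOMPARTMENTS_OF[[k]]
    if (!all(subs %in% names(wide))) next
    m <- as.matrix(wide[subs])
    tot <- rowSums(m)
    for (s in subs) {
      out[[s]] <- ifelse(!is.na(tot) & tot > 0, m[, s] / tot,
                         1 / length(subs))
    }
  }
  out
}

#' Render the whole cohort and write an index
#'
#' One PNG per patient plus an `index.csv` listing each patient's file and
#' phenotype call. Per-patient failures are collected, not fatal.
#'
#' @inheritParams render_patient
#' @param out_dir Output directory (created if needed).
#' @return Tibble index (also written to `out_dir/index.csv`), invisibly.
#' @export
render_cohort <- function(features, matched, clinical, phenotype = NULL,
                          config = viz_config(), out_dir = "figs") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  patients <- sort(unique(features$patient_id))
  rows <- lapply(patients, function(pid) {
    file <- file.path(out_dir, paste0(pid, ".png"))
    err <- tryCatch({
      render_patient(pid, features, matched, clinical, phenotype,
                     config, file)
      NA_character_
    }, error = function(e) conditionMessage(e))
    prog <- NA
    onset <- as.Date(NA)
    if (!is.null(phenotype)) {
      row <- phenotype[phenotype$patient_id == pid, ]
      if (nrow(row) == 1) {
        prog <- row$progressing
        onset <- row$onset_date
      }
    }
    tibble::tibble(patient_id = pid, file = basename(file),
                   progressing = prog, onset_date = onset, error = err)
  })
  empty <- tibble::tibble(patient_id = character(), file = character(),
                          progressing = logical(),
                          onset_date = as.Date(character()),
                          error = character())
  index <- dplyr::bind_rows(c(list(empty), rows))
  readr::write_csv(index, file.path(out_dir, "index.csv"), na = "")
  invisible(index)
}
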