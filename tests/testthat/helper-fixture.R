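# Hand-built matching fixture. Four patients probe the window boundaries:
#   P1 -- five unified dates exercising every fill stage;
#   P2 -- brain MRI 16 days after the clinical visit (outside the 15-day
#         window: parenchyma back-fills, lesions stay missing);
#   P3 -- MRI 274 days after the only clinical visit (inside 9 months);
#   P4 -- MRI 275 days after the only clinical visit (outside 9 months).

fixture_clinical_row <- function(pid, date, edss, age0 = 40) {
  tibble::tibble(
    patient_id = pid, date = as.Date(date), age0 = age0, edss = edss,
    fss_pyramidal = 1, fss_cerebellar = 0, fss_brainstem = 0,
    fss_sensory = 1, fss_bowel_bladder = 0, fss_visual = 0, fss_mental = 0,
    ambulation_affected = FALSE, relapse = FALSE
  )
}

fixture_brain_row <- function(pid, date, juxta, p_cereb,
                              mucca_brain_t1 = NA_real_) {
  tibble::tibble(
    patient_id = pid, date = as.Date(date), scanner_id = "SC01",
    juxtacortical = juxta, deep_white_matter = 0.5, periventricular = 0.8,
    medulla = 0.1, pons = 0.2, midbrain = 0, cerebellum = 0.3,
    p_cereb = p_cereb, p_infra = 150, mucca_brain_t1 = mucca_brain_t1
  )
}

fixture_cord_row <- function(pid, date, hc = 0.2, mucca = 70) {
  tibble::tibble(
    patient_id = pid, date = as.Date(date), scanner_id = "SC01",
    high_cervical = hc, low_cervical = 0.1, mucca = mucca
  )
}

fixture_cohort <- function() {
  clinical <- dplyr::bind_rows(
    fixture_clinical_row("P1", "2015-01-01", 2.0),
    fixture_clinical_row("P1", "2015-07-01", 2.5),
    fixture_clinical_row("P2", "2015-01-01", 3.0),
    fixture_clinical_row("P3", "2015-01-01", 4.0),
    fixture_clinical_row("P4", "2015-01-01", 4.0)
  )
  brain <- dplyr::bind_rows(
    fixture_brain_row("P1", "2015-01-16", juxta = 1.0, p_cereb = 1000),
    fixture_brain_row("P1", "2016-03-01", juxta = 1.2, p_cereb = 990),
    fixture_brain_row("P2", "2015-01-17", juxta = 0.7, p_cereb = 1010),
    fixture_brain_row("P3", "2015-10-02", juxta = 0.4, p_cereb = 1020),
    fixture_brain_row("P4", "2015-10-03", juxta = 0.4, p_cereb = 1020)
  )
  cord <- fixture_cord_row("P1", "2015-12-01")
  list(clinical = clinical, brain_mri = brain, cord_mri = cord)
}

# Hand-derived expected (value, provenance) for the probing measures of P1
# plus the boundary rows of P2-P4.
fixture_expected <- function() {
  d <- as.Date(c("2015-01-01", "2015-01-16", "2015-07-01", "2015-12-01",
                 "2016-03-01"))
  tibble::tribble(
    ~patient_id, ~date, ~measure, ~value, ~provenance,
    "P1", d[1], "juxtacortical", 1.0, "nearest_15d",
    "P1", d[2], "juxtacortical", 1.0, "measured",
    "P1", d[3], "juxtacortical", 1.0, "forward_filled",
    "P1", d[4], "juxtacortical", 1.0, "forward_filled",
    "P1", d[5], "juxtacortical", 1.2, "measured",
    "P1", d[1], "p_cereb", 1000, "nearest_15d",
    "P1", d[2], "p_cereb", 1000, "measured",
    "P1", d[3], "p_cereb", 990, "backward_filled",
    "P1", d[4], "p_cereb", 990, "backward_filled",
    "P1", d[5], "p_cereb", 990, "measured",
    "P1", d[1], "high_cervical", NA, "missing",
    "P1", d[2], "high_cervical", NA, "missing",
    "P1", d[3], "high_cervical", NA, "missing",
    "P1", d[4], "high_cervical", 0.2, "measured",
    "P1", d[5], "high_cervical", 0.2, "forward_filled",
    "P1", d[1], "mucca", 70, "backward_filled",
    "P1", d[2], "mucca", 70, "backward_filled",
    "P1", d[3], "mucca", 70, "backward_filled",
    "P1", d[4], "mucca", 70, "measured",
    "P1", d[5], "mucca", NA, "missing",
    "P1", d[1], "edss", 2.0, "measured",
    "P1", d[2], "edss", 2.0, "clinical_filled_9m",
    "P1", d[3], "edss", 2.5, "measured",
    "P1", d[4], "edss", 2.5, "clinical_filled_9m",
    "P1", d[5], "edss", 2.5, "clinical_filled_9m",
    # P2: 16 days is outside the 15-day window
    "P2", as.Date("2015-01-01"), "juxtacortical", NA, "missing",
    "P2", as.Date("2015-01-01"), "p_cereb", 1010, "backward_filled",
    "P2", as.Date("2015-01-17"), "edss", 3.0, "clinical_filled_9m",
    # P3: 274 days = nine months, inclusive
    "P3", as.Date("2015-10-02"), "edss", 4.0, "clinical_filled_9m",
    # P4: 275 days, outside
    "P4", as.Date("2015-10-03"), "edss", NA, "missing"
  )
}
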