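# Cohort table schema: three comma-separated tables in long format.
#
#   clinical.csv  patient_id, date, age0, edss, fss_* (7), ambulation_affected,
#                 relapse
#   brain_mri.csv patient_id, date, scanner_id, juxtacortical,
#                 deep_white_matter, periventricular, medulla, pons, midbrain,
#                 cerebellum, p_cereb, p_infra, mucca_brain_t1
#   cord_mri.csv  patient_id, date, scanner_id, high_cervical, low_cervical,
#                 mucca
#
# p_cereb is stored already split (whole-brain parenchymal volume minus the
# infratentorial tissue volume); split_whole_brain() performs the subtraction
# for sources that record whole-brain volume instead.

CLINICAL_COLUMNS <- c("patient_id", "date", "age0", "edss", FSS_COLUMNS,
                      "ambulation_affected", "relapse")
BRAIN_MRI_COLUMNS <- c("patient_id", "date", "scanner_id",
                       CEREB_SUBCOMPARTMENTS, INFRA_SUBCOMPARTMENTS,
                       "p_cereb", "p_infra", "mucca_brain_t1")
CORD_MRI_COLUMNS <- c("patient_id", "date", "scanner_id",
                      CORD_SUBCOMPARTMENTS, "mucca")

#' Read and validate a cohort from CSV tables
#'
#' Reads `clinical.csv`, `brain_mri.csv` and `cord_mri.csv` from a directory
#' (or explicit paths), parses dates as ISO-8601 calendar dates, turns empty
#' cells into explicit `NA`s, and validates every cell against the schema:
#' EDSS on its half-step grid, each functional system score within its range,
#' volumes nonnegative, mucca positive when present. Validation is total --
#' any cell that does not parse to its semantic type raises an error naming
#' the file, row and field.
#'
#' @param dir Directory containing the three tables, or `NULL` when paths
#'   are given explicitly.
#' @param clinical,brain_mri,cord_mri Optional explicit file paths.
#' @return A list with validated tibbles `clinical`, `brain_mri`, `cord_mri`.
#' @export
read_cohort <- function(dir = NULL, clinical = NULL, brain_mri = NULL,
                        cord_mri = NULL) {
  if (!is.null(dir)) {
    clinical <- clinical %||% file.path(dir, "clinical.csv")
    brain_mri <- brain_mri %||% file.path(dir, "brain_mri.csv")
    cord_mri <- cord_mri %||% file.path(dir, "cord_mri.csv")
  }
  for (p in c(clinical, brain_mri, cord_mri)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  tables <- list(
    clinical = read_table_checked(clinical, CLINICAL_COLUMNS, "clinical"),
    brain_mri = read_table_checked(brain_mri, BRAIN_MRI_COLUMNS, "brain_mri"),
    cord_mri = read_table_checked(cord_mri, CORD_MRI_COLUMNS, "cord_mri")
  )
  validate_cohort(tables)
  tables
}

read_table_checked <- function(path, columns, label) {
  hdr <- names(utils::read.csv(path, nrows = 0, check.names = FALSE))
  extra <- setdiff(hdr, columns)
  missing <- setdiff(columns, hdr)
  if (length(extra)) {
    stop(label, ": unknown column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (length(missing)) {
    stop(label, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  types <- sapply(columns, function(col) {
    if (col %in% c("patient_id", "scanner_id")) "c"
    else if (col == "date") "D"
    else if (col %in% c("ambulation_affected", "relapse")) "l"
    else "d"
  })
  tb <- suppressWarnings(
    readr::read_csv(path, col_types = paste(types, collapse = ""),
                    progress = FALSE)
  )
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    p1 <- probs[1, ]
    stop(label, ": row ", p1$row, ", field '", columns[p1$col],
         "': expected ", p1$expected, ", got '", p1$actual, "'",
         call. = FALSE)
  }
  tb
}

#' Validate cohort tables against the schema
#'
#' Range-checks every cell of already-typed cohort tables; errors name the
#' table, row and field of the first violation.
#'
#' @param tables List with tibbles `clinical`, `brain_mri`, `cord_mri` (an
#'   [lpf_cohort][generate_cohort()] object also works).
#' @param edss_grid Enforce the half-step EDSS grid (disable for cohorts
#'   generated with `quantize_edss = FALSE`, whose EDSS is continuous).
#' @return The tables, invisibly, when valid.
#' @export
validate_cohort <- function(tables, edss_grid = TRUE) {
  if (inherits(tables, "lpf_cohort") && !is.null(tables$config)) {
    edss_grid <- edss_grid && tables$config$quantize_edss
  }
  bad <- function(label, rows, field, msg) {
    if (any(rows, na.rm = TRUE)) {
      stop(label, ": row ", which(rows)[1], ", field '", field, "': ", msg,
           call. = FALSE)
    }
  }
  cl <- tables$clinical
  bad("clinical", is.na(cl$patient_id) | cl$patient_id == "", "patient_id",
      "must be non-empty")
  bad("clinical", is.na(cl$date), "date", "unparseable or missing date")
  if (edss_grid) {
    bad("clinical", !is.na(cl$edss) & !(cl$edss %in% EDSS_GRID), "edss",
        "EDSS off the valid grid {0, 1.0, 1.5, ..., 10}")
  } else {
    bad("clinical", !is.na(cl$edss) & (cl$edss < 0 | cl$edss > 10), "edss",
        "EDSS must lie in [0, 10]")
  }
  bad("clinical", !is.na(cl$age0) & cl$age0 <= 0, "age0", "must be positive")
  for (col in FSS_COLUMNS) {
    v <- cl[[col]]
    bad("clinical",
        !is.na(v) & (v < 0 | v > FSS_MAX[[col]] | v != round(v)), col,
        paste0("must be an integer in [0, ", FSS_MAX[[col]], "]"))
  }
  for (tab in c("brain_mri", "cord_mri")) {
    mri <- tables[[tab]]
    bad(tab, is.na(mri$patient_id) | mri$patient_id == "", "patient_id",
        "must be non-empty")
    bad(tab, is.na(mri$date), "date", "unparseable or missing date")
    vol_cols <- intersect(names(mri), LESION_SUBCOMPARTMENTS)
    for (col in vol_cols) {
      bad(tab, !is.na(mri[[col]]) & mri[[col]] < 0, col,
          "lesion volume must be nonnegative")
    }
    for (col in intersect(names(mri), c("p_cereb", "p_infra"))) {
      bad(tab, !is.na(mri[[col]]) & mri[[col]] <= 0, col,
          "parenchymal volume must be positive")
    }
    for (col in intersect(names(mri), "mucca")) {
      bad(tab, !is.na(mri[[col]]) & mri[[col]] <= 0, col,
          "mucca must be positive when present")
    }
  }
  invisible(tables)
}

#' Write cohort tables as CSV
#'
#' Writes `clinical.csv`, `brain_mri.csv` and `cord_mri.csv` with a
#' deterministic column order and rows sorted by (patient_id, date), so two
#' writes of the same records are byte-identical. Missing values become
#' empty cells (never zeros). When the cohort carries generative truth, a
#' `truth.json` sidecar is written too.
#'
#' @param cohort An [lpf_cohort][generate_cohort()] or a plain list of the
#'   three tables.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- function(tb) tb[order(tb$patient_id, tb$date), , drop = FALSE]
  readr::write_csv(ord(cohort$clinical)[, CLINICAL_COLUMNS],
                   file.path(dir, "clinical.csv"), na = "")
  readr::write_csv(ord(cohort$brain_mri)[, BRAIN_MRI_COLUMNS],
                   file.path(dir, "brain_mri.csv"), na = "")
  readr::write_csv(ord(cohort$cord_mri)[, CORD_MRI_COLUMNS],
                   file.path(dir, "cord_mri.csv"), na = "")
  if (!is.null(cohort$truth)) {
    write_truth(cohort$truth, file.path(dir, "truth.json"))
  }
  invisible(dir)
}

#' Split whole-brain parenchymal volume into cerebral and infratentorial
#'
#' The cerebral parenchymal volume is defined as the whole-brain parenchymal
#' volume minus the infratentorial tissue volume; sources that record
#' whole-brain volume can be converted at load time.
#'
#' @param whole_brain,p_infra Numeric vectors of the same length.
#' @return `p_cereb = whole_brain - p_infra`.
#' @export
split_whole_brain <- function(whole_brain, p_infra) {
  out <- whole_brain - p_infra
  if (any(out <= 0, na.rm = TRUE)) {
    warning("whole-brain minus infratentorial volume is nonpositive for ",
            sum(out <= 0, na.rm = TRUE), " row(s)")
  }
  out
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Thin wrapper around [stats::ks.test()] returning the two-sample statistic
#' `D = max |ECDF1 - ECDF2|`.
#'
#' @param x,y Numeric samples.
#' @return The KS statistic, a number in \[0, 1\].
#' @export
ks_statistic <- function(x, y) {
  unname(suppressWarnings(stats::ks.test(x, y)$statistic))
}

#' Scanner-harmonization check via pairwise Kolmogorov-Smirnov tests
#'
#' Compares the distribution of every numeric measure between each pair of
#' scanners with the two-sample Kolmogorov-Smirnov test. P-values are
#' Holm-adjusted within a measure (the conservative reading of a pairwise
#' comparison across scanners); a pair is flagged when the adjusted p-value
#' falls below `alpha`. When nothing is flagged the report concludes that no
#' further harmonization is needed.
#'
#' @param mri A data frame with a `scanner_id` column and numeric measure
#'   columns (e.g. a `brain_mri` or `cord_mri` table), or a row-bound
#'   combination.
#' @param measures Character vector of measure columns; default all numeric
#'   columns except identifiers and dates.
#' @param alpha Significance level for flagging.
#' @param min_n Minimum measurements per scanner group; smaller groups are
#'   skipped with a warning.
#' @return A tibble with one row per (measure, scanner pair): `statistic`,
#'   `p_value`, `p_adj`, `flagged`; attribute `harmonization_needed` is
#'   `TRUE` iff any pair is flagged.
#' @export
ks_scanner_check <- function(mri, measures = NULL, alpha = 0.05, min_n = 5) {
  if (!"scanner_id" %in% names(mri)) {
    stop("`mri` must contain a scanner_id column", call. = FALSE)
  }
  if (is.null(measures)) {
    measures <- names(mri)[vapply(mri, is.numeric, logical(1))]
    measures <- setdiff(measures, c("age0"))
  }
  scanners <- sort(unique(mri$scanner_id))
  if (length(scanners) < 2) {
    stop("need measurements from at least 2 scanners", call. = FALSE)
  }
  rows <- list()
  for (m in measures) {
    groups <- split(mri[[m]][!is.na(mri[[m]])],
                    mri$scanner_id[!is.na(mri[[m]])])
    usable <- names(groups)[vapply(groups, length, integer(1)) >= min_n]
    skipped <- setdiff(names(groups), usable)
    if (length(skipped)) {
      warning("measure '", m, "': scanner group(s) below ", min_n,
              " measurements skipped: ", paste(skipped, collapse = ", "),
              call. = FALSE)
    }
    if (length(usable) < 2) next
    pairs <- utils::combn(usable, 2)
    res <- apply(pairs, 2, function(pr) {
      ks <- suppressWarnings(stats::ks.test(groups[[pr[1]]], groups[[pr[2]]]))
      c(statistic = unname(ks$statistic), p_value = ks$p.value)
    })
    tb <- tibble::tibble(
      measure = m,
      scanner_a = pairs[1, ],
      scanner_b = pairs[2, ],
      statistic = as.numeric(res["statistic", ]),
      p_value = as.numeric(res["p_value", ])
    )
    tb$p_adj <- stats::p.adjust(tb$p_value, method = "holm")
    rows[[m]] <- tb
  }
  report <- dplyr::bind_rows(rows)
  if (nrow(report) == 0) {
    report <- tibble::tibble(measure = character(), scanner_a = character(),
                             scanner_b = character(), statistic = numeric(),
                             p_value = numeric(), p_adj = numeric(),
                             flagged = logical())
  } else {
    report$flagged <- report$p_adj < alpha
  }
  attr(report, "harmonization_needed") <- any(report$flagged)
  report
}
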