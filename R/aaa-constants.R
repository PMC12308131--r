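# Shared vocabulary for compartments, measures and clinical scales.

CEREB_SUBCOMPARTMENTS <- c("juxtacortical", "deep_white_matter", "periventricular")
INFRA_SUBCOMPARTMENTS <- c("medulla", "pons", "midbrain", "cerebellum")
CORD_SUBCOMPARTMENTS <- c("high_cervical", "low_cervical")
LESION_SUBCOMPARTMENTS <- c(
  CEREB_SUBCOMPARTMENTS, INFRA_SUBCOMPARTMENTS, CORD_SUBCOMPARTMENTS
)

COMPARTMENTS <- c("cord", "infra", "cereb")

SUBCOMPARTMENTS_OF <- list(
  cord = CORD_SUBCOMPARTMENTS,
  infra = INFRA_SUBCOMPARTMENTS,
  cereb = CEREB_SUBCOMPARTMENTS
)

PARENCHYMA_MEASURES <- c(cord = "mucca", infra = "p_infra", cereb = "p_cereb")
MRI_MEASURES <- c(LESION_SUBCOMPARTMENTS, unname(PARENCHYMA_MEASURES))

FSS_COLUMNS <- c(
  "fss_pyramidal", "fss_cerebellar", "fss_brainstem", "fss_sensory",
  "fss_bowel_bladder", "fss_visual", "fss_mental"
)
# Upper bound of each functional system score (lower bound is 0).
FSS_MAX <- c(
  fss_pyramidal = 6, fss_cerebellar = 5, fss_brainstem = 5, fss_sensory = 6,
  fss_bowel_bladder = 6, fss_visual = 6, fss_mental = 5
)
CLINICAL_MEASURES <- c("edss", FSS_COLUMNS)

# Valid EDSS support: 0, then half steps from 1.0 to 10.
EDSS_GRID <- c(0, seq(1, 10, by = 0.5))

# Nine months expressed in days (365.25 * 0.75, rounded).
CLINICAL_FILL_WINDOW_DAYS <- 274L

PROVENANCE_LEVELS <- c(
  "measured", "nearest_15d", "forward_filled", "backward_filled",
  "clinical_filled_9m", "missing"
)

#' Snap values to the EDSS grid
#'
#' Clips to \[0, 10\] and maps each value to the nearest point of the valid
#' EDSS support (0, then 1.0 to 10 in half steps). Exact midpoints resolve
#' to the lower grid value.
#'
#' @param x Numeric vector.
#' @return Numeric vector on the EDSS grid; `NA` passes through.
#' @export
snap_edss <- function(x) {
  out <- pmin(pmax(x, 0), 10)
  ok <- !is.na(out)
  out[ok] <- vapply(
    out[ok],
    function(v) EDSS_GRID[which.min(abs(EDSS_GRID - v))],
    numeric(1)
  )
  out
}
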