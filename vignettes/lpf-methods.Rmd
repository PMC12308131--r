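---
title: "Modelling MS disease course with the lesion parenchymal fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MS disease course with the lesion parenchymal fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpftraj)
```

## The metric and the model

The topographical view of multiple sclerosis treats the central nervous
system as a pool of compensatory reserve of varying depth: the cervical
cord has the least redundancy, the infratentorium (brainstem and
cerebellum) an intermediate amount, and the cerebral hemispheres the most.
Disability emerges when focal lesion burden outgrows the regional reserve.
The **lesion parenchymal fraction** operationalizes this as a ratio per
compartment $k \in \{\mathrm{cord}, \mathrm{infra}, \mathrm{cereb}\}$:

$$\mathrm{LPF}_k = \frac{L_k}{P_k},$$

where $L_k$ is the regional T2 lesion volume (ml) and $P_k$ the regional
parenchymal measure: head-size-normalized tissue volumes for the brain
compartments and the mean upper cervical cord cross-sectional area (mucca,
mm²) for the cord. Cerebral parenchymal volume is whole-brain volume minus
the infratentorial volume. The cord ratio mixes ml and mm²; it is used as
an internally consistent index because only percentile ranks enter the
models.

Lesion volumes, parenchymal measures and LPF values are transformed to
percentiles *with respect to the study sample* (all patients, all time
points, pooled) to put the compartments on a common scale. We use the
Hazen rank $100\,(r - 0.5)/n$ with midranks for ties: it is symmetric
(mean 50) and stable under ties, and — like any rank transform — invariant
under strictly monotone rescaling of the raw measure. Percentiles are
computed once per run on the full sample rather than inside each
cross-validation fold; refitting the reference distribution per fold would
remove a mild leakage but would also change the meaning of the features
between folds, so the single-reference convention is kept and noted here.

Disability is decoded from the imaging features by four linear models,
fitted on percentile features plus the age at the initial time point
(`age0`):

* **LPF**: $\widehat{\mathrm{EDSS}} = a\,\mathrm{LPF}_{cereb} + b\,\mathrm{LPF}_{infra} + c\,\mathrm{LPF}_{cord} + K\,\mathrm{age}_0$
* **LPV**: separate lesion ($L$) and parenchymal ($P$) percentile terms per compartment
* **LV**: lesion percentile terms only
* **PV**: parenchymal percentile terms only

An intercept is included by default even though the written equations
carry none: percentile predictors have mean near 50, and an
intercept-free fit would absorb that offset into the compartment weights.
`intercept = FALSE` reproduces the literal equations.

Models are evaluated by leave-one-patient-out cross-validation: for each
patient, all other patients' time points fit the model, and the held-out
patient's time points are predicted. Pooled held-out predictions yield
the Pearson correlation, RMSE, and the *MAE without patient bias* — the
mean absolute residual after subtracting each patient's mean signed error,
which scores how well within-patient change is tracked. One coefficient
vector is stored per fold, giving each compartment a distribution with as
many values as patients; dividing the mean cord and infratentorial
coefficients by the mean cerebral coefficient yields the relative
compartment weights used in the trajectory figures (defaults 3.8 and 2.5).
The fold-coefficient bookkeeping is deliberately one record per patient
fold: storing one record per *time point* of each fold would only
replicate identical vectors.

## Matching clinical and MRI streams

Clinical visits and MRI sessions rarely share dates. Matching proceeds in
four strict stages, each seeing the previous stage's output exactly once:

1. all clinical and MRI dates of a patient form the unified time axis;
2. missing MRI values are copied from the nearest measurement within
   ±15 days (inclusive at 15; equidistant ties resolve to the earlier
   measurement, the value that "already existed");
3. lesion volumes are forward-filled (lesions, once formed, are treated
   as permanent) and parenchymal values back-filled (adult parenchyma
   does not regrow); neither fill crosses the first/last measurement;
4. clinical scores are copied from the nearest visit within 9 months,
   implemented as 274 days (365.25 × 0.75, rounded).

Only copies are made — no interpolation — and every value carries a
provenance flag (`measured`, `nearest_15d`, `forward_filled`,
`backward_filled`, `clinical_filled_9m`, `missing`). The 15-day stage
applies to MRI-derived measures only; clinical values are governed solely
by the 9-month rule. The stages do not chain across a single gap: a value
placed by stage 2 is a legitimate source for stage 3, but stage 2 is not
re-run on stage 3's output.

When a time point has brain MRI but no cord scan, mucca is estimated from
the brain-T1-derived reading through a quadratic calibration
$c_0 + c_1 b + c_2 b^2$, least-squares-fitted on time points with both
measurements (anywhere in the cohort, paired within the 15-day window).
With fewer than three distinct pairs the fit degrades, with a message, to
linear and then to the identity; nonpositive calibrated values are
discarded as invalid. Calibrated values enter matching as measurements but
are marked with their source.

A modelling time point must be complete: EDSS, the nine percentile
features and `age0`. Incomplete rows are excluded and counted, never
imputed further.

## The synthetic cohort generator

No individual-level data accompany the analysis (the study cohort is
available only on request), so the generator is a first-class module that
emulates the statistical structure the pipeline assumes. Defaults portray
the modelling cohort scale: 78 patients, half progressing, followed 5-10
years, clinical visits every 6 months, MRI every 12, cord scans at 80% of
MRI sessions, dates jittered by up to ±10 days.

* **Lesion accrual** is a homogeneous Poisson process per compartment with
  lognormal per-lesion volumes (sdlog 0.6), accumulated as a nondecreasing
  step function — lesions are punctate, permanent events. Three eras have
  different rates: the pre-baseline disease-duration era (gamma-distributed
  duration, mean 4 years, rates × 2) representing early, largely untreated
  disease; the observed relapsing-remitting phase (rates × 0.2, as treated
  stable cohorts accrue few new lesions); and, for progressing patients,
  the post-onset era (cord and infratentorial rates × 8). Onset falls
  uniformly in 20-50% of follow-up. Per-patient Dirichlet shares split
  each compartment across its named subcompartments.
* **Parenchymal decline** is geometric, $P(t) = P_0 (1-r)^t$, with
  per-patient rate heterogeneity (×0.6-1.4) and a ×2 acceleration after
  SPMS onset (reserve depletion); observation adds 0.2% multiplicative
  noise.
* **Disability** is an affine function of the weighted compartmental
  percentile signal,
  $\mathrm{EDSS}^* = \beta_0 + K\,\mathrm{age}_0 + s \sum_k w_k\,\mathrm{pct}_k \big/ \textstyle\sum_k w_k$,
  with $w = (3.8, 2.5, 1)$ for cord/infra/cereb, $s$ = 6.5 EDSS units,
  $\beta_0 = -1.2$, $K = 0.02$/yr. The percentile signal is the Hazen rank
  of the true (noise-free) LPF pooled over the generated cohort, or of
  parenchymal loss under the alternative `edss_link = "pv"`. Observed EDSS
  adds Gaussian noise (SD 0.35, a free parameter of the generator — the
  within-patient measurement noise of EDSS is not characterized by the
  source analysis; 0.35 sits below the half-step grid resolution and near
  reported inter-rater variability), clips to [0, 10] and snaps to the
  EDSS grid $\{0\} \cup \{1.0, 1.5, \ldots, 10\}$. Because the weighted
  sum of percentiles spans $[0, 100\sum_k w_k]$, an overall scale $s$ is
  required to land on the EDSS range; only the weight *ratios* are
  therefore identifiable by the decoding models, and recovery is assessed
  on ratios.
* **Functional systems** follow the compartment shares of the latent
  signal: pyramidal, sensory and bowel/bladder track the cord term;
  brainstem and cerebellar the infratentorial term; mental the cerebral
  term; the leading system of the dominant compartment is scaled to track
  EDSS nearly one-to-one, secondary systems lag. The visual score has no
  MRI correlate and is a stable per-patient value. Ambulation is flagged
  at EDSS ≥ 4.5.
* **Relapses** are flags on clinical visits (no EDSS spikes are added):
  rate 0.3/year, restricted to the pre-onset span for progressing patients
  — progression is relapse-free by construction.

With noise at zero and quantization off, pooled EDSS is *exactly* affine
in the weighted percentile signal (R² = 1 by construction), and when the
clinical and MRI schedules coincide the feature table reproduces that
signal exactly, so leave-one-patient-out folds recover the weight ratios
to machine precision. What passing tests show about real data is
correspondingly limited: the generator draws EDSS from the very link the
LPF model fits, so model-ranking results on synthetic cohorts demonstrate
self-consistency of the pipeline, not clinical validity of the metric;
it also omits scanner bias beyond an identity label, relapse-associated
EDSS spikes, segmentation error, and thoracic cord disease.

## Phenotype classification

A patient is called progressing when either pathway fires, always
relapse-free (no relapse 90 days before to 30 days after the event) and
confirmed at the next visit at least 3 months later:

* **EDSS pathway**: a new running-maximum EDSS exceeding 4 and exceeding
  the baseline EDSS by 1.0 (0.5 if baseline ≥ 6) — the conventional
  standardized-definition reading;
* **FSS pathway**: any functional system rising by ≥ 2 steps over its
  baseline, with the confirmed score reaching at least 3. The floor is
  this package's interpretation: a two-step excursion landing in the mild
  range (0-2) is within the measurement variability of low scores and
  does not mark progressive worsening.

Events are restricted to new running maxima so that the relapse veto is
total: every event visit is a strict increase over the previous visit, so
flagging a relapse at every increase suppresses every call. Onset is
dated to the first relapse-free increase in EDSS or any FSS. The 3-month
confirmation, the 90/30-day attribution window and both floors are
configurable; all are documented interpretations of criteria the source
describes only by citation.

## Numerical and design choices

* Ordinary least squares is solved by QR with an explicit rank check;
  a rank-deficient training fold is skipped with a warning naming the
  collinear terms.
* Quantization to the EDSS grid snaps to the nearest point; exact
  midpoints resolve to the lower value.
* Degenerate coefficient distributions (zero variance across folds) are
  reported as a point mass rather than a kernel density; otherwise the
  density uses a Gaussian kernel with Silverman's bandwidth.
* Model comparison restricts all models to the intersection of rows
  complete for every model's terms, so rankings cannot be driven by
  differing completeness.
* Predictions are not clipped to [0, 10] before metric computation
  (clipping is available as an option).
* Percentile columns with fewer than two observed values are wholly
  missing, which excludes the affected rows from modelling rather than
  fabricating a rank.
* The four-panel figure conserves its stack exactly: subcompartment band
  heights are renormalized shares of the compartment contribution, so the
  bands sum to the weighted top line at every date; lesion bars appear
  only at provenance-`measured` MRI dates; intervals before the first
  cord measurement are greyed as missing data.

## Problem sizes used by the test suite

Simulation-based properties run on deliberately small instances chosen
once: 20-patient cohorts over 20 seeds for phenotype recovery, weight
ordering and model ranking; a single 200-patient noise-free cohort for
exact weight recovery; 1000 random instances (n ≤ 30) for the metric
oracles; 2000 simulated scanner pairs (n = 50 each) for the
Kolmogorov-Smirnov calibration. The acceptance script runs the default
78-patient cohort.

## Known limitations

The generator's phenotype separation rests on era-dependent lesion rates;
cohorts whose non-progressing patients accrue lesions as fast as their
pre-baseline era will show lower classification specificity. Cord LPF
units are unnormalized (ml/mm²), so raw cord LPF values are not
comparable across studies — only their within-sample percentiles are.
Percentiles derived from a 78-patient sample are coarse (resolution about
1.3 points at a single time point's rank); a normative external reference
population would be preferable but none exists for cord lesion measures.
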