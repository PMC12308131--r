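# Linear EDSS-decoding models under leave-one-patient-out cross-validation.
#
#   LPF:  EDSS ~ LPFpct_cereb + LPFpct_infra + LPFpct_cord + age0
#   LPV:  EDSS ~ Lpct_* + Ppct_* (3 compartments each) + age0
#   LV:   EDSS ~ Lpct_* + age0
#   PV:   EDSS ~ Ppct_* + age0
#
# Predictors are the percentile-transformed features. An intercept is
# included by default: percentile predictors have mean about 50, so an
# intercept-free fit would be badly biased; `intercept = FALSE` reproduces
# the literal model equations.

MODEL_NAMES <- c("LPF", "LPV", "LV", "PV")

#' Terms of an EDSS-decoding model
#'
#' @param model One of `"LPF"`, `"LPV"`, `"LV"`, `"PV"`; brain-only
#'   (cordless) variants are available as `"LPF_brain"`, `"LPV_brain"`,
#'   `"LV_brain"`, `"PV_brain"`.
#' @return Character vector of feature-column names (excluding intercept).
#' @export
model_terms <- function(model) {
  base <- switch(
    sub("_brain$", "", model),
    LPF = paste0("lpf_pct_", c("cereb", "infra", "cord")),
    LPV = as.vector(rbind(paste0("l_pct_", c("cereb", "infra", "cord")),
                          paste0("p_pct_", c("cereb", "infra", "cord")))),
    LV = paste0("l_pct_", c("cereb", "infra", "cord")),
    PV = paste0("p_pct_", c("cereb", "infra", "cord")),
    stop("unknown model: ", model, call. = FALSE)
  )
  if (grepl("_brain$", model)) {
    base <- base[!grepl("_cord$", base)]
  }
  c(base, "age0")
}

#' Build the design matrix for a model
#'
#' @param features Feature table from [build_feature_table()].
#' @param model Model name (see [model_terms()]).
#' @param intercept Include an intercept column.
#' @return List with `X` (matrix), `y` (measured EDSS), `row_index` (rows of
#'   `features` used) and `terms`.
#' @export
build_design <- function(features, model = "LPF", intercept = TRUE) {
  terms <- model_terms(model)
  missing_cols <- setdiff(terms, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  usable <- stats::complete.cases(features[c(terms, "edss")])
  if (!any(usable)) {
    stop("no usable rows for model ", model, call. = FALSE)
  }
  X <- as.matrix(features[usable, terms])
  if (intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  list(X = X, y = features$edss[usable], row_index = which(usable),
       terms = terms)
}

#' Ordinary least squares with an explicit rank check
#'
#' @param X Design matrix (full column rank required).
#' @param y Response vector.
#' @return Named coefficient vector.
#' @export
fit_least_squares <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.vector(qr.coef(qr_x, y)), colnames(X))
}

#' Leave-one-patient-out cross-validation of an EDSS model
#'
#' One fold per patient: the model is fitted on all other patients' time
#' points and applied to every usable time point of the held-out patient.
#' The fitted coefficients of each fold are recorded, giving per-term
#' coefficient distributions with as many values as patients.
#'
#' @inheritParams build_design
#' @param clip Clip predictions to \[0, 10\] (off by default).
#' @return List with `predictions` (tibble `patient_id`, `date`, `edss`,
#'   `edss_hat`), `coefficients` (tibble, one row per fold keyed by
#'   `held_out_patient_id`), `model`, `terms`.
#' @export
loo_cv <- function(features, model = "LPF", intercept = TRUE, clip = FALSE) {
  terms <- model_terms(model)
  usable <- stats::complete.cases(features[c(terms, "edss")])
  feat <- features[usable, ]
  patients <- sort(unique(feat$patient_id))
  if (length(patients) < 3) {
    stop("leave-one-patient-out needs at least 3 patients", call. = FALSE)
  }
  preds <- vector("list", length(patients))
  coefs <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    pid <- patients[i]
    train <- feat[feat$patient_id != pid, ]
    test <- feat[feat$patient_id == pid, ]
    X_tr <- as.matrix(train[, terms])
    X_te <- as.matrix(test[, terms])
    if (intercept) {
      X_tr <- cbind(`(Intercept)` = 1, X_tr)
      X_te <- cbind(`(Intercept)` = 1, X_te)
    }
    beta <- tryCatch(fit_least_squares(X_tr, train$edss), error = function(e) {
      warning("fold for patient ", pid, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(beta)) next
    y_hat <- as.vector(X_te %*% beta)
    if (clip) y_hat <- pmin(pmax(y_hat, 0), 10)
    preds[[i]] <- tibble::tibble(patient_id = pid, date = test$date,
                                 edss = test$edss, edss_hat = y_hat)
    coefs[[i]] <- tibble::tibble(held_out_patient_id = pid,
                                 !!!as.list(beta))
  }
  list(predictions = dplyr::bind_rows(preds),
       coefficients = dplyr::bind_rows(coefs),
       model = model, terms = terms)
}

#' Root mean squared error
#' @param y,y_hat Numeric vectors of equal length (at least 2).
#' @return RMSE.
#' @export
rmse <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  sqrt(mean((y - y_hat)^2))
}

#' Pearson correlation between measured and estimated scores
#' @inheritParams rmse
#' @return Correlation in \[-1, 1\]; zero variance in either input is an
#'   error.
#' @export
pearson_r <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) {
    stop("pearson correlation undefined for zero-variance input",
         call. = FALSE)
  }
  stats::cor(y, y_hat)
}

#' Mean absolute error without patient bias
#'
#' Per patient, the mean signed error (bias) over that patient's time
#' points is subtracted from the patient's errors; the mean absolute value
#' of the centred errors, over all time points, measures how well relative
#' within-patient changes are matched.
#'
#' @inheritParams rmse
#' @param patient_id Patient identifier per row.
#' @return Nonnegative scalar.
#' @export
mae_without_patient_bias <- function(y, y_hat, patient_id) {
  stopifnot(length(y) == length(y_hat), length(y) == length(patient_id))
  err <- y_hat - y
  bias <- tapply(err, patient_id, mean)
  mean(abs(err - unname(bias[as.character(patient_id)])))
}

#' Evaluate pooled held-out predictions
#'
#' @param loo Result of [loo_cv()].
#' @return One-row tibble: `model`, `pearson_r`, `rmse`, `mae_no_bias`,
#'   `n_timepoints`, `n_patients`.
#' @export
evaluate_predictions <- function(loo) {
  p <- loo$predictions
  tibble::tibble(
    model = loo$model,
    pearson_r = pearson_r(p$edss, p$edss_hat),
    rmse = rmse(p$edss, p$edss_hat),
    mae_no_bias = mae_without_patient_bias(p$edss, p$edss_hat, p$patient_id),
    n_timepoints = nrow(p),
    n_patients = length(unique(p$patient_id))
  )
}

#' Summarize compartmental coefficient distributions across folds
#'
#' Means and SDs of the three compartmental coefficients over the
#' cross-validation folds, their ratios with the cerebral mean set to 1,
#' and a Gaussian kernel density estimate per compartment (Silverman
#' bandwidth) for plotting.
#'
#' @param fold_coefficients The `coefficients` tibble of [loo_cv()].
#' @param model Model whose compartmental terms to summarize; for LPV the
#'   lesion-volume terms are used.
#' @return List with `summary` (tibble `compartment`, `term`, `mean`, `sd`,
#'   `ratio_vs_cereb`) and `density` (per-compartment tibbles `x`, `y`; a
#'   degenerate distribution yields a single-point spike).
#' @export
summarize_coefficients <- function(fold_coefficients, model = "LPF") {
  if (nrow(fold_coefficients) < 2) {
    stop("need at least 2 folds to summarize coefficients", call. = FALSE)
  }
  family <- switch(sub("_brain$", "", model),
                   LPF = "lpf_pct_", LV = "l_pct_", LPV = "l_pct_",
                   PV = "p_pct_")
  comps <- intersect(COMPARTMENTS,
                     sub(family, "",
                         grep(paste0("^", family),
                              names(fold_coefficients), value = TRUE)))
  terms <- paste0(family, comps)
  means <- vapply(terms, function(tm) mean(fold_coefficients[[tm]]),
                  numeric(1))
  sds <- vapply(terms, function(tm) stats::sd(fold_coefficients[[tm]]),
                numeric(1))
  cereb_mean <- if ("cereb" %in% comps) means[paste0(family, "cereb")] else NA
  ratios <- if (!is.na(cereb_mean) && cereb_mean != 0) {
    means / cereb_mean
  } else {
    rep(NA_real_, length(means))
  }
  dens <- lapply(terms, function(tm) {
    v <- fold_coefficients[[tm]]
    if (stats::sd(v) == 0) {
      tibble::tibble(x = v[1], y = Inf) # degenerate spike
    } else {
      d <- stats::density(v, bw = "nrd0")
      tibble::tibble(x = d$x, y = d$y)
    }
  })
  names(dens) <- comps
  list(
    summary = tibble::tibble(compartment = comps, term = terms,
                             mean = unname(means), sd = unname(sds),
                             ratio_vs_cereb = unname(ratios)),
    density = dens
  )
}

#' Fit and rank all EDSS-decoding models on identical time points
#'
#' Restricts the feature table to rows complete for every model's terms
#' (so models are compared on identical time points), runs
#' leave-one-patient-out cross-validation for each model, and ranks the
#' evaluation reports by RMSE.
#'
#' @param features Feature table from [build_feature_table()].
#' @param models Model names (default the four standard models).
#' @inheritParams build_design
#' @return List with `evaluation` (tibble ranked by RMSE), `fits` (named
#'   list of [loo_cv()] results) and `n_shared_rows`.
#' @export
compare_models <- function(features, models = MODEL_NAMES,
                           intercept = TRUE) {
  all_terms <- unique(unlist(lapply(models, model_terms)))
  shared <- stats::complete.cases(features[c(all_terms, "edss")])
  feat <- features[shared, ]
  fits <- lapply(stats::setNames(models, models), function(m) {
    loo_cv(feat, model = m, intercept = intercept)
  })
  evaluation <- dplyr::bind_rows(lapply(fits, evaluate_predictions))
  evaluation <- evaluation[order(evaluation$rmse), ]
  evaluation$rank_rmse <- rank(evaluation$rmse)
  evaluation$rank_pearson <- rank(-evaluation$pearson_r)
  evaluation$rank_mae_no_bias <- rank(evaluation$mae_no_bias)
  list(evaluation = evaluation, fits = fits, n_shared_rows = nrow(feat))
}
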