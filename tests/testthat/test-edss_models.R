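# Hand-built feature tables let the model layer be tested independently of
# the simulator.
toy_features <- function(n_patients = 5, rows_per_patient = 8, seed = 1,
                         beta = c(intercept = 0.5, lpf_pct_cereb = 0.01,
                                  lpf_pct_infra = 0.025, lpf_pct_cord = 0.038,
                                  age0 = 0.02),
                         noise_sd = 0) {
  set.seed(seed)
  n <- n_patients * rows_per_patient
  f <- tibble::tibble(
    patient_id = rep(sprintf("P%02d", seq_len(n_patients)),
                     each = rows_per_patient),
    date = rep(as.Date("2015-01-01") + seq_len(rows_per_patient) * 180,
               n_patients),
    age0 = rep(runif(n_patients, 25, 55), each = rows_per_patient),
    lpf_pct_cereb = runif(n, 0, 100),
    lpf_pct_infra = runif(n, 0, 100),
    lpf_pct_cord = runif(n, 0, 100),
    l_pct_cereb = runif(n, 0, 100), l_pct_infra = runif(n, 0, 100),
    l_pct_cord = runif(n, 0, 100),
    p_pct_cereb = runif(n, 0, 100), p_pct_infra = runif(n, 0, 100),
    p_pct_cord = runif(n, 0, 100)
  )
  f$edss <- beta[["intercept"]] +
    beta[["lpf_pct_cereb"]] * f$lpf_pct_cereb +
    beta[["lpf_pct_infra"]] * f$lpf_pct_infra +
    beta[["lpf_pct_cord"]] * f$lpf_pct_cord +
    beta[["age0"]] * f$age0 + rnorm(n, 0, noise_sd)
  f
}

test_that("model specifications carry the expected terms", {
  expect_length(model_terms("LPF"), 4)
  expect_length(model_terms("LPV"), 7)
  expect_length(model_terms("LV"), 4)
  expect_length(model_terms("PV"), 4)
  expect_false(any(grepl("cord", model_terms("LPF_brain"))))
  expect_error(model_terms("XX"), "unknown model")
})

test_that("design matrices have the right shape and drop incomplete rows", {
  f <- toy_features()
  d <- build_design(f, "LPF")
  expect_equal(ncol(d$X), 5) # intercept + 4 terms
  expect_equal(nrow(d$X), nrow(f))
  d2 <- build_design(f, "LPV")
  expect_equal(ncol(d2$X), 8)
  f$lpf_pct_cord[3] <- NA
  d3 <- build_design(f, "LPF")
  expect_equal(nrow(d3$X), nrow(f) - 1)
  expect_false(3 %in% d3$row_index)
  f$edss <- NA
  expect_error(build_design(f, "LPF"), "no usable rows")
})

test_that("least squares is exact on exact data and detects collinearity", {
  set.seed(2)
  x <- runif(30)
  X <- cbind(`(Intercept)` = 1, x1 = x)
  y <- 0.5 + 2 * x
  beta <- fit_least_squares(X, y)
  expect_equal(unname(beta), c(0.5, 2), tolerance = 1e-12)
  Xdup <- cbind(X, x2 = x)
  expect_error(fit_least_squares(Xdup, y), "collinear")
})

test_that("noise-orthogonal responses give near-zero coefficients", {
  set.seed(3)
  n <- 5000
  X <- cbind(`(Intercept)` = 1, x1 = runif(n), x2 = runif(n))
  y <- rnorm(n)
  beta <- fit_least_squares(X, y)
  # normal-equations oracle
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(beta), as.vector(oracle), tolerance = 1e-10)
  sigma2 <- sum((y - X %*% oracle)^2) / (n - 3)
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  expect_true(all(abs(beta[-1]) < 3 * se[-1]))
})

test_that("leave-one-patient-out produces one fold per patient", {
  f <- toy_features(n_patients = 6, noise_sd = 0.3)
  cv <- loo_cv(f, "LPF")
  expect_equal(nrow(cv$coefficients), 6)
  expect_setequal(cv$coefficients$held_out_patient_id,
                  unique(f$patient_id))
  expect_equal(nrow(cv$predictions), nrow(f))
  expect_error(loo_cv(f[f$patient_id %in% c("P01", "P02"), ], "LPF"),
               "at least 3")
})

test_that("identical patients give identical folds; permutation-invariant", {
  one <- toy_features(n_patients = 1, rows_per_patient = 10, seed = 5,
                      noise_sd = 0.2)
  trip <- dplyr::bind_rows(
    one,
    dplyr::mutate(one, patient_id = "P92"),
    dplyr::mutate(one, patient_id = "P93")
  )
  # without an intercept the constant age0 column stays full rank
  cv <- loo_cv(trip, "LPF", intercept = FALSE)
  co <- as.matrix(cv$coefficients[, -1])
  expect_equal(co[1, ], co[2, ], tolerance = 1e-10)
  expect_equal(co[2, ], co[3, ], tolerance = 1e-10)

  f <- toy_features(n_patients = 5, noise_sd = 0.3, seed = 6)
  ref <- loo_cv(f, "LPF")
  set.seed(7)
  shuf <- loo_cv(f[sample(nrow(f)), ], "LPF")
  p_ref <- ref$predictions[order(ref$predictions$patient_id,
                                 ref$predictions$date), ]
  p_shuf <- shuf$predictions[order(shuf$predictions$patient_id,
                                   shuf$predictions$date), ]
  expect_equal(as.data.frame(p_ref), as.data.frame(p_shuf),
               tolerance = 1e-10)
})

test_that("evaluation metrics match their definitions", {
  y <- c(0, 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(pearson_r(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(rmse(c(0, 1), c(1, 0)), 1)
  expect_equal(pearson_r(c(0, 1), c(1, 0)), -1)
  expect_error(pearson_r(c(1, 1), c(0, 1)), "zero-variance")
  set.seed(8)
  a <- rnorm(10)
  b <- rnorm(10)
  expect_equal(rmse(a, b), brute_rmse(a, b), tolerance = 1e-12)
  expect_equal(pearson_r(a, b), brute_pearson(a, b), tolerance = 1e-12)
})

test_that("patient-bias removal matches the hand computation", {
  expect_equal(mae_without_patient_bias(c(1, 2, 3), c(3, 4, 5),
                                        rep("A", 3)), 0)
  y <- c(0, 0, 0, 0)
  yh <- c(1, -1, 2, 0)
  id <- c("A", "A", "B", "B")
  expect_equal(mae_without_patient_bias(y, yh, id), 1.0)
  expect_equal(mae_without_patient_bias(y, y, id), 0)
  # constant per-patient error: bias-free MAE 0, plain MAE = mean |bias|
  y2 <- rep(0, 4)
  yh2 <- c(2, 2, -1, -1)
  expect_equal(mae_without_patient_bias(y2, yh2, id), 0)
  expect_equal(mean(abs(yh2 - y2)), 1.5)
  set.seed(9)
  a <- rnorm(20)
  b <- rnorm(20)
  ids <- sample(c("A", "B", "C"), 20, replace = TRUE)
  expect_equal(mae_without_patient_bias(a, b, ids),
               brute_mae_nobias(a, b, ids), tolerance = 1e-12)
})

test_that("coefficient summaries report compartment ratios against cereb", {
  co <- tibble::tibble(
    held_out_patient_id = sprintf("P%02d", 1:10),
    `(Intercept)` = 0,
    lpf_pct_cereb = 0.5 + c(-.02, .02, 0, -.01, .01, 0, 0, 0, .005, -.005),
    lpf_pct_infra = 1.25 + rep(0, 10),
    lpf_pct_cord = 1.9 + rep(0, 10),
    age0 = 0.02
  )
  # centre the cereb draws so the mean is exactly 0.5
  co$lpf_pct_cereb <- co$lpf_pct_cereb - mean(co$lpf_pct_cereb) + 0.5
  s <- summarize_coefficients(co, "LPF")
  r <- s$summary
  expect_equal(r$ratio_vs_cereb[r$compartment == "cereb"], 1)
  expect_equal(r$ratio_vs_cereb[r$compartment == "infra"], 2.5)
  expect_equal(r$ratio_vs_cereb[r$compartment == "cord"], 3.8)
  # degenerate distribution collapses to a spike
  expect_equal(nrow(s$density$cord), 1)
  expect_gt(nrow(s$density$cereb), 1)
})

test_that("pure-noise EDSS yields near-zero pooled correlation", {
  set.seed(10)
  f <- toy_features(n_patients = 30, rows_per_patient = 60, seed = 10)
  f$edss <- rnorm(nrow(f)) # sever the link
  cv <- loo_cv(f, "LPF")
  r <- pearson_r(cv$predictions$edss, cv$predictions$edss_hat)
  expect_lt(abs(r), 0.1)
})

test_that("model comparison evaluates all models on identical rows", {
  f <- toy_features(n_patients = 8, noise_sd = 0.4, seed = 11)
  f$p_pct_cord[5] <- NA # incomplete for PV/LPV only
  cmp <- compare_models(f)
  expect_equal(nrow(cmp$evaluation), 4)
  expect_equal(cmp$n_shared_rows, nrow(f) - 1)
  expect_equal(unique(cmp$evaluation$n_timepoints), nrow(f) - 1)
  # reports survive a serialization round-trip
  json <- jsonlite::toJSON(cmp$evaluation, digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$rmse, cmp$evaluation$rmse, tolerance = 1e-12)
})
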