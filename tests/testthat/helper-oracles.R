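# Independent brute-force oracles: direct-summation / pairwise-comparison
# implementations kept deliberately separate from the package's code paths.

brute_hazen <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  for (i in which(ok)) {
    r <- sum(x[ok] < x[i]) + (sum(x[ok] == x[i]) + 1) / 2
    out[i] <- 100 * (r - 0.5) / n
  }
  out
}

brute_ks <- function(x, y) {
  pool <- sort(unique(c(x, y)))
  max(abs(vapply(pool, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

brute_rmse <- function(y, yh) sqrt(sum((y - yh)^2) / length(y))

brute_pearson <- function(y, yh) {
  dy <- y - mean(y)
  dh <- yh - mean(yh)
  sum(dy * dh) / sqrt(sum(dy^2) * sum(dh^2))
}

brute_mae_nobias <- function(y, yh, id) {
  err <- yh - y
  tot <- 0
  for (p in unique(id)) {
    e <- err[id == p]
    tot <- tot + sum(abs(e - mean(e)))
  }
  tot / length(y)
}

# Small cohorts keep the simulation-heavy tests fast.
small_config <- function(n_patients = 8, seed = 1, ...) {
  cohort_config(n_patients = n_patients, seed = seed, ...)
}
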