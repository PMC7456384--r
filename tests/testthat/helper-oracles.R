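# fixtures and independent brute-force oracles shared across test files

# small deterministic sample: 3 event times for cause 1, ties, censoring
toy_sample <- function() {
  crs_sample(
    time = c(1, 1, 2, 2.5, 3, 3.5, 4, 5, 6, 7),
    cause = c(1, 0, 1, 2, 1, 0, 2, 1, 0, 0),
    marker = c(2.1, 0.3, 1.8, 0.9, 2.4, 1.1, 0.5, 1.9, 0.7, 1.4))
}

random_sample <- function(n = 30, j_max = 2) {
  crs_sample(
    time = round(stats::rexp(n, 0.5) + 0.05, 2),
    cause = sample(0:j_max, n, replace = TRUE),
    marker = round(stats::rnorm(n), 2),
    n_causes = j_max)
}

# brute-force observed rank AUC: plain double loop over pairs
brute_rank_auc <- function(sample, t, j) {
  ci <- which(sample$time == t & sample$cause == j)
  ki <- which(sample$time > t)
  if (!length(ci) || !length(ki)) return(NA_real_)
  conc <- 0
  for (i in ci) for (k in ki) conc <- conc + (sample$marker[i] > sample$marker[k])
  conc / (length(ci) * length(ki))
}

# brute-force weighted leave-one-out bandwidth criterion (mirrors the
# documented definition with explicit loops)
brute_cv_criterion <- function(sample, j, h) {
  ev <- csAUC:::event_rank_aucs(sample, j, "discordant")
  ev <- ev[!is.na(ev$auc), , drop = FALSE]
  num <- 0; den <- 0
  for (k in seq_len(nrow(ev))) {
    nb <- which(abs(ev$time - ev$time[k]) < h & seq_len(nrow(ev)) != k)
    if (!length(nb)) next
    pred <- mean(ev$auc[nb])
    num <- num + ev$n_controls[k] * (pred - ev$auc[k])^2
    den <- den + ev$n_controls[k]
  }
  if (den == 0) Inf else num / den
}

# finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(l) {
    e <- rep(0, length(x)); e[l] <- h * max(1, abs(x[l]))
    (f(x + e) - f(x - e)) / (2 * e[l])
  }, numeric(1))
}

expect_no_na <- function(x) expect_false(anyNA(x))
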