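# local weighted-mean-rank estimator and bandwidth selection

test_that("cWMR is the mean of observed rank AUCs over the neighbourhood", {
  s <- toy_sample()
  # singleton neighbourhood collapses to the observed rank AUC
  expect_equal(cwmr_at(s, 2, 1, h = 0.4), observed_rank_auc(s, 2, 1))
  # wider window averages the member AUCs equally
  a <- vapply(c(1, 2, 3), function(t) observed_rank_auc(s, t, 1), numeric(1))
  expect_equal(cwmr_at(s, 2, 1, h = 1.5), mean(a))
  expect_error(cwmr_at(s, 0.2, 1, h = 0.1), "bandwidth")
})

test_that("bandwidth limits recover the local and global averages", {
  set.seed(3)
  s <- random_sample(50)
  ev <- csAUC:::event_rank_aucs(s, 1, "discordant")
  ev <- ev[!is.na(ev$auc), ]
  # h -> Inf: constant in t, equal to the grand mean of the A's
  big <- diff(range(s$time)) + 1
  for (t in ev$time[c(1, nrow(ev))])
    expect_equal(cwmr_at(s, t, 1, h = big), mean(ev$auc))
  # h -> 0 at an event time: the unsmoothed A itself
  t1 <- ev$time[2]
  gap <- min(abs(ev$time[-2] - t1))
  expect_equal(cwmr_at(s, t1, 1, h = gap / 2), ev$auc[ev$time == t1])
})

test_that("cWMR is rank-based: invariant under monotone marker maps", {
  set.seed(13)
  s <- random_sample(60)
  s2 <- crs_sample(time = s$time, cause = s$cause,
                   marker = atan(s$marker) * 10 + 3, n_causes = 2)
  t <- sort(s$time[s$cause == 1])[3]
  expect_equal(cwmr_at(s, t, 1, 1), cwmr_at(s2, t, 1, 1))
})

test_that("cross-validated bandwidth selection matches its definition", {
  # a grid of one value leaves no choice
  set.seed(21)
  s <- random_sample(40)
  expect_equal(as.numeric(select_bandwidth(s, 1, grid = 0.7)), 0.7)
  # criterion equals the brute-force weighted leave-one-out evaluation
  set.seed(22)
  repeat {   # need a sample with ~20 cause-1 event times
    s <- random_sample(60)
    if (sum(s$cause == 1) >= 18) break
  }
  grid <- c(0.3, 0.8, 1.6)
  h <- select_bandwidth(s, 1, grid = grid)
  crit <- attr(h, "criterion")
  for (i in seq_along(grid))
    expect_equal(unname(crit[i]), brute_cv_criterion(s, 1, grid[i]))
  expect_equal(as.numeric(h), grid[which.min(crit)])
})

test_that("constant observed AUCs make every candidate tie; smallest wins", {
  # markers decrease with event time, so every case outranks its whole
  # riskset and A = 1 at every event time
  s <- crs_sample(time = c(1, 2, 3, 4, 10, 11, 12),
                  cause = c(1, 1, 1, 1, 0, 0, 0),
                  marker = c(9, 8, 7, 6, 1, 2, 3))
  h <- select_bandwidth(s, 1, grid = c(1.5, 2, 3))
  expect_equal(as.numeric(h), 1.5)
  expect_true(all(attr(h, "criterion") == 0))
})

test_that("the curve object respects its pointwise contracts", {
  set.seed(31)
  s <- simulate_crs(scenario_config("S1"), n = 250, seed = 5)
  tt <- exp(seq(-1.2, 0.2, 0.35))
  cv <- cwmr(s, 1, times = tt, bandwidth = 0.25, ci_level = 0.9)
  expect_s3_class(cv, "auc_curve")
  expect_equal(nrow(cv), length(tt))
  ok <- !is.na(cv$estimate)
  expect_true(all(cv$lower[ok] <= cv$estimate[ok] + 1e-12))
  expect_true(all(cv$estimate[ok] <= cv$upper[ok] + 1e-12))
  expect_true(all(cv$lower[ok] >= 0 & cv$upper[ok] <= 1))
  expect_true(all(cv$se[ok] >= 0))
  expect_equal(attr(cv, "bandwidth"), 0.25)
  # CSV serialisation keeps the canonical columns
  f <- tempfile(fileext = ".csv")
  write_auc_curve(cv, f)
  got <- utils::read.csv(f)
  expect_named(got, c("time", "estimate", "se", "lo", "hi"))
  expect_equal(got$estimate, cv$estimate)
})
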