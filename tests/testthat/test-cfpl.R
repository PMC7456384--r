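# fractional polynomial basis, partial likelihood, score, fitting

test_that("the fractional polynomial basis evaluates exactly", {
  expect_equal(unname(fp_basis(1)), c(1, 1, 1, 1, 0, 1, 1, 1))
  expect_equal(unname(fp_basis(4)),
               c(1, 0.0625, 0.25, 0.5, log(4), 2, 4, 16))
  expect_error(fp_basis(0), "positive")
  expect_error(fp_basis(-2), "positive")
  X <- fp_basis(c(1, 4))
  expect_equal(dim(X), c(2L, 8L))
})

test_that("concordance records count pairs and partition the riskset", {
  s <- crs_sample(time = c(2, 3, 4, 5), cause = c(1, 0, 0, 0),
                  marker = c(2.5, 1.0, 3.0, 2.0))
  rec <- concordance_records(s, 1)
  expect_equal(rec$n_concordant, 2L)
  expect_equal(rec$n_discordant, 1L)
  # case below every control
  s <- crs_sample(time = c(1, 2, 3), cause = c(1, 0, 0),
                  marker = c(0, 1, 2))
  rec <- concordance_records(s, 1)
  expect_equal(unlist(rec[1, 2:3], use.names = FALSE), c(0L, 2L))
  # partition identity on random data; ties are discordant
  set.seed(61)
  for (rep in 1:20) {
    smp <- random_sample(25)
    rec <- concordance_records(smp, 1)
    for (r in seq_len(nrow(rec))) {
      nt <- sum(smp$time > rec$event_time[r])
      expect_equal(rec$n_concordant[r] + rec$n_discordant[r], nt)
    }
  }
})

test_that("the log partial likelihood matches direct evaluation", {
  rec <- data.frame(event_time = c(0.5, 2), n_concordant = c(3L, 1L),
                    n_discordant = c(1L, 4L))
  b0 <- rep(0, 8)
  expect_equal(log_partial_likelihood(rec, b0), 9 * log(0.5))
  b <- c(0.4, 0.01, -0.02, 0.03, -0.2, 0.1, 0.05, -0.01)
  p <- plogis(drop(fp_basis(c(0.5, 2)) %*% b))
  byhand <- 3 * log(p[1]) + 1 * log(1 - p[1]) +
    1 * log(p[2]) + 4 * log(1 - p[2])
  expect_equal(log_partial_likelihood(rec, b), byhand)
  # permutation invariance of the record list
  expect_equal(log_partial_likelihood(rec[2:1, ], b),
               log_partial_likelihood(rec, b))
})

test_that("the analytic score equals finite differences of the likelihood", {
  set.seed(71)
  for (rep in 1:12) {
    k <- sample(3:8, 1)
    rec <- data.frame(event_time = round(runif(k, 0.4, 2.5), 2),
                      n_concordant = rpois(k, 5),
                      n_discordant = rpois(k, 5))
    rec <- rec[rec$n_concordant + rec$n_discordant > 0, ]
    b <- rnorm(8, sd = 0.1)
    g <- cfpl_score(rec, b)
    g_fd <- fd_grad(function(x) log_partial_likelihood(rec, x), b)
    expect_equal(unname(g), g_fd, tolerance = 1e-6)
  }
})

test_that("intercept stationarity holds at the pooled binomial MLE", {
  set.seed(73)
  rec <- data.frame(event_time = runif(10, 0.5, 2),
                    n_concordant = rpois(10, 6) + 1L,
                    n_discordant = rpois(10, 4) + 1L)
  phat <- sum(rec$n_concordant) /
    sum(rec$n_concordant + rec$n_discordant)
  g <- cfpl_score(rec, c(qlogis(phat), rep(0, 7)))
  expect_equal(unname(g[1]), 0, tolerance = 1e-9)
})

test_that("a single shared event time saturates to the pooled fraction", {
  rec <- data.frame(event_time = rep(1.3, 4), n_concordant = c(5, 7, 2, 6),
                    n_discordant = c(3, 1, 4, 2))
  fit <- cfpl_fit_records(rec)
  p <- plogis(drop(fp_basis(1.3) %*% fit$coefficients))
  expect_equal(p, sum(rec$n_concordant) /
                 sum(rec$n_concordant + rec$n_discordant),
               tolerance = 1e-6)
})

test_that("the fitted model agrees with a weighted logistic GLM oracle", {
  s <- simulate_crs(scenario_config("S1"), n = 300, seed = 23)
  fit <- cfpl(s, 1, variance = FALSE)
  expect_true(fit$converged)
  rec <- fit$records
  Xs <- fp_basis(rec$event_time / fit$time_scale)
  glm_fit <- suppressWarnings(
    glm.fit(Xs, cbind(rec$n_concordant, rec$n_discordant),
            family = binomial()))
  p_glm <- glm_fit$fitted.values
  p_ours <- drop(plogis(Xs %*% fit$beta_std))
  expect_equal(p_ours, unname(p_glm), tolerance = 1e-5)
  # maximised likelihood is no worse than the GLM's
  ll_glm <- sum(rec$n_concordant * log(p_glm) +
                  rec$n_discordant * log(1 - p_glm))
  expect_gte(fit$log_lik, ll_glm - 1e-6)
})

test_that("the fit dominates the null and is invariant to marker maps", {
  s <- simulate_crs(scenario_config("S1"), n = 250, seed = 29)
  fit <- cfpl(s, 1, variance = FALSE)
  rec <- fit$records
  expect_gte(fit$log_lik, log_partial_likelihood(rec, rep(0, 8)))
  # strictly increasing marker transforms leave the rank counts, hence the
  # fitted curve, unchanged
  s2 <- crs_sample(time = s$time, cause = s$cause,
                   marker = exp(s$marker), n_causes = 2)
  fit2 <- cfpl(s2, 1, variance = FALSE)
  tt <- exp(seq(-1.2, 0.3, 0.3))
  expect_equal(as.numeric(predict(fit, tt)), as.numeric(predict(fit2, tt)),
               tolerance = 1e-6)
})

test_that("predictions respect the link and the intercept-only special case", {
  s <- simulate_crs(scenario_config("S1"), n = 200, seed = 31)
  fit <- cfpl(s, 1, variance = FALSE)
  p <- predict(fit, times = c(0.1, 1, 5))
  expect_true(all(p > 0 & p < 1))
  # null coefficients predict 1/2 everywhere; intercept-only is flat
  fit$beta_std <- rep(0, 8)
  expect_equal(unname(as.numeric(predict(fit, c(0.2, 1, 3)))), rep(0.5, 3))
  fit$beta_std <- c(qlogis(0.8), rep(0, 7))
  expect_equal(unname(as.numeric(predict(fit, c(0.2, 1, 3)))), rep(0.8, 3),
               tolerance = 1e-12)
})

test_that("simulated concordance counts have the model's binomial law", {
  s <- simulate_crs(scenario_config("S1"), n = 200, seed = 37)
  fit <- cfpl(s, 1, variance = FALSE)
  sims <- simulate(fit, nsim = 3, seed = 99)
  expect_length(sims, 3)
  tot <- fit$records$n_concordant + fit$records$n_discordant
  for (sm in sims) {
    expect_equal(sm$n_concordant + sm$n_discordant, tot)
    expect_true(all(sm$n_concordant >= 0))
  }
  # seeded reproducibility
  sims2 <- simulate(fit, nsim = 3, seed = 99)
  expect_identical(sims, sims2)
})
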