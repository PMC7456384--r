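# sandwich covariance and delta-method inference for the cFPL model

test_that("sigma2 is symmetric positive semi-definite at tested fits", {
  for (sd0 in c(43, 47)) {
    s <- simulate_crs(scenario_config("S1"), n = 250, seed = sd0)
    fit <- cfpl(s, 1)
    S2 <- fit$sigma2
    expect_equal(S2, t(S2), tolerance = 1e-10)
    # the k != k' double sum omits the squared diagonal, so exact finite-
    # sample PSD-ness is only up to a small numerical margin
    ev <- eigen(S2, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-4 * max(abs(ev)))
  }
})

test_that("sigma1 agrees with a finite-difference Jacobian of the score", {
  # the summed per-pair score is the score vector itself, so sigma1 must be
  # minus its Jacobian divided by n^2; check by central differences on a
  # well-conditioned small sample (times near 1)
  s <- simulate_crs(scenario_config("S1"), n = 150, seed = 53)
  n <- nrow(s)
  fit <- cfpl(s, 1)
  expect_true(fit$converged)
  rec <- fit$records
  beta <- coef(fit)
  J <- vapply(seq_len(8), function(l) {
    e <- rep(0, 8); e[l] <- 1e-6 * max(1, abs(beta[l]))
    (cfpl_score(rec, beta + e) - cfpl_score(rec, beta - e)) / (2 * e[l])
  }, numeric(8))
  S1_fd <- -(J + t(J)) / 2 / n^2
  expect_equal(unname(fit$sigma1), unname(S1_fd), tolerance = 1e-4)
})

test_that("delta-method variances are non-negative and CIs stay in (0,1)", {
  s <- simulate_crs(scenario_config("S1"), n = 300, seed = 59)
  fit <- cfpl(s, 1)
  tt <- exp(seq(-1.5, 0.5, 0.25))
  v <- cfpl_auc_variance(fit, tt)
  expect_true(all(v >= 0))
  cv <- predict(fit, times = tt, se.fit = TRUE, ci_level = 0.9)
  expect_true(all(cv$lower > 0 & cv$upper < 1))
  expect_true(all(cv$lower <= cv$estimate & cv$estimate <= cv$upper))
  expect_equal(cv$se, sqrt(v), tolerance = 1e-12)
  # response-scale intervals clip instead
  cv2 <- predict(fit, times = tt, se.fit = TRUE, ci_level = 0.9,
                 ci_scale = "response")
  expect_true(all(cv2$lower >= 0 & cv2$upper <= 1))
})

test_that("the coefficient covariance transforms exactly between scales", {
  s <- simulate_crs(scenario_config("S1"), n = 200, seed = 61)
  fit <- cfpl(s, 1)
  # the linear-predictor variance must be identical computed on either the
  # standardised or the original coefficient scale
  t0 <- 0.8
  x_raw <- fp_basis(t0)
  x_std <- fp_basis(t0 / fit$time_scale)
  v_raw <- drop(t(x_raw) %*% vcov(fit) %*% x_raw)
  v_std <- drop(t(x_std) %*% fit$vcov_std %*% x_std)
  expect_equal(v_raw, v_std, tolerance = 1e-6)
  # and the two coefficient vectors predict the same curve
  expect_equal(drop(x_raw %*% coef(fit)), drop(x_std %*% fit$beta_std),
               tolerance = 1e-8)
})

test_that("analytic SEs shrink with sample size at interior times", {
  v <- sapply(c(150, 600), function(n) {
    mean(sapply(1:6, function(k) {
      s <- simulate_crs(scenario_config("S1"), n = n, seed = 200 + k)
      fit <- cfpl(s, 1)
      cfpl_auc_variance(fit, exp(-0.6))
    }))
  })
  # ~1/n rate: quadrupling n should cut the average variance by roughly 4
  expect_lt(v[2], v[1])
  expect_gt(v[1] / v[2], 1.8)
})

test_that("curves beyond the data tail are refused cleanly at bad inputs", {
  s <- simulate_crs(scenario_config("S1"), n = 150, seed = 71)
  fit <- cfpl(s, 1)
  expect_error(predict(fit, times = c(-1, 1)), "positive")
  expect_error(cfpl_auc_variance(fit, 0), "positive")
  fit$vcov_std <- NULL
  expect_error(predict(fit, times = 1, se.fit = TRUE), "covariance")
})
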