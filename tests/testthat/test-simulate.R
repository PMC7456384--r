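# data generator, bootstrap machinery, study driver

test_that("simulation is seed-deterministic and leaves the RNG alone", {
  cfg <- scenario_config("S1")
  s1 <- simulate_crs(cfg, 100, seed = 5)
  s2 <- simulate_crs(cfg, 100, seed = 5)
  expect_identical(s1$time, s2$time)
  expect_identical(s1$marker, s2$marker)
  s3 <- simulate_crs(cfg, 100, seed = 6)
  expect_false(identical(s1$time, s3$time))
  # ambient RNG stream is restored
  set.seed(77); before <- rnorm(1)
  set.seed(77); invisible(simulate_crs(cfg, 50, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("large-sample moments match the generative law", {
  s <- simulate_crs(scenario_config("S1"), n = 1e5, seed = 2)
  ev1 <- s$cause == 1
  # corr(log T1, M) among cause-1 events is attenuated by selection, so
  # check the full latent draw through cause proportions and marginals
  expect_equal(mean(s$cause == 0), 1 / 3, tolerance = 0.02)
  expect_equal(mean(ev1), 1 / 3, tolerance = 0.02)
  expect_equal(mean(s$cause == 2), 1 / 3, tolerance = 0.02)
  expect_equal(mean(s$marker), 0, tolerance = 0.02)
  expect_equal(sd(s$marker), 1, tolerance = 0.02)
  # uncensored-and-cause-1 subjects observe T1: check the joint law via
  # the observed correlation on a fresh uncensored configuration
  cfg_nc <- scenario_config("S1",
                            competing_meanlog = 20, censor_meanlog = 20)
  s2 <- simulate_crs(cfg_nc, n = 1e5, seed = 3)
  expect_true(all(s2$cause == 1))
  expect_equal(cor(log(s2$time), s2$marker), -0.7, tolerance = 0.01)
  expect_equal(mean(log(s2$time)), 0, tolerance = 0.02)
  expect_equal(sd(log(s2$time)), 1, tolerance = 0.01)
  # mixture class frequency
  s4 <- simulate_crs(scenario_config("S2a"), n = 1e5, seed = 4)
  expect_equal(mean(attr(s4, "latent") == 1L), 0.2, tolerance = 0.01)
})

test_that("bootstrap SEs are seeded, and zero for a constant statistic", {
  s <- simulate_crs(scenario_config("S1"), n = 120, seed = 8)
  const <- function(sample, times) rep(0.7, length(times))
  se <- bootstrap_se(s, const, times = c(0.5, 1), B = 25, seed = 3)
  expect_equal(as.numeric(se), c(0, 0))
  expect_equal(attr(se, "boot_mean"), c(0.7, 0.7))
  est <- cwmr_estimator(1, bandwidth = 0.3)
  se1 <- bootstrap_se(s, est, times = exp(c(-1, -0.5)), B = 20, seed = 9)
  se2 <- bootstrap_se(s, est, times = exp(c(-1, -0.5)), B = 20, seed = 9)
  expect_identical(se1, se2)
  expect_true(all(se1 > 0))
})

test_that("failed bootstrap replicates are dropped and flagged", {
  s <- simulate_crs(scenario_config("S1"), n = 80, seed = 10)
  flaky <- local({
    k <- 0
    function(sample, times) {
      k <<- k + 1
      if (k %% 3 == 0) stop("no fit")
      rep(0.6, length(times)) + k / 100
    }
  })
  se <- bootstrap_se(s, flaky, times = 1, B = 12, seed = 2)
  expect_lt(attr(se, "n_used")[1], 12)
  expect_false(attr(se, "unreliable")[1])
  always_fail <- function(sample, times) stop("nope")
  expect_warning(bootstrap_se(s, always_fail, times = 1, B = 4, seed = 2),
                 "unreliable")
})

test_that("a small study run is well-formed and internally consistent", {
  rep <- run_study(scenario_config("S1"), n = 150, n_replicates = 4, B = 5,
                   grid = c(-1.2, -0.6, 0), method = "both", causes = 1:2,
                   nominal_level = 0.9, seed = 11)
  expect_s3_class(rep, "sim_report")
  expect_equal(nrow(rep), 2 * 2 * 3)
  expect_named(
    as.data.frame(rep),
    c("method", "cause", "log_time", "time", "true_auc", "mean",
      "mean_point", "arb", "bse", "se", "cp", "n_ok"))
  expect_equal(rep$arb, 100 * abs(rep$mean - rep$true_auc) / rep$true_auc)
  expect_true(all(rep$cp >= 0 & rep$cp <= 100, na.rm = TRUE))
  expect_true(all(rep$bse >= 0, na.rm = TRUE))
  # reproducible from the master seed
  rep2 <- run_study(scenario_config("S1"), n = 150, n_replicates = 4, B = 5,
                    grid = c(-1.2, -0.6, 0), method = "both", causes = 1:2,
                    nominal_level = 0.9, seed = 11)
  expect_equal(as.data.frame(rep), as.data.frame(rep2))
})
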