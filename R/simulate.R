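# ---- data generation, bootstrap, and the Monte-Carlo study driver ----------

# evaluate `expr` under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed streams below 2^31
.spawn_seeds <- function(seed, n, offset = 0L) {
  .with_seed(seed + offset, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a competing-risks sample from a scenario
#'
#' Draws `(log T^{(1)}, M)` from the scenario's bivariate normal (or
#' two-component mixture, latent class first), an independent lognormal
#' competing event time \eqn{T^{(2)}} and independent lognormal censoring
#' time \eqn{C}, and returns the observed data
#' \eqn{Z = \min(T^{(1)}, T^{(2)}, C)} with cause indicator 1, 2, or 0
#' (censored).  Fully reproducible from `seed`; the caller's RNG state is
#' untouched.
#'
#' @param config a [scenario_config()].
#' @param n number of subjects (>= 2).
#' @param seed optional integer seed.
#' @return A [crs_sample()] with `n_causes = 2` and attribute `"latent"`
#'   holding the component labels.
#' @examples
#' s <- simulate_crs(scenario_config("S1"), n = 100, seed = 7)
#' table(s$cause)
#' @export
simulate_crs <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (n < 2L) stop("'n' must be at least 2")
  .with_seed(seed, {
    k <- length(config$components)
    g <- if (k == 1L) rep(1L, n)
         else sample.int(k, n, replace = TRUE, prob = config$weights)
    mu1 <- vapply(config$components, `[[`, numeric(1), "mu1")[g]
    mu2 <- vapply(config$components, `[[`, numeric(1), "mu2")[g]
    s1 <- vapply(config$components, `[[`, numeric(1), "s1")[g]
    s2 <- vapply(config$components, `[[`, numeric(1), "s2")[g]
    rho <- vapply(config$components, `[[`, numeric(1), "rho")[g]
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    log_t1 <- mu1 + s1 * z1
    marker <- mu2 + s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
    t1 <- exp(log_t1)
    t2 <- stats::rlnorm(n, config$competing_meanlog, config$competing_sdlog)
    cc <- stats::rlnorm(n, config$censor_meanlog, config$censor_sdlog)
    z <- pmin(t1, t2, cc)
    cause <- ifelse(z == t1, 1L, ifelse(z == t2, 2L, 0L))
    out <- crs_sample(time = z, cause = cause, marker = marker,
                      n_causes = 2L)
    attr(out, "latent") <- g
    out
  })
}

#' Nonparametric bootstrap standard errors of an AUC estimator
#'
#' Resamples subjects with replacement `B` times, re-runs `estimator` on
#' each resample, and returns the per-time-point standard deviation of the
#' bootstrap estimates.  Resamples on which the estimator fails (error, or
#' `NA` at a point, e.g. an empty smoothing neighbourhood) are dropped
#' pointwise with a count kept in the attributes; a point with more than
#' half of its replicates missing is flagged unreliable.
#'
#' @param sample a [crs_sample()].
#' @param estimator `function(sample, times)` returning estimates at
#'   `times` (see [cwmr_estimator()] / [cfpl_estimator()]).
#' @param times evaluation times.
#' @param B number of bootstrap resamples (>= 2).
#' @param seed optional integer seed.
#' @return Numeric vector of bootstrap SEs with attributes `boot_mean`,
#'   `n_used` (replicates contributing per point) and `unreliable`.
#' @export
bootstrap_se <- function(sample, estimator, times, B, seed = NULL) {
  .assert_crs(sample)
  if (B < 2L) stop("'B' must be at least 2")
  n <- nrow(sample)
  seeds <- .spawn_seeds(if (is.null(seed)) 0L else seed, B)
  est <- matrix(NA_real_, B, length(times))
  for (b in seq_len(B)) {
    idx <- .with_seed(if (is.null(seed)) NULL else seeds[b],
                      sample.int(n, n, replace = TRUE))
    bs <- crs_sample(time = sample$time[idx], cause = sample$cause[idx],
                     marker = sample$marker[idx],
                     n_causes = n_causes(sample))
    est[b, ] <- tryCatch(
      suppressWarnings(as.numeric(estimator(bs, times))),
      error = function(e) rep(NA_real_, length(times)))
  }
  n_used <- colSums(!is.na(est))
  se <- apply(est, 2, stats::sd, na.rm = TRUE)
  se[n_used < 2L] <- NA_real_
  unreliable <- n_used < B / 2
  if (any(unreliable))
    warning(sum(unreliable), " point(s) had more than half of their ",
            "bootstrap replicates fail; their SEs are unreliable")
  attr(se, "boot_mean") <- colMeans(est, na.rm = TRUE)
  attr(se, "n_used") <- n_used
  attr(se, "unreliable") <- unreliable
  se
}

#' Estimator adapters for the study driver and the bootstrap
#'
#' Package the two estimators as plain `function(sample, times)` point
#' estimators for a fixed cause: `cwmr_estimator()` smooths with a fixed
#' bandwidth (or re-selects it by cross-validation when `bandwidth =
#' "cv"`), `cfpl_estimator()` refits the fractional polynomial model.
#'
#' @inheritParams cwmr
#' @return A function of `(sample, times)` returning estimates.
#' @export
cwmr_estimator <- function(cause, bandwidth, ties = "discordant") {
  force(cause); force(bandwidth); force(ties)
  function(sample, times) {
    h <- if (identical(bandwidth, "cv"))
      as.numeric(select_bandwidth(sample, cause, ties = ties))
    else bandwidth
    ev <- event_rank_aucs(sample, cause, ties)
    vapply(times, function(t) .cwmr_point(ev, t, h), numeric(1))
  }
}

#' @rdname cwmr_estimator
#' @export
cfpl_estimator <- function(cause) {
  force(cause)
  function(sample, times) {
    fit <- cfpl(sample, cause, variance = FALSE)
    as.numeric(predict(fit, times = times))
  }
}
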