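# ---- Monte-Carlo + bootstrap simulation study ------------------------------

#' Run a Monte-Carlo simulation study of the AUC estimators
#'
#' Generates `n_replicates` competing-risks datasets of size `n` from
#' `config`, estimates the cause-specific AUC on the time grid with the
#' requested method(s) for each cause, and summarises per grid point:
#'
#' * `true_auc` -- the exact truth from [true_auc()];
#' * `mean` -- Monte-Carlo average of the per-replicate estimate (the
#'   average of bootstrap means when `B > 0`, the table-comparison reading);
#' * `mean_point` -- average of the raw point estimates;
#' * `arb` -- absolute relative bias, `100 |mean - true| / true`;
#' * `bse` -- average bootstrap standard error over replicates (`B > 0`);
#' * `se` -- average model-based (analytic) standard error;
#' * `cp` -- empirical coverage (%) of the nominal-level model-based
#'   confidence intervals.
#'
#' cWMR bandwidths are re-selected by leave-one-out cross-validation within
#' every replicate (and held fixed across that replicate's bootstrap
#' resamples); cFPL confidence intervals are built on the linear-predictor
#' scale.  A master seed spawns independent per-replicate and per-bootstrap
#' streams, so any report is reproducible from its seed.
#'
#' @param config a [scenario_config()].
#' @param n subjects per replicate.
#' @param n_replicates Monte-Carlo replicates.
#' @param B bootstrap resamples per replicate (0 = no bootstrap).
#' @param grid evaluation grid on the `log(t)` scale.
#' @param method `"both"`, `"cwmr"`, or `"cfpl"`.
#' @param causes causes to estimate.
#' @param nominal_level confidence level for the coverage summary.
#' @param seed master seed.
#' @param progress print a dot per replicate.
#' @return A data frame of class `"sim_report"`, one row per
#'   (method, cause, grid point), with the study settings in attributes.
#' @examples
#' \donttest{
#' rep <- run_study(scenario_config("S1"), n = 200, n_replicates = 5,
#'                  B = 0, method = "cfpl", causes = 1, seed = 1)
#' rep
#' }
#' @export
run_study <- function(config, n = 500, n_replicates = 100, B = 0,
                      grid = seq(-1.5, 0.6, by = 0.3),
                      method = c("both", "cwmr", "cfpl"), causes = 1:2,
                      nominal_level = 0.90, seed = 1, progress = FALSE) {
  method <- match.arg(method)
  methods <- if (method == "both") c("cwmr", "cfpl") else method
  stopifnot(inherits(config, "scenario_config"))
  times <- exp(grid)
  z <- stats::qnorm(1 - (1 - nominal_level) / 2)
  rep_seeds <- .spawn_seeds(seed, n_replicates)
  boot_seeds <- .spawn_seeds(seed, n_replicates, offset = 1L)

  truth <- lapply(causes, function(j) true_auc(config, times, j))
  names(truth) <- as.character(causes)

  dims <- c(n_replicates, length(times))
  arr <- function() matrix(NA_real_, dims[1], dims[2])
  res <- list()
  for (m in methods) for (j in causes) {
    key <- paste(m, j, sep = ".")
    res[[key]] <- list(est = arr(), se = arr(), lo = arr(), hi = arr(),
                       bmean = arr(), bse = arr())
  }
  n_failed <- stats::setNames(integer(length(methods) * length(causes)),
                              names(res))

  for (r in seq_len(n_replicates)) {
    smp <- simulate_crs(config, n, seed = rep_seeds[r])
    for (j in causes) {
      if ("cwmr" %in% methods) {
        key <- paste("cwmr", j, sep = ".")
        ok <- tryCatch({
          h <- as.numeric(select_bandwidth(smp, j))
          cv <- suppressWarnings(
            cwmr(smp, j, times = times, bandwidth = h,
                 ci_level = nominal_level))
          res[[key]]$est[r, ] <- cv$estimate
          res[[key]]$se[r, ] <- cv$se
          res[[key]]$lo[r, ] <- cv$lower
          res[[key]]$hi[r, ] <- cv$upper
          if (B > 0) {
            bs <- bootstrap_se(smp, cwmr_estimator(j, h), times, B,
                               seed = boot_seeds[r])
            res[[key]]$bse[r, ] <- bs
            res[[key]]$bmean[r, ] <- attr(bs, "boot_mean")
          }
          TRUE
        }, error = function(e) FALSE)
        if (!ok) n_failed[key] <- n_failed[key] + 1L
      }
      if ("cfpl" %in% methods) {
        key <- paste("cfpl", j, sep = ".")
        ok <- tryCatch({
          fit <- suppressWarnings(cfpl(smp, j))
          cv <- predict(fit, times = times, se.fit = TRUE,
                        ci_level = nominal_level)
          res[[key]]$est[r, ] <- cv$estimate
          res[[key]]$se[r, ] <- cv$se
          res[[key]]$lo[r, ] <- cv$lower
          res[[key]]$hi[r, ] <- cv$upper
          if (B > 0) {
            bs <- suppressWarnings(
              bootstrap_se(smp, cfpl_estimator(j), times, B,
                           seed = boot_seeds[r]))
            res[[key]]$bse[r, ] <- bs
            res[[key]]$bmean[r, ] <- attr(bs, "boot_mean")
          }
          TRUE
        }, error = function(e) FALSE)
        if (!ok) n_failed[key] <- n_failed[key] + 1L
      }
    }
    if (progress) cat(".", if (r %% 50 == 0) "\n")
  }

  rows <- list()
  for (m in methods) for (j in causes) {
    key <- paste(m, j, sep = ".")
    x <- res[[key]]
    mean_point <- colMeans(x$est, na.rm = TRUE)
    bmean <- colMeans(x$bmean, na.rm = TRUE)
    mc_mean <- if (B > 0 && any(is.finite(bmean))) bmean else mean_point
    tr <- truth[[as.character(j)]]
    cover <- colMeans(x$lo <= matrix(tr, dims[1], dims[2], byrow = TRUE) &
                        matrix(tr, dims[1], dims[2], byrow = TRUE) <= x$hi,
                      na.rm = TRUE)
    rows[[key]] <- data.frame(
      method = if (m == "cwmr") "cWMR" else "cFPL", cause = j,
      log_time = grid, time = times, true_auc = tr,
      mean = mc_mean, mean_point = mean_point,
      arb = 100 * abs(mc_mean - tr) / tr,
      bse = if (B > 0) colMeans(x$bse, na.rm = TRUE) else NA_real_,
      se = colMeans(x$se, na.rm = TRUE),
      cp = 100 * cover,
      n_ok = colSums(!is.na(x$est)))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "scenario") <- config$scenario
  attr(out, "n") <- n
  attr(out, "n_replicates") <- n_replicates
  attr(out, "B") <- B
  attr(out, "nominal_level") <- nominal_level
  attr(out, "seed") <- seed
  attr(out, "n_failed") <- n_failed
  class(out) <- c("sim_report", "data.frame")
  out
}

#' @export
print.sim_report <- function(x, digits = 3, ...) {
  cat("Simulation study: scenario ", attr(x, "scenario"),
      ", n = ", attr(x, "n"), ", ", attr(x, "n_replicates"),
      " replicates, B = ", attr(x, "B"), ", nominal ",
      100 * attr(x, "nominal_level"), "% CIs, seed ", attr(x, "seed"),
      "\n", sep = "")
  nf <- attr(x, "n_failed")
  if (any(nf > 0))
    cat("  failed replicates: ",
        paste(names(nf)[nf > 0], nf[nf > 0], collapse = ", "), "\n",
        sep = "")
  cat("\n")
  df <- as.data.frame(x)
  df$time <- NULL
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
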