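# ---- cause-specific weighted mean rank (cWMR) estimator ---------------------

# mean observed rank AUC over neighbourhood members, given the per-event-time
# table from event_rank_aucs(); members with no controls (possible only at the
# sample maximum) are dropped.
.cwmr_point <- function(ev, t, h) {
  keep <- abs(ev$time - t) < h & !is.na(ev$auc)
  if (!any(keep)) return(NA_real_)
  mean(ev$auc[keep])
}

#' cWMR point estimate of the cause-specific AUC at one time
#'
#' The local estimator: the unweighted mean of the observed rank AUCs
#' \eqn{A^{(j)}(t_k)} over the distinct cause-`j` event times in the open
#' neighbourhood `(t - h, t + h)` (see [auc_neighborhood()]).  Event times
#' whose riskset contains no controls are dropped from the average.
#'
#' @inheritParams observed_rank_auc
#' @param h positive bandwidth.
#' @return A number in `[0, 1]`.
#' @export
cwmr_at <- function(sample, t, cause, h, ties = c("discordant", "half")) {
  ties <- match.arg(ties)
  nb <- auc_neighborhood(sample, t, cause, h)
  if (nb$size == 0L)
    stop("empty neighbourhood around t = ", t,
         "; increase the bandwidth (h = ", h, ")")
  ev <- event_rank_aucs(sample, cause, ties)
  est <- .cwmr_point(ev, t, h)
  if (is.na(est))
    stop("all event times in the neighbourhood of t = ", t,
         " lack controls; increase the bandwidth")
  est
}

#' Default candidate bandwidth grid
#'
#' Fifteen log-spaced values spanning the 2nd to the 50th percentile of the
#' pairwise gaps between distinct cause-`j` event times, i.e. from clearly
#' under-smoothed to clearly over-smoothed neighbourhoods.
#'
#' @inheritParams cwmr_at
#' @param length.out number of candidates.
#' @return A numeric vector of candidate bandwidths, increasing.
#' @export
bandwidth_grid <- function(sample, cause, length.out = 15L) {
  .assert_crs(sample)
  cause <- .assert_cause(sample, cause)
  times <- sort(unique(sample$time[sample$cause == cause]))
  if (length(times) < 2L)
    stop("need at least 2 distinct cause-", cause, " event times")
  gaps <- as.numeric(stats::dist(times))
  gaps <- gaps[gaps > 0]
  q <- stats::quantile(gaps, c(0.02, 0.50), names = FALSE)
  if (q[1] <= 0 || q[2] <= q[1]) q <- range(gaps)
  exp(seq(log(q[1]), log(q[2]), length.out = length.out))
}

#' Leave-one-out cross-validated bandwidth selection
#'
#' For each candidate `h`, every distinct cause-`j` event time `t_k` is
#' predicted by the cWMR average over its neighbourhood with `t_k` itself
#' removed, and the squared prediction errors against the observed
#' \eqn{A^{(j)}(t_k)} are accumulated into an integrated squared-error
#' criterion: the riskset-size-weighted mean squared error
#' \deqn{\mathrm{CV}(h) = \sum_k w_k \{\hat A_{-k}(t_k) - A^{(j)}(t_k)\}^2
#'       \Big/ \sum_k w_k, \qquad w_k = n_{t_k},}
#' taken over the event times whose leave-one-out neighbourhood is nonempty
#' at that `h`.  The weights are the binomial denominators of the observed
#' rank AUCs, so the erratic small-riskset tail does not dominate the
#' criterion, and averaging (rather than summing) keeps candidates that
#' cover different numbers of event times comparable.  A candidate with no
#' predictable event time at all is assigned an infinite criterion.  The
#' minimising candidate is returned; ties break toward the smaller
#' bandwidth.
#'
#' @inheritParams cwmr_at
#' @param grid increasing vector of candidate bandwidths; defaults to
#'   [bandwidth_grid()].
#' @return The selected bandwidth, with the criterion values attached as
#'   attribute `"criterion"`.
#' @export
select_bandwidth <- function(sample, cause, grid = NULL,
                             ties = c("discordant", "half")) {
  ties <- match.arg(ties)
  .assert_crs(sample)
  cause <- .assert_cause(sample, cause)
  if (is.null(grid)) grid <- bandwidth_grid(sample, cause)
  if (!length(grid) || any(!is.finite(grid) | grid <= 0))
    stop("'grid' must be a nonempty vector of positive bandwidths")
  grid <- sort(grid)
  ev <- event_rank_aucs(sample, cause, ties)
  ev <- ev[!is.na(ev$auc), , drop = FALSE]
  if (nrow(ev) < 2L)
    stop("need at least 2 cause-", cause, " event times with controls")
  D <- abs(outer(ev$time, ev$time, "-"))
  w <- ev$n_controls
  crit <- vapply(grid, function(h) {
    W <- D < h & D > 0        # open window, self excluded
    m <- rowSums(W)
    if (all(m == 0L)) return(Inf)
    pred <- as.numeric(W %*% ev$auc) / pmax(m, 1L)
    ok <- m > 0L
    sum(w[ok] * (pred - ev$auc)[ok]^2) / sum(w[ok])
  }, numeric(1))
  if (all(!is.finite(crit)))
    stop("no candidate bandwidth yields any leave-one-out neighbour; ",
         "supply a wider grid")
  h <- grid[which.min(crit)]   # which.min takes the first (smallest) minimiser
  attr(h, "criterion") <- stats::setNames(crit, format(grid, digits = 6))
  h
}

#' Fit a cWMR cause-specific AUC curve
#'
#' Evaluates the local weighted-mean-rank estimator of the incident/dynamic
#' cause-specific AUC on a grid of times, together with its
#' normal-approximation standard errors ([cwmr_variance()]) and pointwise
#' Wald confidence intervals clipped to `[0, 1]`.
#'
#' @inheritParams cwmr_at
#' @param times evaluation times; defaults to the distinct cause-`j` event
#'   times not exceeding the 90th percentile of all observed times.
#' @param bandwidth `"cv"` (default) for leave-one-out cross-validation via
#'   [select_bandwidth()], or a positive number.
#' @param ci_level confidence level, default 0.95.
#' @param variance compute standard errors and intervals (default `TRUE`).
#' @return An [auc_curve] object (method `"cWMR"`); grid points with an empty
#'   neighbourhood carry `NA` and a warning is issued.
#' @examples
#' set.seed(1)
#' s <- simulate_crs(scenario_config("S1"), n = 200)
#' fit <- cwmr(s, cause = 1, times = exp(seq(-1, 0.5, 0.5)))
#' fit
#' @export
cwmr <- function(sample, cause, times = NULL, bandwidth = "cv",
                 ci_level = 0.95, ties = c("discordant", "half"),
                 variance = TRUE) {
  ties <- match.arg(ties)
  .assert_crs(sample)
  cause <- .assert_cause(sample, cause)
  if (length(ci_level) != 1L || ci_level <= 0 || ci_level >= 1)
    stop("'ci_level' must be in (0, 1)")
  if (identical(bandwidth, "cv")) {
    h <- as.numeric(select_bandwidth(sample, cause, ties = ties))
  } else {
    h <- as.numeric(bandwidth)
    if (length(h) != 1L || !is.finite(h) || h <= 0)
      stop("'bandwidth' must be \"cv\" or a single positive number")
  }
  ev <- event_rank_aucs(sample, cause, ties)
  if (is.null(times)) {
    tmax <- stats::quantile(sample$time, 0.9, names = FALSE)
    times <- ev$time[ev$time <= tmax & !is.na(ev$auc)]
    if (!length(times)) times <- ev$time[!is.na(ev$auc)]
  }
  times <- sort(as.numeric(times))
  est <- vapply(times, function(t) .cwmr_point(ev, t, h), numeric(1))
  if (anyNA(est))
    warning(sum(is.na(est)), " grid point(s) have an empty neighbourhood ",
            "at h = ", format(h, digits = 4), " and are returned as NA")
  se <- rep(NA_real_, length(times))
  if (variance) {
    pars <- .time_score_params(sample, cause, ev$time[!is.na(ev$auc)])
    for (i in seq_along(times)) {
      if (is.na(est[i])) next
      v <- .cwmr_variance_cached(pars, times[i], h,
                                 ev = ev[!is.na(ev$auc), , drop = FALSE])
      se[i] <- sqrt(v)
    }
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  new_auc_curve(method = "cWMR", cause = cause, times = times,
                estimate = est, se = se,
                lower = pmax(0, est - z * se), upper = pmin(1, est + z * se),
                ci_level = ci_level, bandwidth = h,
                n = nrow(sample))
}
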