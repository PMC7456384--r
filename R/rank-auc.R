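#' Observed rank AUC at a single event time
#'
#' The unsmoothed, time-local concordance
#' \deqn{A^{(j)}(t) = \frac{1}{d_t^{(j)} n_t} \sum_{i \in cases}
#'       \sum_{k \in controls} 1\{M_i > M_k\},}
#' the proportion of case--control pairs at `t` in which the cause-`j`
#' incident case carries the larger marker.  The indicator is strict: a
#' marker tie contributes nothing (set `ties = "half"` for the conventional
#' half-credit variant).
#'
#' @param sample a [crs_sample()].
#' @param t a positive time with at least one cause-`j` event.
#' @param cause cause index `j`.
#' @param ties `"discordant"` (default; ties score 0) or `"half"`.
#' @return A number in `[0, 1]`.
#' @examples
#' s <- crs_sample(time = c(2, 3, 4, 5), cause = c(1, 0, 0, 0),
#'                 marker = c(2.5, 1.0, 3.0, 2.0))
#' observed_rank_auc(s, 2, cause = 1)  # 2/3
#' @export
observed_rank_auc <- function(sample, t, cause,
                              ties = c("discordant", "half")) {
  ties <- match.arg(ties)
  rs <- riskset_at(sample, t, cause)
  if (rs$n_cases == 0L)
    stop("no incident cases of cause ", cause, " at t = ", t)
  if (rs$n_controls == 0L)
    stop("no dynamic controls at t = ", t)
  mc <- sample$marker[match(rs$case_ids, sample$id)]
  mk <- sample$marker[match(rs$control_ids, sample$id)]
  conc <- sum(vapply(mc, function(m) sum(m > mk), numeric(1)))
  if (ties == "half")
    conc <- conc + 0.5 * sum(vapply(mc, function(m) sum(m == mk), numeric(1)))
  conc / (rs$n_cases * rs$n_controls)
}

# Observed rank AUC at every distinct cause-j event time.
# Returns a data.frame (time, d, n_controls, auc); auc is NA where the
# riskset holds no controls (only possible at the sample maximum).
event_rank_aucs <- function(sample, cause, ties = "discordant") {
  times <- sort(unique(sample$time[sample$cause == cause]))
  d <- integer(length(times)); nc <- integer(length(times))
  auc <- rep(NA_real_, length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    case_m <- sample$marker[sample$time == t & sample$cause == cause]
    ctrl_m <- sample$marker[sample$time > t]
    d[i] <- length(case_m); nc[i] <- length(ctrl_m)
    if (nc[i] > 0L) {
      conc <- sum(vapply(case_m, function(m) sum(m > ctrl_m), numeric(1)))
      if (ties == "half")
        conc <- conc +
          0.5 * sum(vapply(case_m, function(m) sum(m == ctrl_m), numeric(1)))
      auc[i] <- conc / (d[i] * nc[i])
    }
  }
  data.frame(time = times, d = d, n_controls = nc, auc = auc)
}

#' Neighbourhood of cause-specific event times
#'
#' The set \eqn{N_t^{(j)}(h) = \{t_k : |t - t_k| < h, \delta = j\}} of
#' distinct cause-`j` event times falling in the open window `(t - h, t + h)`.
#' The window truncates naturally at the edges of the data; it is never
#' widened to guarantee a nonempty set.
#'
#' @param sample a [crs_sample()].
#' @param t centre time.
#' @param cause cause index `j`.
#' @param h positive bandwidth (half-width).
#' @return A list of class `"auc_neighborhood"` with elements `center_time`,
#'   `bandwidth`, `cause`, `member_times`, `size`.
#' @export
auc_neighborhood <- function(sample, t, cause, h) {
  .assert_crs(sample)
  cause <- .assert_cause(sample, cause)
  if (length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a single positive bandwidth")
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("'t' must be a single positive time")
  times <- sort(unique(sample$time[sample$cause == cause]))
  member <- times[abs(times - t) < h]
  structure(list(center_time = t, bandwidth = h, cause = cause,
                 member_times = member, size = length(member)),
            class = "auc_neighborhood")
}

#' @export
print.auc_neighborhood <- function(x, ...) {
  cat("Neighbourhood of t = ", format(x$center_time, digits = 6),
      " (h = ", format(x$bandwidth, digits = 4), ", cause ", x$cause,
      "): ", x$size, " event time(s)\n", sep = "")
  invisible(x)
}
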