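# ---- normal-approximation variance of the cWMR estimator -------------------
#
# Marker values in each riskset are rank-transformed to normal scores; the
# case and control score distributions are then approximated by normals and
# the placement probabilities entering var[A(t)] and cov[A(t), A(s)] are
# evaluated under those normals by Gauss-Hermite quadrature.

.gh_env <- new.env(parent = emptyenv())

.gh_nodes <- function(n = 40L) {
  key <- as.character(n)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- pracma::gaussHermite(n)
  .gh_env[[key]]
}

# E[g(X)] for X ~ N(mu, sd^2): (1/sqrt(pi)) sum w_i g(mu + sqrt(2) sd z_i)

#' Placement probabilities under a normal approximation
#'
#' For independent case score \eqn{X \sim N(\mu_1, \sigma_1^2)} and control
#' scores \eqn{Y, Y' \sim N(\mu_0, \sigma_0^2)}, returns
#' `p0` \eqn{= \Pr(X > Y)} (closed form) and
#' `p1` \eqn{= \Pr(X > Y, X > Y')} (one-dimensional Gauss--Hermite
#' quadrature), the two quantities entering the variance of a time-local
#' rank AUC.
#'
#' @param case_mean,case_sd moments of the case score distribution.
#' @param ctrl_mean,ctrl_sd moments of the control score distribution.
#' @return A list with elements `p0` and `p1`, both in `[0, 1]`.
#' @examples
#' normal_placement_probs(1, 1, 0, 1)$p0  # pnorm(1 / sqrt(2))
#' @export
normal_placement_probs <- function(case_mean, case_sd = 1,
                                   ctrl_mean = 0, ctrl_sd = 1) {
  if (case_sd <= 0 || ctrl_sd <= 0) stop("score SDs must be positive")
  p0 <- stats::pnorm((case_mean - ctrl_mean) / sqrt(case_sd^2 + ctrl_sd^2))
  gh <- .gh_nodes()
  x <- case_mean + sqrt(2) * case_sd * gh$x
  p1 <- sum(gh$w * stats::pnorm((x - ctrl_mean) / ctrl_sd)^2) / sqrt(pi)
  list(p0 = p0, p1 = min(max(p1, 0), 1))
}

# Normal-score summaries of the riskset at each requested time: the pooled
# at-risk markers (cases at t plus controls) are ranked and mapped through
# qnorm(rank / (N + 1)); the case and control scores are then summarised by
# empirical means/SDs.  case_sd is NA when there is a single case.
.time_score_params <- function(sample, cause, times) {
  out <- data.frame(time = times, d = NA_integer_, n_controls = NA_integer_,
                    case_mean = NA_real_, case_sd = NA_real_,
                    ctrl_mean = NA_real_, ctrl_sd = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    is_case <- sample$time == t & sample$cause == cause
    is_ctrl <- sample$time > t
    d <- sum(is_case); nc <- sum(is_ctrl)
    out$d[i] <- d; out$n_controls[i] <- nc
    if (d == 0L || nc < 2L) next
    m <- c(sample$marker[is_case], sample$marker[is_ctrl])
    sc <- stats::qnorm(rank(m, ties.method = "average") / (length(m) + 1))
    cs <- sc[seq_len(d)]; ks <- sc[-seq_len(d)]
    out$case_mean[i] <- mean(cs)
    out$case_sd[i] <- if (d >= 2L) stats::sd(cs) else NA_real_
    out$ctrl_mean[i] <- mean(ks)
    out$ctrl_sd[i] <- stats::sd(ks)
  }
  out
}

#' Variance and covariance components of time-local rank AUCs
#'
#' Estimates the placement probabilities entering
#' \eqn{\mathrm{var}[A^{(j)}(t)]} and
#' \eqn{\mathrm{cov}[A^{(j)}(t), A^{(j)}(s)]} under a normal approximation of
#' the rank-transformed case and control marker scores at `t` and `s`
#' (`t <= s` after internal ordering):
#' `p0` and `p1` are the single- and double-control placement probabilities
#' at `t`; `p2` is the probability that the cases at `t` and at `s` both
#' outrank one shared control; `p3` is the probability that the case at `t`
#' outranks the case at `s` (which is itself a dynamic control at `t`) while
#' the latter outranks a control at `s`; `p2_0` and `p3_0` are the
#' corresponding independence products.
#'
#' Case score standard deviations are taken from the data when a time holds
#' two or more cases, and otherwise fall back to `case_sd` (default 1, the
#' scale of the normal scores); [cwmr_variance()] passes the spread of the
#' case scores across the smoothing neighbourhood instead.
#'
#' @inheritParams cwmr_at
#' @param s second time point (may equal `t`).
#' @param case_sd fallback case-score SD used when a time has a single case.
#' @return A list with components `p0`, `p1`, `p2`, `p2_0`, `p3`, `p3_0`
#'   (all in `[0, 1]`), the per-time normal parameters, and the control
#'   counts.
#' @export
variance_components <- function(sample, t, s, cause, case_sd = NULL) {
  .assert_crs(sample)
  cause <- .assert_cause(sample, cause)
  tt <- sort(c(t, s))
  pars <- .time_score_params(sample, cause, tt)
  if (any(pars$d == 0L))
    stop("no cause-", cause, " cases at t = ", tt[which(pars$d == 0L)[1L]])
  if (any(pars$n_controls < 2L))
    stop("fewer than 2 controls at t = ",
         tt[which(pars$n_controls < 2L)[1L]], "; variance is undefined")
  fb <- if (is.null(case_sd)) 1 else as.numeric(case_sd)
  pars$case_sd[is.na(pars$case_sd)] <- fb
  comp <- .pair_components(pars[1, ], pars[2, ])
  c(comp, list(params = pars))
}

# placement probabilities for an ordered pair of per-time parameter rows
# (earlier row first); vectorised over equal-length data.frames.
.pair_components <- function(a, b) {
  gh <- .gh_nodes(); zw <- gh$w / sqrt(pi); z <- sqrt(2) * gh$x
  p0a <- stats::pnorm((a$case_mean - a$ctrl_mean) /
                        sqrt(a$case_sd^2 + a$ctrl_sd^2))
  p0b <- stats::pnorm((b$case_mean - b$ctrl_mean) /
                        sqrt(b$case_sd^2 + b$ctrl_sd^2))
  # p1 at the earlier time: case outranks two independent controls
  X <- a$case_mean + outer(a$case_sd, z)                   # pairs x nodes
  p1 <- drop(stats::pnorm((X - a$ctrl_mean) / a$ctrl_sd)^2 %*% zw)
  # p2: shared control Y (earlier-time control law) below both cases
  Y <- a$ctrl_mean + outer(a$ctrl_sd, z)
  p2 <- drop((stats::pnorm((a$case_mean - Y) / a$case_sd) *
                stats::pnorm((b$case_mean - Y) / b$case_sd)) %*% zw)
  # p3: later case U is a control at the earlier time; earlier case above U,
  # U above a control at the later time
  U <- b$case_mean + outer(b$case_sd, z)
  p3 <- drop((stats::pnorm((a$case_mean - U) / a$case_sd) *
                stats::pnorm((U - b$ctrl_mean) / b$ctrl_sd)) %*% zw)
  p3_0 <- stats::pnorm((a$case_mean - b$case_mean) /
                         sqrt(a$case_sd^2 + b$case_sd^2)) * p0b
  clip <- function(x) pmin(pmax(x, 0), 1)
  list(p0 = clip(p0a), p1 = clip(p1), p2 = clip(p2),
       p2_0 = clip(p0a * p0b), p3 = clip(p3), p3_0 = clip(p3_0))
}

# assembled cWMR variance from a precomputed parameter table
.cwmr_variance_cached <- function(pars, t, h, ev = NULL) {
  keep <- abs(pars$time - t) < h & pars$n_controls >= 2L & pars$d >= 1L
  mem <- pars[keep, , drop = FALSE]
  m <- nrow(mem)
  if (m == 0L)
    stop("empty neighbourhood around t = ", t,
         "; increase the bandwidth (h = ", h, ")")
  # fallback case-score SD: spread of the case scores across the
  # neighbourhood (the local case population), else the per-time SD, else 1
  fb <- if (m >= 2L) stats::sd(mem$case_mean) else NA_real_
  if (!is.na(fb) && fb <= 0) fb <- NA_real_
  mem$case_sd[is.na(mem$case_sd)] <- fb
  mem$case_sd[is.na(mem$case_sd)] <- 1
  # per-member variance of A(t_i)
  X <- mem$case_mean + outer(mem$case_sd, sqrt(2) * .gh_nodes()$x)
  p1 <- drop(stats::pnorm((X - mem$ctrl_mean) / mem$ctrl_sd)^2 %*%
               (.gh_nodes()$w / sqrt(pi)))
  p0 <- stats::pnorm((mem$case_mean - mem$ctrl_mean) /
                       sqrt(mem$case_sd^2 + mem$ctrl_sd^2))
  n <- mem$n_controls
  v <- ((n - 1) / n) * (p1 - p0^2) + (p0 * (1 - p0)) / n
  total <- sum(v)
  if (m >= 2L) {
    idx <- utils::combn(m, 2L)
    a <- mem[idx[1L, ], , drop = FALSE]   # earlier (times sorted increasing)
    b <- mem[idx[2L, ], , drop = FALSE]
    comp <- .pair_components(a, b)
    cv <- ((comp$p2 - comp$p2_0) + (comp$p3 - comp$p3_0)) / a$n_controls
    total <- total + 2 * sum(cv)
  }
  V <- total / m^2
  if (V < 0) {
    warning("assembled cWMR variance at t = ", format(t, digits = 4),
            " is negative (", format(V, digits = 3), "); floored at 0")
    V <- 0
  }
  V
}

#' Normal-approximation variance of the cWMR estimator
#'
#' Assembles
#' \deqn{V = \frac{1}{m^2}\Big[\sum_i \mathrm{var}\,A^{(j)}(t_{(i)}) +
#'   \sum_{i \neq k} \mathrm{cov}\big(A^{(j)}(t_{(i)}), A^{(j)}(t_{(k)})\big)\Big]}
#' over the `m` member times of the neighbourhood of `t`, with
#' \eqn{\mathrm{var}[A^{(j)}(t)] = \frac{n_t - 1}{n_t}(P_1 - P_0^2) +
#' \frac{1}{n_t} P_0 (1 - P_0)} and
#' \eqn{\mathrm{cov} = \frac{1}{n_t}[(P_2 - P_{2.0}) + (P_3 - P_{3.0})]},
#' the components estimated as in [variance_components()].  A slightly
#' negative assembled value is floored at zero with a warning.
#'
#' @inheritParams cwmr_at
#' @return A non-negative variance.
#' @export
cwmr_variance <- function(sample, t, cause, h,
                          ties = c("discordant", "half")) {
  ties <- match.arg(ties)
  .assert_crs(sample)
  cause <- .assert_cause(sample, cause)
  nb <- auc_neighborhood(sample, t, cause, h)
  if (nb$size == 0L)
    stop("empty neighbourhood around t = ", t,
         "; increase the bandwidth (h = ", h, ")")
  pars <- .time_score_params(sample, cause, nb$member_times)
  if (all(pars$n_controls < 2L))
    stop("fewer than 2 controls at every neighbourhood member of t = ", t)
  .cwmr_variance_cached(pars, t, h)
}
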