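# ---- cause-specific fractional polynomial likelihood (cFPL) estimator ------

.fp_powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2)
.fp_names <- c("(Intercept)", "t^-2", "t^-1", "t^-0.5", "ln(t)",
               "t^0.5", "t", "t^2")
.lp_clamp <- 35   # |linear predictor| bound; keeps log(AUC) finite

#' Fractional polynomial basis of time
#'
#' The full degree-7 basis with the fixed power set
#' \eqn{\{-2, -1, -0.5, 0, 0.5, 1, 2\}} (0 meaning \eqn{\ln t}):
#' \eqn{(1, t^{-2}, t^{-1}, t^{-1/2}, \ln t, t^{1/2}, t, t^2)}.
#'
#' @param t positive time(s).
#' @return For scalar `t` a named numeric vector of length 8; for vector `t`
#'   a matrix with one row per time.
#' @examples
#' fp_basis(1)
#' fp_basis(4)
#' @export
fp_basis <- function(t) {
  if (any(!is.finite(t) | t <= 0)) stop("'t' must be positive")
  X <- cbind(1, t^-2, t^-1, t^-0.5, log(t), t^0.5, t, t^2)
  colnames(X) <- .fp_names
  if (length(t) == 1L) X[1L, ] else X
}

#' Concordant/discordant pair counts at the cause-specific event times
#'
#' One record per cause-`j` case subject (tied event times yield one record
#' per case): the event time, the number of dynamic controls with a strictly
#' lower marker (`n_concordant`), and the number with a greater-or-equal
#' marker (`n_discordant`; marker ties are discordant, matching the strict
#' concordance indicator).  The two counts always partition the riskset:
#' `n_concordant + n_discordant` equals the number of controls at the event
#' time.  Events with no controls yield `(0, 0)` records, which contribute
#' nothing to the likelihood.
#'
#' @inheritParams cwmr_at
#' @return A data frame with columns `event_time`, `n_concordant`,
#'   `n_discordant`.
#' @export
concordance_records <- function(sample, cause) {
  .assert_crs(sample)
  cause <- .assert_cause(sample, cause)
  idx <- which(sample$cause == cause)
  idx <- idx[order(sample$time[idx])]
  n1 <- integer(length(idx)); n2 <- integer(length(idx))
  for (r in seq_along(idx)) {
    i <- idx[r]
    ctrl <- sample$marker[sample$time > sample$time[i]]
    n1[r] <- sum(sample$marker[i] > ctrl)
    n2[r] <- length(ctrl) - n1[r]
  }
  data.frame(event_time = sample$time[idx], n_concordant = n1,
             n_discordant = n2)
}

#' Binomial partial log-likelihood of the fractional polynomial model
#'
#' \deqn{\ell(\beta) = \sum_H \big[n_1(t_{(H)}) \log \mathrm{AUC}(t_{(H)}) +
#'   n_2(t_{(H)}) \log\{1 - \mathrm{AUC}(t_{(H)})\}\big],}
#' with \eqn{\mathrm{AUC}(t) = \mathrm{logit}^{-1}\{x(t)^\top \beta\}} and
#' \eqn{x(t)} the [fp_basis()].  The binomial-coefficient constant is
#' omitted (it does not involve \eqn{\beta}).  The linear predictor is
#' clamped to \eqn{\pm 35} so the value is always finite.
#'
#' @param records a [concordance_records()] data frame.
#' @param coefficients numeric vector of length 8.
#' @return The log partial likelihood (a scalar).
#' @export
log_partial_likelihood <- function(records, coefficients) {
  if (!nrow(records)) stop("'records' is empty")
  if (length(coefficients) != 8L) stop("'coefficients' must have length 8")
  eta <- .clamp(fp_basis(records$event_time) %*% coefficients)
  p <- stats::plogis(eta)
  sum(records$n_concordant * log(p) + records$n_discordant * log1p(-p))
}

.clamp <- function(eta) pmin(pmax(drop(eta), -.lp_clamp), .lp_clamp)

#' Analytic score of the partial log-likelihood
#'
#' Element `l` of the score is
#' \eqn{\sum_H t_{(H)}^{(p_l)} [n_1 (1 - \mathrm{AUC}) - n_2\,
#' \mathrm{AUC}]} evaluated at the event times (with
#' \eqn{t^{(p_0)} \equiv 1} for the intercept) -- the gradient of
#' [log_partial_likelihood()].
#'
#' @inheritParams log_partial_likelihood
#' @return A numeric vector of length 8.
#' @export
cfpl_score <- function(records, coefficients) {
  if (!nrow(records)) stop("'records' is empty")
  X <- fp_basis(records$event_time)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  p <- stats::plogis(.clamp(X %*% coefficients))
  drop(crossprod(X, records$n_concordant * (1 - p) -
                      records$n_discordant * p))
}

# ---- fitting (internal, on a standardised time scale) ----------------------
#
# The raw basis spans t^-2 .. t^2 and is catastrophically ill-conditioned
# when event times sit far from 1; internally time is divided by the
# geometric mean event time and the coefficients are mapped back exactly
# through the linear relation between the two bases.

# x_std(t) = A %*% x_raw(t) for t_std = t / s
.fp_scale_matrix <- function(s) {
  A <- diag(c(1, s^2, s, sqrt(s), 1, 1 / sqrt(s), 1 / s, 1 / s^2))
  A[5L, 1L] <- -log(s)
  A
}

# Newton--Raphson on the (concave) binomial partial likelihood, warm-started
# by BFGS with the analytic gradient; everything on the standardised scale.
.cfpl_fit_records <- function(times_std, n1, n2, grad_tol = 1e-6,
                              max_newton = 50L) {
  X <- fp_basis(times_std)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  tot <- n1 + n2
  npairs <- max(1, sum(tot))
  nll <- function(b) {
    p <- stats::plogis(.clamp(X %*% b))
    -sum(n1 * log(p) + n2 * log1p(-p))
  }
  ngr <- function(b) {
    p <- stats::plogis(.clamp(X %*% b))
    -drop(crossprod(X, n1 * (1 - p) - n2 * p))
  }
  newton <- function(b) {
    for (it in seq_len(max_newton)) {
      p <- drop(stats::plogis(.clamp(X %*% b)))
      g <- drop(crossprod(X, n1 * (1 - p) - n2 * p))
      if (max(abs(g)) / npairs < grad_tol) break
      w <- tot * p * (1 - p)
      H <- crossprod(X, X * w)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      # halve until the likelihood does not deteriorate
      f0 <- nll(b)
      lam <- 1
      repeat {
        bn <- b + lam * step
        if (nll(bn) <= f0 + 1e-12 || lam < 1e-8) break
        lam <- lam / 2
      }
      if (lam < 1e-8) break
      b <- bn
    }
    b
  }
  # deterministic start ladder: null model, then small fixed perturbations
  starts <- list(rep(0, 8),
                 0.05 * rep_len(c(1, -1), 8),
                 0.1 * rep_len(c(-1, 1), 8))
  best <- NULL
  for (b0 in starts) {
    op <- stats::optim(b0, nll, ngr, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    b <- newton(op$par)
    val <- nll(b)
    if (is.null(best) || val < best$val) best <- list(b = b, val = val)
    if (max(abs(ngr(best$b))) / npairs < grad_tol) break
  }
  g <- ngr(best$b)
  list(beta = best$b, log_lik = -best$val,
       grad_norm = max(abs(g)) / npairs,
       converged = max(abs(g)) / npairs < grad_tol)
}

#' Fit the cause-specific fractional polynomial AUC model
#'
#' Models the incident/dynamic cause-`j` AUC(t) on the logit scale as a
#' degree-7 fractional polynomial of time (all powers
#' \eqn{\{-2,-1,-0.5,\ln,0.5,1,2\}} enter simultaneously; 8 coefficients)
#' and maximises the binomial partial likelihood built from the
#' concordant/discordant pair counts at each cause-`j` event time
#' ([concordance_records()]).  The likelihood is concave in the
#' coefficients; it is maximised by Newton--Raphson with analytic score,
#' warm-started by BFGS, on an internally standardised time scale (time
#' divided by the geometric mean event time) with the coefficients mapped
#' back exactly.  The pairwise sandwich covariance of the coefficients
#' (see [sandwich_components()]) is attached unless `variance = FALSE`.
#'
#' @inheritParams cwmr_at
#' @param variance compute the sandwich covariance (default `TRUE`).
#' @param grad_tol convergence tolerance on the maximum absolute score per
#'   case--control pair.
#' @return An object of class `"cfpl"` with methods [coef()], [vcov()],
#'   [predict.cfpl()], [logLik()], [plot()], [simulate()] and
#'   [residuals()].
#' @examples
#' set.seed(1)
#' s <- simulate_crs(scenario_config("S1"), n = 300)
#' fit <- cfpl(s, cause = 1)
#' fit
#' predict(fit, times = exp(c(-1.5, 0)))
#' @export
cfpl <- function(sample, cause, variance = TRUE, grad_tol = 1e-6) {
  .assert_crs(sample)
  cause <- .assert_cause(sample, cause)
  rec <- concordance_records(sample, cause)
  rec <- rec[rec$n_concordant + rec$n_discordant > 0L, , drop = FALSE]
  if (!nrow(rec)) stop("no cause-", cause, " events with controls")
  if (length(unique(rec$event_time)) < 8L)
    warning("fewer than 8 distinct cause-", cause,
            " event times; the 8-coefficient model is under-determined")
  s_time <- exp(mean(log(rec$event_time)))
  fit <- .cfpl_fit_records(rec$event_time / s_time, rec$n_concordant,
                           rec$n_discordant, grad_tol = grad_tol)
  if (!fit$converged)
    warning("cFPL fit did not reach the score tolerance (",
            format(fit$grad_norm, digits = 3), " per pair)")
  A <- .fp_scale_matrix(s_time)
  beta <- drop(crossprod(A, fit$beta))          # original-scale coefficients
  names(beta) <- .fp_names
  obj <- structure(
    list(coefficients = beta, powers = .fp_powers, link = "logit",
         cause = cause, time_scale = s_time, beta_std = fit$beta,
         log_lik = fit$log_lik, converged = fit$converged,
         grad_norm = fit$grad_norm, records = rec,
         n = nrow(sample), n_events = nrow(rec),
         vcov_std = NULL, sandwich_cov = NULL,
         sigma1 = NULL, sigma2 = NULL),
    class = "cfpl")
  if (variance) {
    sc <- tryCatch(sandwich_components(sample, cause, obj),
                   error = function(e) {
                     warning("sandwich covariance unavailable: ",
                             conditionMessage(e))
                     NULL
                   })
    if (!is.null(sc)) {
      obj$sigma1 <- sc$sigma1_hat
      obj$sigma2 <- sc$sigma2_hat
      obj$vcov_std <- sc$vcov_std
      obj$sandwich_cov <- sc$vcov
    }
  }
  obj
}

#' Predicted AUC(t) from a fitted cFPL model
#'
#' \eqn{\mathrm{logit}^{-1}\{x(t)^\top \hat\beta\}}, always strictly inside
#' (0, 1).  With `se.fit = TRUE`, delta-method standard errors on the AUC
#' scale and pointwise confidence limits are returned; limits are built on
#' the linear-predictor scale and back-transformed by default (`ci_scale =
#' "link"`), which keeps them inside (0, 1), or directly on the AUC scale
#' and clipped (`ci_scale = "response"`).
#'
#' @param object a fitted [cfpl()] model.
#' @param times positive evaluation times; defaults to the model's event
#'   times.
#' @param se.fit return standard errors and confidence limits.
#' @param ci_level confidence level.
#' @param ci_scale `"link"` (default) or `"response"`.
#' @param ... unused.
#' @return A numeric vector of AUC values, or (with `se.fit`) an
#'   [auc_curve] data frame.
#' @export
predict.cfpl <- function(object, times = NULL, se.fit = FALSE,
                         ci_level = 0.95,
                         ci_scale = c("link", "response"), ...) {
  ci_scale <- match.arg(ci_scale)
  if (is.null(times)) times <- sort(unique(object$records$event_time))
  times <- as.numeric(times)
  if (any(times <= 0)) stop("'times' must be positive")
  Xs <- fp_basis(times / object$time_scale)
  if (is.null(dim(Xs))) Xs <- matrix(Xs, nrow = 1)
  eta <- .clamp(Xs %*% object$beta_std)
  p <- stats::plogis(eta)
  if (!se.fit) return(stats::setNames(p, format(times, digits = 6)))
  if (is.null(object$vcov_std))
    stop("model carries no sandwich covariance; refit with variance = TRUE")
  # tiny negative quadratic forms can arise because the U-statistic middle
  # matrix is PSD only up to numerical tolerance
  v_eta <- pmax(rowSums((Xs %*% object$vcov_std) * Xs), 0)
  se_auc <- p * (1 - p) * sqrt(v_eta)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (ci_scale == "link") {
    lo <- stats::plogis(eta - z * sqrt(v_eta))
    hi <- stats::plogis(eta + z * sqrt(v_eta))
  } else {
    lo <- pmax(0, p - z * se_auc)
    hi <- pmin(1, p + z * se_auc)
  }
  new_auc_curve(method = "cFPL", cause = object$cause, times = times,
                estimate = as.numeric(p), se = as.numeric(se_auc),
                lower = as.numeric(lo), upper = as.numeric(hi),
                ci_level = ci_level, n = object$n)
}

#' cFPL AUC curve on a time grid
#'
#' Convenience wrapper: [predict.cfpl()] with `se.fit = TRUE` on a default
#' grid capped at the 90th percentile of the model's event times (estimates
#' beyond that are dominated by tail oversmoothing).
#'
#' @param object a fitted [cfpl()] model.
#' @param times evaluation times.
#' @param ci_level confidence level.
#' @param ci_scale see [predict.cfpl()].
#' @return An [auc_curve] data frame.
#' @export
cfpl_curve <- function(object, times = NULL, ci_level = 0.95,
                       ci_scale = c("link", "response")) {
  stopifnot(inherits(object, "cfpl"))
  if (is.null(times)) {
    et <- unique(object$records$event_time)
    times <- et[et <= stats::quantile(et, 0.9, names = FALSE)]
  }
  predict(object, times = times, se.fit = TRUE, ci_level = ci_level,
          ci_scale = match.arg(ci_scale))
}
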