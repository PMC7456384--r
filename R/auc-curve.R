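# ---- common container for estimated AUC(t) curves --------------------------

#' Estimated cause-specific AUC curve
#'
#' Both estimators return their pointwise results in this container: a data
#' frame with columns `time`, `estimate`, `se`, `lower`, `upper` and
#' attributes `method` (`"cWMR"` or `"cFPL"`), `cause`, `ci_level`, and (for
#' cWMR) `bandwidth`.  `lower <= estimate <= upper` holds pointwise and all
#' columns share the length of `time`.
#'
#' @param method estimator tag.
#' @param cause cause index.
#' @param times,estimate,se,lower,upper equal-length numeric vectors.
#' @param ci_level confidence level in (0, 1).
#' @param bandwidth smoothing bandwidth (cWMR only).
#' @param n number of subjects the curve was estimated from.
#' @return A data frame of class `"auc_curve"`.
#' @name auc_curve
#' @export
new_auc_curve <- function(method, cause, times, estimate, se, lower, upper,
                          ci_level, bandwidth = NULL, n = NA_integer_) {
  k <- length(times)
  stopifnot(length(estimate) == k, length(se) == k,
            length(lower) == k, length(upper) == k)
  out <- data.frame(time = times, estimate = estimate, se = se,
                    lower = lower, upper = upper)
  attr(out, "method") <- method
  attr(out, "cause") <- as.integer(cause)
  attr(out, "ci_level") <- ci_level
  attr(out, "bandwidth") <- bandwidth
  attr(out, "n") <- n
  class(out) <- c("auc_curve", "data.frame")
  out
}

#' @export
print.auc_curve <- function(x, digits = 4, ...) {
  cat(attr(x, "method"), " estimate of cause-", attr(x, "cause"),
      " incident/dynamic AUC(t)  [n = ", attr(x, "n"), "]\n", sep = "")
  if (!is.null(attr(x, "bandwidth")))
    cat("  bandwidth h = ", format(attr(x, "bandwidth"), digits = 4),
        "\n", sep = "")
  cat("  ", nrow(x), " time point(s), ",
      100 * attr(x, "ci_level"), "% pointwise CIs\n\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = digits),
                   row.names = FALSE)
  invisible(x)
}

#' @export
summary.auc_curve <- function(object, ...) {
  est <- object$estimate[!is.na(object$estimate)]
  cat(attr(object, "method"), " AUC(t) curve, cause ",
      attr(object, "cause"), ": range ",
      format(min(est), digits = 4), " .. ", format(max(est), digits = 4),
      " over t in [", format(min(object$time), digits = 4), ", ",
      format(max(object$time), digits = 4), "]\n", sep = "")
  invisible(object)
}

#' Write an AUC curve to CSV
#'
#' Columns `time, estimate, se, lo, hi` -- the canonical tabular output.
#'
#' @param curve an [auc_curve] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_auc_curve <- function(curve, path) {
  stopifnot(inherits(curve, "auc_curve"))
  out <- data.frame(time = curve$time, estimate = curve$estimate,
                    se = curve$se, lo = curve$lower, hi = curve$upper)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot an estimated AUC curve
#'
#' Draws the pointwise estimate with a shaded confidence band and the
#' non-informative reference line at 0.5.
#'
#' @param x an [auc_curve] object.
#' @param log_time plot against `log(t)` (default `TRUE`).
#' @param col line colour.
#' @param add add to an existing plot.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.auc_curve <- function(x, log_time = TRUE, col = "steelblue",
                           add = FALSE, ...) {
  ok <- !is.na(x$estimate)
  tt <- if (log_time) log(x$time[ok]) else x$time[ok]
  if (!add) {
    graphics::plot(tt, x$estimate[ok], type = "n", ylim = c(0, 1),
                   xlab = if (log_time) "log(t)" else "t",
                   ylab = sprintf("AUC(t), cause %d", attr(x, "cause")),
                   main = paste0(attr(x, "method"), " cause-specific AUC(t)"),
                   ...)
    graphics::abline(h = 0.5, lty = 3, col = "grey50")
  }
  band <- ok & !is.na(x$lower)
  if (any(band)) {
    tb <- if (log_time) log(x$time[band]) else x$time[band]
    graphics::polygon(c(tb, rev(tb)), c(x$lower[band], rev(x$upper[band])),
                      col = grDevices::adjustcolor(col, 0.2), border = NA)
  }
  graphics::lines(tt, x$estimate[ok], col = col, lwd = 2)
  invisible(x)
}
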