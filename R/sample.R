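#' Construct a competing-risks sample
#'
#' Bundles one row per subject: the observed follow-up time
#' \eqn{Z = \min(T, C)}, the event indicator \eqn{\delta \in \{0, 1, \dots,
#' J\}} (0 = censored, positive integers label the competing causes of
#' failure), and a numeric baseline marker \eqn{M}.  All estimators in the
#' package consume this container.
#'
#' Times must be strictly positive (the fractional-polynomial basis includes
#' \eqn{\ln t} and \eqn{t^{-2}}), causes must be non-negative integers, and
#' markers must be finite with no missing values; rows violating these
#' constraints raise an error naming the offending row rather than being
#' dropped silently.
#'
#' @param time numeric vector of positive observed times \eqn{Z}.
#' @param cause integer vector of event indicators; 0 means censored.
#' @param marker numeric vector of baseline marker values.
#' @param id optional subject labels; defaults to `1:n`.
#' @param n_causes number of competing causes `J`; defaults to the largest
#'   observed cause.
#' @return A data frame of class `"crs_sample"` with columns `id`, `time`,
#'   `cause`, `marker` and attribute `n_causes`.
#' @examples
#' s <- crs_sample(time = c(1, 2, 3), cause = c(1, 0, 2), marker = c(2.5, 1.1, 0.7))
#' s
#' @seealso [read_crs()], [riskset_at()], [simulate_crs()]
#' @export
crs_sample <- function(time, cause, marker, id = NULL, n_causes = NULL) {
  n <- length(time)
  if (length(cause) != n || length(marker) != n)
    stop("'time', 'cause' and 'marker' must have equal length")
  if (is.null(id)) id <- seq_len(n)
  if (length(id) != n) stop("'id' must have length ", n)
  if (anyDuplicated(id)) stop("subject ids must be unique")

  time <- as.numeric(time)
  marker <- as.numeric(marker)
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad))
    stop("non-positive or non-finite observed time in row ", bad[1L],
         " (time = ", time[bad[1L]], ")")
  if (any(!is.finite(cause) | cause < 0 | cause != round(cause)))
    stop("event indicator must be a non-negative integer; offending row ",
         which(!is.finite(cause) | cause < 0 | cause != round(cause))[1L])
  cause <- as.integer(round(cause))
  bad <- which(!is.finite(marker))
  if (length(bad))
    stop("missing or non-finite marker in row ", bad[1L])

  if (is.null(n_causes)) n_causes <- max(cause, 1L)
  n_causes <- as.integer(n_causes)
  if (n_causes < 1L) stop("'n_causes' must be >= 1")
  if (any(cause > n_causes))
    stop("cause ", max(cause), " exceeds n_causes = ", n_causes,
         " (row ", which(cause > n_causes)[1L], ")")

  out <- data.frame(id = id, time = time, cause = cause, marker = marker,
                    stringsAsFactors = FALSE)
  attr(out, "n_causes") <- n_causes
  class(out) <- c("crs_sample", "data.frame")
  out
}

#' Number of competing causes of a sample
#' @param sample a [crs_sample()].
#' @return integer `J`.
#' @export
n_causes <- function(sample) {
  j <- attr(sample, "n_causes")
  if (is.null(j)) max(sample$cause, 1L) else j
}

.assert_crs <- function(sample) {
  if (!inherits(sample, "crs_sample"))
    stop("expected a 'crs_sample' object; see ?crs_sample")
  invisible(sample)
}

.assert_cause <- function(sample, cause) {
  j <- n_causes(sample)
  if (length(cause) != 1L || !is.finite(cause) || cause < 1 || cause > j ||
      cause != round(cause))
    stop("'cause' must be a single integer in 1..", j)
  if (!any(sample$cause == cause))
    stop("no events of cause ", cause, " in the sample")
  as.integer(cause)
}

#' @export
print.crs_sample <- function(x, ...) {
  j <- n_causes(x)
  cat("Competing-risks sample: ", nrow(x), " subjects, J = ", j,
      " causes\n", sep = "")
  tab <- table(factor(x$cause, levels = 0:j))
  cat("  censored: ", tab[["0"]],
      sprintf(" (%.1f%%)", 100 * tab[["0"]] / nrow(x)), "\n", sep = "")
  for (k in seq_len(j))
    cat("  cause ", k, " events: ", tab[[as.character(k)]], "\n", sep = "")
  cat("  follow-up: ", format(min(x$time), digits = 4), " .. ",
      format(max(x$time), digits = 4), "\n", sep = "")
  cat("  marker:    ", format(min(x$marker), digits = 4), " .. ",
      format(max(x$marker), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Read a subject-level survival table
#'
#' Reads a delimited text file (comma-separated by default; tab-separated for
#' `.tsv`/`.txt` unless `sep` is given) with a mandatory header row, and
#' validates it into a [crs_sample()].  Column names are configurable so that
#' existing files need not be rewritten.  Times are used on the scale given in
#' the file; no transformation is applied at I/O.
#'
#' @param path path to the file.
#' @param time,cause,marker,id column names holding the observed time, the
#'   event indicator (0 = censored, positive integers = causes), the marker,
#'   and (optionally) the subject id.
#' @param sep field separator; inferred from the file extension when `NULL`.
#' @param n_causes number of causes `J`; inferred as the maximum observed
#'   cause when `NULL`.
#' @return a [crs_sample()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(time = c(1, 2), status = c(1, 0), marker = c(2, 1)),
#'           f, row.names = FALSE)
#' read_crs(f)
#' @export
read_crs <- function(path, time = "time", cause = "status",
                     marker = "marker", id = NULL, sep = NULL,
                     n_causes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(time, cause, marker, id)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  zt <- suppressWarnings(as.numeric(raw[[time]]))
  if (anyNA(zt))
    stop("unparseable time in row ", which(is.na(zt))[1L], " of ", path)
  dl <- suppressWarnings(as.numeric(raw[[cause]]))
  if (anyNA(dl))
    stop("unparseable event indicator in row ", which(is.na(dl))[1L],
         " of ", path)
  mk <- suppressWarnings(as.numeric(raw[[marker]]))
  crs_sample(time = zt, cause = dl, marker = mk,
             id = if (is.null(id)) NULL else raw[[id]],
             n_causes = n_causes)
}

#' Write a competing-risks sample to delimited text
#'
#' Inverse of [read_crs()]: writes columns `id`, `time`, `status`, `marker`
#' with a header row.  Comma-separated unless the path ends in `.tsv`/`.txt`.
#'
#' @param sample a [crs_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crs <- function(sample, path) {
  .assert_crs(sample)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- data.frame(id = sample$id, time = sample$time,
                    status = sample$cause, marker = sample$marker)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Incident cases and dynamic controls at a time point
#'
#' Classifies the sample at time `t` for cause `j`: incident cases are
#' subjects observed to fail from cause `j` exactly at `t`
#' (\eqn{Z_i = t, \delta_i = j}); dynamic controls are subjects still under
#' observation strictly beyond `t` (\eqn{Z_k > t}).  A subject censored after
#' `t` therefore counts as a control at `t`, which is the only
#' censoring-consistent reading, while a subject censored exactly at `t` is
#' excluded.  Times outside the observed range simply yield empty sets.
#'
#' @param sample a [crs_sample()].
#' @param t a positive time.
#' @param cause cause index `j` in `1..J`.
#' @return A list of class `"crs_riskset"` with elements `time`, `cause`,
#'   `case_ids`, `control_ids`, `n_cases`, `n_controls`.
#' @examples
#' s <- crs_sample(time = c(1, 2, 3), cause = c(1, 0, 2), marker = c(2.5, 1.1, 0.7))
#' riskset_at(s, 1, cause = 1)
#' @export
riskset_at <- function(sample, t, cause) {
  .assert_crs(sample)
  j <- n_causes(sample)
  if (length(cause) != 1L || cause < 1 || cause > j || cause != round(cause))
    stop("'cause' must be a single integer in 1..", j)
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("'t' must be a single positive time")
  cases <- sample$time == t & sample$cause == cause
  controls <- sample$time > t
  structure(list(time = t, cause = as.integer(cause),
                 case_ids = sample$id[cases],
                 control_ids = sample$id[controls],
                 n_cases = sum(cases), n_controls = sum(controls)),
            class = "crs_riskset")
}

#' @export
print.crs_riskset <- function(x, ...) {
  cat("Riskset at t = ", format(x$time, digits = 6), ", cause ", x$cause,
      ": ", x$n_cases, " incident case(s), ", x$n_controls,
      " dynamic control(s)\n", sep = "")
  invisible(x)
}
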