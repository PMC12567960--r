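#' Uniformly sampled triaxial acceleration record
#'
#' Container for a seat-surface acceleration measurement on the X, Y and Z
#' axes at a common sample rate.
#'
#' @param fs sample rate (Hz), positive
#' @param ax,ay,az acceleration channels (m/s^2), equal length >= 2, finite
#' @param t0 start time (s), informational
#' @return Object of class `triaxial_signal`.
#' @export
triaxial_signal <- function(fs, ax, ay, az, t0 = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive sample rate", call. = FALSE)
  n <- length(az)
  if (n < 2L || length(ax) != n || length(ay) != n)
    stop("channels 'ax', 'ay', 'az' must have equal length >= 2", call. = FALSE)
  if (!all(is.finite(ax), is.finite(ay), is.finite(az)))
    stop("acceleration channels must be finite", call. = FALSE)
  structure(list(fs = fs, t0 = t0,
                 ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)),
            class = "triaxial_signal")
}

#' @export
print.triaxial_signal <- function(x, ...) {
  n <- length(x$az)
  cat(sprintf("Triaxial acceleration signal: %d samples at %g Hz (%.1f s)\n",
              n, x$fs, n / x$fs))
  cat(sprintf("  raw RMS (m/s^2): x %.4g, y %.4g, z %.4g\n",
              weighted_rms(x$ax), weighted_rms(x$ay), weighted_rms(x$az)))
  invisible(x)
}

#' Duration of a triaxial signal in seconds
#' @param signal a [triaxial_signal()]
#' @return numeric scalar (s)
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "triaxial_signal"))
  length(signal$az) / signal$fs
}

#' Read a triaxial time series from delimited text
#'
#' Expects a header with a time column `t` (s) and at least one of `ax`,
#' `ay`, `az` (m/s^2). The sampling grid must be uniform: the maximum
#' deviation of successive time steps from their median must stay below
#' `jitter_tol` (fraction of the step). Missing axis columns are filled with
#' zeros with a warning.
#'
#' @param path file path
#' @param jitter_tol maximum relative timing jitter tolerated (default 1%)
#' @return A [triaxial_signal()]; sample rate inferred from the time column.
#' @export
read_timeseries <- function(path, jitter_tol = 0.01) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"t" %in% names(df))
    stop("time-series file must contain a 't' column", call. = FALSE)
  axes <- intersect(c("ax", "ay", "az"), names(df))
  if (length(axes) == 0L)
    stop("time-series file must contain at least one of 'ax', 'ay', 'az'",
         call. = FALSE)
  if (nrow(df) < 2L) stop("time series too short", call. = FALSE)
  dtv <- diff(df$t)
  dt <- stats::median(dtv)
  if (dt <= 0 || max(abs(dtv - dt)) > jitter_tol * dt)
    stop(sprintf("non-uniform sampling: time-step jitter exceeds %g%% of dt",
                 100 * jitter_tol), call. = FALSE)
  miss <- setdiff(c("ax", "ay", "az"), axes)
  if (length(miss)) {
    warning("missing axis column(s) filled with zeros: ",
            paste(miss, collapse = ", "), call. = FALSE)
    for (m in miss) df[[m]] <- 0
  }
  triaxial_signal(fs = 1 / dt, ax = df$ax, ay = df$ay, az = df$az, t0 = df$t[1L])
}

#' Write a triaxial signal as delimited text
#'
#' Columns `t,ax,ay,az`, readable back with [read_timeseries()].
#'
#' @param signal a [triaxial_signal()]
#' @param path file path
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(signal, path) {
  stopifnot(inherits(signal, "triaxial_signal"))
  n <- length(signal$az)
  df <- data.frame(t = signal$t0 + (seq_len(n) - 1L) / signal$fs,
                   ax = signal$ax, ay = signal$ay, az = signal$az)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
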