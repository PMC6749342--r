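#' Uniformly sampled gait signal
#'
#' `gait_ts()` is the package's universal carrier for single-channel
#' elevation-angle time series: a numeric vector of angles (rad), a sampling
#' rate, a start time and a channel label. All estimators and detectors in
#' the package consume and produce this class.
#'
#' @param values numeric vector of angles, in radians; must be finite.
#' @param fs_hz sampling rate in samples per second (default 100, the rate
#'   of typical wearable IMU pipelines).
#' @param t0_s time of the first sample, seconds.
#' @param channel label, conventionally one of `"shank"`, `"foot"`,
#'   `"thigh"`.
#' @return An object of class `gait_ts`.
#' @examples
#' x <- gait_ts(sin(2 * pi * 0.8 * seq(0, 5, by = 0.01)), fs_hz = 100)
#' head(as.data.frame(x))
#' @export
gait_ts <- function(values, fs_hz = 100, t0_s = 0, channel = "shank") {
  values <- as.numeric(values)
  if (length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    stop("`fs_hz` must be a single positive finite number", call. = FALSE)
  }
  if (length(values) && any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  if (length(t0_s) != 1L || !is.finite(t0_s)) {
    stop("`t0_s` must be a single finite number", call. = FALSE)
  }
  structure(
    list(values = values, fs_hz = as.numeric(fs_hz),
         t0_s = as.numeric(t0_s), channel = as.character(channel)[1L]),
    class = "gait_ts"
  )
}

#' Sample times of a gait_ts
#'
#' @param x a [gait_ts] object.
#' @return numeric vector of sample times, seconds.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "gait_ts"))
  if (!length(x$values)) return(numeric(0))
  x$t0_s + (seq_along(x$values) - 1) / x$fs_hz
}

#' @export
length.gait_ts <- function(x) length(x$values)

#' @export
print.gait_ts <- function(x, ...) {
  cat(sprintf("<gait_ts> channel=%s  n=%d  fs=%g Hz  duration=%.2f s\n",
              x$channel, length(x$values), x$fs_hz,
              length(x$values) / x$fs_hz))
  invisible(x)
}

#' @export
as.data.frame.gait_ts <- function(x, ...) {
  data.frame(time_s = ts_time(x), angle_rad = x$values)
}

# Extract a sub-interval [from_s, to_s] (closed, in seconds from t0) as a
# new gait_ts. Used by the tuning window machinery.
#' Extract a time window from a signal
#'
#' @param x a [gait_ts].
#' @param from_s,to_s window bounds in seconds (absolute, i.e. on the same
#'   axis as [ts_time]).
#' @return a [gait_ts] holding the samples with `from_s <= t <= to_s`.
#' @export
ts_window <- function(x, from_s, to_s) {
  stopifnot(inherits(x, "gait_ts"), from_s <= to_s)
  t <- ts_time(x)
  keep <- t >= from_s - 1e-9 & t <= to_s + 1e-9
  gait_ts(x$values[keep], x$fs_hz,
          t0_s = if (any(keep)) t[which(keep)[1L]] else x$t0_s,
          channel = x$channel)
}
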