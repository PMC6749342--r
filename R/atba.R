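#' Adaptive threshold-based detector parameters
#'
#' The detector watches the oscillator's prediction-error stream through a
#' sliding window of the `w` samples strictly preceding the current frame,
#' computes their mean and standard deviation, and emits a warning whenever
#' the current error leaves the band `mu +/- k*sigma`. A run of `r`
#' consecutive warnings signals a loss of balance.
#'
#' @param w window length, samples (>= 2). At 100 Hz the default 400
#'   samples span 4 s, roughly four strides.
#' @param k threshold shaping factor (> 0). With Gaussian residuals,
#'   `k = 3.5` puts the per-sample warning probability below 0.05%.
#' @param r consecutive warnings required for a detection (>= 1).
#' @param sigma_floor lower bound on the usable sigma, rad; guards the
#'   degenerate zero-variance window.
#' @return an object of class `atba_params`.
#' @export
atba_params <- function(w = 400L, k = 3.5, r = 6L, sigma_floor = 1e-6) {
  vals <- c(w, k, r, sigma_floor)
  if (any(!is.finite(vals))) stop("non-finite atba_params value", call. = FALSE)
  if (w < 2) stop("w must be >= 2", call. = FALSE)
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  if (sigma_floor < 0) stop("sigma_floor must be >= 0", call. = FALSE)
  structure(list(w = as.integer(w), k = k, r = as.integer(r),
                 sigma_floor = sigma_floor),
            class = "atba_params")
}

#' Initialise a detector state
#'
#' @param params an [atba_params()].
#' @return an `atba_state` with an empty buffer, zero streak and no
#'   detection.
#' @export
atba_init <- function(params) {
  stopifnot(inherits(params, "atba_params"))
  structure(list(buffer = numeric(0), mu = NA_real_, sigma = NA_real_,
                 streak = 0L, detected_at = NA_integer_,
                 warmed_up = FALSE, n_seen = 0L),
            class = "atba_state")
}

#' One step of the adaptive threshold detector
#'
#' During warm-up (fewer than `w` samples seen) the buffer grows and no
#' warning can be emitted. Afterwards the window statistics are computed
#' from the `w` samples strictly before the current frame — the tested
#' sample never enters its own statistics — and the buffer then advances to
#' include it. Detection fires once, when the warning streak first reaches
#' `r`; the streak is capped at `r`.
#'
#' @param state an `atba_state`.
#' @param e_t current error sample, rad (finite).
#' @param params an [atba_params()].
#' @return a list: `state` (updated), `warning` (logical), `detection`
#'   (logical, `TRUE` only at the sample where the streak first reaches
#'   `r`).
#' @export
atba_step <- function(state, e_t, params) {
  if (!is.finite(e_t)) stop("e_t must be finite", call. = FALSE)
  state$n_seen <- state$n_seen + 1L
  warning_flag <- FALSE
  detection <- FALSE
  if (length(state$buffer) < params$w) {
    state$mu <- NA_real_
    state$sigma <- NA_real_
    state$streak <- 0L
  } else {
    state$warmed_up <- TRUE
    state$mu <- mean(state$buffer)
    state$sigma <- stats::sd(state$buffer)
    thr <- params$k * max(state$sigma, params$sigma_floor)
    warning_flag <- abs(e_t - state$mu) > thr
    if (warning_flag) {
      new_streak <- min(state$streak + 1L, params$r)
      if (state$streak + 1L == params$r && is.na(state$detected_at)) {
        detection <- TRUE
        state$detected_at <- state$n_seen
      }
      state$streak <- new_streak
    } else {
      state$streak <- 0L
    }
  }
  state$buffer <- c(state$buffer, e_t)
  if (length(state$buffer) > params$w) {
    state$buffer <- state$buffer[-1L]
  }
  list(state = state, warning = warning_flag, detection = detection)
}

# Rolling mean/sd of the w samples strictly before each frame, computed
# streaming via cumulative sums (R accumulates cumsum in long double, so
# these agree with per-window recomputation to ~1e-13). Frames 1..w get NA.
rolling_prior_stats <- function(e, w) {
  n <- length(e)
  mu <- rep(NA_real_, n)
  sg <- rep(NA_real_, n)
  if (n > w) {
    s1 <- c(0, cumsum(e))
    s2 <- c(0, cumsum(e * e))
    idx <- (w + 1):n
    sw <- s1[idx] - s1[idx - w]          # sums over e[(t-w)..(t-1)]
    sw2 <- s2[idx] - s2[idx - w]
    m <- sw / w
    v <- pmax((sw2 - w * m * m) / (w - 1), 0)
    mu[idx] <- m
    sg[idx] <- sqrt(v)
  }
  list(mu = mu, sigma = sg)
}

#' Run the detector over an error stream
#'
#' Batch equivalent of sequentially applying [atba_step()] (the equivalence
#' is enforced by tests). Returns the full per-sample trace for diagnostics
#' and the first detection, if any.
#'
#' @param errors a [gait_ts] or numeric vector of prediction errors; for a
#'   plain vector supply `fs_hz`.
#' @param params an [atba_params()].
#' @param fs_hz sampling rate when `errors` is a plain vector.
#' @return an object of class `detection_trace`: list with `trace` (a
#'   data.frame: `time_s`, `e`, `mu`, `sigma`, `warning`, `streak`,
#'   `detected`), `detected_at` (1-based sample index or `NA`),
#'   `detected_at_s` (seconds or `NA`), `warmed_up`, `params`.
#' @export
run_detector <- function(errors, params, fs_hz = NULL) {
  stopifnot(inherits(params, "atba_params"))
  if (inherits(errors, "gait_ts")) {
    fs_hz <- errors$fs_hz
    t0 <- errors$t0_s
    e <- errors$values
  } else {
    if (is.null(fs_hz)) stop("fs_hz required for plain vectors", call. = FALSE)
    t0 <- 0
    e <- as.numeric(errors)
  }
  n <- length(e)
  w <- params$w
  stats <- rolling_prior_stats(e, w)
  warn <- !is.na(stats$mu) &
    abs(e - stats$mu) > params$k * pmax(stats$sigma, params$sigma_floor)
  # consecutive-warning streak, capped at r
  streak <- integer(n)
  if (n) {
    runs <- rle(warn)
    streak <- sequence(runs$lengths)
    streak[!warn] <- 0L
    streak <- pmin(streak, params$r)
  }
  detected_at <- NA_integer_
  if (n) {
    raw <- sequence(rle(warn)$lengths)
    raw[!warn] <- 0L
    hit <- which(raw == params$r)
    if (length(hit)) detected_at <- hit[1L]
  }
  detected <- rep(FALSE, n)
  if (!is.na(detected_at)) detected[detected_at] <- TRUE
  trace <- data.frame(
    time_s = t0 + (seq_len(n) - 1) / fs_hz,
    e = e, mu = stats$mu, sigma = stats$sigma,
    warning = warn, streak = streak, detected = detected
  )
  structure(list(
    trace = trace,
    detected_at = detected_at,
    detected_at_s = if (is.na(detected_at)) NA_real_ else
      t0 + (detected_at - 1) / fs_hz,
    warmed_up = n > w,
    fs_hz = fs_hz,
    params = params
  ), class = "detection_trace")
}

#' @export
print.detection_trace <- function(x, ...) {
  cat(sprintf("<detection_trace> n=%d  w=%d k=%.2f r=%d  %s\n",
              nrow(x$trace), x$params$w, x$params$k, x$params$r,
              if (is.na(x$detected_at)) {
                if (x$warmed_up) "no detection" else "no detection (never warmed up)"
              } else {
                sprintf("detected at sample %d (%.2f s)", x$detected_at,
                        x$detected_at_s)
              }))
  invisible(x)
}
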