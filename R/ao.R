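#' Adaptive-oscillator parameters
#'
#' The estimator is a pool of phase-locked oscillators sharing one
#' fundamental phase/frequency and an adaptive waveform: it synchronises to
#' a quasi-periodic input and emits a zero-lag prediction. Two waveform
#' backends realise the same contract. The default `"fourier"` backend
#' carries a sine and a cosine amplitude per harmonic of the fundamental,
#' so cycles with arbitrary per-harmonic phases are representable; the
#' `"kernel"`
#' backend carries weights on a bank of von Mises bumps over the phase
#' circle (a kernel-based non-linear filter).
#'
#' @param k_P phase/frequency learning gain (dimensionless, >= 0). Governs
#'   how fast the oscillator's phase and frequency chase the input.
#' @param k_A amplitude learning gain (dimensionless, >= 0). Governs how
#'   fast the waveform coefficients adapt.
#' @param n_harmonics number of harmonics of the Fourier backend (>= 1).
#'   Default 6: enough to cover the foot channel's harmonic content at a
#'   ~0.8 Hz fundamental.
#' @param omega_init_rad_s initial fundamental frequency, rad/s. Default
#'   `2*pi/1.25`, the nominal stride frequency.
#' @param omega_min_rad_s,omega_max_rad_s clamp bounds on the learned
#'   frequency, rad/s. The clamp prevents frequency collapse during the
#'   large-error perturbation transient.
#' @param backend `"fourier"` or `"kernel"`.
#' @param n_kernels number of phase kernels for the kernel backend.
#' @return an object of class `ao_params`.
#' @export
ao_params <- function(k_P = 20, k_A = 1, n_harmonics = 6L,
                      omega_init_rad_s = 2 * pi / 1.25,
                      omega_min_rad_s = 2 * pi * 0.3,
                      omega_max_rad_s = 2 * pi * 2.5,
                      backend = c("fourier", "kernel"),
                      n_kernels = 20L) {
  backend <- match.arg(backend)
  vals <- c(k_P, k_A, n_harmonics, omega_init_rad_s, omega_min_rad_s,
            omega_max_rad_s, n_kernels)
  if (any(!is.finite(vals))) stop("non-finite ao_params value", call. = FALSE)
  if (k_P < 0 || k_A < 0) stop("learning gains must be >= 0", call. = FALSE)
  if (n_harmonics < 1) stop("n_harmonics must be >= 1", call. = FALSE)
  if (!(0 < omega_min_rad_s && omega_min_rad_s < omega_max_rad_s)) {
    stop("need 0 < omega_min < omega_max", call. = FALSE)
  }
  if (n_kernels < 3) stop("n_kernels must be >= 3", call. = FALSE)
  structure(list(k_P = k_P, k_A = k_A, n_harmonics = as.integer(n_harmonics),
                 omega_init_rad_s = omega_init_rad_s,
                 omega_min_rad_s = omega_min_rad_s,
                 omega_max_rad_s = omega_max_rad_s,
                 backend = backend, n_kernels = as.integer(n_kernels)),
            class = "ao_params")
}

# von Mises kernel bank: centres c_j equispaced on [0, 2pi); concentration
# set so neighbouring kernels overlap at half height.
kernel_basis <- function(phi, centres, kappa) {
  psi <- exp(kappa * (cos(phi - centres) - 1))
  psi / sum(psi)
}

#' Initialise an adaptive-oscillator state
#'
#' @param params an [ao_params()].
#' @return an `ao_state`: phase `phi = 0`, frequency `omega = omega_init`,
#'   zero offset and waveform coefficients, `y_hat = 0`, `e = NA`.
#' @export
ao_init <- function(params) {
  stopifnot(inherits(params, "ao_params"))
  if (params$omega_init_rad_s < params$omega_min_rad_s ||
      params$omega_init_rad_s > params$omega_max_rad_s) {
    stop("omega_init outside [omega_min, omega_max]", call. = FALSE)
  }
  ncoef <- if (params$backend == "fourier") params$n_harmonics else params$n_kernels
  st <- list(phi = 0, omega = params$omega_init_rad_s, alpha0 = 0,
             alpha = numeric(ncoef),
             beta = if (params$backend == "fourier") numeric(ncoef) else NULL,
             y_hat = 0, e = NA_real_)
  if (params$backend == "kernel") {
    st$centres <- 2 * pi * (seq_len(params$n_kernels) - 1) / params$n_kernels
    delta <- 2 * pi / params$n_kernels
    st$kappa <- log(2) / (1 - cos(delta))
  }
  structure(st, class = "ao_state")
}

ao_output <- function(state, params) {
  if (params$backend == "fourier") {
    ip <- seq_along(state$alpha) * state$phi
    state$alpha0 + sum(state$alpha * sin(ip)) + sum(state$beta * cos(ip))
  } else {
    state$alpha0 + sum(state$alpha * kernel_basis(state$phi, state$centres,
                                                  state$kappa))
  }
}

#' One forward-Euler step of the adaptive oscillator
#'
#' Computes the current prediction and error, then updates phase, frequency
#' (clamped) and waveform coefficients, and finally recomputes the
#' prediction and error of the updated state. With both gains at zero the
#' oscillator runs free: the phase advances at `omega` but no coefficient
#' changes.
#'
#' @param state an `ao_state`.
#' @param y_t measured angle at this sample, rad (finite).
#' @param dt sample interval, seconds (> 0).
#' @param params the [ao_params()] used at [ao_init()].
#' @return the updated `ao_state`, with `y_hat` and `e = y_t - y_hat`
#'   recomputed after the update.
#' @export
ao_step <- function(state, y_t, dt, params) {
  if (!is.finite(y_t)) stop("y_t must be finite", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  y_hat <- ao_output(state, params)
  e <- y_t - y_hat
  if (!is.finite(e) || abs(e) > 1e4) {
    stop("adaptive oscillator diverged (learning gains too large for dt)",
         call. = FALSE)
  }
  coup <- params$k_P * e * cos(state$phi)
  phi_new <- (state$phi + dt * (state$omega + coup)) %% (2 * pi)
  omega_new <- min(max(state$omega + dt * coup, params$omega_min_rad_s),
                   params$omega_max_rad_s)
  if (params$backend == "fourier") {
    ip <- seq_along(state$alpha) * state$phi
    state$alpha <- state$alpha + dt * params$k_A * e * sin(ip)
    state$beta <- state$beta + dt * params$k_A * e * cos(ip)
  } else {
    basis <- kernel_basis(state$phi, state$centres, state$kappa)
    state$alpha <- state$alpha + dt * params$k_A * e * basis
  }
  state$alpha0 <- state$alpha0 + dt * params$k_A * e
  state$phi <- phi_new
  state$omega <- omega_new
  state$y_hat <- ao_output(state, params)
  state$e <- y_t - state$y_hat
  if (!all(is.finite(c(state$phi, state$omega, state$alpha0, state$alpha,
                       state$beta)))) {
    stop("adaptive oscillator diverged (learning gains too large for dt)",
         call. = FALSE)
  }
  state
}

#' Track a signal with the adaptive oscillator
#'
#' Applies [ao_step()] sequentially over a uniformly sampled signal and
#' returns the per-sample record: measured angle, prediction, error,
#' learned frequency and phase. The error column is the stream the
#' threshold detector consumes.
#'
#' @param signal a [gait_ts].
#' @param params an [ao_params()].
#' @return a data.frame with columns `time_s`, `y`, `y_hat`, `e`, `omega`,
#'   `phi`, one row per input sample (zero rows for an empty signal);
#'   attribute `fs_hz` carries the sampling rate.
#' @examples
#' x <- generate_steady(gait_preset("shank"), duration_s = 10)
#' tr <- ao_track(x, ao_params(k_P = 20, k_A = 1))
#' tail(tr[c("time_s", "y", "y_hat", "e")])
#' @export
ao_track <- function(signal, params) {
  stopifnot(inherits(signal, "gait_ts"), inherits(params, "ao_params"))
  y <- signal$values
  n <- length(y)
  out <- data.frame(time_s = ts_time(signal), y = y,
                    y_hat = numeric(n), e = numeric(n),
                    omega = numeric(n), phi = numeric(n))
  attr(out, "fs_hz") <- signal$fs_hz
  if (n == 0L) return(out)
  dt <- 1 / signal$fs_hz
  kP <- params$k_P; kA <- params$k_A
  wmin <- params$omega_min_rad_s; wmax <- params$omega_max_rad_s
  fourier <- params$backend == "fourier"
  st <- ao_init(params)
  phi <- st$phi; omega <- st$omega; alpha0 <- st$alpha0; alpha <- st$alpha
  beta <- st$beta
  if (fourier) orders <- seq_along(alpha)
  # inlined ao_step loop; equivalence with the step function is under test
  for (i in seq_len(n)) {
    if (fourier) {
      ip <- orders * phi
      s_out <- sin(ip); c_out <- cos(ip)
      e_i <- y[i] - (alpha0 + sum(alpha * s_out) + sum(beta * c_out))
    } else {
      basis_out <- kernel_basis(phi, st$centres, st$kappa)
      e_i <- y[i] - (alpha0 + sum(alpha * basis_out))
    }
    # fail fast on blow-up: angles live on ~1 rad scales, so an error of
    # this size can only mean the Euler update has gone unstable
    if (!is.finite(e_i) || abs(e_i) > 1e4) {
      stop(sprintf(
        "adaptive oscillator diverged at sample %d (gains too large for dt)",
        i), call. = FALSE)
    }
    coup <- kP * e_i * cos(phi)
    if (fourier) {
      alpha <- alpha + dt * kA * e_i * s_out
      beta <- beta + dt * kA * e_i * c_out
    } else {
      alpha <- alpha + dt * kA * e_i * basis_out
    }
    alpha0 <- alpha0 + dt * kA * e_i
    phi <- (phi + dt * (omega + coup)) %% (2 * pi)
    omega <- min(max(omega + dt * coup, wmin), wmax)
    if (fourier) {
      ip <- orders * phi
      yh <- alpha0 + sum(alpha * sin(ip)) + sum(beta * cos(ip))
    } else {
      yh <- alpha0 + sum(alpha * kernel_basis(phi, st$centres, st$kappa))
    }
    out$y_hat[i] <- yh
    out$e[i] <- y[i] - yh
    out$omega[i] <- omega
    out$phi[i] <- phi
    if (!is.finite(yh)) {
      stop(sprintf(
        "adaptive oscillator diverged at sample %d (gains too large for dt)",
        i), call. = FALSE)
    }
  }
  out
}

#' Tracking accuracy over a trailing window
#'
#' Root-mean-square difference and Pearson correlation between a measured
#' and an estimated signal over the last `window_s` seconds — the tuning
#' gates for the oscillator stage (suitable tracking: RMSD < 0.1 rad and
#' rho > 0.9 over the 3 s preceding the perturbation onset).
#'
#' @param measured,estimated numeric vectors or [gait_ts] of equal length.
#' @param fs_hz sampling rate; taken from `measured` when it is a
#'   [gait_ts].
#' @param window_s trailing window length, seconds (default 3).
#' @return a list with `rmsd` (rad), `rho` (dimensionless, `NA` with a
#'   warning when either series has zero variance) and `n` (samples used).
#' @export
tracking_metrics <- function(measured, estimated, fs_hz = NULL,
                             window_s = 3) {
  if (inherits(measured, "gait_ts")) {
    fs_hz <- measured$fs_hz
    measured <- measured$values
  }
  if (inherits(estimated, "gait_ts")) estimated <- estimated$values
  if (is.null(fs_hz)) stop("fs_hz required for plain vectors", call. = FALSE)
  n <- length(measured)
  if (length(estimated) != n) stop("length mismatch", call. = FALSE)
  k <- min(n, round(window_s * fs_hz))
  if (k < 2) stop("window too short", call. = FALSE)
  m <- measured[(n - k + 1):n]
  est <- estimated[(n - k + 1):n]
  rmsd <- sqrt(mean((m - est)^2))
  rho <- if (stats::sd(m) == 0 || stats::sd(est) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(m, est)
  }
  list(rmsd = rmsd, rho = rho, n = k)
}
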