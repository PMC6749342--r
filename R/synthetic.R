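#' Configuration for the synthetic gait generator
#'
#' The generator models a segment elevation angle during steady treadmill
#' walking as a truncated Fourier series on a jittered stride clock:
#' within each stride the fundamental phase advances linearly over a period
#' drawn as `stride_period_s * (1 + period_jitter_frac * z)`, `z ~ N(0, 1)`,
#' and the angle is `mean + sum_h amp_h * sin(order_h * phase + phase_h)`
#' plus white measurement noise. This reproduces the features the detection
#' pipeline is sensitive to — stride period near 1.25 s, amplitudes of a few
#' tenths of a radian, stride-to-stride timing variability, and channel-
#' dependent harmonic content — without claiming biomechanical fidelity.
#'
#' @param stride_period_s mean stride period, seconds. Default 1.25 s, the
#'   typical unperturbed stride duration at 1 m/s treadmill walking.
#' @param fs_hz sampling rate, Hz.
#' @param harmonics data.frame with columns `order` (integer >= 1, distinct),
#'   `amplitude` (rad) and `phase` (rad): the Fourier description of the
#'   cycle shape.
#' @param mean_angle_rad constant offset, rad.
#' @param noise_sd_rad standard deviation of additive Gaussian measurement
#'   noise, rad. Default 0.01 rad.
#' @param period_jitter_frac stride-to-stride period variability as a
#'   fraction of the mean period. Default 0.048 (a 1.25 s stride with 0.06 s
#'   standard deviation).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `gait_config`.
#' @seealso [gait_preset()] for ready-made shank/foot channels.
#' @export
gait_config <- function(stride_period_s = 1.25, fs_hz = 100,
                        harmonics = data.frame(order = 1L, amplitude = 0.3,
                                               phase = 0),
                        mean_angle_rad = 0, noise_sd_rad = 0.01,
                        period_jitter_frac = 0.048, seed = 1L) {
  h <- as.data.frame(harmonics)
  if (nrow(h) && !all(c("order", "amplitude", "phase") %in% names(h))) {
    stop("`harmonics` needs columns order, amplitude, phase", call. = FALSE)
  }
  vals <- c(stride_period_s, fs_hz, mean_angle_rad, noise_sd_rad,
            period_jitter_frac, if (nrow(h)) unlist(h[c("order", "amplitude", "phase")]))
  if (any(!is.finite(vals))) stop("non-finite gait_config value", call. = FALSE)
  if (stride_period_s <= 0) stop("stride_period_s must be > 0", call. = FALSE)
  if (fs_hz <= 0) stop("fs_hz must be > 0", call. = FALSE)
  if (noise_sd_rad < 0) stop("noise_sd_rad must be >= 0", call. = FALSE)
  if (period_jitter_frac < 0) stop("period_jitter_frac must be >= 0", call. = FALSE)
  if (nrow(h)) {
    if (any(h$order < 1) || anyDuplicated(h$order)) {
      stop("harmonic orders must be >= 1 and distinct", call. = FALSE)
    }
    h$order <- as.integer(h$order)
  }
  structure(list(stride_period_s = stride_period_s, fs_hz = fs_hz,
                 harmonics = h, mean_angle_rad = mean_angle_rad,
                 noise_sd_rad = noise_sd_rad,
                 period_jitter_frac = period_jitter_frac,
                 seed = as.integer(seed)),
            class = "gait_config")
}

#' Channel presets for the synthetic generator
#'
#' Ready-made shank and foot elevation-angle channels. Both share the same
#' stride clock; the foot carries substantially more power in the higher
#' harmonics (orders up to 6, i.e. up to ~4.8 Hz at a 0.8 Hz fundamental)
#' than the shank (orders 1-3 dominant), mirroring the spectral ordering of
#' distal vs proximal segment kinematics. Amplitudes are in the
#' tenths-of-a-radian range typical of sagittal elevation angles.
#'
#' @param channel `"shank"` or `"foot"`.
#' @param seed RNG seed stored in the config.
#' @param ... overrides passed on to [gait_config()].
#' @return a `gait_config`.
#' @export
gait_preset <- function(channel = c("shank", "foot"), seed = 1L, ...) {
  channel <- match.arg(channel)
  h <- switch(channel,
    shank = data.frame(order = 1:4,
                       amplitude = c(0.30, 0.10, 0.040, 0.015),
                       phase = c(0, 1.1, 2.3, 0.7)),
    foot  = data.frame(order = 1:6,
                       amplitude = c(0.25, 0.15, 0.12, 0.10, 0.09, 0.08),
                       phase = c(0, 0.9, 1.8, 2.7, 3.6, 4.5))
  )
  mean_angle <- switch(channel, shank = 0.05, foot = 0.0)
  cfg <- gait_config(harmonics = h, mean_angle_rad = mean_angle,
                     seed = seed, ...)
  attr(cfg, "channel") <- channel
  cfg
}

#' Perturbation configuration
#'
#' Describes an abrupt deviation injected into a steady trial, emulating a
#' tripping perturbation delivered during the swing phase: the default
#' `arrest` mode holds the angle at its onset value for `hold_duration_s`
#' (the foot is braked and cannot move forward), then lets the signal
#' re-entrain exponentially to the steady pattern with time constant
#' `recovery_tau_s`. `offset` adds a constant bias from the onset on;
#' `ramp` adds a drift growing linearly to `magnitude_rad` over the hold.
#'
#' @param onset_s nominal perturbation onset, seconds from trial start.
#'   Default 15 s (trials are 15 s of steady walking plus 3 s after the
#'   onset).
#' @param hold_duration_s duration of the arrest/ramp, seconds. Default
#'   0.9 s, the duration the braked rope blocks the foot.
#' @param mode one of `"arrest"`, `"offset"`, `"ramp"`.
#' @param magnitude_rad deviation magnitude for offset/ramp modes, rad.
#' @param recovery_tau_s exponential re-entrainment time constant after an
#'   arrest, seconds.
#' @param onset_phase fundamental phase (rad in `[0, 2*pi)`, or `NA`) the
#'   onset snaps to: the perturbation starts at the first crossing of this
#'   phase at or after `onset_s`, emulating a trip triggered by a gait
#'   event (the braking cam is released at the contralateral heel strike,
#'   so the limb is arrested at a fixed, fast-moving point of its cycle).
#'   Default `pi`, the steepest part of the fundamental; `NA` disables
#'   snapping and the onset lands exactly at `onset_s`.
#' @return an object of class `pert_config`.
#' @export
pert_config <- function(onset_s = 15, hold_duration_s = 0.9,
                        mode = c("arrest", "offset", "ramp"),
                        magnitude_rad = 0.2, recovery_tau_s = 0.3,
                        onset_phase = pi) {
  mode <- match.arg(mode)
  vals <- c(onset_s, hold_duration_s, magnitude_rad, recovery_tau_s)
  if (any(!is.finite(vals))) stop("non-finite pert_config value", call. = FALSE)
  if (onset_s < 0 || hold_duration_s < 0 || recovery_tau_s <= 0) {
    stop("invalid pert_config timing", call. = FALSE)
  }
  if (!is.na(onset_phase) && (onset_phase < 0 || onset_phase >= 2 * pi)) {
    stop("onset_phase must be in [0, 2*pi) or NA", call. = FALSE)
  }
  structure(list(onset_s = onset_s, hold_duration_s = hold_duration_s,
                 mode = mode, magnitude_rad = magnitude_rad,
                 recovery_tau_s = recovery_tau_s, onset_phase = onset_phase),
            class = "pert_config")
}

# Jittered fundamental phase at the sample times t (seconds). Stride
# boundaries jitter around the treadmill-anchored grid j*T (bounded
# deviation: constant belt speed paces the walker, so stride timing varies
# stride-to-stride without accumulating phase drift). Boundary offsets are
# scaled so that stride DURATIONS have standard deviation
# period_jitter_frac * T. Phase is piecewise linear, advancing 2*pi per
# stride. Draws n_strides normals from the current RNG stream.
stride_phase <- function(t, cfg) {
  Tm <- cfg$stride_period_s
  n_str <- ceiling(max(t, 0) / Tm) + 2L
  z <- stats::rnorm(n_str)
  c_b <- cfg$period_jitter_frac / sqrt(2)          # boundary-offset scale
  bounds <- Tm * (seq_len(n_str) + pmax(pmin(c_b * z, 0.45), -0.45))
  bounds <- c(0, bounds)                           # trial starts on a stride
  j <- findInterval(t, bounds)                     # stride index, 1-based
  periods <- diff(bounds)
  phase <- 2 * pi * ((j - 1) + (t - bounds[j]) / periods[j])
  attr(phase, "bounds") <- bounds
  phase
}

# Deterministic core: returns list(clean, noise, phase) for n samples.
# Consumes the RNG stream in a fixed order (periods first, then noise) so
# perturbed/unperturbed trials from one seed share their pre-onset samples.
steady_components <- function(cfg, n) {
  t <- (seq_len(n) - 1) / cfg$fs_hz
  set.seed(cfg$seed)
  phase <- stride_phase(t, cfg)
  clean <- rep(cfg$mean_angle_rad, n)
  h <- cfg$harmonics
  for (i in seq_len(nrow(h))) {
    clean <- clean + h$amplitude[i] * sin(h$order[i] * phase + h$phase[i])
  }
  noise <- if (cfg$noise_sd_rad > 0) stats::rnorm(n, 0, cfg$noise_sd_rad) else numeric(n)
  list(t = t, clean = clean, noise = noise, phase = phase,
       bounds = attr(phase, "bounds"))
}

#' Generate a steady-walking elevation-angle signal
#'
#' @param cfg a [gait_config()].
#' @param duration_s signal duration, seconds; must cover at least two
#'   strides.
#' @return a [gait_ts] of `round(duration_s * fs_hz)` samples.
#' @examples
#' x <- generate_steady(gait_preset("shank"), duration_s = 10)
#' x
#' @export
generate_steady <- function(cfg, duration_s) {
  stopifnot(inherits(cfg, "gait_config"))
  if (!is.finite(duration_s) || duration_s < 2 * cfg$stride_period_s) {
    stop("duration_s must cover at least two strides", call. = FALSE)
  }
  n <- round(duration_s * cfg$fs_hz)
  comp <- steady_components(cfg, n)
  gait_ts(comp$clean + comp$noise, cfg$fs_hz,
          channel = attr(cfg, "channel") %||% "shank")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a (possibly perturbed) trial
#'
#' Builds an 18-s trial by default: steady walking, and — when `pert` is
#' given — an abrupt kinematic deviation from `onset_s` on. The perturbation
#' acts on the noiseless steady pattern; measurement noise is added on top
#' throughout, so a perturbed and an unperturbed trial generated from the
#' same config are sample-for-sample identical strictly before the onset.
#'
#' @param cfg a [gait_config()].
#' @param pert a [pert_config()], or `NULL` for an unperturbed trial.
#' @param duration_s trial duration, seconds (default 18: 15 s before the
#'   onset and 3 s after).
#' @return an object of class `gait_trial`: a list with elements `signal`
#'   ([gait_ts]), `onset_index` (1-based sample index, `NA` if unperturbed),
#'   `channel`, `perturbed`, and `events` — the generator's ground-truth
#'   stride-boundary sample indices (the synthetic stand-in for heel-strike
#'   events).
#' @export
generate_trial <- function(cfg, pert = NULL, duration_s = 18) {
  stopifnot(inherits(cfg, "gait_config"))
  n <- round(duration_s * cfg$fs_hz)
  if (!is.null(pert)) {
    stopifnot(inherits(pert, "pert_config"))
    if (pert$onset_s + pert$hold_duration_s >= duration_s) {
      stop("perturbation must end before the trial does", call. = FALSE)
    }
  }
  comp <- steady_components(cfg, n)
  clean <- comp$clean
  onset_index <- NA_integer_
  if (!is.null(pert)) {
    onset_index <- as.integer(round(pert$onset_s * cfg$fs_hz)) + 1L
    if (!is.na(pert$onset_phase)) {
      # snap to the next crossing of onset_phase on the fundamental cycle
      target <- pert$onset_phase +
        2 * pi * ceiling((comp$phase[onset_index] - pert$onset_phase) / (2 * pi))
      hit <- which(comp$phase[onset_index:n] >= target)
      if (!length(hit)) {
        stop("no onset-phase crossing before trial end", call. = FALSE)
      }
      onset_index <- onset_index + hit[1L] - 1L
    }
    if ((onset_index - 1L) / cfg$fs_hz + pert$hold_duration_s >= duration_s) {
      stop("perturbation must end before the trial does", call. = FALSE)
    }
    idx <- onset_index:n
    t_rel <- (idx - onset_index) / cfg$fs_hz        # seconds past onset
    clean[idx] <- switch(pert$mode,
      arrest = {
        held <- clean[onset_index]
        hold <- t_rel < pert$hold_duration_s
        out <- clean[idx]
        out[hold] <- held
        rel <- which(!hold)
        if (length(rel)) {
          t_release <- pert$hold_duration_s
          i_rel <- idx[rel][1L]
          gap <- held - clean[i_rel]
          out[rel] <- clean[idx[rel]] +
            gap * exp(-(t_rel[rel] - t_release) / pert$recovery_tau_s)
        }
        out
      },
      offset = clean[idx] + pert$magnitude_rad,
      ramp = clean[idx] + pert$magnitude_rad *
        pmin(t_rel / pert$hold_duration_s, 1)
    )
  }
  sig <- gait_ts(clean + comp$noise, cfg$fs_hz,
                 channel = attr(cfg, "channel") %||% "shank")
  events <- as.integer(round(comp$bounds * cfg$fs_hz)) + 1L
  events <- events[events >= 1L & events <= n]
  structure(list(signal = sig, onset_index = onset_index,
                 channel = sig$channel, perturbed = !is.null(pert),
                 events = events, gait_cfg = cfg, pert_cfg = pert),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> channel=%s  %s  n=%d @ %g Hz%s\n",
              x$channel,
              if (x$perturbed) "perturbed" else "unperturbed",
              length(x$signal$values), x$signal$fs_hz,
              if (x$perturbed)
                sprintf("  onset at sample %d (%.2f s)", x$onset_index,
                        (x$onset_index - 1) / x$signal$fs_hz)
              else ""))
  invisible(x)
}

#' Generate a reproducible benchmark of perturbed and unperturbed trials
#'
#' Each trial receives an independent sub-seed derived from the master seed
#' and the trial counter, so enlarging the benchmark never changes earlier
#' trials. Perturbed trials come first in the returned list.
#'
#' @param n_perturbed,n_unperturbed trial counts (>= 0).
#' @param cfg a [gait_config()] (its own `seed` field is overridden per
#'   trial).
#' @param pert a [pert_config()] applied to the perturbed trials.
#' @param seed master seed.
#' @param duration_s per-trial duration, seconds.
#' @return list of `gait_trial` objects, length `n_perturbed +
#'   n_unperturbed`.
#' @export
generate_benchmark <- function(n_perturbed, n_unperturbed, cfg,
                               pert = pert_config(), seed = 1L,
                               duration_s = 18) {
  stopifnot(n_perturbed >= 0, n_unperturbed >= 0)
  n_tot <- n_perturbed + n_unperturbed
  trials <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((as.numeric(seed) + 10007 * i) %% 2147483647)
    trials[[i]] <- generate_trial(
      cfg_i,
      pert = if (i <= n_perturbed) pert else NULL,
      duration_s = duration_s
    )
    trials[[i]]$trial_id <- i
  }
  trials
}
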