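#' Parameter grid for the two-stage tuning procedure
#'
#' The default grid spans the ranges practitioners sweep for this
#' detector: phase gains 1 to 100 in steps
#' of 10 (with 1 included), amplitude gains 1 to 50 likewise, window
#' lengths 200/300/400 samples, shaping factors 3/3.5/4 and warning counts
#' 6/8/10.
#'
#' @param kP_values,kA_values oscillator learning-gain candidates.
#' @param w_values,k_values,r_values detector candidates.
#' @return an object of class `tuning_grid`.
#' @export
tuning_grid <- function(kP_values = c(1, seq(10, 100, by = 10)),
                        kA_values = c(1, seq(10, 50, by = 10)),
                        w_values = c(200L, 300L, 400L),
                        k_values = c(3, 3.5, 4),
                        r_values = c(6L, 8L, 10L)) {
  if (!length(kP_values) || !length(kA_values) || !length(w_values) ||
      !length(k_values) || !length(r_values)) {
    stop("all grid dimensions must be non-empty", call. = FALSE)
  }
  structure(list(kP_values = kP_values, kA_values = kA_values,
                 w_values = as.integer(w_values), k_values = k_values,
                 r_values = as.integer(r_values)),
            class = "tuning_grid")
}

#' Run the full detection pipeline on one trial and classify the outcome
#'
#' Tracks the trial's signal with the adaptive oscillator, feeds the error
#' stream to the threshold detector, and classifies the result:
#' \describe{
#'   \item{TP}{perturbed trial detected within (0, 1] s after the onset.}
#'   \item{FP}{detection at or before the onset (perturbed trial), or any
#'     detection on an unperturbed trial. A detection exactly at the onset
#'     sample requires `r - 1` pre-onset warnings, i.e. a pre-onset
#'     anomaly, so it counts as FP.}
#'   \item{FN}{perturbed trial with no detection within 1 s after the
#'     onset.}
#'   \item{TN}{unperturbed trial with no detection.}
#' }
#'
#' @param trial a `gait_trial` (see [generate_trial()] or
#'   [read_trial_csv()]).
#' @param ao_params an [ao_params()].
#' @param atba_params an [atba_params()].
#' @param keep_trace keep the full detection trace in the result (default
#'   `FALSE` to keep benchmark sweeps light).
#' @return an object of class `detection_result`: `trial_id`,
#'   `classification` (`"TP"`, `"FP"`, `"FN"`, `"TN"`), `detected_at_s`,
#'   `detection_time_s` (seconds after onset, `NA` unless detected on a
#'   perturbed trial), `evaluable`.
#' @export
detect_trial <- function(trial, ao_params, atba_params, keep_trace = FALSE) {
  stopifnot(inherits(trial, "gait_trial"))
  n <- length(trial$signal$values)
  fs <- trial$signal$fs_hz
  if (n < atba_params$w + 1L) {
    return(structure(list(trial_id = trial$trial_id %||% NA,
                          classification = NA_character_,
                          detected_at_s = NA_real_,
                          detection_time_s = NA_real_,
                          evaluable = FALSE),
                     class = "detection_result"))
  }
  tr <- ao_track(trial$signal, ao_params)
  det <- run_detector(gait_ts(tr$e, fs, t0_s = trial$signal$t0_s),
                      atba_params)
  d <- det$detected_at
  detection_time_s <- NA_real_
  if (!trial$perturbed) {
    cls <- if (is.na(d)) "TN" else "FP"
  } else if (is.na(d)) {
    cls <- "FN"
  } else if (d <= trial$onset_index) {
    cls <- "FP"
  } else {
    detection_time_s <- (d - trial$onset_index) / fs
    cls <- if (detection_time_s <= 1) "TP" else "FN"
  }
  structure(list(trial_id = trial$trial_id %||% NA,
                 classification = cls,
                 detected_at_s = det$detected_at_s,
                 detection_time_s = if (cls == "TP") detection_time_s else NA_real_,
                 evaluable = TRUE,
                 trace = if (keep_trace) det else NULL),
            class = "detection_result")
}

#' Evaluate the pipeline over a set of trials
#'
#' @param trials list of `gait_trial` objects (at least one).
#' @param ao_params,atba_params pipeline parameters.
#' @return an object of class `eval_summary`: classification counts, mean
#'   detection time `mdt_s` and its across-trial standard deviation
#'   `mdt_sd_s` over TP trials (`NA` when there are none), false-alarm
#'   percentage `fa_pct = 100 * (FP + FN) / n_trials`, and the per-trial
#'   `results` data.frame.
#' @export
evaluate_trials <- function(trials, ao_params, atba_params) {
  if (!length(trials)) stop("need at least one trial", call. = FALSE)
  res <- lapply(trials, detect_trial, ao_params = ao_params,
                atba_params = atba_params)
  df <- data.frame(
    trial_id = vapply(res, function(r) as.numeric(r$trial_id %||% NA), 1),
    classification = vapply(res, function(r) r$classification, ""),
    detected_at_s = vapply(res, function(r) r$detected_at_s, 1),
    detection_time_s = vapply(res, function(r) r$detection_time_s, 1),
    evaluable = vapply(res, function(r) r$evaluable, TRUE)
  )
  ev <- df[df$evaluable, ]
  counts <- c(TP = sum(ev$classification == "TP"),
              FP = sum(ev$classification == "FP"),
              FN = sum(ev$classification == "FN"),
              TN = sum(ev$classification == "TN"))
  tp_times <- ev$detection_time_s[ev$classification == "TP"]
  n_eval <- nrow(ev)
  structure(list(
    counts = counts,
    n_trials = n_eval,
    mdt_s = if (length(tp_times)) mean(tp_times) else NA_real_,
    mdt_sd_s = if (length(tp_times) > 1) stats::sd(tp_times) else NA_real_,
    fa_pct = if (n_eval) 100 * (counts[["FP"]] + counts[["FN"]]) / n_eval else NA_real_,
    results = df
  ), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> n=%d  TP=%d FP=%d FN=%d TN=%d  FA=%.1f%%",
              x$n_trials, x$counts[["TP"]], x$counts[["FP"]],
              x$counts[["FN"]], x$counts[["TN"]], x$fa_pct))
  if (!is.na(x$mdt_s)) {
    cat(sprintf("  MDT=%.3f", x$mdt_s))
    if (!is.na(x$mdt_sd_s)) cat(sprintf(" +/- %.3f", x$mdt_sd_s))
    cat(" s")
  }
  cat("\n")
  invisible(x)
}

# Pre-onset portion of a trial: everything before onset for a perturbed
# trial, the whole signal otherwise.
pre_onset_signal <- function(trial) {
  if (trial$perturbed) {
    gait_ts(trial$signal$values[seq_len(trial$onset_index - 1L)],
            trial$signal$fs_hz, t0_s = trial$signal$t0_s,
            channel = trial$channel)
  } else {
    trial$signal
  }
}

#' Tune the oscillator learning gains
#'
#' For every `(k_P, k_A)` pair of the grid, tracks the steady (pre-onset)
#' part of each trial, computes RMSD and Pearson correlation over the
#' trailing `window_s` seconds, and averages across trials. A pair passes
#' when mean RMSD < `rmsd_max` and mean rho > `rho_min`.
#'
#' @param trials list of `gait_trial` with at least `window_s` seconds of
#'   steady walking before any onset.
#' @param grid a [tuning_grid()] (only `kP_values`/`kA_values` are used).
#' @param window_s trailing evaluation window, seconds.
#' @param rmsd_max,rho_min pass gates (defaults 0.1 rad and 0.9).
#' @param ao_base an [ao_params()] providing the non-gain settings.
#' @return data.frame with one row per gain pair: `k_P`, `k_A`, `rmsd`,
#'   `rho`, `pass`.
#' @export
tune_ao <- function(trials, grid = tuning_grid(), window_s = 3,
                    rmsd_max = 0.1, rho_min = 0.9,
                    ao_base = ao_params()) {
  if (!length(trials)) stop("need at least one trial", call. = FALSE)
  pre <- lapply(trials, pre_onset_signal)
  for (p in pre) {
    if (length(p$values) < round(window_s * p$fs_hz)) {
      stop("trials must hold >= window_s of steady walking", call. = FALSE)
    }
  }
  cells <- expand.grid(k_P = grid$kP_values, k_A = grid$kA_values)
  rmsd <- rho <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- ao_base
    p$k_P <- cells$k_P[i]
    p$k_A <- cells$k_A[i]
    # a diverging oscillator (gains too large for dt) simply fails the gate
    mm <- vapply(pre, function(sig) {
      tryCatch({
        tr <- ao_track(sig, p)
        m <- tracking_metrics(sig$values, tr$y_hat, fs_hz = sig$fs_hz,
                              window_s = window_s)
        c(m$rmsd, m$rho)
      }, error = function(e) c(Inf, NA_real_))
    }, numeric(2))
    rmsd[i] <- mean(mm[1, ])
    rho[i] <- mean(mm[2, ])
  }
  pass <- rmsd < rmsd_max & rho > rho_min
  pass[is.na(pass)] <- FALSE
  data.frame(k_P = cells$k_P, k_A = cells$k_A, rmsd = rmsd, rho = rho,
             pass = pass)
}

#' Tune the threshold detector over the (w, k, r) grid
#'
#' With the oscillator gains fixed, evaluates every detector cell on the
#' same trials (error streams are computed once and reused) and selects
#' the best cell: minimum mean detection time among cells with a
#' false-alarm percentage below `fa_max_pct`.
#'
#' @param trials list of `gait_trial`.
#' @param ao_params fixed oscillator parameters (already tuned).
#' @param grid a [tuning_grid()] (only `w/k/r` dimensions are used).
#' @param fa_max_pct false-alarm ceiling for the best-cell selector,
#'   percent (default 10).
#' @return data.frame with one row per `(w, k, r)` cell: counts, `mdt_s`,
#'   `mdt_sd_s`, `fa_pct`. Attribute `"best"` holds the selected row (zero
#'   rows if no cell meets the ceiling).
#' @export
tune_atba <- function(trials, ao_params, grid = tuning_grid(),
                      fa_max_pct = 10) {
  if (!length(trials)) stop("need at least one trial", call. = FALSE)
  fs <- trials[[1]]$signal$fs_hz
  err <- lapply(trials, function(tr) ao_track(tr$signal, ao_params)$e)
  cells <- expand.grid(w = grid$w_values, k = grid$k_values,
                       r = grid$r_values)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ap <- atba_params(w = cells$w[i], k = cells$k[i], r = cells$r[i])
    cls <- character(length(trials))
    dts <- rep(NA_real_, length(trials))
    for (j in seq_along(trials)) {
      trial <- trials[[j]]
      if (length(err[[j]]) < ap$w + 1L) {
        cls[j] <- NA_character_
        next
      }
      det <- run_detector(err[[j]], ap, fs_hz = fs)
      d <- det$detected_at
      if (!trial$perturbed) {
        cls[j] <- if (is.na(d)) "TN" else "FP"
      } else if (is.na(d)) {
        cls[j] <- "FN"
      } else if (d <= trial$onset_index) {
        cls[j] <- "FP"
      } else {
        dt <- (d - trial$onset_index) / fs
        if (dt <= 1) {
          cls[j] <- "TP"
          dts[j] <- dt
        } else cls[j] <- "FN"
      }
    }
    ok <- !is.na(cls)
    tp <- dts[ok & cls == "TP"]
    rows[[i]] <- data.frame(
      w = cells$w[i], k = cells$k[i], r = cells$r[i],
      TP = sum(cls[ok] == "TP"), FP = sum(cls[ok] == "FP"),
      FN = sum(cls[ok] == "FN"), TN = sum(cls[ok] == "TN"),
      mdt_s = if (length(tp)) mean(tp) else NA_real_,
      mdt_sd_s = if (length(tp) > 1) stats::sd(tp) else NA_real_,
      fa_pct = 100 * (sum(cls[ok] == "FP") + sum(cls[ok] == "FN")) / sum(ok)
    )
  }
  out <- do.call(rbind, rows)
  eligible <- out[!is.na(out$mdt_s) & out$fa_pct < fa_max_pct, ]
  best <- eligible[order(eligible$mdt_s), ][seq_len(min(1, nrow(eligible))), ]
  attr(out, "best") <- best
  out
}

#' Segment a signal into normalised stride cycles
#'
#' Cuts the signal at the supplied gait-event indices (each cycle runs from
#' one event to the next) and linearly time-interpolates every cycle over
#' 101 points (0, 1, ..., 100 percent of the cycle), then computes the
#' pointwise mean and standard deviation cycle.
#'
#' @param signal a [gait_ts].
#' @param events strictly increasing 1-based sample indices of the gait
#'   events (>= 2, within the signal).
#' @return an object of class `stride_set`: matrix `strides` (one row per
#'   cycle, 101 columns), `mean_cycle`, `sd_cycle`, `stride_durations_s`.
#' @export
segment_strides <- function(signal, events) {
  stopifnot(inherits(signal, "gait_ts"))
  events <- as.integer(events)
  n <- length(signal$values)
  if (length(events) < 2) stop("need at least two events", call. = FALSE)
  if (any(diff(events) <= 0)) stop("events must be strictly increasing", call. = FALSE)
  if (events[1] < 1 || events[length(events)] > n) {
    stop("events out of signal range", call. = FALSE)
  }
  n_str <- length(events) - 1L
  strides <- matrix(NA_real_, n_str, 101L)
  for (i in seq_len(n_str)) {
    a <- events[i]; b <- events[i + 1L]
    seg <- signal$values[a:b]
    strides[i, ] <- stats::approx(seq(0, 1, length.out = length(seg)), seg,
                                  xout = seq(0, 1, length.out = 101L))$y
  }
  structure(list(
    strides = strides,
    mean_cycle = colMeans(strides),
    sd_cycle = apply(strides, 2, stats::sd),
    stride_durations_s = diff(events) / signal$fs_hz
  ), class = "stride_set")
}
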