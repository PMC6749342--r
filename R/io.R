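#' Write a trial to CSV with a JSON sidecar
#'
#' The CSV holds two columns, `time_s` and `angle_rad`, formatted with 12
#' significant digits so writes are byte-for-byte deterministic. Trial
#' metadata (channel, perturbed flag, onset index, sampling rate) go to a
#' sidecar JSON next to the CSV (same path, `.json` extension).
#'
#' @param trial a `gait_trial`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  df <- as.data.frame(trial$signal)
  lines <- c("time_s,angle_rad",
             sprintf("%.12g,%.12g", df$time_s, df$angle_rad))
  writeLines(lines, path)
  meta <- list(channel = trial$channel,
               perturbed = trial$perturbed,
               onset_index = if (is.na(trial$onset_index)) NULL else trial$onset_index,
               fs_hz = trial$signal$fs_hz,
               t0_s = trial$signal$t0_s,
               events = trial$events)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[Cc][Ss][Vv]$", ".json", path)

#' Read a trial from CSV (+ optional JSON sidecar)
#'
#' Timestamps must be uniform to within 1e-6 s; a gap is reported with the
#' offending row number. Without a sidecar the trial loads as unperturbed
#' with a warning.
#'
#' @param path CSV path with columns `time_s`, `angle_rad`.
#' @return a `gait_trial`.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "angle_rad") %in% names(df))) {
    stop("CSV must have columns time_s and angle_rad", call. = FALSE)
  }
  if (nrow(df) < 2) stop("trial too short", call. = FALSE)
  dts <- diff(df$time_s)
  dt <- stats::median(dts)
  bad <- which(abs(dts - dt) > 1e-6)
  if (length(bad)) {
    stop(sprintf("non-uniform timestamp at row %d (dt %.6g, expected %.6g)",
                 bad[1L] + 1L, dts[bad[1L]], dt), call. = FALSE)
  }
  fs <- 1 / dt
  side <- sidecar_path(path)
  if (file.exists(side) && side != path) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    onset <- if (is.null(meta$onset_index)) NA_integer_ else as.integer(meta$onset_index)
    perturbed <- isTRUE(meta$perturbed)
    channel <- meta$channel %||% "shank"
    fs <- meta$fs_hz %||% fs
    events <- if (is.null(meta$events)) NULL else as.integer(meta$events)
  } else {
    warning("no sidecar JSON found; loading as unperturbed", call. = FALSE)
    onset <- NA_integer_
    perturbed <- FALSE
    channel <- "shank"
    events <- NULL
  }
  sig <- gait_ts(df$angle_rad, fs, t0_s = df$time_s[1L], channel = channel)
  structure(list(signal = sig, onset_index = onset, channel = channel,
                 perturbed = perturbed, events = events),
            class = "gait_trial")
}

#' Second time-derivative by central finite differences
#'
#' Interior samples use the central second difference; the two edge
#' samples reuse their nearest interior estimate (one-sided stencil).
#'
#' @param x a [gait_ts].
#' @return a [gait_ts] in units of rad/s^2 (input units per second
#'   squared).
#' @export
second_derivative <- function(x) {
  stopifnot(inherits(x, "gait_ts"))
  v <- x$values
  n <- length(v)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  dt <- 1 / x$fs_hz
  d2 <- numeric(n)
  i <- 2:(n - 1)
  d2[i] <- (v[i + 1] - 2 * v[i] + v[i - 1]) / dt^2
  d2[1] <- (v[3] - 2 * v[2] + v[1]) / dt^2
  d2[n] <- (v[n] - 2 * v[n - 1] + v[n - 2]) / dt^2
  gait_ts(d2, x$fs_hz, t0_s = x$t0_s, channel = x$channel)
}

#' Time-lag between two records by normalised cross-correlation
#'
#' Scans lags in `[-max_lag_s, +max_lag_s]` and returns the lag maximising
#' the Pearson correlation of the overlapping parts. Sign convention:
#' a positive lag means `b` is delayed with respect to `a` (i.e.
#' `b(t) = a(t - lag)`). Ties are broken toward the smallest `|lag|`.
#'
#' @param a,b [gait_ts] objects with equal sampling rates.
#' @param max_lag_s maximum absolute lag scanned, seconds (default 1).
#' @return a list: `lag_samples` (signed integer), `lag_s`, `peak_corr`.
#' @export
estimate_lag <- function(a, b, max_lag_s = 1) {
  stopifnot(inherits(a, "gait_ts"), inherits(b, "gait_ts"))
  if (abs(a$fs_hz - b$fs_hz) > 1e-9) stop("sampling rates differ", call. = FALSE)
  fs <- a$fs_hz
  L <- as.integer(round(max_lag_s * fs))
  na <- length(a$values); nb <- length(b$values)
  if (min(na, nb) < 2 * L + 2) stop("signals too short for max_lag", call. = FALSE)
  if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  lags <- (-L):L
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      ia <- seq_len(min(na, nb - l))   # a[1..] vs b[(1+l)..]
      ib <- ia + l
    } else {
      ia <- seq_len(min(na + l, nb)) - l
      ib <- ia + l
    }
    if (length(ia) < 2) return(-Inf)
    suppressWarnings(stats::cor(a$values[ia], b$values[ib]))
  }, 1)
  cc[!is.finite(cc)] <- -Inf
  peak <- max(cc)
  cand <- which(cc >= peak - 1e-12)
  best <- cand[which.min(abs(lags[cand]))]
  list(lag_samples = lags[best], lag_s = lags[best] / fs,
       peak_corr = cc[best])
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments with 50% overlap,
#' per-segment mean removal, one-sided scaling such that the integral of
#' the PSD over frequency approximates the signal variance (Parseval).
#'
#' @param x a [gait_ts] holding at least 2 s of data.
#' @param seg_s segment length, seconds (default 4; shortened if the
#'   signal is shorter).
#' @return a data.frame with columns `freq_hz` and `power` (rad^2/Hz).
#' @export
psd_welch <- function(x, seg_s = 4) {
  stopifnot(inherits(x, "gait_ts"))
  v <- x$values
  fs <- x$fs_hz
  n <- length(v)
  if (n < 2 * fs) stop("need at least 2 s of data", call. = FALSE)
  nseg <- min(n, round(seg_s * fs))
  step <- max(1L, floor(nseg / 2))
  win <- signal::hanning(nseg)
  U <- sum(win^2)
  starts <- seq(1L, n - nseg + 1L, by = step)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- v[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    X <- stats::fft(seg)[seq_len(nf)]
    P <- (Mod(X)^2) / (fs * U)
    # one-sided: double everything except DC (and Nyquist for even nseg)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + P * dbl
  }
  data.frame(freq_hz = (seq_len(nf) - 1) * fs / nseg,
             power = acc / length(starts))
}

#' Spectral centroid of a PSD
#'
#' Power-weighted mean frequency, excluding the DC bin.
#'
#' @param psd data.frame from [psd_welch()].
#' @return centroid frequency, Hz.
#' @export
spectral_centroid <- function(psd) {
  stopifnot(all(c("freq_hz", "power") %in% names(psd)))
  keep <- psd$freq_hz > 0
  sum(psd$freq_hz[keep] * psd$power[keep]) / sum(psd$power[keep])
}
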