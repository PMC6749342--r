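# Independent oracles used across the suite. These deliberately do not call
# package internals beyond parameter containers.

# Reference integration of the adaptive-oscillator ODE with a plain Euler
# loop at an arbitrary (fine) step, driven by a continuous-time input
# function. Written independently of ao_track: scalar state updates, no
# shared code path.
ao_reference <- function(input_fn, duration_s, dt, k_P, k_A, n_harm = 6,
                         omega0 = 2 * pi / 1.25,
                         omega_min = 2 * pi * 0.3, omega_max = 2 * pi * 2.5) {
  n <- floor(duration_s / dt)
  phi <- 0; omega <- omega0; a0 <- 0
  a <- numeric(n_harm); b <- numeric(n_harm)
  ords <- seq_len(n_harm)
  for (i in seq_len(n)) {
    y <- input_fn((i - 1) * dt)
    s <- sin(ords * phi); cc <- cos(ords * phi)
    e <- y - (a0 + sum(a * s) + sum(b * cc))
    coup <- k_P * e * cos(phi)
    a <- a + dt * k_A * e * s
    b <- b + dt * k_A * e * cc
    a0 <- a0 + dt * k_A * e
    phi <- (phi + dt * (omega + coup)) %% (2 * pi)
    omega <- min(max(omega + dt * coup, omega_min), omega_max)
  }
  list(omega = omega, phi = phi)
}

# Brute-force rolling statistics of the w samples strictly before each
# frame: O(n*w) recomputation with mean()/sd() per window.
rolling_stats_bruteforce <- function(e, w) {
  n <- length(e)
  mu <- rep(NA_real_, n)
  sg <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t > w) {
      win <- e[(t - w):(t - 1)]
      mu[t] <- mean(win)
      sg[t] <- sd(win)
    }
  }
  list(mu = mu, sigma = sg)
}

# Plain sinusoid as a gait_ts.
sine_ts <- function(freq_hz, amp = 0.3, duration_s = 15, fs = 100,
                    phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  gait_ts(amp * sin(2 * pi * freq_hz * t + phase), fs)
}

# Small, fast session-like benchmark for pipeline tests.
small_benchmark <- function(n_pert, n_unpert, preset = "shank", seed = 101,
                            duration_s = 18) {
  generate_benchmark(n_pert, n_unpert, gait_preset(preset),
                     pert = pert_config(), seed = seed,
                     duration_s = duration_s)
}
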