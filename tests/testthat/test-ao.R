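test_that("initialisation validates parameters and is reproducible", {
  p <- ao_params()
  s1 <- ao_init(p)
  s2 <- ao_init(p)
  expect_identical(s1, s2)
  expect_equal(s1$y_hat, 0)
  expect_equal(s1$phi, 0)
  expect_equal(s1$omega, p$omega_init_rad_s)
  expect_error(ao_init(ao_params(omega_init_rad_s = 2 * pi * 5)), "clamp|omega")
  expect_error(ao_params(k_P = -1), "gains")
  expect_error(ao_params(omega_min_rad_s = 3, omega_max_rad_s = 2), "omega")
})

test_that("zero gains freeze every learned quantity", {
  p <- ao_params(k_P = 0, k_A = 0)
  st <- ao_init(p)
  for (y in c(0.5, -0.2, 1.0)) {
    st2 <- ao_step(st, y, 0.01, p)
    expect_identical(st2$omega, st$omega)
    expect_identical(st2$alpha, st$alpha)
    expect_identical(st2$beta, st$beta)
    expect_identical(st2$alpha0, st$alpha0)
    expect_equal(st2$e, y)            # alpha = 0 so y_hat stays 0
    st <- st2
  }
  expect_equal(st$phi, 3 * 0.01 * p$omega_init_rad_s, tolerance = 1e-12)
})

test_that("ao_track equals sequential ao_step application", {
  sig <- generate_steady(gait_preset("shank", seed = 9), 4)
  for (backend in c("fourier", "kernel")) {
    p <- ao_params(k_P = 20, k_A = 1, backend = backend)
    tr <- ao_track(sig, p)
    st <- ao_init(p)
    e_seq <- omega_seq <- numeric(length(sig$values))
    for (i in seq_along(sig$values)) {
      st <- ao_step(st, sig$values[i], 1 / sig$fs_hz, p)
      e_seq[i] <- st$e
      omega_seq[i] <- st$omega
    }
    expect_equal(tr$e, e_seq, tolerance = 1e-12)
    expect_equal(tr$omega, omega_seq, tolerance = 1e-12)
  }
  expect_identical(nrow(ao_track(gait_ts(numeric(0), 100), ao_params())), 0L)
})

test_that("oscillator locks onto a sinusoid and recovers its frequency", {
  # cross-checked against an independent fine-step reference integration
  for (f in c(0.5, 1.0, 1.5)) {
    x <- sine_ts(f)
    tr <- ao_track(x, ao_params(k_P = 20, k_A = 1))
    w_true <- 2 * pi * f
    expect_lt(abs(tail(tr$omega, 1) - w_true) / w_true, 0.05)
  }
  x <- sine_ts(0.8)
  tr <- ao_track(x, ao_params(k_P = 20, k_A = 1))
  expect_lt(sqrt(mean(tail(tr$e, 300)^2)), 0.02)   # RMS error, last 3 s
  ref <- ao_reference(function(t) 0.3 * sin(2 * pi * 0.8 * t),
                      duration_s = 15, dt = 1e-4, k_P = 20, k_A = 1)
  expect_lt(abs(tail(tr$omega, 1) - ref$omega) / ref$omega, 0.02)
})

test_that("halving the step changes the learned frequency by < 1%", {
  f <- 0.8
  w100 <- tail(ao_track(sine_ts(f, fs = 100), ao_params(20, 1))$omega, 1)
  w200 <- tail(ao_track(sine_ts(f, fs = 200), ao_params(20, 1))$omega, 1)
  expect_lt(abs(w100 - w200) / w200, 0.01)
})

test_that("constant input drives the offset coefficient to the constant", {
  x <- gait_ts(rep(0.4, 800), 100)
  tr <- ao_track(x, ao_params(k_P = 0, k_A = 2))
  expect_lt(abs(tail(tr$e, 1)), abs(tr$e[1]))
  # envelope of |e| decays: compare maxima over successive 2-s blocks
  env <- vapply(split(abs(tr$e), rep(1:4, each = 200)), max, 1)
  expect_true(all(diff(env) < 0))
})

test_that("steady tracking error grows with input frequency (low-pass)", {
  rmsds <- vapply(c(0.5, 1.0, 1.5), function(f) {
    cfg <- gait_config(stride_period_s = 1 / f,
                       harmonics = data.frame(order = 1, amplitude = 0.3,
                                              phase = 0),
                       noise_sd_rad = 0, seed = 5)
    sig <- generate_steady(cfg, 15)
    tr <- ao_track(sig, ao_params(k_P = 20, k_A = 1))
    tracking_metrics(sig$values, tr$y_hat, fs_hz = 100, window_s = 3)$rmsd
  }, 1)
  expect_true(all(diff(rmsds) > 0))
})

test_that("error jumps after an arrest perturbation on a tracked trial", {
  tr <- generate_trial(gait_preset("shank", seed = 21), pert_config())
  rec <- ao_track(tr$signal, ao_params(k_P = 20, k_A = 1))
  on <- tr$onset_index
  post <- mean(abs(rec$e[on:(on + 49)]))
  pre <- mean(abs(rec$e[(on - 300):(on - 1)]))
  expect_gt(post, 3 * pre)
})

test_that("kernel backend fulfils the same tracking contract", {
  sig <- generate_steady(gait_preset("shank", seed = 33), 15)
  tr <- ao_track(sig, ao_params(k_P = 20, k_A = 2, backend = "kernel",
                                n_kernels = 25))
  m <- tracking_metrics(sig$values, tr$y_hat, fs_hz = 100, window_s = 3)
  expect_lt(m$rmsd, 0.1)
  expect_gt(m$rho, 0.9)
})

test_that("tracking metrics follow their closed-form cases", {
  x <- sin(seq(0, 10, by = 0.01))
  m <- tracking_metrics(x, x, fs_hz = 100)
  expect_equal(m$rmsd, 0)
  expect_equal(m$rho, 1)
  m2 <- tracking_metrics(x, x + 0.05, fs_hz = 100)
  expect_equal(m2$rmsd, 0.05, tolerance = 1e-12)
  expect_equal(m2$rho, 1)
  expect_equal(tracking_metrics(x, -x, fs_hz = 100)$rho, -1)
  expect_warning(tracking_metrics(rep(1, 500), x[1:500], fs_hz = 100),
                 "zero variance")
  expect_error(tracking_metrics(x, x[-1], fs_hz = 100), "length")
})

test_that("diverging gains raise a diagnostic error", {
  sig <- generate_steady(gait_preset("shank", seed = 2), 15)
  expect_error(ao_track(sig, ao_params(k_P = 20, k_A = 50)), "diverged")
})
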