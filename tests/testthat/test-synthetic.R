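test_that("generator is deterministic and validates its configuration", {
  cfg <- gait_preset("shank", seed = 42)
  a <- generate_steady(cfg, 10)
  b <- generate_steady(cfg, 10)
  expect_identical(a$values, b$values)
  expect_length(a$values, 1000L)

  expect_error(gait_config(stride_period_s = -1), "stride_period")
  expect_error(gait_config(noise_sd_rad = NaN), "non-finite")
  expect_error(
    gait_config(harmonics = data.frame(order = c(1, 1), amplitude = 0.1,
                                       phase = 0)),
    "distinct")
  expect_error(generate_steady(cfg, 1), "two strides")
})

test_that("waveform follows the configured Fourier series", {
  # no harmonics, no noise: constant at the mean angle
  flat <- gait_config(harmonics = data.frame(order = integer(0),
                                             amplitude = numeric(0),
                                             phase = numeric(0)),
                      mean_angle_rad = 0.1, noise_sd_rad = 0, seed = 1)
  x <- generate_steady(flat, 5)
  expect_equal(x$values, rep(0.1, 500))

  # one harmonic, no jitter/noise: quarter-period sample hits mean + amp
  one <- gait_config(stride_period_s = 1, fs_hz = 100,
                     harmonics = data.frame(order = 1, amplitude = 0.3,
                                            phase = 0),
                     mean_angle_rad = 0.1, noise_sd_rad = 0,
                     period_jitter_frac = 0, seed = 1)
  y <- generate_steady(one, 5)
  expect_equal(y$values[26], 0.1 + 0.3, tolerance = 1e-12)  # t = T/4
})

test_that("channel presets have the expected spectral structure", {
  shank <- psd_welch(generate_steady(gait_preset("shank", seed = 3), 60))
  foot <- psd_welch(generate_steady(gait_preset("foot", seed = 3), 60))
  frac_above <- function(p, f0) sum(p$power[p$freq_hz >= f0]) / sum(p$power)
  # shank: >90% of power below 4 Hz; foot carries strictly more above
  expect_gt(1 - frac_above(shank, 4), 0.9)
  expect_gt(frac_above(foot, 4), frac_above(shank, 4))
  expect_gt(spectral_centroid(foot), spectral_centroid(shank))
})

test_that("perturbation modes behave as defined", {
  cfg <- gait_preset("shank", seed = 7, noise_sd_rad = 0)
  pert <- pert_config(onset_s = 10, hold_duration_s = 0.9)
  tr <- generate_trial(cfg, pert, duration_s = 15)
  st <- generate_trial(cfg, NULL, duration_s = 15)
  on <- tr$onset_index
  # arrest: constant over the hold
  hold <- on:(on + 89L)
  expect_equal(diff(tr$signal$values[hold]), rep(0, 89), tolerance = 1e-12)
  # identical to the unperturbed trial strictly before the onset
  expect_identical(tr$signal$values[1:(on - 1)], st$signal$values[1:(on - 1)])
  expect_false(st$perturbed)
  expect_true(is.na(st$onset_index))

  # offset with zero magnitude is a no-op
  z <- generate_trial(cfg, pert_config(onset_s = 10, mode = "offset",
                                       magnitude_rad = 0),
                      duration_s = 15)
  expect_identical(z$signal$values, st$signal$values)

  # onset beyond the trial end is rejected
  expect_error(generate_trial(cfg, pert_config(onset_s = 20), duration_s = 15),
               "before the trial")
  # phase snapping lands the onset on the requested fundamental phase
  expect_gte(on, 1001L)
})

test_that("benchmarks are reproducible and stable under extension", {
  cfg <- gait_preset("shank")
  b1 <- generate_benchmark(2, 1, cfg, pert_config(), seed = 5)
  b2 <- generate_benchmark(2, 1, cfg, pert_config(), seed = 5)
  expect_identical(lapply(b1, `[[`, "signal"), lapply(b2, `[[`, "signal"))
  expect_length(b1, 3L)
  expect_identical(vapply(generate_benchmark(0, 3, cfg, seed = 5),
                          `[[`, TRUE, "perturbed"),
                   rep(FALSE, 3))
  # counter-based sub-seeds: enlarging the set never changes earlier trials
  b3 <- generate_benchmark(2, 4, cfg, pert_config(), seed = 5)
  expect_identical(b1[[1]]$signal$values, b3[[1]]$signal$values)
  expect_identical(b1[[3]]$signal$values, b3[[3]]$signal$values)
})

test_that("stride timing statistics match the configured jitter", {
  cfg <- gait_preset("shank", seed = 13)   # jitter 0.048, T = 1.25 s
  trials <- generate_benchmark(0, 10, cfg, seed = 13)
  durs <- unlist(lapply(trials, function(tr) diff(tr$events) / 100))
  expect_equal(mean(durs), 1.25, tolerance = 0.02)      # mean within 2%
  cv <- sd(durs) / mean(durs)
  expect_gt(cv, 0.048 * 0.7)
  expect_lt(cv, 0.048 * 1.3)
})
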