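test_that("parameters are validated", {
  expect_error(atba_params(w = 1), "w")
  expect_error(atba_params(k = 0), "k")
  expect_error(atba_params(r = 0), "r")
  expect_error(atba_params(sigma_floor = -1), "sigma_floor")
})

test_that("no warning can be emitted during warm-up", {
  p <- atba_params(w = 50, k = 3, r = 3)
  set.seed(1)
  det <- run_detector(rnorm(50) * 10, p, fs_hz = 100)
  expect_false(any(det$trace$warning))
  expect_false(det$warmed_up)
  expect_true(is.na(det$detected_at))
})

test_that("a constant error stream never warns", {
  p <- atba_params(w = 20, k = 3, r = 2, sigma_floor = 1e-6)
  det <- run_detector(rep(0.3, 500), p, fs_hz = 100)
  expect_false(any(det$trace$warning))
  expect_true(is.na(det$detected_at))
})

test_that("a saturating step is detected exactly r samples after onset", {
  fs <- 100
  set.seed(42)
  base_sd <- 0.01
  pre <- rnorm(500, 0, base_sd)
  for (r in c(6L, 8L, 10L)) {
    p <- atba_params(w = 400, k = 3.5, r = r)
    e <- c(pre, rep(10 * 3.5 * base_sd, 100))
    det <- run_detector(e, p, fs_hz = fs)
    expect_identical(det$detected_at, 500L + r)
  }
})

test_that("detection latency is monotone in r and k on a fixed stream", {
  tr <- generate_trial(gait_preset("shank", seed = 55), pert_config())
  e <- ao_track(tr$signal, ao_params(k_P = 20, k_A = 1))$e
  latency <- function(d) if (is.na(d)) Inf else as.numeric(d)  # no detection: infinite
  det_r <- vapply(c(6L, 8L, 10L), function(r)
    latency(run_detector(e, atba_params(w = 400, k = 3.5, r = r),
                         fs_hz = 100)$detected_at), 1)
  expect_false(is.infinite(det_r[1]))
  expect_true(all(diff(det_r) >= 0))
  det_k <- vapply(c(3, 3.5, 4), function(k)
    latency(run_detector(e, atba_params(w = 400, k = k, r = 6),
                         fs_hz = 100)$detected_at), 1)
  expect_true(all(diff(det_k) >= 0))
})

test_that("streaming statistics equal brute-force recomputation", {
  set.seed(7)
  e <- rnorm(3000, 0, 0.05) + 0.2 * sin(seq_len(3000) / 40)
  p <- atba_params(w = 400, k = 3.5, r = 6)
  det <- run_detector(e, p, fs_hz = 100)
  ref <- rolling_stats_bruteforce(e, 400)
  expect_equal(det$trace$mu, ref$mu, tolerance = 1e-10)
  expect_equal(det$trace$sigma, ref$sigma, tolerance = 1e-10)
})

test_that("batch detector equals sequential atba_step application", {
  set.seed(11)
  e <- c(rnorm(250, 0, 0.02), rnorm(100, 0.15, 0.02), rnorm(150, 0, 0.02))
  p <- atba_params(w = 100, k = 3, r = 4)
  det <- run_detector(e, p, fs_hz = 100)
  st <- atba_init(p)
  warn_seq <- logical(length(e))
  streak_seq <- integer(length(e))
  detected_seq <- NA_integer_
  for (i in seq_along(e)) {
    out <- atba_step(st, e[i], p)
    st <- out$state
    warn_seq[i] <- out$warning
    streak_seq[i] <- st$streak
    if (out$detection) detected_seq <- i
  }
  expect_identical(det$trace$warning, warn_seq)
  expect_identical(det$trace$streak, streak_seq)
  expect_identical(det$detected_at, detected_seq)
  expect_identical(detected_seq, st$detected_at)
})

test_that("white Gaussian noise virtually never triggers a detection", {
  # per-sample tail probability at k = 3.5 is ~4.7e-4, so six consecutive
  # warnings are vanishingly unlikely; no detection expected across streams
  p <- atba_params(w = 400, k = 3.5, r = 6)
  set.seed(2024)
  hits <- 0L
  for (i in 1:2000) {
    det <- run_detector(rnorm(1500), p, fs_hz = 100)
    if (!is.na(det$detected_at)) hits <- hits + 1L
  }
  expect_identical(hits, 0L)
})

test_that("detection fires once and the streak stays capped at r", {
  p <- atba_params(w = 50, k = 3, r = 4)
  e <- c(rnorm(100, 0, 0.01), rep(1, 200))
  det <- run_detector(e, p, fs_hz = 100)
  expect_identical(sum(det$trace$detected), 1L)
  expect_lte(max(det$trace$streak), 4L)
})
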