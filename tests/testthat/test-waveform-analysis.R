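test_that("detect_peaks finds sine peaks at the right spacing", {
  t <- seq(0, 10 * 22e-6, by = 1e-7)
  pk <- detect_peaks(sin(2 * pi * t / 22e-6), t)
  expect_equal(nrow(pk), 10)
  expect_equal(diff(pk$time), rep(22e-6, 9), tolerance = 1e-7 / 22e-6)
})

test_that("degenerate inputs raise no-peaks errors", {
  t <- seq(0, 1e-4, by = 1e-7)
  expect_error(detect_peaks(rep(1, length(t)), t), class = "oscsense_error_no_peaks")
  expect_error(detect_peaks(c(1, 2), c(0, 1)), class = "oscsense_error_no_peaks")
})

test_that("relaxation-waveform peak spacing matches the analytic period", {
  wf <- sim_single()
  pk <- detect_peaks(wf$node_1, wf$time_s)
  t_an <- as.numeric(analytic_period(ref_node(), 10))
  dt_rec <- wf$time_s[2] - wf$time_s[1]
  expect_true(all(abs(diff(pk$time) - t_an) <= dt_rec))
})

test_that("dominant_frequency nails synthetic spectra", {
  t <- seq(0, 2e-3, by = 1e-7) # 2 ms at 10 MS/s
  expect_equal(dominant_frequency(sin(2 * pi * 45e3 * t), t), 45e3, tolerance = 1e-4)
  mix <- sin(2 * pi * 45e3 * t) + 0.3 * sin(2 * pi * 90e3 * t)
  expect_equal(dominant_frequency(mix, t), 45e3, tolerance = 1e-4)
  expect_error(dominant_frequency(rep(2.5, length(t)), t),
               class = "oscsense_error_degenerate_spectrum")
  short_t <- seq(0, 4 / 45e3, by = 1e-7)
  expect_warning(dominant_frequency(sin(2 * pi * 45e3 * short_t), short_t),
                 regexp = "8 periods")
})

test_that("FFT and inter-peak frequency agree on oscillator waveforms", {
  wf <- sim_single(n_periods = 12)
  f_fft <- dominant_frequency(wf$node_1, wf$time_s)
  f_pk <- 1 / median(diff(detect_peaks(wf$node_1, wf$time_s)$time))
  expect_equal(f_fft, f_pk, tolerance = 0.01)
})

test_that("is_synchronized separates locked from unlocked channel sets", {
  t <- seq(0, 1e-3, by = 1e-7)
  same <- tibble::tibble(time_s = t,
                         node_1 = sin(2 * pi * 45e3 * t),
                         node_2 = cos(2 * pi * 45e3 * t))
  expect_true(is_synchronized(same))
  apart <- tibble::tibble(time_s = t,
                          node_1 = sin(2 * pi * 100e3 * t),
                          node_2 = sin(2 * pi * 150e3 * t))
  expect_false(is_synchronized(apart, rel_tol = 0.01))
  # coupled pair inside the locking range locks; far mismatch does not
  expect_true(is_synchronized(sim_pair(seed = 1)))
  nodes <- list(oscillator_node(1, 8.2e3, 1e-9), oscillator_node(2, 8.2e3, 2e-9))
  wf <- simulate_onn(onn_config(nodes, coupling = 100e-12,
                                pulse_duration = 300e-6, record_stride = 2L))
  expect_false(is_synchronized(wf))
})

test_that("phase_pattern measures half-period shifts as 180 degrees", {
  t <- seq(0, 1e-3, by = 1e-7)
  wf <- tibble::tibble(time_s = t,
                       node_1 = sin(2 * pi * 45e3 * t),
                       node_2 = sin(2 * pi * 45e3 * t - pi))
  pp <- phase_pattern(wf)
  expect_equal(pp$phase_deg[pp$channel == "node_1"], 0)
  expect_equal(pp$phase_deg[pp$channel == "node_2"], 180, tolerance = 0.01)
  expect_equal(attr(pp, "common_frequency"), 45e3, tolerance = 1e-3)
})

test_that("phase patterns are invariant to time shift and voltage scaling", {
  wf <- sim_pair(seed = 2)
  tmax <- max(wf$time_s)
  win <- c(0.8 * tmax, tmax)
  pp <- phase_pattern(wf, window = win)
  shifted <- wf
  shifted$time_s <- shifted$time_s + 1.234e-3
  pp_shift <- phase_pattern(shifted, window = win + 1.234e-3)
  expect_equal(pp_shift$phase_deg, pp$phase_deg, tolerance = 1e-6)
  scaled <- wf
  scaled$node_1 <- 3 * scaled$node_1
  scaled$node_2 <- 3 * scaled$node_2
  pp_scale <- phase_pattern(scaled, window = win)
  expect_equal(pp_scale$phase_deg, pp$phase_deg, tolerance = 1e-6)
})

test_that("phase_pattern guards its preconditions", {
  t <- seq(0, 1e-3, by = 1e-7)
  apart <- tibble::tibble(time_s = t,
                          node_1 = sin(2 * pi * 100e3 * t),
                          node_2 = sin(2 * pi * 150e3 * t))
  expect_error(phase_pattern(apart), class = "oscsense_error_not_synchronized")
  # an absurdly tight spread bound flags the per-period jitter of a
  # noisy record as unstable phase
  wf <- sim_pair(seed = 2)
  set.seed(1)
  wf$node_2 <- wf$node_2 + rnorm(nrow(wf), 0, 0.05)
  tmax <- max(wf$time_s)
  expect_error(phase_pattern(wf, window = c(0.8 * tmax, tmax),
                             max_spread_deg = 1e-4),
               class = "oscsense_error_unstable_phase")
})

test_that("the printed phase pattern round-trips through JSON", {
  pat <- structure(tibble::tibble(channel = c("node_1", "node_2", "node_3"),
                                  phase_deg = c(0, 236, 105)),
                   common_frequency = 45e3, ref_channel = "node_1",
                   synchronized = TRUE,
                   class = c("phase_pattern", "tbl_df", "tbl", "data.frame"))
  back <- phase_pattern_from_json(phase_pattern_to_json(pat))
  expect_equal(back$channel, pat$channel)
  expect_equal(back$phase_deg, pat$phase_deg)
  expect_equal(attr(back, "common_frequency"), 45e3)
  expect_equal(attr(back, "ref_channel"), "node_1")
})

test_that("limit_cycle trims the transient and closes once per period", {
  wf <- sim_pair(seed = 1)
  lc <- limit_cycle(wf, transient_cut = 200e-6)
  expect_true(min(lc$time_s) > 200e-6)
  # Poincare section: upward crossings of the node_1 midline happen once
  # per period
  mid <- mean(range(lc$node_1))
  up <- which(diff(lc$node_1 > mid) == 1)
  f <- dominant_frequency(lc$node_1, lc$time_s)
  expected_loops <- (max(lc$time_s) - min(lc$time_s)) * f
  expect_equal(length(up), expected_loops, tolerance = 0.05)
  expect_error(limit_cycle(wf, transient_cut = 1), class = "oscsense_error_empty_window")
  one <- tibble::tibble(time_s = wf$time_s, node_1 = wf$node_1)
  expect_error(limit_cycle(one), class = "oscsense_error_invalid_params")
})

test_that("three-channel limit cycles expose the three 2-D projections", {
  nodes <- purrr::map(1:3, ~oscillator_node(.x, 10.2e3, 1e-9))
  wf <- simulate_onn(onn_config(nodes, coupling = 100e-12,
                                pulse_duration = 150e-6, record_stride = 4L))
  proj <- limit_cycle_projections(limit_cycle(wf, transient_cut = 100e-6))
  expect_setequal(unique(proj$plane),
                  c("node_1-node_2", "node_1-node_3", "node_2-node_3"))
})

test_that("waveforms round-trip through the CSV dialect", {
  wf <- sim_single(n_periods = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_waveforms(wf, path)
  back <- read_waveforms(path)
  expect_equal(names(back), c("time_s", "node_1"))
  expect_equal(back$node_1, wf$node_1, tolerance = 1e-12)
})
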