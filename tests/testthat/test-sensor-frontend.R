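test_that("sensor_model validates its inputs", {
  s <- sensor_model("pressure", "1n", gain = 1)
  expect_equal(s$c_base, 1e-9)
  expect_error(sensor_model("pressure", -1e-9, 1), class = "oscsense_error_invalid_params")
  expect_error(sensor_model("stretch", 1e-9, 0), class = "oscsense_error_invalid_params")
  expect_error(sensor_model("stretch", 1e-9, 1, jitter_sigma = -0.1),
               class = "oscsense_error_invalid_params")
  expect_error(sensor_model("smell", 1e-9, 1))
})

test_that("capacitance increases with stimulus and respects jitter", {
  s <- sensor_model("stretch", 330e-12, gain = 0.035)
  expect_equal(sensor_capacitance(s, 0), 330e-12)
  expect_equal(sensor_capacitance(s, 1), 330e-12 * 1.035)
  stim <- seq(0, 3, by = 0.5)
  caps <- vapply(stim, function(x) sensor_capacitance(s, x), numeric(1))
  expect_true(all(diff(caps) > 0))
  sj <- sensor_model("pressure", 1e-9, gain = 1, jitter_sigma = 0.01)
  set.seed(1)
  draws <- replicate(200, sensor_capacitance(sj, 0))
  expect_gt(length(unique(draws)), 100)
  expect_equal(mean(draws) / 1e-9, 1, tolerance = 0.01)
  expect_error(sensor_capacitance(s, -1))
})

test_that("gestures map to the documented finger stimuli", {
  rock <- gesture_to_stimuli("rock")
  expect_equal(rock$finger, c("thumb", "forefinger", "middle"))
  expect_equal(rock$stimulus, c(1, 1, 1))
  expect_equal(gesture_to_stimuli("paper")$stimulus, c(0, 0, 0))
  expect_equal(gesture_to_stimuli("scissor")$stimulus, c(1, 0, 0))
  expect_equal(gesture_to_stimuli("101")$stimulus, c(1, 0, 1))
  expect_error(gesture_to_stimuli("spock"), class = "oscsense_error_unknown_gesture")
})

test_that("fixtures are labeled, complete, and reproducible", {
  setup <- task_setup("touch")
  fx <- generate_fixture("touch", setup$template, setup$sensors,
                         n_trials = 2, seed = 42, noise_snr_db = Inf)
  expect_s3_class(fx, "onn_fixture")
  expect_equal(nrow(fx), 4) # 2 labels x 2 trials
  expect_setequal(unique(fx$label), c("touch", "no-touch"))
  expect_true(all(purrr::map_lgl(fx$wf, tibble::is_tibble)))
  fx2 <- generate_fixture("touch", setup$template, setup$sensors,
                          n_trials = 2, seed = 42, noise_snr_db = Inf)
  expect_identical(purrr::map(fx$wf, as.data.frame),
                   purrr::map(fx2$wf, as.data.frame))
  # a different seed changes the jittered waveforms
  fx3 <- generate_fixture("touch", setup$template, setup$sensors,
                          n_trials = 2, seed = 43, noise_snr_db = Inf)
  expect_false(identical(fx$wf[[1]]$node_2, fx3$wf[[1]]$node_2))
})

test_that("measurement noise hits the configured SNR", {
  setup <- task_setup("touch")
  clean <- generate_fixture("touch", setup$template, setup$sensors,
                            n_trials = 1, seed = 7, noise_snr_db = Inf)
  noisy <- generate_fixture("touch", setup$template, setup$sensors,
                            n_trials = 1, seed = 7, noise_snr_db = 30)
  resid <- noisy$wf[[1]]$node_1 - clean$wf[[1]]$node_1
  snr_db <- 20 * log10(sd(clean$wf[[1]]$node_1) / sd(resid))
  expect_equal(snr_db, 30, tolerance = 0.05)
})

test_that("a pinned device_variation seed fixes one network across trials", {
  setup <- task_setup("modes8", n_nodes = 2)
  dv <- c(d2d_halfwidth, list(seed = 1))
  fx <- generate_fixture("modes8", setup$template, setup$sensors,
                         n_trials = 2, seed = 5, device_variation = dv,
                         noise_snr_db = Inf)
  vths <- purrr::map(fx$config, function(cfg)
    purrr::map_dbl(cfg$nodes, function(nd) nd$device$v_th))
  expect_true(all(purrr::map_lgl(vths, identical, vths[[1]])))
  expect_false(identical(vths[[1]], rep(4.0, 2)))
  # without a pinned seed, trials draw fresh devices
  fx2 <- generate_fixture("modes8", setup$template, setup$sensors,
                          n_trials = 2, seed = 5, device_variation = d2d_halfwidth,
                          noise_snr_db = Inf)
  vths2 <- purrr::map(fx2$config, function(cfg)
    purrr::map_dbl(cfg$nodes, function(nd) nd$device$v_th))
  expect_false(identical(vths2[[1]], vths2[[2]]))
})

test_that("fixture directories round-trip with full provenance", {
  setup <- task_setup("touch")
  fx <- generate_fixture("touch", setup$template, setup$sensors,
                         n_trials = 1, seed = 9)
  dir <- tempfile("fixture")
  on.exit(unlink(dir, recursive = TRUE))
  write_fixture(fx, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_fixture(dir)
  expect_equal(back$label, fx$label)
  expect_equal(back$trial_seed, fx$trial_seed)
  expect_equal(attr(back, "task"), "touch")
  expect_equal(attr(back, "seed"), 9L)
  for (i in seq_len(nrow(fx)))
    expect_equal(back$wf[[i]]$node_1, fx$wf[[i]]$node_1, tolerance = 1e-12)
})

test_that("modes8 labels enumerate all binary stimulus combinations", {
  labs <- task_labels("modes8", 3)
  expect_equal(length(labs), 8)
  expect_setequal(labs, c("000", "100", "010", "110", "001", "101", "011", "111"))
  expect_equal(length(task_labels("modes8", 2)), 4)
})
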