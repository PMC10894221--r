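test_that("training_config validates targets and regularization", {
  cfg <- training_config()
  expect_null(cfg$target_neg) # resolved per training set
  expect_error(training_config(target_pos = -1), class = "oscsense_error_invalid_params")
  expect_error(training_config(target_neg = 0.5), class = "oscsense_error_invalid_params")
  expect_error(training_config(rls_lambda = 0), class = "oscsense_error_invalid_params")
})

make_two_channel_wf <- function(phase2 = pi / 2, f = 45e3, tmax = 500e-6) {
  t <- seq(0, tmax, by = 2e-7)
  tibble::tibble(time_s = t,
                 node_1 = 2 + sin(2 * pi * f * t),
                 node_2 = 2 + sin(2 * pi * f * t - phase2))
}

test_that("waveform_features builds the documented columns", {
  cfg <- training_config(tap_delay = 5.5e-6, n_taps = 2L)
  wf <- make_two_channel_wf()
  u <- waveform_features(wf, c(300e-6, 480e-6), cfg)
  nms <- colnames(u)
  expect_equal(nms[length(nms)], "bias")
  expect_true(all(u[, "bias"] == 1))
  expect_true(all(c("node_1", "node_1_lag1", "node_2_lag2") %in% nms))
  expect_true("node_1*node_2" %in% nms)          # zero-lag cross product
  expect_false("node_2*node_1" %in% nms)          # deduplicated symmetric pair
  expect_false("node_1*node_1" %in% nms)          # plain squares dropped
  expect_true(all(c("node_1*node_1_flag1", "node_2*node_2_flag2") %in% nms))
  expect_true(all(is.finite(u)))
  expect_error(waveform_features(wf, c(300e-6, 300.1e-6), cfg),
               class = "oscsense_error_trace_too_short")
})

test_that("cross-product features separate phase patterns that voltages cannot", {
  cfg <- training_config(tap_delay = 5.5e-6, n_taps = 2L)
  u_a <- waveform_features(make_two_channel_wf(0), c(300e-6, 480e-6), cfg)
  u_b <- waveform_features(make_two_channel_wf(pi), c(300e-6, 480e-6), cfg)
  # per-channel means are (nearly) identical across the two phase patterns
  # (sub-1% edge effects from the non-integer number of periods in the window)
  expect_equal(mean(u_a[, "node_1"]), mean(u_b[, "node_1"]), tolerance = 0.01)
  expect_equal(mean(u_a[, "node_2"]), mean(u_b[, "node_2"]), tolerance = 0.01)
  # ...but the zero-lag cross product flips sign between in-phase and anti-phase
  expect_gt(mean(u_a[, "node_1*node_2"]), 0.4)
  expect_lt(mean(u_b[, "node_1*node_2"]), -0.4)
})

test_that("build_training_set balances targets and shuffles reproducibly", {
  setup <- task_setup("gesture")
  fx <- generate_fixture("gesture", setup$template, setup$sensors,
                         n_trials = 1, seed = 3)
  cfg <- setup$training
  st <- build_training_set(fx, cfg)
  expect_equal(st$labels, sort(c("rock", "paper", "scissor")))
  expect_equal(colnames(st$Y), st$labels)
  # class-balanced targets: each row holds target_pos once and
  # -target_pos/(K-1) elsewhere, so rows sum to zero
  expect_equal(unname(rowSums(st$Y)), rep(0, nrow(st$Y)))
  expect_setequal(unique(as.vector(st$Y)), c(1, -0.5))
  expect_equal(nrow(st$U), nrow(st$Y))
  expect_equal(length(st$sample_label), nrow(st$U))
  st2 <- build_training_set(fx, cfg)
  expect_identical(st$U, st2$U)
})

test_that("FORCE with stride 1 equals ridge-regularized batch least squares", {
  set.seed(10)
  n <- 400; nf <- 12
  U <- matrix(rnorm(n * nf), n, nf,
              dimnames = list(NULL, paste0("f", seq_len(nf))))
  W_true <- matrix(rnorm(2 * nf), 2, nf)
  Y <- U %*% t(W_true) + 0.01 * matrix(rnorm(n * 2), n, 2)
  colnames(Y) <- c("A", "B")
  cfg <- training_config(rls_lambda = 1, update_stride = 1L)
  ro <- force_train(list(U = U, Y = Y), cfg)
  W_ridge <- t(solve(crossprod(U) + cfg$rls_lambda * diag(nf), crossprod(U, Y)))
  expect_lt(max(abs(ro$W - W_ridge)) / max(abs(W_ridge)), 1e-6)
  # training error decreases overall
  g <- glance(ro)
  expect_lt(g$final_rmse, g$initial_rmse)
  expect_equal(g$n_updates, n)
})

test_that("stride > 1 skips updates but still trains", {
  set.seed(11)
  U <- matrix(rnorm(200 * 6), 200, 6)
  Y <- matrix(U[, 1] - U[, 2], ncol = 1, dimnames = list(NULL, "A"))
  ro <- force_train(list(U = U, Y = Y), training_config(update_stride = 4L))
  expect_equal(length(ro$error_trace), 50)
})

test_that("tidy weights and JSON serialization round-trip", {
  set.seed(12)
  U <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  Y <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("A", "B")))
  ro <- force_train(list(U = U, Y = Y), training_config())
  td <- tidy(ro)
  expect_setequal(names(td), c("class", "feature", "weight"))
  expect_equal(nrow(td), 8)
  back <- readout_from_json(readout_to_json(ro))
  expect_equal(back$W, ro$W)
  expect_equal(back$classes, ro$classes)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  readout_to_json(ro, path)
  expect_equal(readout_from_json(paste(readLines(path), collapse = ""))$W, ro$W)
})

test_that("evaluate_readout reports per-trial verdicts in tidy shape", {
  setup <- task_setup("touch")
  fx <- generate_fixture("touch", setup$template, setup$sensors,
                         n_trials = 2, seed = 21)
  cfg <- setup$training
  ro <- force_train(build_training_set(fx, cfg), cfg)
  fx_test <- generate_fixture("touch", setup$template, setup$sensors,
                              n_trials = 2, seed = 1021)
  ev <- evaluate_readout(ro, fx_test, setup$dm, cfg)
  trials <- tidy(ev)
  expect_setequal(names(trials), c("label", "predicted", "correct", "margin", "decided"))
  expect_equal(nrow(trials), 4)
  g <- glance(ev)
  expect_equal(g$n_trials, 4)
  expect_equal(g$accuracy, mean(trials$correct))
  expect_s3_class(ev$confusion, "table")
})
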