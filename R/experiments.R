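#' End-to-end sensory recognition experiments
#'
#' Each driver generates labeled synthetic fixtures through the
#' oscillator network, verifies the synchronization structure the task
#' relies on, trains the FORCE readout on trailing windows of the
#' training fixture, and classifies held-out windows of a separately
#' seeded test fixture through the decision network.
#'
#' * `run_touch_experiment`: 2 oscillators (fixed-frequency reference +
#'   pressure-sensing node). A touch slows the sensory node into the
#'   locking range, so touch trials synchronize and no-touch trials do
#'   not; the 2-neuron decision network reports which happened.
#' * `run_gesture_experiment`: 3 stretch-sensing oscillators encode
#'   rock / paper / scissor as phase patterns at a common frequency
#'   (rock, with all fingers bent, locks lowest).
#' * `run_modes8_experiment`: all `2^n` binary stimulus combinations on
#'   `n` oscillators; reports how many modes are distinguishable from
#'   the phase patterns and classifies all of them.
#'
#' @param n_train_trials,n_test_trials Trials per label in the training
#'   and test fixtures.
#' @param seed Master integer seed (test fixture uses `seed + 1000`).
#' @param setup Optional [task_setup()] list to override the defaults.
#' @param device_variation Optional list with `vth_range` / `vhold_range`
#'   (and optionally a fixed `seed`) to draw varied device parameters
#'   (device-to-device variation); see [generate_fixture()]. When set,
#'   the strict all-trials-synchronized calibration check is skipped:
#'   sufficiently mismatched devices can push single stimulus modes out
#'   of the locking range, and the point of a variation run is to
#'   measure how well classification survives that.
#' @param n_nodes Oscillator count for the modes experiment.
#' @return A `report_bundle`: list with the task name, both fixtures,
#'   per-trial synchronization verdicts (`sync`), phase patterns of the
#'   synchronized trials (`patterns`), mode-separability summary
#'   (`separability`, where applicable), the trained `readout`, the
#'   `evaluation`, example decision trajectories (`dm_example`), and the
#'   seeds.
#' @export
run_touch_experiment <- function(n_train_trials = 5, n_test_trials = 5,
                                 seed = 1L, setup = NULL,
                                 device_variation = NULL) {
  setup <- setup %||% task_setup("touch", seed = seed)
  bundle <- run_sensory_experiment(setup, n_train_trials, n_test_trials, seed,
                                   device_variation)
  sync <- bundle$sync
  bad_touch <- sync$label == "touch" & !sync$synchronized
  bad_rest <- sync$label == "no-touch" & sync$synchronized
  if (any(bad_touch) || any(bad_rest))
    osc_abort("calibration",
              paste0("touch dichotomy violated: ",
                     sum(bad_touch), " touch trial(s) unsynchronized, ",
                     sum(bad_rest), " no-touch trial(s) synchronized"))
  bundle
}

#' @rdname run_touch_experiment
#' @export
run_gesture_experiment <- function(n_train_trials = 5, n_test_trials = 5,
                                   seed = 1L, setup = NULL,
                                   device_variation = NULL) {
  setup <- setup %||% task_setup("gesture", seed = seed)
  bundle <- run_sensory_experiment(setup, n_train_trials, n_test_trials, seed,
                                   device_variation)
  if (is.null(device_variation) && !all(bundle$sync$synchronized))
    osc_abort("calibration", "a gesture trial failed to synchronize")
  bundle
}

#' @rdname run_touch_experiment
#' @export
run_modes8_experiment <- function(n_train_trials = 5, n_test_trials = 5,
                                  seed = 1L, n_nodes = 3, setup = NULL,
                                  device_variation = NULL) {
  setup <- setup %||% task_setup("modes8", n_nodes = n_nodes, seed = seed)
  bundle <- run_sensory_experiment(setup, n_train_trials, n_test_trials, seed,
                                   device_variation)
  if (is.null(device_variation) && !all(bundle$sync$synchronized))
    osc_abort("calibration", "a stimulus mode failed to synchronize")
  bundle
}

# shared driver
run_sensory_experiment <- function(setup, n_train_trials, n_test_trials, seed,
                                   device_variation = NULL) {
  calib <- osc_calibration()
  fx_train <- generate_fixture(setup$task, setup$template, setup$sensors,
                               n_trials = n_train_trials, seed = seed,
                               device_variation = device_variation,
                               noise_snr_db = calib$noise_snr_db)
  sync <- dplyr::mutate(fx_train[c("label", "trial")],
                        synchronized = purrr::map_lgl(fx_train$wf, function(w)
                          isTRUE(is_synchronized(w))))
  synced_idx <- which(sync$synchronized)
  # measure the pattern code on the settled tail of each record, past the
  # slow phase-convergence transient; drop trials whose phase is still
  # wandering there (possible for marginally locked device-varied trials)
  patterns <- tibble(label = fx_train$label[synced_idx],
                     trial = fx_train$trial[synced_idx],
                     pattern = purrr::map(fx_train$wf[synced_idx], function(w) {
                       tmax <- max(w$time_s)
                       tryCatch(phase_pattern(w, window = c(0.7 * tmax, tmax)),
                                oscsense_error_unstable_phase = function(e) NULL)
                     }))
  patterns <- patterns[!purrr::map_lgl(patterns$pattern, is.null), ]
  separability <- if (setup$task %in% c("gesture", "modes8") && nrow(patterns) > 1)
    phase_mode_separability(patterns) else NULL

  cfg <- setup$training
  cfg$seed <- as.integer(seed)
  stream <- build_training_set(fx_train, cfg)
  readout <- force_train(stream, cfg)

  fx_test <- generate_fixture(setup$task, setup$template, setup$sensors,
                              n_trials = n_test_trials, seed = seed + 1000L,
                              device_variation = device_variation,
                              noise_snr_db = calib$noise_snr_db)
  evaluation <- evaluate_readout(readout, fx_test, setup$dm, cfg)

  # one decision trajectory per label, for plots / reports
  first_idx <- match(unique(fx_test$label), fx_test$label)
  dm_example <- purrr::map(first_idx, function(i) {
    u <- waveform_features(fx_test$wf[[i]],
                           c(cfg$eval_offset_range[1],
                             cfg$eval_offset_range[1] + cfg$eval_window), cfg)
    I <- u %*% t(readout$W)
    I <- do.call(rbind, replicate(cfg$eval_repeats, I, simplify = FALSE))
    run_dm(I, setup$dm)
  })
  names(dm_example) <- unique(fx_test$label)

  structure(list(task = setup$task, fixture_train = fx_train,
                 fixture_test = fx_test, sync = sync, patterns = patterns,
                 separability = separability, readout = readout,
                 evaluation = evaluation, dm_example = dm_example,
                 setup = setup, seed = as.integer(seed)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> task '%s'\n", x$task))
  cat(sprintf("  %d/%d training trials synchronized\n",
              sum(x$sync$synchronized), nrow(x$sync)))
  if (!is.null(x$separability))
    cat(sprintf("  %d distinguishable phase modes (min inter %.1f deg > max intra %.1f deg: %s)\n",
                x$separability$n_distinguishable, x$separability$min_inter,
                x$separability$max_intra, x$separability$separable))
  cat(sprintf("  test accuracy %.3f (%d undecided)\n",
              x$evaluation$accuracy, x$evaluation$n_undecided))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Machine-readable outputs: fixture manifests and waveform CSVs, phase
#' patterns (JSON), limit-cycle trajectories (CSV), the training error
#' trace (CSV), readout weights (JSON), the per-trial evaluation (CSV)
#' and a summary JSON with the seeds needed to regenerate everything.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fixture(bundle$fixture_train, file.path(dir, "fixture_train"))
  write_fixture(bundle$fixture_test, file.path(dir, "fixture_test"))
  if (nrow(bundle$patterns)) {
    pdir <- file.path(dir, "phase_patterns")
    dir.create(pdir, showWarnings = FALSE)
    purrr::pwalk(bundle$patterns, function(label, trial, pattern)
      phase_pattern_to_json(pattern,
                            file.path(pdir, sprintf("%s_%03d.json",
                                                    gsub("[^A-Za-z0-9]", "-", label), trial))))
  }
  utils::write.csv(data.frame(update = seq_along(bundle$readout$error_trace),
                              rmse = bundle$readout$error_trace),
                   file.path(dir, "training_error.csv"), row.names = FALSE)
  readout_to_json(bundle$readout, file.path(dir, "readout_weights.json"))
  utils::write.csv(as.data.frame(tidy(bundle$evaluation)),
                   file.path(dir, "evaluation.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(task = bundle$task, seed = bundle$seed,
         accuracy = bundle$evaluation$accuracy,
         n_undecided = bundle$evaluation$n_undecided,
         n_distinguishable = bundle$separability$n_distinguishable %||% NA,
         synchronized_trials = sum(bundle$sync$synchronized),
         total_trials = nrow(bundle$sync)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}
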