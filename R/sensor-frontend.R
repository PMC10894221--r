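#' Capacitive sensor model
#'
#' Both supported sensor kinds increase their capacitance with the
#' stimulus: a pressure sensor's capacitance rises as the electrodes are
#' pressed together, and a stretch sensor's capacitance grows in
#' proportion to the degree of stretch. The model is
#' `C = c_base * (1 + eps) * (1 + gain * stimulus)` with a per-trial
#' relative jitter `eps ~ Normal(0, jitter_sigma)`.
#'
#' @param kind `"pressure"` or `"stretch"`.
#' @param c_base Unstimulated capacitance (F).
#' @param gain Relative capacitance increase per unit stimulus (> 0).
#' @param jitter_sigma Relative trial-to-trial jitter.
#' @return A `sensor_model` object.
#' @export
sensor_model <- function(kind = c("pressure", "stretch"), c_base, gain,
                         jitter_sigma = 0) {
  kind <- match.arg(kind)
  c_base <- si_parse(c_base)
  if (c_base <= 0 || gain <= 0)
    osc_abort("invalid_params", "c_base and gain must be positive")
  if (jitter_sigma < 0) osc_abort("invalid_params", "jitter_sigma must be >= 0")
  structure(list(kind = kind, c_base = c_base, gain = gain,
                 jitter_sigma = jitter_sigma), class = "sensor_model")
}

#' Sensor capacitance under a stimulus
#'
#' Strictly increasing in the stimulus at fixed jitter. Jitter draws use
#' R's RNG (seed with `set.seed()`); a draw pushing the capacitance
#' non-positive is resampled up to 100 times, then errors.
#'
#' @param sensor A [sensor_model()].
#' @param stimulus Non-negative stimulus magnitude (dimensionless; 0 = rest).
#' @return Capacitance in farads.
#' @export
sensor_capacitance <- function(sensor, stimulus) {
  stopifnot(stimulus >= 0)
  for (i in seq_len(100)) {
    eps <- if (sensor$jitter_sigma > 0) rnorm(1, 0, sensor$jitter_sigma) else 0
    val <- sensor$c_base * (1 + eps) * (1 + sensor$gain * stimulus)
    if (val > 0) return(val)
  }
  osc_abort("negative_capacitance", "jitter drove the capacitance non-positive")
}

#' Map a gesture to per-finger stimulus levels
#'
#' The three sensory channels carry the stretch state of the thumb,
#' forefinger, and middle finger (in that order). A bent finger
#' stretches its sensor (stimulus 1); an extended finger leaves it at
#' rest (0). "rock" bends all three, "paper" extends all three,
#' "scissor" extends the forefinger and middle finger with the thumb
#' bent. A 3-character bit string maps bit `1` to bent.
#'
#' @param gesture `"rock"`, `"paper"`, `"scissor"`, or a 3-bit string
#'   such as `"101"`.
#' @return A tibble with columns `finger` and `stimulus`, attribute
#'   `label`.
#' @examples
#' gesture_to_stimuli("scissor")
#' @export
gesture_to_stimuli <- function(gesture) {
  fingers <- c("thumb", "forefinger", "middle")
  s <- switch(gesture,
              rock = c(1, 1, 1),
              paper = c(0, 0, 0),
              scissor = c(1, 0, 0),
              {
                if (!grepl("^[01]{3}$", gesture))
                  osc_abort("unknown_gesture", paste0("unknown gesture: '", gesture, "'"))
                as.integer(strsplit(gesture, "")[[1]])
              })
  structure(tibble(finger = fingers, stimulus = as.numeric(s)), label = gesture)
}

# task vocabularies and their per-node stimulus patterns
task_labels <- function(task, n_nodes = 3) {
  switch(task,
         touch = c("no-touch", "touch"),
         gesture = c("rock", "paper", "scissor"),
         modes8 = apply(expand.grid(rep(list(0:1), n_nodes))[, n_nodes:1, drop = FALSE],
                        1, paste, collapse = ""),
         osc_abort("invalid_params", paste0("unknown task: ", task)))
}

task_stimuli <- function(task, label, n_nodes) {
  switch(task,
         touch = c(0, if (label == "touch") 1 else 0),
         gesture = gesture_to_stimuli(label)$stimulus,
         modes8 = as.numeric(strsplit(label, "")[[1]]))
}

#' Generate a labeled synthetic waveform fixture
#'
#' For every label of the task's vocabulary and every trial: draw sensor
#' jitter (and optionally fresh device parameters for device-to-device
#' variation), set each node's parallel capacitance from its sensor,
#' simulate the coupled network, add measurement noise at the configured
#' SNR, and attach the label. Deterministic under a fixed seed;
#' per-trial seeds are derived from `seed` and recorded for bit-exact
#' regeneration.
#'
#' @param task `"touch"`, `"gesture"`, or `"modes8"`.
#' @param onn_template An [onn_config()] whose nodes define the circuit;
#'   per-trial capacitances overwrite each sensed node's `c_parallel`.
#' @param sensors List of [sensor_model()] per node; `NULL` entries mark
#'   reference nodes whose capacitance stays at the template value.
#' @param n_trials Trials per label.
#' @param seed Master integer seed.
#' @param device_variation `NULL`, or a list with `vth_range` and
#'   `vhold_range` (volts) from which device thresholds are drawn
#'   uniformly; an optional `seed` entry pins one sampled device set
#'   for the whole fixture (one physical network across all trials),
#'   otherwise each trial draws fresh devices.
#' @param noise_snr_db Additive Gaussian measurement noise level
#'   (signal-RMS to noise-RMS, dB); `Inf` disables noise.
#' @return A tibble of class `onn_fixture`: one row per trial with
#'   columns `label`, `trial`, `trial_seed`, and list-columns `wf`
#'   (waveform tibbles) and `config`.
#' @export
generate_fixture <- function(task, onn_template, sensors, n_trials = 1, seed = 1,
                             device_variation = NULL, noise_snr_db = 30) {
  stopifnot(inherits(onn_template, "onn_config"), n_trials >= 1)
  labels <- task_labels(task, length(onn_template$nodes))
  n_nodes <- length(onn_template$nodes)
  stopifnot(length(sensors) == n_nodes)
  grid <- tidyr::expand_grid(label = labels, trial = seq_len(n_trials))
  k <- seq_len(nrow(grid))
  grid$trial_seed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max

  run_trial <- function(label, trial, trial_seed) {
    set.seed(trial_seed)
    stim <- task_stimuli(task, label, n_nodes)
    cfg <- onn_template
    cfg$seed <- trial_seed
    if (!is.null(device_variation)) {
      # a fixed `seed` in device_variation pins one sampled device set
      # for the whole fixture (one physical network); otherwise each
      # trial draws fresh devices
      devs <- sample_devices(n_nodes,
                             vth_range = device_variation$vth_range,
                             vhold_range = device_variation$vhold_range,
                             seed = device_variation$seed %||% trial_seed)
      for (i in seq_len(n_nodes)) {
        tmpl <- cfg$nodes[[i]]$device
        cfg$nodes[[i]]$device$v_th <- devs$v_th[i]
        cfg$nodes[[i]]$device$v_hold <- devs$v_hold[i]
      }
      set.seed(trial_seed + 1L) # device draw consumed the stream; restart for jitter
    }
    for (i in seq_len(n_nodes)) {
      if (!is.null(sensors[[i]]))
        cfg$nodes[[i]]$c_parallel <- sensor_capacitance(sensors[[i]], stim[i])
    }
    wf <- withCallingHandlers(
      simulate_onn(cfg),
      error = function(e) osc_abort("fixture",
                                    paste0("label '", label, "' trial ", trial, ": ",
                                           conditionMessage(e))))
    if (is.finite(noise_snr_db)) {
      set.seed(trial_seed + 2L)
      for (ch in waveform_channels(wf)) {
        rms <- sd(wf[[ch]])
        wf[[ch]] <- wf[[ch]] + rnorm(nrow(wf), 0, rms / 10^(noise_snr_db / 20))
      }
    }
    list(wf = wf, config = cfg)
  }

  res <- purrr::pmap(grid, run_trial)
  out <- dplyr::mutate(grid,
                       wf = purrr::map(res, "wf"),
                       config = purrr::map(res, "config"))
  structure(out, task = task, seed = as.integer(seed),
            noise_snr_db = noise_snr_db,
            device_variation = device_variation,
            class = c("onn_fixture", class(out)))
}

#' Write / read a fixture directory (CSV waveforms + JSON manifest)
#'
#' Each trial's waveforms go to `label_trial.csv`; the manifest records
#' the task, master seed, per-trial seeds and labels -- enough
#' provenance to regenerate the fixture bit-exactly with
#' [generate_fixture()].
#'
#' @param fixture An `onn_fixture` tibble.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.csv", gsub("[^A-Za-z0-9]", "-", fixture$label),
                   fixture$trial)
  purrr::walk2(fixture$wf, files, function(wf, f) write_waveforms(wf, file.path(dir, f)))
  manifest <- list(task = attr(fixture, "task"), seed = attr(fixture, "seed"),
                   noise_snr_db = attr(fixture, "noise_snr_db"),
                   trials = data.frame(label = fixture$label, trial = fixture$trial,
                                       trial_seed = fixture$trial_seed, file = files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  tr <- manifest$trials
  out <- as_tibble(tr[c("label", "trial", "trial_seed")])
  out$wf <- purrr::map(tr$file, function(f) read_waveforms(file.path(dir, f)))
  structure(out, task = manifest$task, seed = manifest$seed,
            noise_snr_db = manifest$noise_snr_db,
            class = c("onn_fixture", class(out)))
}
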