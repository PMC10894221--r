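#' FORCE training configuration
#'
#' Settings for the online recursive-least-squares training of the
#' linear readout that maps oscillator waveforms to decision-network
#' inputs. Training samples are a few periods taken towards the end of
#' each trace, concatenated and repeated in the time dimension; the
#' target is a positive constant on the correct class's neuron and a
#' negative constant on the others.
#'
#' @param target_pos,target_neg Target constants for the correct / other
#'   classes (`target_pos > 0 > target_neg`). The default
#'   `target_neg = NULL` resolves to the class-balanced value
#'   `-target_pos / (n_classes - 1)` when the training set is built, so
#'   that the per-sample target vector sums to zero and the readout's
#'   resting output level does not drift with the class count (with a
#'   constant `-1` and 8 classes, seven-eighths of every column's
#'   targets are negative and even a perfectly separated class is fit
#'   around a deeply negative offset).
#' @param rls_lambda Inverse initial regularization of the RLS update
#'   matrix (`P0 = I / rls_lambda`); with stride 1 the final weights
#'   equal ridge regression with penalty `rls_lambda`.
#' @param update_stride Samples between weight updates.
#' @param train_window Seconds taken from the end of each trace.
#' @param n_repeats Times each trace's window is repeated in the stream.
#' @param feature_dt Sampling step (s) of the feature/decision grid the
#'   waveforms are linearly interpolated onto.
#' @param n_taps Number of delayed copies of each channel appended to
#'   the instantaneous voltages (phase is not a linear functional of
#'   instantaneous voltages alone; delay embedding makes it linearly
#'   readable).
#' @param tap_delay Delay between taps (s); typically a quarter of the
#'   task's nominal period.
#' @param freq_tap_delay Long lag (s) for the per-channel
#'   autocorrelation products that make the *common frequency* linearly
#'   readable: two stimulus modes with identical phase patterns (the
#'   symmetric modes) trace the same curve in delay space at different
#'   speeds, and only a lag several periods long turns that speed
#'   difference into a large mean-feature separation. Default
#'   `20 * tap_delay` (about five nominal periods).
#' @param eval_window Seconds of trace used per evaluation trial.
#' @param eval_offset_range Start of the evaluation window is drawn
#'   uniformly (seeded) in this interval (s), near the beginning of the
#'   trace and disjoint from the training window.
#' @param eval_repeats Times the evaluation window is tiled to span
#'   several synaptic time constants of DM time.
#' @param seed Integer seed for the label shuffling and offsets.
#' @return A `training_config` object.
#' @export
training_config <- function(target_pos = 1, target_neg = NULL, rls_lambda = 1,
                            update_stride = 1L, train_window = 80e-6,
                            n_repeats = 3L, feature_dt = 0.3e-6, n_taps = 2L,
                            tap_delay = 5.5e-6, freq_tap_delay = 20 * tap_delay,
                            eval_window = 120e-6,
                            eval_offset_range = c(25e-6, 75e-6),
                            eval_repeats = 4L, seed = 1L) {
  if (!(target_pos > 0 && (is.null(target_neg) || target_neg < 0)))
    osc_abort("invalid_params", "need target_pos > 0 > target_neg")
  if (rls_lambda <= 0 || update_stride < 1)
    osc_abort("invalid_params", "rls_lambda > 0 and update_stride >= 1 required")
  structure(list(target_pos = target_pos, target_neg = target_neg,
                 rls_lambda = rls_lambda, update_stride = as.integer(update_stride),
                 train_window = train_window, n_repeats = as.integer(n_repeats),
                 feature_dt = feature_dt, n_taps = as.integer(n_taps),
                 tap_delay = tap_delay, freq_tap_delay = freq_tap_delay,
                 eval_window = eval_window,
                 eval_offset_range = eval_offset_range,
                 eval_repeats = as.integer(eval_repeats),
                 seed = as.integer(seed)), class = "training_config")
}

#' Delay-embedded feature matrix of a waveform window
#'
#' Interpolates each channel onto a uniform feature grid and builds,
#' per sample: the instantaneous channel voltages, `n_taps` delayed
#' copies (`t - k * tap_delay`), pairwise cross-products of the
#' window-centred channels at every tap lag, and a constant bias
#' column.
#'
#' The cross-products are what make a *linear* readout with constant
#' targets workable: every channel sweeps the same relaxation
#' waveform, so per-channel time averages are identical across
#' stimulus classes and a readout on voltages alone reduces to the
#' (zero) difference of class means. Phase relations live in second
#' moments -- the window mean of `x_i(t) * x_j(t - k tap_delay)` for
#' centred channels `x` encodes the phase difference between channels
#' `i` and `j` (and, for `i == j` at nonzero lag, the common
#' frequency) -- so exposing those products as features makes the
#' phase pattern linearly readable.
#'
#' @param wf A waveform tibble.
#' @param window Length-2 time window (s) to featurize.
#' @param cfg A [training_config()].
#' @return Matrix (samples x features) with named columns; the last
#'   column is the bias.
#' @export
waveform_features <- function(wf, window, cfg) {
  chans <- waveform_channels(wf)
  ftap <- cfg$freq_tap_delay %||% (20 * cfg$tap_delay)
  max_lag <- max(cfg$n_taps * cfg$tap_delay, ftap + cfg$tap_delay)
  t0 <- max(window[1], min(wf$time_s) + max_lag)
  if (window[2] - t0 < 2 * cfg$feature_dt)
    osc_abort("trace_too_short", "window too short for the requested features")
  g <- seq(t0, window[2], by = cfg$feature_dt)
  raw <- list()
  for (ch in chans) {
    for (k in 0:cfg$n_taps) {
      raw[[paste0(ch, if (k > 0) paste0("_lag", k) else "")]] <-
        approx(wf$time_s, wf[[ch]], xout = g - k * cfg$tap_delay, rule = 2)$y
    }
  }
  cols <- raw
  ctr <- purrr::map(raw, function(v) v - mean(v))
  nm <- function(ch, k) paste0(ch, if (k > 0) paste0("_lag", k) else "")
  for (a in seq_along(chans)) for (b in seq_along(chans)) {
    for (k in 0:cfg$n_taps) {
      if (k == 0 && b < a) next          # zero-lag products are symmetric
      if (k == 0 && a == b) next         # drop plain squares; autocorrelation
                                         # terms (k > 0) carry the frequency
      cols[[paste0(nm(chans[a], 0), "*", nm(chans[b], k))]] <-
        ctr[[nm(chans[a], 0)]] * ctr[[nm(chans[b], k)]]
    }
  }
  # long-lag autocorrelation pair (quadrature: ftap and ftap + quarter
  # period) -- the linear observable of the common frequency
  for (ch in chans) {
    x0 <- ctr[[nm(ch, 0)]]
    for (j in 1:2) {
      lag <- ftap + (j - 1) * cfg$tap_delay
      xl <- approx(wf$time_s, wf[[ch]], xout = g - lag, rule = 2)$y
      cols[[paste0(ch, "*", ch, "_flag", j)]] <- x0 * (xl - mean(xl))
    }
  }
  cols[["bias"]] <- rep(1, length(g))
  do.call(cbind, cols)
}

#' Build the training sample stream
#'
#' Per trace: take the trailing `train_window`, featurize it, repeat it
#' `n_repeats` times, and attach per-sample target vectors
#' (`target_pos` at the true class, `target_neg` elsewhere). Traces are
#' concatenated in seeded shuffled order.
#'
#' @param fixture An `onn_fixture` (see [generate_fixture()]).
#' @param cfg A [training_config()].
#' @return List with `U` (samples x features), `Y` (samples x classes),
#'   `labels` (class vocabulary), and `sample_label`.
#' @export
build_training_set <- function(fixture, cfg) {
  classes <- sort(unique(fixture$label))
  if (is.null(cfg$target_neg))
    cfg$target_neg <- -cfg$target_pos / max(1L, length(classes) - 1L)
  set.seed(cfg$seed)
  order_idx <- sample(nrow(fixture))
  pieces <- purrr::map(order_idx, function(i) {
    wf <- fixture$wf[[i]]
    t_end <- max(wf$time_s)
    if (t_end < cfg$train_window + cfg$n_taps * cfg$tap_delay)
      osc_abort("trace_too_short",
                paste0("trace '", fixture$label[i], "' shorter than the training window"))
    u <- waveform_features(wf, c(t_end - cfg$train_window, t_end), cfg)
    u <- do.call(rbind, replicate(cfg$n_repeats, u, simplify = FALSE))
    y <- matrix(cfg$target_neg, nrow(u), length(classes),
                dimnames = list(NULL, classes))
    y[, fixture$label[i]] <- cfg$target_pos
    list(u = u, y = y, lab = rep(fixture$label[i], nrow(u)))
  })
  list(U = do.call(rbind, purrr::map(pieces, "u")),
       Y = do.call(rbind, purrr::map(pieces, "y")),
       labels = classes,
       sample_label = unlist(purrr::map(pieces, "lab")))
}

#' Train the linear readout by FORCE (recursive least squares)
#'
#' Standard RLS/FORCE: the update matrix starts at
#' `P = I / rls_lambda`; every `update_stride` samples the pre-update
#' error `e = W u - y` adjusts all rows of `W` by `-e (P u)'` with `P`
#' rank-one downdated. With stride 1 and zero initial weights the final
#' weights equal ridge-regularized batch least squares with the same
#' penalty.
#'
#' @param stream Output of [build_training_set()].
#' @param cfg A [training_config()].
#' @return A `force_readout` object: `W` (classes x features, bias
#'   merged as the last column), `classes`, `features`, `error_trace`
#'   (per-update RMS error), `cfg`.
#' @export
force_train <- function(stream, cfg = training_config()) {
  U <- stream$U; Y <- stream$Y
  if (nrow(U) == 0) osc_abort("invalid_params", "empty training stream")
  nf <- ncol(U); nc <- ncol(Y)
  W <- matrix(0, nc, nf, dimnames = list(colnames(Y), colnames(U)))
  P <- diag(nf) / cfg$rls_lambda
  upd <- seq(1, nrow(U), by = cfg$update_stride)
  err <- numeric(length(upd))
  e0 <- NA_real_
  for (ii in seq_along(upd)) {
    t <- upd[ii]
    u <- U[t, ]
    e <- drop(W %*% u) - Y[t, ]
    Pu <- drop(P %*% u)
    k <- Pu / (1 + sum(u * Pu))
    P <- P - tcrossprod(k, Pu)
    W <- W - tcrossprod(e, k)
    err[ii] <- sqrt(mean(e^2))
    if (ii == 1) e0 <- max(err[1], .Machine$double.eps)
    if (err[ii] > 1e3 * e0)
      osc_abort("divergence", "running FORCE error exceeded 1000x its initial value")
  }
  structure(list(W = W, classes = rownames(W), features = colnames(W),
                 error_trace = err, cfg = cfg), class = "force_readout")
}

#' @export
print.force_readout <- function(x, ...) {
  cat(sprintf("<force_readout> %d classes x %d features; final RMS error %.3g\n",
              nrow(x$W), ncol(x$W), tail(x$error_trace, 1)))
  invisible(x)
}

#' Tidy a trained readout
#'
#' @param x A `force_readout`.
#' @param ... Unused.
#' @return Long tibble `class`, `feature`, `weight`.
#' @export
tidy.force_readout <- function(x, ...) {
  as_tibble(as.data.frame.table(x$W, responseName = "weight",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(class = "Var1", feature = "Var2")
}

#' @rdname tidy.force_readout
#' @return `glance`: one-row tibble with update count, initial and final
#'   RMS error.
#' @export
glance.force_readout <- function(x, ...) {
  tibble(n_updates = length(x$error_trace),
         initial_rmse = x$error_trace[1],
         final_rmse = tail(x$error_trace, 1))
}

#' Serialize / deserialize readout weights as JSON
#'
#' Rows are labelled by class, columns by feature name.
#'
#' @param readout A `force_readout`.
#' @param path Optional file path.
#' @return JSON string / a `force_readout`.
#' @export
readout_to_json <- function(readout, path = NULL) {
  x <- list(classes = readout$classes, features = readout$features,
            W = readout$W)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname readout_to_json
#' @param json JSON string or file path.
#' @export
readout_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  W <- x$W
  dimnames(W) <- list(x$classes, x$features)
  structure(list(W = W, classes = x$classes, features = x$features,
                 error_trace = numeric(0), cfg = NULL), class = "force_readout")
}

#' Classify fixture trials through the readout and decision network
#'
#' For each trial: draw a seeded-random window start near the beginning
#' of the trace (disjoint from the training window at the end), project
#' the delay-embedded waveform through the readout weights to a
#' per-neuron input trace, tile it `eval_repeats` times so it spans
#' several synaptic time constants, run the decision network, and record
#' the winner. `"undecided"` trials count as incorrect and are reported
#' separately.
#'
#' @param readout A trained `force_readout`.
#' @param fixture Test fixture (an `onn_fixture`).
#' @param dm A [dm_params()] (its `n_dm` is set to the class count).
#' @param cfg The [training_config()] used in training (supplies feature
#'   and window settings).
#' @return A `readout_evaluation` object: `trials` tibble (label,
#'   predicted, correct, margin, decided), `confusion` table, `accuracy`,
#'   `n_undecided`.
#' @export
evaluate_readout <- function(readout, fixture, dm = dm_params(), cfg = NULL) {
  cfg <- cfg %||% readout$cfg %||% training_config()
  dm$n_dm <- length(readout$classes)
  set.seed(cfg$seed + 1L)
  offsets <- runif(nrow(fixture), cfg$eval_offset_range[1], cfg$eval_offset_range[2])
  res <- purrr::map2(seq_len(nrow(fixture)), offsets, function(i, off) {
    wf <- fixture$wf[[i]]
    u <- waveform_features(wf, c(off, off + cfg$eval_window), cfg)
    I <- u %*% t(readout$W)
    I <- do.call(rbind, replicate(cfg$eval_repeats, I, simplify = FALSE))
    run <- run_dm(I, dm)
    g <- glance(run)
    tibble(label = fixture$label[i], predicted = run$winner,
           correct = run$winner == fixture$label[i],
           margin = g$margin, decided = g$decided)
  })
  trials <- dplyr::bind_rows(res)
  confusion <- table(true = trials$label, predicted = trials$predicted)
  structure(list(trials = trials, confusion = confusion,
                 accuracy = mean(trials$correct),
                 n_undecided = sum(!trials$decided)),
            class = "readout_evaluation")
}

#' @export
print.readout_evaluation <- function(x, ...) {
  cat(sprintf("<readout_evaluation> accuracy %.3f (%d/%d correct, %d undecided)\n",
              x$accuracy, sum(x$trials$correct), nrow(x$trials), x$n_undecided))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `readout_evaluation`.
#' @param ... Unused.
#' @return The per-trial tibble.
#' @export
tidy.readout_evaluation <- function(x, ...) x$trials

#' @rdname tidy.readout_evaluation
#' @export
glance.readout_evaluation <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_trials = nrow(x$trials),
         n_correct = sum(x$trials$correct), n_undecided = x$n_undecided)
}
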