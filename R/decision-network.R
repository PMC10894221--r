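#' Winner-take-all decision-network parameters
#'
#' A simplified mean-field decision-making model: each neuron receives
#' self-excitation `j_e * s_i` (j_e >= 0), mutual inhibition
#' `j_m * s_j` from every other neuron (j_m <= 0), and a feedforward
#' input `I_i`; the activity passes through a thresholded softplus-log
#' activation and drives slow synaptic dynamics
#' `tau_s ds/dt = -s + gamma * (1 - s) * r`, which keep `s` in `[0, 1]`
#' and give the network its evidence-integration time window.
#'
#' The default constants were chosen by the package (the reference
#' model's table is not public) to put the network in a genuine
#' winner-take-all regime at the readout's target scale (+/-1): with two
#' constant inputs differing by at least 10%, exactly one neuron
#' crosses `r_dec` while the others are suppressed far below it, and
#' exact ties are preserved by symmetry.
#'
#' @param n_dm Number of decision neurons.
#' @param j_e Self-excitation gain (>= 0).
#' @param j_m Mutual-inhibition gain (<= 0).
#' @param alpha Activation width.
#' @param beta Activation gain.
#' @param gamma Synaptic gain.
#' @param theta Activation threshold. Because the default couplings
#'   satisfy `j_e + j_m = 0`, a neuron ignites roughly when its external
#'   input exceeds `theta`; the default sits midway between the no-evidence level (zero) and the readout's
#'   shrunken correct-class drive (about half the +1 training target
#'   under ridge penalty 1) and far above the near-zero wrong-class
#'   drive.
#' @param tau_s Synaptic time constant (decision-network clock units);
#'   must be at least `50 * dt_dm`.
#' @param dt_dm Euler integration step (default `tau_s / 200`).
#' @param r_dec Decision threshold on activity.
#' @return A `dm_params` object.
#' @export
dm_params <- function(n_dm = 2, j_e = 2.0, j_m = -2.0, alpha = 0.1,
                      beta = 0.7, gamma = 0.641, theta = 0.25,
                      tau_s = 100, dt_dm = tau_s / 200, r_dec = 15) {
  if (j_e < 0) osc_abort("invalid_params", "j_e must be >= 0")
  if (j_m > 0) osc_abort("invalid_params", "j_m must be <= 0")
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    osc_abort("invalid_params", "alpha, beta, gamma must be positive")
  if (tau_s < 50 * dt_dm)
    osc_abort("invalid_params", "need tau_s >= 50 * dt_dm")
  structure(list(n_dm = as.integer(n_dm), j_e = j_e, j_m = j_m, alpha = alpha,
                 beta = beta, gamma = gamma, theta = theta, tau_s = tau_s,
                 dt_dm = dt_dm, r_dec = r_dec), class = "dm_params")
}

#' Thresholded softplus-log activation
#'
#' `r(x) = (beta/gamma) * log(1 + exp((x - theta)/alpha))`, evaluated
#' overflow-safely: for `(x - theta)/alpha > 30` the linear asymptote
#' `(beta/gamma) * (x - theta)/alpha` is used.
#'
#' @param x Synaptic input (vectorized).
#' @param params A [dm_params()].
#' @return Non-negative activity.
#' @export
dm_activation <- function(x, params) {
  z <- (x - params$theta) / params$alpha
  out <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  (params$beta / params$gamma) * out
}

#' Decision-network state
#'
#' @param s Synaptic variables in `[0, 1]` (one per neuron).
#' @param params A [dm_params()].
#' @return A `dm_state` object with fields `s`, `r`, `x`, `t`.
#' @export
dm_state <- function(s = rep(0.1, params$n_dm), params = dm_params()) {
  if (any(s < 0 | s > 1)) osc_abort("invalid_params", "s must lie in [0, 1]")
  structure(list(s = s, r = rep(0, length(s)), x = rep(0, length(s)), t = 0),
            class = "dm_state")
}

#' One Euler step of the decision network
#'
#' Computes `x_i = j_e*s_i + sum_{j != i} j_m*s_j + I_i`, the activity
#' `r_i = activation(x_i)`, then advances the slow synaptic dynamics
#' `tau_s ds_i/dt = -s_i + gamma*(1 - s_i)*r_i` by `dt_dm`. The
#' dynamics preserve `[0, 1]`; clamping is applied only as a numerical
#' guard.
#'
#' @param state A [dm_state()].
#' @param I_t Per-neuron feedforward input at this step.
#' @param params A [dm_params()].
#' @return The advanced `dm_state`.
#' @export
dm_step <- function(state, I_t, params) {
  s <- state$s
  x <- params$j_e * s + params$j_m * (sum(s) - s) + I_t
  r <- dm_activation(x, params)
  ds <- (-s + params$gamma * (1 - s) * r) / params$tau_s
  s_new <- pmin(1, pmax(0, s + params$dt_dm * ds))
  if (any(!is.finite(s_new)) || any(!is.finite(r)))
    osc_abort("nonfinite_state", "decision-network state became non-finite")
  structure(list(s = s_new, r = r, x = x, t = state$t + params$dt_dm),
            class = "dm_state")
}

#' Run the decision network over an input trace
#'
#' Integrates [dm_step()] over a per-neuron input trace and reads out
#' the winner: the unique neuron whose activity, averaged over the
#' trailing synaptic time constant `tau_s` (so that oscillations of the
#' feedforward drive within a cycle do not matter), exceeds `r_dec`
#' (the argmax if several exceed it); `"undecided"` when none does or
#' when the top activities tie exactly -- ties are never broken by
#' index.
#'
#' @param inputs Matrix (steps x neurons) or data frame of feedforward
#'   inputs, one row per DM step; column names label the choices.
#' @param params A [dm_params()].
#' @param init A [dm_state()]; default symmetric `s = 0.1`.
#' @param record_stride Keep every this-many steps in the trajectory.
#' @return A `dm_run` object: list with `trajectory` (tibble of `time`,
#'   `s_*`, `r_*`), `winner` (choice label or `"undecided"`),
#'   `final_r` (per-neuron activity averaged over the trailing `tau_s`),
#'   and `params`. Use [tidy()] / [glance()] on it.
#' @export
run_dm <- function(inputs, params = dm_params(), init = NULL,
                   record_stride = 1L) {
  inputs <- as.matrix(inputs)
  n <- ncol(inputs)
  if (n != params$n_dm) params$n_dm <- n
  choices <- colnames(inputs) %||% paste0("choice_", seq_len(n))
  state <- init %||% dm_state(rep(0.1, n), params)
  n_steps <- nrow(inputs)
  keep <- seq(1, n_steps, by = record_stride)
  s_out <- matrix(NA_real_, length(keep), n)
  r_out <- matrix(NA_real_, length(keep), n)
  n_tail <- min(n_steps, max(1L, ceiling(params$tau_s / params$dt_dm)))
  r_tail <- matrix(0, n_tail, n)
  ki <- 1
  for (t in seq_len(n_steps)) {
    state <- dm_step(state, inputs[t, ], params)
    r_tail[1L + (t - 1L) %% n_tail, ] <- state$r
    if (ki <= length(keep) && t == keep[ki]) {
      s_out[ki, ] <- state$s
      r_out[ki, ] <- state$r
      ki <- ki + 1
    }
  }
  final_r <- setNames(colMeans(r_tail[seq_len(min(n_steps, n_tail)), , drop = FALSE]),
                      choices)
  above <- which(final_r > params$r_dec)
  winner <- if (length(above) == 0) "undecided"
  else {
    top <- max(final_r)
    if (sum(final_r == top) > 1) "undecided" else choices[which.max(final_r)]
  }
  traj <- as_tibble(as.data.frame(cbind(s_out, r_out)))
  names(traj) <- c(paste0("s_", choices), paste0("r_", choices))
  traj <- dplyr::bind_cols(tibble(time = (keep) * params$dt_dm), traj)
  structure(list(trajectory = traj, winner = winner, final_r = final_r,
                 params = params), class = "dm_run")
}

#' @export
print.dm_run <- function(x, ...) {
  cat(sprintf("<dm_run> winner: %s; final activities: %s\n", x$winner,
              paste(sprintf("%s=%.3g", names(x$final_r), x$final_r), collapse = ", ")))
  invisible(x)
}

#' Tidy a decision-network run
#'
#' @param x A `dm_run`.
#' @param ... Unused.
#' @return Long tibble with `time`, `neuron`, `s`, `r`.
#' @export
tidy.dm_run <- function(x, ...) {
  traj <- x$trajectory
  s_long <- tidyr::pivot_longer(traj[c("time", grep("^s_", names(traj), value = TRUE))],
                                -"time", names_to = "neuron", values_to = "s",
                                names_prefix = "s_")
  r_long <- tidyr::pivot_longer(traj[c("time", grep("^r_", names(traj), value = TRUE))],
                                -"time", names_to = "neuron", values_to = "r",
                                names_prefix = "r_")
  dplyr::inner_join(s_long, r_long, by = c("time", "neuron"))
}

#' @rdname tidy.dm_run
#' @return `glance`: one-row tibble with `winner`, `margin` (top minus
#'   runner-up final activity) and `decided`.
#' @export
glance.dm_run <- function(x, ...) {
  r <- sort(x$final_r, decreasing = TRUE)
  tibble(winner = x$winner,
         margin = if (length(r) > 1) r[1] - r[2] else r[1],
         decided = x$winner != "undecided")
}
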