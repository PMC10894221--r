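#' Load the sensor / circuit calibration
#'
#' The numeric calibration of the synthetic sensor frontends (base
#' capacitances, gains, jitter), circuit defaults, and decision-network
#' constants lives in one documented JSON file shipped with the package;
#' see `system.file("extdata", "calibration.json", package = "oscsense")`.
#'
#' @param path Optional path to an alternative calibration file.
#' @return Nested list of calibration constants.
#' @export
osc_calibration <- function(path = NULL) {
  path <- path %||% system.file("extdata", "calibration.json", package = "oscsense")
  jsonlite::fromJSON(path)
}

#' Assemble circuit, sensors and readout settings for a task
#'
#' Builds the oscillator-network template (printed circuit values:
#' 10 V / 300 us supply pulse, 8.2 kOhm loads, 100 pF coupling), the
#' per-node sensor models, the decision-network parameters and the
#' training configuration for one of the three demonstration tasks.
#'
#' @param task `"touch"` (2 nodes: reference + pressure-sensing),
#'   `"gesture"` (3 stretch-sensing nodes), or `"modes8"` (binary
#'   stimulus combinations on stretch-sensing nodes).
#' @param n_nodes Node count for `"modes8"` (2^n modes); fixed at 2 / 3
#'   for touch / gesture.
#' @param calib Calibration list from [osc_calibration()].
#' @param seed Integer seed stored in the template.
#' @return List with `template` ([onn_config()]), `sensors`, `dm`
#'   ([dm_params()]), `training` ([training_config()]), and `labels`.
#' @export
task_setup <- function(task = c("touch", "gesture", "modes8"), n_nodes = 3,
                       calib = osc_calibration(), seed = 1L) {
  task <- match.arg(task)
  cc <- calib$circuit
  dev <- device_params()
  mk_node <- function(i, c_par) oscillator_node(i, cc$r_load_ohm, c_par, dev)
  if (task == "touch") {
    n_nodes <- 2
    s <- calib$touch
    nodes <- list(mk_node(1, s$c_reference_f), mk_node(2, s$pressure_c_base_f))
    sensors <- list(NULL, sensor_model("pressure", s$pressure_c_base_f,
                                       s$pressure_gain, s$jitter_sigma))
    tap <- s$tap_delay_s
  } else {
    if (task == "gesture") n_nodes <- 3
    s <- calib$stretch
    nodes <- purrr::map(seq_len(n_nodes), mk_node, c_par = s$c_base_f)
    sensors <- purrr::map(seq_len(n_nodes), function(i)
      sensor_model("stretch", s$c_base_f, s$gain, s$jitter_sigma))
    tap <- s$tap_delay_s
  }
  template <- onn_config(nodes, coupling = cc$c_coupling_f, v_dd = cc$v_dd,
                         pulse_duration = cc$pulse_duration_s,
                         record_stride = 4L, seed = seed)
  labels <- task_labels(task, n_nodes)
  dmp <- do.call(dm_params, c(list(n_dm = length(labels)), calib$dm))
  list(template = template, sensors = sensors, dm = dmp,
       training = training_config(tap_delay = tap,
                                  freq_tap_delay = s$freq_tap_delay_s %||% (20 * tap),
                                  seed = seed),
       labels = labels, task = task)
}

#' Distance between two phase patterns
#'
#' Circular per-channel phase distance combined with the relative
#' common-frequency difference. Two symmetric stimulus modes can settle
#' to the same splay phase pattern while oscillating at different
#' common frequencies, so the common frequency is a first-class part of
#' the code (a fully bent hand is read out as "the lowest synchronized
#' frequency"). The default weight makes a frequency difference equal
#' to the synchronization tolerance (1%) count like a 36 degree
#' per-channel phase offset, comparable to the phase steps between
#' neighbouring stimulus modes: two patterns whose frequencies differ
#' by the locking tolerance are different network states no matter how
#' similar their phases are.
#'
#' @param p1,p2 [phase_pattern()] tibbles over the same channels.
#' @param freq_weight Degrees of distance per unit relative frequency
#'   difference.
#' @return Non-negative distance in degrees.
#' @export
pattern_distance <- function(p1, p2, freq_weight = 3600) {
  stopifnot(identical(p1$channel, p2$channel))
  dphi <- circ_dist(p1$phase_deg * pi / 180, p2$phase_deg * pi / 180) * 180 / pi
  f1 <- attr(p1, "common_frequency"); f2 <- attr(p2, "common_frequency")
  df <- freq_weight * abs(f1 - f2) / mean(c(f1, f2))
  sqrt(sum(dphi^2) + df^2)
}

#' How many stimulus modes are distinguishable from their phase patterns?
#'
#' Computes all pairwise [pattern_distance()]s, the maximum intra-label
#' spread and minimum inter-label distance, and counts distinguishable
#' clusters: two labels merge when the smallest distance between their
#' members does not exceed the larger of their intra-label spreads; the
#' cluster count is the number of connected components of that merge
#' graph.
#'
#' @param patterns Tibble with a `label` column and a `pattern`
#'   list-column of [phase_pattern()]s (several trials per label).
#' @return List with `n_distinguishable`, `min_inter`, `max_intra`,
#'   `separable` (`min_inter > max_intra`), and the per-pair distance
#'   tibble.
#' @export
phase_mode_separability <- function(patterns) {
  labs <- unique(patterns$label)
  n <- nrow(patterns)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  d <- tibble(
    i = pairs[, 1], j = pairs[, 2],
    label_i = patterns$label[pairs[, 1]], label_j = patterns$label[pairs[, 2]],
    dist = purrr::map2_dbl(pairs[, 1], pairs[, 2], function(a, b)
      pattern_distance(patterns$pattern[[a]], patterns$pattern[[b]])))
  intra <- d[d$label_i == d$label_j, ]
  inter <- d[d$label_i != d$label_j, ]
  max_intra <- if (nrow(intra)) max(intra$dist) else 0
  min_inter <- if (nrow(inter)) min(inter$dist) else Inf
  spread <- vapply(labs, function(l) {
    s <- intra[intra$label_i == l, ]
    if (nrow(s)) max(s$dist) else 0
  }, numeric(1))
  # merge graph over labels
  adj <- diag(length(labs)) == 1
  dimnames(adj) <- list(labs, labs)
  for (a in seq_along(labs)) for (b in seq_along(labs)) {
    if (a >= b) next
    cross <- inter[(inter$label_i == labs[a] & inter$label_j == labs[b]) |
                   (inter$label_i == labs[b] & inter$label_j == labs[a]), ]
    if (nrow(cross) && min(cross$dist) <= max(spread[a], spread[b]))
      adj[a, b] <- adj[b, a] <- TRUE
  }
  # connected components by repeated boolean closure (few labels)
  reach <- adj
  for (k in seq_along(labs)) reach <- reach | (reach %*% reach > 0)
  comp <- nrow(unique(reach))
  list(n_distinguishable = comp, min_inter = min_inter, max_intra = max_intra,
       separable = min_inter > max_intra, distances = d)
}

#' Two-oscillator locking range
#'
#' Sweeps the series resistance of a variable node away from a
#' reference node and reports the largest mismatch at which the pair
#' still locks to a common frequency -- the locking range at the given
#' coupling capacitance. Stronger coupling capacitors widen it.
#'
#' @param c_c Coupling capacitance (F).
#' @param r_ref Reference series resistance (Ohm).
#' @param r_var_grid Ascending grid of variable-node resistances (Ohm),
#'   starting at or above `r_ref`.
#' @param c_parallel Parallel capacitance of both nodes (F).
#' @param v_dd,pulse_duration Supply settings.
#' @param rel_tol Synchronization tolerance passed to
#'   [is_synchronized()].
#' @return List with `max_mismatch_ohm` (largest `r_var - r_ref` still
#'   locked; 0 if none beyond the first grid point) and the per-point
#'   `sweep` tibble.
#' @export
measure_locking_range <- function(c_c, r_ref = 8.2e3,
                                  r_var_grid = r_ref * (1 + seq(0, 0.2, by = 0.02)),
                                  c_parallel = 1e-9, v_dd = 10,
                                  pulse_duration = 300e-6, rel_tol = 0.01) {
  dev <- device_params()
  synced <- vapply(r_var_grid, function(rv) {
    nodes <- list(oscillator_node(1, r_ref, c_parallel, dev),
                  oscillator_node(2, rv, c_parallel, dev))
    wf <- simulate_onn(onn_config(nodes, coupling = c_c, v_dd = v_dd,
                                  pulse_duration = pulse_duration,
                                  record_stride = 4L))
    isTRUE(is_synchronized(wf, rel_tol = rel_tol))
  }, logical(1))
  # contiguous locked prefix
  first_fail <- which(!synced)[1]
  last_locked <- if (is.na(first_fail)) length(synced) else first_fail - 1
  max_mismatch <- if (last_locked >= 1) r_var_grid[last_locked] - r_ref else 0
  list(max_mismatch_ohm = max_mismatch,
       sweep = tibble(r_var = r_var_grid, mismatch = r_var_grid - r_ref,
                      synchronized = synced))
}

#' Measured frequency across a parameter grid
#'
#' Simulates a single uncoupled oscillator across a grid of parallel
#' capacitances or series resistances and measures the dominant output
#' frequency; the frequency falls monotonically with either parameter.
#'
#' @param values Grid of parameter values (F or Ohm).
#' @param vary `"c_parallel"` or `"r_load"`.
#' @param r_load,c_parallel The fixed parameter.
#' @param v_dd Supply voltage.
#' @param n_periods Simulated duration in analytic periods.
#' @return Tibble with `value`, `frequency_hz`, `analytic_hz`.
#' @export
measure_frequency_curve <- function(values, vary = c("c_parallel", "r_load"),
                                    r_load = 8.2e3, c_parallel = 10e-9,
                                    v_dd = 10, n_periods = 20) {
  vary <- match.arg(vary)
  rows <- purrr::map(values, function(v) {
    nd <- if (vary == "c_parallel") oscillator_node(1, r_load, v)
          else oscillator_node(1, v, c_parallel)
    t_an <- analytic_period(nd, v_dd)
    wf <- simulate_onn(onn_config(list(nd), pulse_duration = n_periods * t_an,
                                  record_stride = 2L))
    tibble(value = v,
           frequency_hz = suppressWarnings(dominant_frequency(wf$node_1, wf$time_s)),
           analytic_hz = 1 / t_an)
  })
  dplyr::bind_rows(rows)
}
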