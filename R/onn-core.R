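#' One relaxation-oscillator node
#'
#' A node is a series load resistor feeding a threshold-switch device with
#' a sensing capacitor in parallel. Its natural frequency is set by the
#' RC times of the charge (HRS) and discharge (LRS) phases between the
#' device's hysteresis thresholds.
#'
#' @param node_id Identifier (string or integer); node outputs are named
#'   `node_<id>` in waveform tables.
#' @param r_load Series resistance (Ohm; accepts suffixed strings, "8.2k").
#' @param c_parallel Parallel sensing capacitance (F; accepts "10n").
#' @param device A [device_params()] object.
#' @return An `oscillator_node` object.
#' @examples
#' oscillator_node(1, "8.2k", "10n")
#' @export
oscillator_node <- function(node_id, r_load, c_parallel, device = device_params()) {
  r_load <- si_parse(r_load); c_parallel <- si_parse(c_parallel)
  if (r_load <= 0 || c_parallel <= 0)
    osc_abort("invalid_params", "r_load and c_parallel must be positive")
  structure(list(node_id = as.character(node_id), r_load = r_load,
                 c_parallel = c_parallel, device = device),
            class = "oscillator_node")
}

#' Oscillation feasibility of a node
#'
#' A node self-oscillates iff the HRS voltage-divider level exceeds the
#' threshold voltage (so the switch always fires) and the LRS level sits
#' below the hold voltage (so the on state always collapses):
#' `v_dd * r_off/(r_load + r_off) > v_th` and
#' `v_dd * r_on/(r_load + r_on) < v_hold`.
#'
#' @param node An [oscillator_node()].
#' @param v_dd Supply voltage (V).
#' @return One-row tibble with `oscillates`, the two conditions
#'   (`fires_from_hrs`, `collapses_from_lrs`), the two divider levels, and
#'   a `diagnosis` string ("ok", "stuck HRS", "stuck LRS", or both).
#' @examples
#' check_oscillates(oscillator_node(1, 8.2e3, 10e-9), 10)
#' @export
check_oscillates <- function(node, v_dd) {
  d <- node$device
  v_hrs <- v_dd * d$r_off / (node$r_load + d$r_off)
  v_lrs <- v_dd * d$r_on / (node$r_load + d$r_on)
  fires <- v_hrs > d$v_th
  collapses <- v_lrs < d$v_hold
  diagnosis <- if (fires && collapses) "ok"
    else paste(c(if (!fires) "stuck HRS", if (!collapses) "stuck LRS"), collapse = " + ")
  tibble(oscillates = fires && collapses, fires_from_hrs = fires,
         collapses_from_lrs = collapses, v_hrs = v_hrs, v_lrs = v_lrs,
         diagnosis = diagnosis)
}

#' Closed-form period of an uncoupled oscillator
#'
#' Exact two-phase RC solution. Charge phase (device in HRS): the node
#' relaxes towards the Thevenin level `V_inf = v_dd*r_off/(r_load+r_off)`
#' with `tau = (r_load || r_off) * c_parallel`, so
#' `t_charge = tau * log((V_inf - v_hold)/(V_inf - v_th))`; the discharge
#' phase is the same expression with `r_on`, traversed from `v_th` down to
#' `v_hold`. Optional switching dead-times add on top.
#'
#' @param node An [oscillator_node()].
#' @param v_dd Supply voltage (V).
#' @param include_dead_time Add the device's `t_sw_on`/`t_sw_off`
#'   dead-times to the period (default `FALSE`, the analytic-comparable
#'   mode).
#' @return Period in seconds, with attribute `components` holding
#'   `t_charge` and `t_discharge`.
#' @examples
#' analytic_period(oscillator_node(1, 8.2e3, 10e-9), 10) # ~35.3 us
#' @export
analytic_period <- function(node, v_dd, include_dead_time = FALSE) {
  chk <- check_oscillates(node, v_dd)
  if (!chk$oscillates)
    osc_abort("non_oscillating",
              paste0("node ", node$node_id, " does not oscillate: ", chk$diagnosis))
  d <- node$device
  phase_time <- function(r_dev) {
    v_inf <- v_dd * r_dev / (node$r_load + r_dev)
    tau <- (node$r_load * r_dev / (node$r_load + r_dev)) * node$c_parallel
    tau * log((v_inf - d$v_hold) / (v_inf - d$v_th))
  }
  t_charge <- phase_time(d$r_off)
  # discharge: relax from v_th down to v_hold towards the (low) LRS level
  v_inf_on <- v_dd * d$r_on / (node$r_load + d$r_on)
  tau_on <- (node$r_load * d$r_on / (node$r_load + d$r_on)) * node$c_parallel
  t_discharge <- tau_on * log((d$v_th - v_inf_on) / (d$v_hold - v_inf_on))
  period <- t_charge + t_discharge
  if (include_dead_time) period <- period + d$t_sw_on + d$t_sw_off
  structure(period, components = c(t_charge = t_charge, t_discharge = t_discharge))
}

#' Network configuration for a coupled-oscillator simulation
#'
#' @param nodes List of [oscillator_node()] objects (order defines node
#'   indices).
#' @param coupling Coupling capacitances: either a symmetric N x N matrix
#'   (farads, zero diagonal), a single scalar applied to every pair
#'   (all-to-all, the default topology for small networks), or a data
#'   frame with columns `i, j, c` for arbitrary graphs. `NULL` or 0 means
#'   uncoupled.
#' @param v_dd Supply voltage (V), applied for `pulse_duration`.
#' @param pulse_duration Length of the supply pulse / simulation (s).
#' @param init_voltages Per-node initial voltages (V), or `NULL` to use
#'   [startup_init()] in deterministic mode.
#' @param init_mode `"deterministic"` (staggered sub-threshold divider
#'   pattern) or `"random"` (seeded uniform draws in `[0, v_hold]`), used
#'   when `init_voltages` is `NULL`.
#' @param dt Integration step (s); `NULL` picks `min-RC/200` where
#'   `min-RC = (r_load || r_on) * min(c_parallel)` over nodes -- the
#'   stiffest (discharge) time constant.
#' @param record_stride Record every this-many integration steps.
#' @param seed Integer seed for threshold jitter / random init.
#' @param max_dv_frac Error if a node voltage moves more than this
#'   fraction of its hysteresis window in one step.
#' @param force Skip the per-node oscillation feasibility check.
#' @return An `onn_config` object.
#' @export
onn_config <- function(nodes, coupling = NULL, v_dd = 10,
                       pulse_duration = 300e-6, init_voltages = NULL,
                       init_mode = c("deterministic", "random"), dt = NULL,
                       record_stride = 1L, seed = 1L, max_dv_frac = 0.25,
                       force = FALSE) {
  init_mode <- match.arg(init_mode)
  stopifnot(length(nodes) >= 1)
  if (inherits(nodes, "oscillator_node")) nodes <- list(nodes)
  n <- length(nodes)
  cmat <- coupling_matrix(coupling, n)
  v_dd <- si_parse(v_dd)
  if (v_dd <= 0) osc_abort("invalid_params", "v_dd must be positive")
  if (!is.null(init_voltages)) {
    stopifnot(length(init_voltages) == n)
    if (any(init_voltages < 0 | init_voltages > v_dd))
      osc_abort("invalid_params", "init voltages must lie in [0, v_dd]")
  }
  if (is.null(dt)) {
    rc <- vapply(nodes, function(nd) {
      ron <- nd$device$r_on
      (nd$r_load * ron / (nd$r_load + ron))
    }, numeric(1))
    dt <- min(rc) * min(vapply(nodes, `[[`, numeric(1), "c_parallel")) / 200
  }
  if (dt <= 0) osc_abort("invalid_params", "dt must be positive")
  structure(list(nodes = nodes, coupling = cmat, v_dd = v_dd,
                 pulse_duration = pulse_duration, init_voltages = init_voltages,
                 init_mode = init_mode, dt = dt,
                 record_stride = as.integer(record_stride),
                 seed = as.integer(seed), max_dv_frac = max_dv_frac,
                 force = force),
            class = "onn_config")
}

# normalize the coupling argument to a symmetric zero-diagonal matrix
coupling_matrix <- function(coupling, n) {
  if (is.null(coupling)) return(matrix(0, n, n))
  if (is.data.frame(coupling)) {
    m <- matrix(0, n, n)
    for (k in seq_len(nrow(coupling))) {
      i <- coupling$i[k]; j <- coupling$j[k]; c <- si_parse(coupling$c[k])
      m[i, j] <- m[j, i] <- c
    }
    coupling <- m
  } else if (length(coupling) == 1) {
    coupling <- matrix(si_parse(coupling), n, n)
    diag(coupling) <- 0
  }
  stopifnot(is.matrix(coupling), nrow(coupling) == n, ncol(coupling) == n)
  if (any(coupling < 0)) osc_abort("invalid_params", "coupling capacitances must be >= 0")
  if (any(abs(coupling - t(coupling)) > 0))
    osc_abort("invalid_params", "coupling map must be symmetric")
  diag(coupling) <- 0
  coupling
}

#' Capacitance matrix of the coupled network
#'
#' Collecting all derivative terms of the coupled node equations on the
#' left gives `M dV/dt = b(V)` with
#' `M[i,i] = c_parallel_i + sum_j coupling(i,j)` and
#' `M[i,j] = -coupling(i,j)`. M is symmetric and strictly diagonally
#' dominant (hence invertible) whenever all parallel capacitances are
#' positive.
#'
#' @param config An [onn_config()].
#' @return The N x N capacitance matrix (farads).
#' @export
build_capacitance_matrix <- function(config) {
  cp <- vapply(config$nodes, `[[`, numeric(1), "c_parallel")
  m <- -config$coupling
  diag(m) <- cp + rowSums(config$coupling)
  if (any(diag(m) <= 0)) osc_abort("singular_matrix", "non-positive diagonal entry")
  m
}

#' Start-up initial voltages
#'
#' Emulates the start-up voltage-divider circuit that pins the network to
#' a reproducible initial state so the settled phase mode is stable
#' across runs. Deterministic mode staggers node i of N at
#' `v_hold + i/(N+1) * (v_th - v_hold)` (distinct, sub-threshold);
#' random mode draws seeded uniforms in `[0, v_hold]`.
#'
#' @param config An [onn_config()].
#' @return Numeric vector of per-node initial voltages (V).
#' @export
startup_init <- function(config) {
  n <- length(config$nodes)
  if (config$init_mode == "random") {
    set.seed(config$seed)
    vapply(seq_len(n), function(i) runif(1, 0, config$nodes[[i]]$device$v_hold),
           numeric(1))
  } else {
    vapply(seq_len(n), function(i) {
      d <- config$nodes[[i]]$device
      d$v_hold + (i / (n + 1)) * (d$v_th - d$v_hold)
    }, numeric(1))
  }
}

#' Simulate the coupled oscillator network
#'
#' Integrates `M dV/dt = b(V)` with a fixed-step explicit midpoint (RK2)
#' scheme; `b_i = (v_dd - V_i)/r_load_i - V_i/R_device_i`. Device
#' switching events are located by bisection of the sub-step to within
#' `dt/100` before the hysteretic state flips; simultaneous crossings
#' resolve in ascending node order. Deterministic under a fixed seed and
#' fixed initial voltages.
#'
#' @param config An [onn_config()].
#' @return A wide tibble of class `onn_waveforms`: column `time_s` plus
#'   one `node_<id>` column per node. Attributes: `config` (the resolved
#'   configuration) and `n_events` (number of switching events).
#' @examples
#' nd <- oscillator_node(1, 8.2e3, 10e-9)
#' wf <- simulate_onn(onn_config(list(nd), pulse_duration = 100e-6))
#' @export
simulate_onn <- function(config) {
  stopifnot(inherits(config, "onn_config"))
  nodes <- config$nodes
  n <- length(nodes)
  if (!config$force) {
    for (nd in nodes) {
      chk <- check_oscillates(nd, config$v_dd)
      if (!chk$oscillates)
        osc_abort("non_oscillating",
                  paste0("node ", nd$node_id, ": ", chk$diagnosis,
                         " (set force = TRUE to simulate anyway)"))
      f <- 1 / analytic_period(nd, config$v_dd)
      if (f > 2.6e6)
        warn(paste0("node ", nd$node_id, " natural frequency ", signif(f / 1e6, 3),
                    " MHz exceeds the 2.6 MHz device limit"))
    }
  }
  m <- build_capacitance_matrix(config)
  minv <- solve(m)
  v0 <- config$init_voltages %||% startup_init(config)
  n_steps <- ceiling(config$pulse_duration / config$dt)
  set.seed(config$seed)
  res <- onn_simulate_cpp(
    minv = minv,
    r_load = vapply(nodes, `[[`, numeric(1), "r_load"),
    r_on = vapply(nodes, function(x) x$device$r_on, numeric(1)),
    r_off = vapply(nodes, function(x) x$device$r_off, numeric(1)),
    vth = vapply(nodes, function(x) x$device$v_th, numeric(1)),
    vhold = vapply(nodes, function(x) x$device$v_hold, numeric(1)),
    sig_vth = vapply(nodes, function(x) x$device$sigma_vth_c2c, numeric(1)),
    sig_vhold = vapply(nodes, function(x) x$device$sigma_vhold_c2c, numeric(1)),
    v_dd = config$v_dd, v0 = v0,
    phase0 = rep(0L, n),
    dt = config$dt, n_steps = as.integer(n_steps),
    record_stride = config$record_stride,
    max_dv_frac = config$max_dv_frac)
  out <- as_tibble(as.data.frame(res$voltages))
  names(out) <- paste0("node_", vapply(nodes, `[[`, character(1), "node_id"))
  out <- dplyr::bind_cols(tibble(time_s = res$time), out)
  structure(out, config = config, n_events = res$n_events,
            class = c("onn_waveforms", class(out)))
}

#' Channel (node output) columns of a waveform table
#'
#' @param wf An `onn_waveforms` tibble (or any data frame with a
#'   `time_s` column and `node_*` channels).
#' @return Character vector of channel column names.
#' @export
waveform_channels <- function(wf) setdiff(names(wf), "time_s")
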