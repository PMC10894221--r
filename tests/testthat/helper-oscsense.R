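# Shared fixtures for the test suite.

# Half-width device-to-device threshold intervals: the measured spans
# (3.55-4.10 V and 1.52-1.96 V) shrunk to half their width about their
# centres.
d2d_halfwidth <- list(vth_range = c(3.6875, 3.9625),
                      vhold_range = c(1.63, 1.85))

# A fast single-oscillator waveform reused across analysis tests.
ref_node <- function() oscillator_node(1, 8.2e3, 10e-9)

sim_single <- function(n_periods = 12, record_stride = 2L) {
  nd <- ref_node()
  simulate_onn(onn_config(list(nd),
                          pulse_duration = n_periods * analytic_period(nd, 10),
                          record_stride = record_stride))
}

# Two identical coupled nodes in the anti-phase band.
sim_pair <- function(seed = 1, c_parallel = 1e-9, pulse = 300e-6) {
  nodes <- list(oscillator_node(1, 8.2e3, c_parallel),
                oscillator_node(2, 8.2e3, c_parallel))
  simulate_onn(onn_config(nodes, coupling = 100e-12, pulse_duration = pulse,
                          init_mode = "random", seed = seed,
                          record_stride = 2L))
}
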