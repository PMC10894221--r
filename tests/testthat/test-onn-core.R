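test_that("si_parse handles suffixed quantities", {
  expect_equal(si_parse("8.2k"), 8200)
  expect_equal(si_parse("100p"), 1e-10)
  expect_equal(si_parse("10n"), 1e-8)
  expect_equal(si_parse("3.3u"), 3.3e-6)
  expect_equal(si_parse(42), 42)
  expect_error(si_parse("ten ohms"), class = "oscsense_error_parse")
})

test_that("check_oscillates reproduces the divider arithmetic", {
  chk <- check_oscillates(ref_node(), 10)
  expect_true(chk$oscillates)
  expect_equal(chk$v_hrs, 10 * 20e3 / 28.2e3, tolerance = 1e-12)
  expect_equal(chk$v_lrs, 10 * 300 / 8500, tolerance = 1e-12)
  # huge load: divider level below v_th, stuck HRS
  stuck_h <- check_oscillates(oscillator_node(1, 1e6, 10e-9), 10)
  expect_false(stuck_h$oscillates)
  expect_match(stuck_h$diagnosis, "stuck HRS")
  # tiny load: LRS level above v_hold, stuck LRS
  stuck_l <- check_oscillates(oscillator_node(1, 1, 10e-9), 10)
  expect_false(stuck_l$oscillates)
  expect_match(stuck_l$diagnosis, "stuck LRS")
})

test_that("analytic_period matches the hand-evaluated closed form", {
  # independent hand evaluation for 10 V, 8.2 kOhm, 20 kOhm/300 Ohm,
  # 4.0/1.7 V, 10 nF:
  #   V_inf = 10*20000/28200 = 7.09220 V
  #   tau_charge = (8200*20000/28200)*1e-8 = 58.156 us
  #   t_charge = 58.156us * ln(5.39220/3.09220) = 32.339 us
  #   V_inf_on = 10*300/8500 = 0.35294 V; tau_on = (8200*300/8500)*1e-8
  #   t_discharge = 2.8943us * ln(3.64706/1.34706) = 2.8825 us
  #   T = 35.221 us
  p <- analytic_period(ref_node(), 10)
  comp <- attr(p, "components")
  expect_equal(as.numeric(p), 35.2214e-6, tolerance = 5e-4)
  expect_equal(unname(comp["t_charge"]), 32.339e-6, tolerance = 1e-3)
  expect_equal(unname(comp["t_discharge"]), 2.8825e-6, tolerance = 1e-3)
})

test_that("doubling c_parallel doubles the period exactly", {
  p1 <- analytic_period(oscillator_node(1, 8.2e3, 10e-9), 10)
  p2 <- analytic_period(oscillator_node(1, 8.2e3, 20e-9), 10)
  expect_equal(as.numeric(p2), 2 * as.numeric(p1), tolerance = 1e-12)
})

test_that("non-oscillating nodes raise", {
  expect_error(analytic_period(oscillator_node(1, 1e6, 10e-9), 10),
               class = "oscsense_error_non_oscillating")
  expect_error(simulate_onn(onn_config(list(oscillator_node(1, 1e6, 10e-9)))),
               class = "oscsense_error_non_oscillating")
})

test_that("capacitance matrix collects parallel and coupling terms", {
  nodes <- list(oscillator_node(1, 8.2e3, 10e-9), oscillator_node(2, 8.2e3, 10e-9))
  m <- build_capacitance_matrix(onn_config(nodes, coupling = 100e-12))
  expect_equal(m, matrix(c(10.1e-9, -0.1e-9, -0.1e-9, 10.1e-9), 2, 2))
  expect_equal(m, t(m))
  m0 <- build_capacitance_matrix(onn_config(nodes))
  expect_equal(m0, diag(c(10e-9, 10e-9)))
})

test_that("coupling maps accept scalars, matrices and edge lists only when valid", {
  nodes <- list(oscillator_node(1, 8.2e3, 10e-9), oscillator_node(2, 8.2e3, 10e-9),
                oscillator_node(3, 8.2e3, 10e-9))
  cfg <- onn_config(nodes, coupling = 100e-12)
  expect_equal(cfg$coupling[1, 2], 100e-12)
  expect_equal(diag(cfg$coupling), rep(0, 3))
  edges <- data.frame(i = 1, j = 3, c = "47p")
  cfg2 <- onn_config(nodes, coupling = edges)
  expect_equal(cfg2$coupling[1, 3], 47e-12)
  expect_equal(cfg2$coupling[1, 2], 0)
  bad <- matrix(c(0, 1e-10, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(onn_config(nodes, coupling = bad), class = "oscsense_error_invalid_params")
  expect_error(onn_config(nodes, coupling = -1e-12), class = "oscsense_error_invalid_params")
})

test_that("startup_init staggers distinct sub-threshold voltages", {
  nodes <- purrr::map(1:3, ~oscillator_node(.x, 8.2e3, 10e-9))
  v <- startup_init(onn_config(nodes))
  expect_equal(v, 1.7 + (1:3) / 4 * (4.0 - 1.7))
  expect_equal(length(unique(v)), 3)
  expect_true(all(v < 4.0))
  cfgr <- onn_config(nodes, init_mode = "random", seed = 11)
  vr <- startup_init(cfgr)
  expect_identical(vr, startup_init(cfgr))
  expect_true(all(vr >= 0 & vr <= 1.7))
})

test_that("simulated period matches the analytic oracle within 0.5%", {
  wf <- sim_single()
  pk <- detect_peaks(wf$node_1, wf$time_s)
  t_sim <- median(diff(pk$time))
  t_an <- as.numeric(analytic_period(ref_node(), 10))
  expect_lt(abs(t_sim - t_an) / t_an, 0.005)
})

test_that("voltages stay inside [0, v_dd] and the run is deterministic", {
  wf1 <- sim_pair(seed = 3, pulse = 100e-6)
  expect_true(all(wf1$node_1 >= 0 & wf1$node_1 <= 10))
  expect_true(all(wf1$node_2 >= 0 & wf1$node_2 <= 10))
  wf2 <- sim_pair(seed = 3, pulse = 100e-6)
  expect_identical(as.data.frame(wf1), as.data.frame(wf2))
})

test_that("uncoupled nodes keep their own analytic frequencies", {
  nodes <- list(oscillator_node(1, 8.2e3, 10e-9), oscillator_node(2, 8.2e3, 15e-9))
  t2 <- as.numeric(analytic_period(nodes[[2]], 10))
  wf <- simulate_onn(onn_config(nodes, pulse_duration = 15 * t2, record_stride = 2L))
  for (i in 1:2) {
    f <- dominant_frequency(wf[[paste0("node_", i)]], wf$time_s)
    expect_equal(f, 1 / as.numeric(analytic_period(nodes[[i]], 10)), tolerance = 0.01)
  }
})

test_that("the simulator warns above the 2.6 MHz device limit", {
  nd <- oscillator_node(1, 8.2e3, 100e-12) # ~2.8 MHz natural frequency
  expect_warning(simulate_onn(onn_config(list(nd), pulse_duration = 20e-6)),
                 regexp = "2.6 MHz")
})

test_that("network configurations round-trip through JSON", {
  nodes <- list(oscillator_node(1, "8.2k", "1n"), oscillator_node(2, 9e3, 1.1e-9))
  cfg <- onn_config(nodes, coupling = "100p", pulse_duration = 50e-6,
                    init_mode = "random", seed = 5, record_stride = 4L)
  back <- onn_config_from_json(onn_config_to_json(cfg))
  expect_equal(back$coupling, cfg$coupling)
  expect_equal(back$v_dd, cfg$v_dd)
  expect_equal(back$dt, cfg$dt)
  wf1 <- simulate_onn(cfg)
  wf2 <- simulate_onn(back)
  expect_identical(as.data.frame(wf1), as.data.frame(wf2))
})

test_that("record_stride thins the sample grid", {
  nd <- ref_node()
  cfg1 <- onn_config(list(nd), pulse_duration = 50e-6, record_stride = 1L)
  cfg4 <- onn_config(list(nd), pulse_duration = 50e-6, record_stride = 4L)
  wf1 <- simulate_onn(cfg1)
  wf4 <- simulate_onn(cfg4)
  expect_equal(wf4$time_s[2] - wf4$time_s[1], 4 * (wf1$time_s[2] - wf1$time_s[1]),
               tolerance = 1e-9)
})
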