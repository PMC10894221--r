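#' VO2 threshold-switch device parameters
#'
#' Compact behavioural model of a volatile VO2 threshold switch: two
#' resistance states with voltage hysteresis. Charging the parallel
#' capacitor in the high-resistive state (HRS, `r_off`) until the device
#' voltage reaches `v_th` fires the metal-insulator transition into the
#' low-resistive state (LRS, `r_on`); discharge below `v_hold` reverts it.
#' Cycle-to-cycle variability redraws the effective thresholds on every
#' transition with the given relative standard deviations.
#'
#' Defaults are the nominal mid-range values of the device family this
#' model emulates: thresholds 4.0 / 1.7 V (mid-points of the
#' device-to-device spans 3.55--4.10 V and 1.52--1.96 V), resistances
#' 20 kOhm / 300 Ohm, saturated switching times 115 ns (off to on) and
#' 90 ns (on to off). The cycle-to-cycle deviations 2.1e-4 and 1.3e-4 are
#' interpreted as relative standard deviations.
#'
#' @param v_th Threshold voltage for the HRS to LRS transition (V).
#' @param v_hold Hold voltage below which the LRS collapses back (V);
#'   must be below `v_th`.
#' @param r_on,r_off LRS and HRS resistances (Ohm), `r_on < r_off`.
#' @param t_sw_on,t_sw_off Switching dead-times (s); modelled as a pure
#'   delay during which the resistance holds its pre-transition value.
#'   Zero (the default analytic-comparable mode) switches instantaneously.
#' @param sigma_vth_c2c,sigma_vhold_c2c Relative cycle-to-cycle standard
#'   deviations of the two thresholds.
#' @return A `vo2_device_params` object (named list).
#' @examples
#' dev <- device_params()
#' dev$v_th
#' @export
device_params <- function(v_th = 4.0, v_hold = 1.7,
                          r_on = 300, r_off = 20e3,
                          t_sw_on = 115e-9, t_sw_off = 90e-9,
                          sigma_vth_c2c = 2.1e-4, sigma_vhold_c2c = 1.3e-4) {
  v_th <- si_parse(v_th); v_hold <- si_parse(v_hold)
  r_on <- si_parse(r_on); r_off <- si_parse(r_off)
  if (!(v_hold < v_th)) osc_abort("invalid_params", "v_hold must be < v_th")
  if (!(0 < r_on && r_on < r_off)) osc_abort("invalid_params", "need 0 < r_on < r_off")
  if (t_sw_on < 0 || t_sw_off < 0) osc_abort("invalid_params", "switching times must be >= 0")
  if (sigma_vth_c2c < 0 || sigma_vhold_c2c < 0) osc_abort("invalid_params", "sigmas must be >= 0")
  structure(list(v_th = v_th, v_hold = v_hold, r_on = r_on, r_off = r_off,
                 t_sw_on = t_sw_on, t_sw_off = t_sw_off,
                 sigma_vth_c2c = sigma_vth_c2c, sigma_vhold_c2c = sigma_vhold_c2c),
            class = "vo2_device_params")
}

#' @export
print.vo2_device_params <- function(x, ...) {
  cat(sprintf("<vo2_device_params> v_th=%.3g V, v_hold=%.3g V, r_off=%.3g Ohm, r_on=%.3g Ohm\n",
              x$v_th, x$v_hold, x$r_off, x$r_on))
  invisible(x)
}

#' Instantaneous device state
#'
#' Tracks which resistive branch the switch is on plus this cycle's
#' jittered effective thresholds.
#'
#' @param phase `"HRS"` or `"LRS"`.
#' @param params A [device_params()] object supplying the nominal
#'   thresholds used as the initial effective ones.
#' @return A `vo2_device_state` object.
#' @export
device_state <- function(phase = c("HRS", "LRS"), params = device_params()) {
  phase <- match.arg(phase)
  structure(list(phase = phase,
                 effective_vth = params$v_th,
                 effective_vhold = params$v_hold),
            class = "vo2_device_state")
}

#' Device resistance in a given state
#'
#' @param state A [device_state()].
#' @param params A [device_params()].
#' @return Resistance in ohms: `r_off` in HRS, `r_on` in LRS.
#' @export
device_resistance <- function(state, params) {
  if (state$phase == "HRS") params$r_off else params$r_on
}

#' Advance the hysteretic switch by one voltage sample
#'
#' HRS switches to LRS iff the device voltage reaches the effective
#' threshold; LRS reverts iff it falls to the effective hold voltage;
#' anywhere inside the hysteresis window the state is unchanged. On each
#' transition new effective thresholds are redrawn with the
#' cycle-to-cycle sigmas (at most 100 redraws enforcing
#' `v_hold < v_th`, then an error). Uses R's RNG; seed with `set.seed()`.
#'
#' @param state A [device_state()].
#' @param v_device Instantaneous voltage across the device (V).
#' @param params A [device_params()].
#' @return The (possibly updated) `vo2_device_state`.
#' @export
step_device <- function(state, v_device, params) {
  fire <- state$phase == "HRS" && v_device >= state$effective_vth
  drop <- state$phase == "LRS" && v_device <= state$effective_vhold
  if (!fire && !drop) return(state)
  state$phase <- if (fire) "LRS" else "HRS"
  for (i in seq_len(100)) {
    vt <- params$v_th * (1 + params$sigma_vth_c2c * rnorm(1))
    vh <- params$v_hold * (1 + params$sigma_vhold_c2c * rnorm(1))
    if (vh < vt) {
      state$effective_vth <- vt
      state$effective_vhold <- vh
      return(state)
    }
  }
  osc_abort("invalid_state", "effective thresholds violate v_hold < v_th after 100 redraws")
}

#' Sample a population of devices (device-to-device variation)
#'
#' Draws `n` parameter sets with `v_th` and `v_hold` independent and
#' uniform over the given intervals, rejecting (up to 100 redraws per
#' device) any pair violating `v_hold < v_th`. The default intervals are
#' the measured device-to-device spans of the emulated device family.
#'
#' @param n Number of devices.
#' @param vth_range,vhold_range Length-2 numeric intervals (V).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param template A [device_params()] supplying the non-threshold fields.
#' @return A tibble with one row per device and columns
#'   `device_id, v_th, v_hold, r_on, r_off, ...`; convert one row with
#'   [as_device_params()].
#' @examples
#' sample_devices(3, seed = 1)
#' @export
sample_devices <- function(n, vth_range = c(3.55, 4.10),
                           vhold_range = c(1.52, 1.96), seed,
                           template = device_params()) {
  stopifnot(n >= 1, length(vth_range) == 2, length(vhold_range) == 2)
  if (diff(vth_range) < 0 || diff(vhold_range) < 0)
    osc_abort("invalid_range", "ranges must be non-decreasing intervals")
  set.seed(as.integer(seed))
  draw_one <- function(i) {
    for (k in seq_len(100)) {
      vt <- runif(1, vth_range[1], vth_range[2])
      vh <- runif(1, vhold_range[1], vhold_range[2])
      if (vh < vt) return(c(v_th = vt, v_hold = vh))
    }
    osc_abort("invalid_range", "drawn pair violates v_hold < v_th after 100 redraws")
  }
  draws <- t(vapply(seq_len(n), draw_one, numeric(2)))
  tibble(device_id = seq_len(n),
         v_th = draws[, "v_th"], v_hold = draws[, "v_hold"],
         r_on = template$r_on, r_off = template$r_off,
         t_sw_on = template$t_sw_on, t_sw_off = template$t_sw_off,
         sigma_vth_c2c = template$sigma_vth_c2c,
         sigma_vhold_c2c = template$sigma_vhold_c2c)
}

#' Convert a row of a device table to device parameters
#'
#' @param row One-row data frame as produced by [sample_devices()].
#' @return A [device_params()] object.
#' @export
as_device_params <- function(row) {
  row <- as.list(row)
  device_params(v_th = row$v_th, v_hold = row$v_hold, r_on = row$r_on,
                r_off = row$r_off, t_sw_on = row$t_sw_on %||% 0,
                t_sw_off = row$t_sw_off %||% 0,
                sigma_vth_c2c = row$sigma_vth_c2c %||% 0,
                sigma_vhold_c2c = row$sigma_vhold_c2c %||% 0)
}

#' Serialize / deserialize device parameters as JSON
#'
#' @param params A [device_params()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `device_params_to_json`: JSON string (invisibly, if written to
#'   a file); `device_params_from_json`: a [device_params()] object.
#' @export
device_params_to_json <- function(params, path = NULL) {
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname device_params_to_json
#' @param json JSON string or file path to read.
#' @export
device_params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(device_params, x)
}
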