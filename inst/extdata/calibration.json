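{
  "comment": "Numeric calibration of the synthetic sensor frontends and circuit defaults. Frequencies follow f = 1/(3529 * C) for the nominal circuit (10 V supply, 8.2 kOhm load, 20 kOhm/300 Ohm device, 4.0/1.7 V thresholds). The touch task uses a ~1-2 nF band where the printed 100 pF coupling is a 5-10% relative kick per firing: the pressure sensor doubles the sensory node capacitance when pressed (1 -> 2 nF), moving it from a 2x natural-frequency mismatch with the fixed 2 nF reference node (far outside the locking range, so the untouched pair cannot lock) to a matched pair inside it. The stretch (gesture/modes) band is 330 pF, where the 100 pF coupling is a ~23% relative kick: this strong-coupling regime is where frequency locking is wide enough to absorb device-to-device threshold spread (a three-node network with ~6% natural-frequency spread still locks) while the sensor swing of 3.5% when fully bent keeps every stimulus mode synchronized on nominal devices and encoded in the phase pattern and common frequency.",
  "circuit": {
    "v_dd": 10,
    "pulse_duration_s": 300e-6,
    "r_load_ohm": 8200,
    "c_coupling_f": 100e-12
  },
  "touch": {
    "c_reference_f": 2.0e-9,
    "pressure_c_base_f": 1.0e-9,
    "pressure_gain": 1.0,
    "jitter_sigma": 0.002,
    "tap_delay_s": 1.75e-6,
    "freq_tap_delay_s": 35e-6
  },
  "stretch": {
    "c_base_f": 330e-12,
    "gain": 0.035,
    "jitter_sigma": 0.002,
    "tap_delay_s": 0.45e-6,
    "freq_tap_delay_s": 36e-6
  },
  "noise_snr_db": 30,
  "dm": {
    "j_e": 2.0, "j_m": -2.0, "alpha": 0.1, "beta": 0.7,
    "gamma": 0.641, "theta": 0.25, "tau_s": 100, "r_dec": 15
  }
}
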