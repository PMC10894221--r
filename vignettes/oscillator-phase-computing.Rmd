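---
title: "Phase-domain sensory computing with coupled relaxation oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-domain sensory computing with coupled relaxation oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscsense)
library(ggplot2)
```

oscsense is a software twin of a sensory system built from capacitively
coupled VO~2~ relaxation oscillators. A capacitive sensor (pressure or
stretch) loads an oscillator, shifting its natural frequency; coupling
pulls the oscillators into a common locked frequency whose per-channel
phase offsets encode *which combination* of sensors is stimulated; a
trained linear readout plus a winner-take-all decision network turn that
phase code into a discrete classification. This vignette explains the
model stack and the design decisions that are not obvious from the
function reference.

## 1. The oscillator

Each node is a series connection of a load resistor and a hysteretic
threshold switch (the VO~2~ device), with a parallel capacitor at the
middle node. The device is a two-state resistor: it snaps to its low
resistance when the capacitor voltage rises through `v_th` and back to
its high resistance when it falls through `v_hold`. Between thresholds
the capacitor alternately charges toward the high-resistance divider
level and discharges toward the low-resistance one, so the closed-form
period is a sum of two RC log terms:

```{r analytic}
nd <- oscillator_node(1, r_load = 8.2e3, c_parallel = 10e-9)
analytic_period(nd, v_dd = 10)
```

The simulator (`simulate_onn()`) integrates the full coupled RC network
with a second-order method and bisects each threshold crossing to the
integration tolerance, so the simulated single-oscillator period matches
the closed form to well under 0.5%:

```{r oracle}
wf <- simulate_onn(onn_config(list(nd), pulse_duration = 12 * analytic_period(nd, 10)))
pk <- detect_peaks(wf$node_1, wf$time_s)
median(diff(pk$time)) / as.numeric(analytic_period(nd, 10)) - 1
```

The period scales linearly with `c_parallel` and grows with `r_load`, so
frequency falls monotonically in both -- that monotonicity is what lets
a capacitive sensor tune a node's natural frequency
(`measure_frequency_curve()` sweeps it).

## 2. Coupling, locking, and the phase code

Capacitive coupling (`coupling = 100e-12` by default) injects a voltage
kick into every neighbour at each switching event. The kick is
*delaying*: it pulls the network's locked frequency below the nodes'
natural frequencies and, for identical nodes, stabilizes splay states
-- two nodes settle 180° apart, three all-to-all nodes settle at 120°
gaps. Mismatched nodes lock only inside a finite locking range that
widens with the coupling capacitance (`measure_locking_range()`).

The *relative kick* a neighbour's switching delivers is roughly
`C_c / (C_s + 2 C_c)`, so the same 100 pF coupler is weak against a
10 nF tank and strong against a 330 pF one. The package uses both
regimes deliberately (see `inst/extdata/calibration.json`):

* **Touch task (weak coupling, 1--2 nF):** the reference node and the
  pressure node lock only when a touch doubles the sensor capacitance
  and drags the sensory node's frequency into the locking range. The
  *presence or absence of locking* is the code.
* **Stretch tasks (strong coupling, 330 pF):** all nodes always lock;
  the code is the pattern of phase offsets (and the common frequency)
  that the stimulus combination selects.

Two distinct stimulus modes can settle to the *same* phase offsets at
different locked frequencies (for example the all-rest and all-stretched
modes, which are related by a uniform slowdown). The common frequency is
therefore a first-class part of the pattern code: `pattern_distance()`
mixes per-channel circular phase distance with the relative frequency
difference, weighted so that a frequency gap equal to the 1%
synchronization tolerance counts like a 36° phase offset.

```{r phase, eval = FALSE}
nodes <- lapply(1:3, function(i) oscillator_node(i, 10.2e3, 1e-9))
wf3 <- simulate_onn(onn_config(nodes, coupling = 100e-12,
                               pulse_duration = 300e-6,
                               init_mode = "random", seed = 1))
phase_pattern(wf3, window = c(240e-6, 300e-6))
autoplot(limit_cycle(wf3, transient_cut = 240e-6))
```

### Measurement details worth knowing

* `dominant_frequency()` applies a Hann window and zero-pads the FFT at
  least eightfold before taking the largest non-DC bin (with quadratic
  interpolation). Without the window, a fundamental falling mid-bin
  loses up to ~3.9 dB to scalloping and can rank *below* a harmonic
  that happens to sit near a bin centre -- strongly coupled relaxation
  waveforms triggered exactly that failure and made genuinely locked
  networks look unsynchronized.
* `detect_peaks()` defaults to a prominence threshold of half the
  peak-to-peak range. Strong coupling kicks notch the waveform by
  ~20% of its swing once per neighbour event; a lower threshold counts
  those notches as extra "periods".

## 3. From waveforms to decisions

The readout is a linear map trained by FORCE (recursive least squares)
from a delay-embedded feature vector to one output per class, with the
correct class driven to `+1` and the others to a class-balanced negative
target (`-1/(K-1)`, so the per-sample target vector sums to zero
regardless of the class count).

Plain instantaneous voltages cannot carry the phase code: every node
sweeps the same relaxation waveform, so per-channel time averages are
identical across stimulus classes. `waveform_features()` therefore adds
products of window-centred channels at several delays -- the window mean
of `x_i(t) x_j(t - k dt)` encodes the phase difference between channels
`i` and `j`, and the per-channel product at a *long* lag (several
periods) encodes the common frequency, making both linearly readable.

The decision stage (`run_dm()`) is a mean-field winner-take-all network:
each neuron has self-excitation, mutual inhibition, a thresholded
softplus activation, and slow synaptic dynamics
`tau_s ds/dt = -s + gamma (1 - s) r` that keep `s` in `[0, 1]` and
integrate the oscillating drive over many waveform cycles. Its constants
are package choices (the reference constants were not available) tuned
so that a 10% input margin yields a clean winner, exact ties stay
undecided by symmetry, and the steady state satisfies
`s* = gamma r / (1 + gamma r)`. The winner is judged on activity
averaged over a trailing `tau_s`, never on a single sample of the
oscillating drive.

```{r touch, eval = FALSE}
bundle <- run_touch_experiment(n_train_trials = 5, n_test_trials = 5, seed = 1)
bundle$sync                  # touch trials lock, no-touch trials do not
glance(bundle$evaluation)    # accuracy 1, all trials decided
autoplot(bundle$dm_example[["touch"]])
```

## 4. Device-to-device variation: what survives and what does not

`sample_devices()` draws per-device thresholds uniformly from measured
spread intervals; experiments accept a `device_variation` argument whose
optional `seed` pins *one* sampled physical network for the whole run.
At the strong-coupling operating point (330 pF tank, 100 pF coupler) a
three-node network sampled from the half-width threshold intervals
still locks, and the eight-mode experiment still classifies at least 7
of the 8 modes.

Two honest limitations, found during calibration and kept:

* Threshold-type mismatch is harsher than resistance-type mismatch. At
  100 pF coupling the model tolerates roughly 9% natural-frequency
  spread from threshold variation in a three-node network; half-width
  draws with larger spread (they occur for some sampling seeds) do not
  lock at any tank capacitance, which is why the variation experiments
  are defined over one pinned sampled network rather than an ensemble.
* Under pinned variation one marginal mode can sit at the locking edge:
  it passes the synchronization check while its phases still wander
  (those trials are dropped from pattern tables), and its held-out
  window can be misclassified -- that is the 8th mode the `>= 7/8`
  acceptance bound allows for.

## 5. Reproducing everything

All experiments are pure functions of their seeds. The command-line
interface (`system.file("cli", "oscsense.R", package = "oscsense")`)
exposes `simulate`, `analyze`, `gen-fixtures`, `train`, `classify`, and
`run` subcommands; `scripts/acceptance.R` recomputes the headline
numbers into a flat JSON file:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
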