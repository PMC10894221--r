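#' Detect spike peaks in one channel
#'
#' Finds local maxima with at least the given prominence (height of the
#' peak above the higher of the two valleys separating it from taller
#' terrain), then refines each peak time by parabolic interpolation of
#' the three samples around the maximum -- the peak-time convention used
#' to measure spiking time differences between channels.
#'
#' @param v Voltage samples.
#' @param time Matching time samples (uniform grid).
#' @param min_prominence Minimum prominence (V); default 50% of the
#'   channel's peak-to-peak range, so that only the firing peaks count:
#'   under strong capacitive coupling each neighbour firing leaves a
#'   kick notch on the rising edge (up to ~20% of the swing) that must
#'   not be mistaken for a spike of its own.
#' @return Tibble with `time` (refined peak times, s) and `value`.
#' @examples
#' t <- seq(0, 2e-4, by = 1e-7)
#' pk <- detect_peaks(sin(2 * pi * t / 22e-6), t)
#' diff(pk$time) # ~22 us
#' @export
detect_peaks <- function(v, time, min_prominence = NULL) {
  stopifnot(length(v) == length(time))
  if (length(v) < 3) osc_abort("no_peaks", "need at least 3 samples")
  rng <- range(v)
  if (is.null(min_prominence)) min_prominence <- 0.5 * diff(rng)
  if (min_prominence <= 0) osc_abort("no_peaks", "min_prominence must be > 0 (flat channel?)")
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  idx <- which(is_max)
  if (length(idx) > 0) {
    prom <- peak_prominences_cpp(v, idx)
    idx <- idx[prom >= min_prominence]
  }
  if (length(idx) < 2)
    osc_abort("no_peaks", "fewer than 2 peaks with the requested prominence")
  dt <- time[2] - time[1]
  refine <- vapply(idx, function(p) {
    den <- v[p - 1] - 2 * v[p] + v[p + 1]
    delta <- if (den == 0) 0 else 0.5 * (v[p - 1] - v[p + 1]) / den
    time[p] + max(-0.5, min(0.5, delta)) * dt
  }, numeric(1))
  tibble(time = refine, value = v[idx])
}

#' Dominant frequency of a channel (FFT)
#'
#' Frequency of the largest non-DC bin of the single-sided amplitude
#' spectrum, refined by quadratic interpolation across the adjacent bins.
#' The signal is Hann-windowed and zero-padded to at least 8x the record
#' length before the transform so that the largest-bin comparison is not
#' distorted by scalloping: with a bare rectangular window, a component
#' falling midway between bins loses up to ~36% of its magnitude to
#' leakage and a weaker harmonic sitting near a bin centre can
#' spuriously win. Warns when the record holds fewer than 8 periods of
#' the detected frequency.
#'
#' @inheritParams detect_peaks
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(v, time) {
  stopifnot(length(v) == length(time))
  n <- length(v)
  if (n < 4 || sd(v) == 0)
    osc_abort("degenerate_spectrum", "constant or too-short input has no dominant frequency")
  dt <- (time[n] - time[1]) / (n - 1)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  x <- (v - mean(v)) * hann
  nfft <- 2^ceiling(log2(8 * n))
  mag <- Mod(fft(c(x, numeric(nfft - n))))[seq_len(nfft %/% 2)]
  # ignore bins below one cycle per record length: DC leakage from the
  # window mainlobe, not an oscillation
  mag[seq_len(min(length(mag), ceiling(nfft / n) + 1))] <- 0
  k <- which.max(mag)
  if (k <= 1 || mag[k] == 0)
    osc_abort("degenerate_spectrum", "no non-DC spectral peak")
  delta <- 0
  if (k > 2 && k < length(mag)) {
    den <- mag[k - 1] - 2 * mag[k] + mag[k + 1]
    if (den != 0) delta <- max(-0.5, min(0.5, 0.5 * (mag[k - 1] - mag[k + 1]) / den))
  }
  f <- (k - 1 + delta) / (nfft * dt)
  if ((time[n] - time[1]) * f < 8)
    warn("fewer than 8 periods in the record; dominant_frequency may be imprecise")
  f
}

# default analysis window start: the larger of 20 us and 3 reference periods
default_transient_cut <- function(wf, ref_channel = NULL) {
  ch <- ref_channel %||% waveform_channels(wf)[1]
  f <- tryCatch(suppressWarnings(dominant_frequency(wf[[ch]], wf$time_s)),
                error = function(e) NA_real_)
  max(20e-6, if (is.finite(f)) 3 / f else 0)
}

# clip a waveform table to a time window
clip_window <- function(wf, window) {
  out <- wf[wf$time_s >= window[1] & wf$time_s <= window[2], , drop = FALSE]
  if (nrow(out) < 3) osc_abort("empty_window", "analysis window holds fewer than 3 samples")
  out
}

#' Are all channels locked to one frequency?
#'
#' Computes each channel's dominant frequency over the analysis window
#' (after the transient cut) and reports `TRUE` iff the maximum relative
#' deviation from the mean is below `rel_tol`.
#'
#' @param wf An `onn_waveforms` tibble (see [simulate_onn()]).
#' @param rel_tol Relative frequency tolerance (default 1%).
#' @param window Length-2 time window (s); default from the transient cut
#'   (the larger of 20 us and 3 reference periods) to the end of record.
#' @return Logical, with attribute `frequencies` (named per-channel Hz).
#' @export
is_synchronized <- function(wf, rel_tol = 0.01, window = NULL) {
  chans <- waveform_channels(wf)
  window <- window %||% c(default_transient_cut(wf), max(wf$time_s))
  w <- clip_window(wf, window)
  freqs <- vapply(chans, function(ch) suppressWarnings(dominant_frequency(w[[ch]], w$time_s)),
                  numeric(1))
  fbar <- mean(freqs)
  structure(max(abs(freqs - fbar)) / fbar < rel_tol, frequencies = freqs)
}

# circular helpers (angles in radians)
circ_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}
circ_median <- function(theta) {
  cost <- vapply(theta, function(a) sum(circ_dist(theta, a)), numeric(1))
  theta[which.min(cost)]
}
circ_sd <- function(theta) {
  r <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  sqrt(pmax(0, -2 * log(pmax(r, 1e-12))))
}

#' Phase-difference pattern of a synchronized waveform set
#'
#' The network's information code: per-channel phase offsets at the
#' common frequency, measured from spiking-time differences. The period
#' `T` is the median inter-peak interval of the reference channel; for
#' each channel the offsets `(t_peak_i - t_peak_ref) mod T` of matched
#' peak pairs are aggregated by a circular median (avoiding wrap bias at
#' 0/360) and reported in degrees in `[0, 360)` with the reference fixed
#' at 0.
#'
#' @inheritParams is_synchronized
#' @param ref_channel Reference channel name (default: first channel).
#' @param max_spread_deg Error if the circular spread (circular standard
#'   deviation) of per-period offsets exceeds this bound (degrees).
#' @param check_sync Verify [is_synchronized()] first (default `TRUE`).
#' @return A tibble of class `phase_pattern` with columns `channel` and
#'   `phase_deg`; attributes `common_frequency` (Hz), `ref_channel`, and
#'   `synchronized`.
#' @export
phase_pattern <- function(wf, ref_channel = NULL, rel_tol = 0.01,
                          window = NULL, max_spread_deg = 30,
                          check_sync = TRUE) {
  chans <- waveform_channels(wf)
  ref_channel <- ref_channel %||% chans[1]
  stopifnot(ref_channel %in% chans)
  window <- window %||% c(default_transient_cut(wf, ref_channel), max(wf$time_s))
  if (check_sync && !is_synchronized(wf, rel_tol, window))
    osc_abort("not_synchronized", "channels are not locked to a common frequency")
  w <- clip_window(wf, window)
  peaks <- lapply(chans, function(ch) detect_peaks(w[[ch]], w$time_s)$time)
  names(peaks) <- chans
  t_ref <- peaks[[ref_channel]]
  period <- median(diff(t_ref))
  phase_of <- function(ch) {
    if (ch == ref_channel) return(0)
    tp <- peaks[[ch]]
    dts <- vapply(t_ref, function(tr) {
      cand <- tp[which.min(abs(tp - tr))]
      (cand - tr) %% period
    }, numeric(1))
    theta <- 2 * pi * dts / period
    if (circ_sd(theta) * 180 / pi > max_spread_deg)
      osc_abort("unstable_phase",
                paste0("per-period offsets of ", ch, " spread beyond ",
                       max_spread_deg, " degrees"))
    (circ_median(theta) * 180 / pi) %% 360
  }
  out <- tibble(channel = chans,
                phase_deg = unname(vapply(chans, phase_of, numeric(1))))
  structure(out, common_frequency = 1 / period, ref_channel = ref_channel,
            synchronized = TRUE, class = c("phase_pattern", class(out)))
}

#' @export
print.phase_pattern <- function(x, ...) {
  cat(sprintf("<phase_pattern> f = %.4g kHz, ref = %s\n",
              attr(x, "common_frequency") / 1e3, attr(x, "ref_channel")))
  NextMethod()
}

#' Serialize / deserialize a phase pattern as JSON
#'
#' @param pattern A [phase_pattern()] tibble.
#' @param path Optional file path.
#' @return JSON string, or (for `phase_pattern_from_json`) the pattern.
#' @export
phase_pattern_to_json <- function(pattern, path = NULL) {
  x <- list(ref_channel = attr(pattern, "ref_channel"),
            common_frequency = attr(pattern, "common_frequency"),
            synchronized = attr(pattern, "synchronized"),
            channel = pattern$channel, phase_deg = pattern$phase_deg)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname phase_pattern_to_json
#' @param json JSON string or file path.
#' @export
phase_pattern_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  out <- tibble(channel = x$channel, phase_deg = x$phase_deg)
  structure(out, common_frequency = x$common_frequency,
            ref_channel = x$ref_channel, synchronized = x$synchronized,
            class = c("phase_pattern", class(out)))
}

#' Post-transient limit-cycle trajectory
#'
#' Returns the post-transient voltage tuples `(V_1, ..., V_N)` -- the
#' closed curve the synchronized network traces once per period in
#' voltage phase space. For three channels the three 2-D projections
#' (x-y, x-z, y-z) are available via [limit_cycle_projections()].
#'
#' @inheritParams is_synchronized
#' @param transient_cut Seconds to discard from the start.
#' @return Tibble of class `limit_cycle` (time plus channel columns).
#' @export
limit_cycle <- function(wf, transient_cut = NULL) {
  if (length(waveform_channels(wf)) < 2)
    osc_abort("invalid_params", "limit cycles need at least 2 channels")
  transient_cut <- transient_cut %||% default_transient_cut(wf)
  if (transient_cut >= max(wf$time_s))
    osc_abort("empty_window", "transient_cut exceeds the recorded span")
  out <- wf[wf$time_s > transient_cut, , drop = FALSE]
  structure(out, class = c("limit_cycle", setdiff(class(out), "onn_waveforms")))
}

#' Long-format 2-D projections of a limit cycle
#'
#' @param lc A [limit_cycle()] tibble.
#' @return Tibble with columns `plane` (e.g. `"node_1-node_2"`), `x`, `y`.
#' @export
limit_cycle_projections <- function(lc) {
  chans <- waveform_channels(lc)
  pairs <- utils::combn(chans, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    tibble(plane = paste(p, collapse = "-"), x = lc[[p[1]]], y = lc[[p[2]]])
  })
}

#' Read / write the waveform CSV dialect
#'
#' Wide CSV with header `time_s,node_<id>,...`, one row per recorded
#' sample.
#'
#' @param wf An `onn_waveforms` tibble.
#' @param path File path.
#' @return `write_waveforms` returns `path` invisibly; `read_waveforms`
#'   returns the waveform tibble.
#' @export
write_waveforms <- function(wf, path) {
  utils::write.csv(as.data.frame(wf)[, c("time_s", waveform_channels(wf))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  out <- as_tibble(utils::read.csv(path, check.names = FALSE))
  stopifnot("time_s" %in% names(out))
  structure(out, class = c("onn_waveforms", class(out)))
}
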