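#' Beat morphology parameters
#'
#' Sum-of-Gaussians model of one P-QRS-T heartbeat. Each wave is a Gaussian
#' bump with an amplitude (mV), a width (Gaussian sigma, ms) and a center
#' offset from the R peak (ms). `st_offset` adds a smooth plateau between
#' the end of the S wave and the onset of the T wave (the J-to-K span);
#' `t_sign` flips the T wave for T-inversion morphologies.
#'
#' Defaults give a normal sinus beat: P(0.15 mV, 20 ms, -180 ms),
#' Q(-0.10, 10, -25), R(1.0, 12, 0), S(-0.15, 10, +25), T(0.30, 25, +200),
#' i.e. a QT interval near 275 ms. The T wave is kept compact so that the
#' elevated ST-plus-T span of a pathological beat stays well under half of
#' the 600 ms median window used for baseline estimation; a broader, later
#' T would be partially treated as baseline and the injected ST offset
#' would not be recoverable downstream.
#'
#' @param p,q,r,s,t Length-3 numeric vectors `c(amplitude_mV, width_ms,
#'   center_ms)` per wave; centers are offsets from the R peak.
#' @param st_offset ST plateau level in mV (positive = elevation).
#' @param t_sign `+1` or `-1` multiplier on the T wave.
#' @return A `beat_morphology` object.
#' @export
beat_morphology <- function(p = c(0.15, 20, -180),
                            q = c(-0.10, 10, -25),
                            r = c(1.00, 12, 0),
                            s = c(-0.15, 10, 25),
                            t = c(0.30, 25, 200),
                            st_offset = 0, t_sign = 1) {
  waves <- list(p = p, q = q, r = r, s = s, t = t)
  for (w in names(waves)) {
    if (length(waves[[w]]) != 3L || !all(is.finite(waves[[w]])))
      stop("wave '", w, "' must be c(amplitude, width_ms, center_ms)")
    if (waves[[w]][2] <= 0) stop("wave widths must be positive")
  }
  if (r[1] <= 0) stop("R amplitude must be positive for a valid beat")
  if (!t_sign %in% c(-1, 1)) stop("t_sign must be +1 or -1")
  structure(c(waves, list(st_offset = st_offset, t_sign = t_sign)),
            class = "beat_morphology")
}

#' Class-specific morphology presets
#'
#' `NORMAL` is the [beat_morphology()] default; `ST_ELEVATION` adds a
#' +0.20 mV ST plateau, `ST_DEPRESSION` a -0.20 mV plateau, and
#' `T_INVERSION` flips the T wave (`t_sign = -1`).
#'
#' @param label One of [ecg_classes()].
#' @return A `beat_morphology`.
#' @export
morphology_for_class <- function(label) {
  switch(label,
    NORMAL = beat_morphology(),
    ST_ELEVATION = beat_morphology(st_offset = 0.20),
    ST_DEPRESSION = beat_morphology(st_offset = -0.20),
    T_INVERSION = beat_morphology(t_sign = -1),
    stop("invalid class label: ", label)
  )
}

#' Wearable noise model configuration
#'
#' @param baseline_amp,baseline_freq Baseline-wander sinusoid amplitude (mV)
#'   and frequency (Hz), emulating respiration drift.
#' @param powerline_amp 50 Hz mains interference amplitude (mV).
#' @param emg_sigma Broadband (white) EMG-like noise standard deviation (mV).
#' @param motion_rate Motion-artifact events per minute.
#' @param motion_amp Motion-artifact peak amplitude (mV).
#' @param seed RNG seed making generation reproducible.
#' @return A `noise_config` object.
#' @export
noise_config <- function(baseline_amp = 0.1, baseline_freq = 0.3,
                         powerline_amp = 0.02, emg_sigma = 0.01,
                         motion_rate = 0, motion_amp = 0, seed = 1L) {
  vals <- c(baseline_amp, powerline_amp, emg_sigma, motion_rate, motion_amp)
  if (any(vals < 0)) stop("noise amplitudes and rates must be >= 0")
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 powerline_amp = powerline_amp, emg_sigma = emg_sigma,
                 motion_rate = motion_rate, motion_amp = motion_amp,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Noise presets
#'
#' `"none"` disables every noise source; `"wearable"` is the default
#' chest-belt level (0.1 mV baseline wander at 0.3 Hz, 0.02 mV mains,
#' 0.01 mV EMG); `"motion"` adds large motion artifacts (2 mV, 6/min)
#' on top of the wearable level.
#'
#' @param preset `"none"`, `"wearable"` or `"motion"`.
#' @param seed RNG seed.
#' @return A [noise_config()].
#' @export
noise_preset <- function(preset = c("wearable", "none", "motion"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    none = noise_config(0, 0.3, 0, 0, 0, 0, seed = seed),
    wearable = noise_config(seed = seed),
    motion = noise_config(motion_rate = 6, motion_amp = 2.0, seed = seed)
  )
}

#' ADC model configuration
#'
#' Emulates the wearable front-end converter: 10-bit resolution at a 3.0 V
#' reference gives the device's 2.93 mV quantization step. `gain` is the
#' analog front-end amplification applied to the mV-scale ECG before
#' conversion (single-supply, mid-rail biased).
#'
#' @param bits ADC resolution in bits (>= 1).
#' @param vref Reference voltage in volts (> 0).
#' @param fs Converter sampling rate in Hz.
#' @param gain Front-end voltage gain (V/V).
#' @return An `adc_config` object.
#' @export
adc_config <- function(bits = 10L, vref = 3.0, fs = 500, gain = 100) {
  if (bits < 1) stop("bits must be >= 1")
  if (vref <= 0) stop("vref must be positive")
  structure(list(bits = as.integer(bits), vref = vref, fs = fs, gain = gain),
            class = "adc_config")
}

#' ADC quantization step in volts
#' @param adc An [adc_config()].
#' @return Step size `vref / 2^bits` in volts.
#' @export
adc_step <- function(adc) adc$vref / 2^adc$bits

#' Quantize a voltage sequence
#'
#' `code = floor(v / step)` clipped to `[0, 2^bits - 1]`. Inputs are
#' expected in `[0, vref]` after mid-rail offset mapping of bipolar
#' signals; out-of-range values clip (that is the contract, not an error).
#'
#' @param volts Numeric vector of voltages.
#' @param adc An [adc_config()].
#' @return Integer ADC codes.
#' @export
quantize_adc <- function(volts, adc = adc_config()) {
  step <- adc_step(adc)
  code <- floor(volts / step)
  pmax(0, pmin(2^adc$bits - 1, code))
}

#' Reconstruct voltages from ADC codes (mid-step)
#' @param codes Integer codes from [quantize_adc()].
#' @param adc An [adc_config()].
#' @return Voltages in volts.
#' @export
dequantize_adc <- function(codes, adc = adc_config()) {
  (codes + 0.5) * adc_step(adc)
}

# Pass an mV signal through the emulated front end: amplify, bias to
# mid-rail, quantize, reconstruct, and refer back to input mV.
adc_roundtrip_mv <- function(x_mv, adc) {
  v <- adc$vref / 2 + adc$gain * x_mv / 1000
  codes <- quantize_adc(v, adc)
  (dequantize_adc(codes, adc) - adc$vref / 2) / adc$gain * 1000
}

#' Power budget of the wearable subsystem
#'
#' @param capacity_mAh Battery capacity in mAh.
#' @param load_mA Continuous load current in mA.
#' @param derating Unitless derating factor in (0, 1] accounting for
#'   external factors that shorten battery life (default 0.70).
#' @return A `power_budget` object.
#' @export
power_budget <- function(capacity_mAh, load_mA, derating = 0.70) {
  if (capacity_mAh < 0 || load_mA < 0) stop("capacity and load must be >= 0")
  if (derating <= 0 || derating > 1) stop("derating must be in (0, 1]")
  structure(list(capacity_mAh = capacity_mAh, load_mA = load_mA,
                 derating = derating), class = "power_budget")
}

#' Battery life in hours
#'
#' `capacity / load * derating`; a 1000 mAh battery at a 9.3 mA continuous
#' draw with the default 0.70 derating runs for about 75 h.
#'
#' @param budget A [power_budget()].
#' @return Hours of operation.
#' @export
battery_life <- function(budget) {
  if (budget$load_mA <= 0) stop("load current must be positive")
  budget$capacity_mAh / budget$load_mA * budget$derating
}

#' Battery capacity required for a target runtime
#'
#' Inverse of [battery_life()]: `hours * load / derating`.
#'
#' @param hours Target runtime in hours.
#' @param load_mA Continuous load current in mA.
#' @param derating Derating factor in (0, 1].
#' @return Required capacity in mAh.
#' @export
required_capacity <- function(hours, load_mA, derating = 0.70) {
  if (derating <= 0) stop("derating must be positive")
  hours * load_mA / derating
}

#' Generate one synthetic heartbeat
#'
#' Renders one beat of `round(rr_ms * fs / 1000)` samples from a
#' [beat_morphology()]: each wave is a Gaussian bump at its offset from the
#' R center, the ST plateau (if any) is added between the S end and T onset
#' with raised-cosine ramps, and the T wave is multiplied by `t_sign`. The
#' R center is placed at 45% of the beat so the P wave and T tail both fit
#' at normal heart rates.
#'
#' @param morph A [beat_morphology()].
#' @param fs Sampling rate in Hz.
#' @param rr_ms Beat (RR interval) duration in ms.
#' @return List with `samples` (mV) and `r_center` (0-based index of the
#'   R peak sample within the beat).
#' @export
generate_beat <- function(morph = beat_morphology(), fs = 500, rr_ms = 1000) {
  if (fs <= 0 || rr_ms <= 0) stop("fs and rr_ms must be positive")
  n <- as.integer(round(rr_ms * fs / 1000))
  r_center <- as.integer(round(0.45 * n))
  t_ms <- ((seq_len(n) - 1) - r_center) * 1000 / fs  # ms relative to R
  gauss <- function(w) w[1] * exp(-0.5 * ((t_ms - w[3]) / w[2])^2)
  x <- gauss(morph$p) + gauss(morph$q) + gauss(morph$r) + gauss(morph$s) +
    morph$t_sign * gauss(morph$t)
  if (morph$st_offset != 0) {
    s_end <- morph$s[3] + 2 * morph$s[2]
    t_onset <- morph$t[3] - 2 * morph$t[2]
    ramp <- 20  # ms raised-cosine edges
    u <- rep(0, n)
    u[t_ms >= s_end & t_ms <= t_onset] <- 1
    lead <- t_ms >= s_end - ramp & t_ms < s_end
    u[lead] <- 0.5 * (1 + cos(pi * (s_end - t_ms[lead]) / ramp))
    trail <- t_ms > t_onset & t_ms <= t_onset + ramp
    u[trail] <- 0.5 * (1 + cos(pi * (t_ms[trail] - t_onset) / ramp))
    x <- x + morph$st_offset * u
  }
  list(samples = x, r_center = r_center)
}

# Motion-artifact event: a sustained shaking burst — a low-frequency
# oscillation under a raised-cosine envelope centered at `center`
# (samples). Electrode motion during driving corrupts the trace for
# seconds at a time, not as an isolated spike.
motion_bump <- function(n, center, width_samples, amp, freq_hz = 3, fs = 500) {
  i <- seq_len(n) - 1
  u <- (i - center) / (width_samples / 2)
  b <- rep(0, n)
  sel <- abs(u) <= 1
  env <- 0.5 * (1 + cos(pi * u[sel]))
  b[sel] <- amp * env * cos(2 * pi * freq_hz * (i[sel] - center) / fs)
  b
}

#' Generate a synthetic annotated ECG record
#'
#' Concatenates `n_beats` beats of the class morphology with RR jitter,
#' adds the configured noise components (baseline wander, 50 Hz mains,
#' broadband EMG, raised-cosine motion artifacts), optionally passes the
#' signal through the emulated ADC front end, and annotates every R center
#' with the class label. Identical seeds give bitwise-identical records.
#'
#' @param label One of [ecg_classes()].
#' @param n_beats Number of beats (>= 1).
#' @param fs Sampling rate in Hz.
#' @param morph Beat morphology; default [morphology_for_class()] of `label`.
#' @param noise A [noise_config()]; default the `"wearable"` preset.
#' @param adc `NULL` (no quantization) or an [adc_config()].
#' @param mean_bpm Mean heart rate in beats per minute.
#' @param rr_jitter Standard deviation of the per-beat RR interval in ms.
#' @param record_id Record/subject identifier.
#' @return An [ecg_record()] with reference annotations at R centers.
#' @export
generate_record <- function(label = "NORMAL", n_beats = 10L, fs = 500,
                            morph = NULL, noise = noise_preset("wearable"),
                            adc = NULL, mean_bpm = 60, rr_jitter = 0,
                            record_id = NULL) {
  if (!label %in% ECG_CLASSES) stop("invalid class label: ", label)
  if (n_beats < 1L) stop("n_beats must be >= 1")
  if (is.null(morph)) morph <- morphology_for_class(label)
  if (is.null(record_id)) record_id <- paste0("synth_", tolower(label))
  mean_rr <- 60000 / mean_bpm
  with_seed(noise$seed, {
    rr <- rep(mean_rr, n_beats) +
      if (rr_jitter > 0) rnorm(n_beats, 0, rr_jitter) else 0
    rr <- pmax(0.5 * mean_rr, rr)
    beats <- lapply(rr, function(r) generate_beat(morph, fs, r))
    samples <- unlist(lapply(beats, `[[`, "samples"))
    offsets <- cumsum(c(0L, vapply(head(beats, -1L),
                                   function(b) length(b$samples), 1L)))
    r_idx <- offsets + vapply(beats, `[[`, 1L, "r_center")
    n <- length(samples)
    tt <- (seq_len(n) - 1) / fs
    if (noise$baseline_amp > 0)
      samples <- samples + noise$baseline_amp *
        sin(2 * pi * noise$baseline_freq * tt + runif(1, 0, 2 * pi))
    if (noise$powerline_amp > 0)
      samples <- samples + noise$powerline_amp *
        sin(2 * pi * 50 * tt + runif(1, 0, 2 * pi))
    if (noise$emg_sigma > 0)
      samples <- samples + rnorm(n, 0, noise$emg_sigma)
    if (noise$motion_rate > 0 && noise$motion_amp > 0) {
      n_events <- rpois(1, noise$motion_rate * n / fs / 60)
      if (n_events > 0) {
        centers <- runif(n_events, 0, n - 1)
        for (ce in centers)
          samples <- samples + motion_bump(
            n, ce, ms_to_samples(3000, fs),
            noise$motion_amp * sample(c(-1, 1), 1),
            freq_hz = runif(1, 2, 5), fs = fs
          )
      }
    }
    if (!is.null(adc)) samples <- adc_roundtrip_mv(samples, adc)
    ann <- data.frame(sample_index = as.integer(r_idx), label = label,
                      source = "reference", stringsAsFactors = FALSE)
    ecg_record(samples, fs = fs, record_id = record_id, annotations = ann)
  })
}
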