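#' Preprocessing configuration
#'
#' @param ma_window_ms Moving-average (FIR smoothing) window in ms.
#' @param median1_ms First running-median width in ms (removes QRS and P).
#' @param median2_ms Second running-median width in ms (removes T); must
#'   exceed `median1_ms`.
#' @param notch_freq_hz Mains notch center frequency in Hz.
#' @param notch_q Notch quality factor (center / -3 dB bandwidth).
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(ma_window_ms = 20, median1_ms = 200,
                              median2_ms = 600, notch_freq_hz = 50,
                              notch_q = 30) {
  if (ma_window_ms <= 0 || median1_ms <= 0) stop("windows must be positive")
  if (median2_ms <= median1_ms) stop("median2_ms must exceed median1_ms")
  structure(list(ma_window_ms = ma_window_ms, median1_ms = median1_ms,
                 median2_ms = median2_ms, notch_freq_hz = notch_freq_hz,
                 notch_q = notch_q), class = "preprocess_config")
}

#' Centered moving average
#'
#' Length-preserving centered moving mean with reflect padding at the
#' edges. Even window lengths are rounded up to the next odd value so the
#' window has a center sample.
#'
#' @param samples Numeric vector.
#' @param window_len Window length in samples (>= 1).
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(samples, window_len) {
  if (window_len < 1) stop("window_len must be >= 1")
  w <- odd_window(window_len)
  if (w == 1L || length(samples) == 1L) return(samples)
  k <- (w - 1L) %/% 2L
  xp <- reflect_pad(samples, k)
  cs <- cumsum(c(0, xp))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' Estimate the baseline wander of an ECG
#'
#' Cascade of two running medians: a 200 ms window that flattens QRS
#' complexes and P waves, followed by a 600 ms window that flattens T
#' waves. What survives is the slow baseline drift. Widths are rounded to
#' the nearest odd sample count; edges are reflect-padded.
#'
#' @param samples Numeric vector (mV).
#' @param fs Sampling rate in Hz.
#' @param cfg A [preprocess_config()].
#' @return Baseline estimate, same length as the input.
#' @export
estimate_baseline <- function(samples, fs, cfg = preprocess_config()) {
  w1 <- odd_window(cfg$median1_ms * fs / 1000)
  w2 <- odd_window(cfg$median2_ms * fs / 1000)
  if (length(samples) <= w2) stop("record too short for baseline estimation")
  k <- (w2 - 1L) %/% 2L
  xp <- reflect_pad(samples, k)
  b <- runmed(runmed(xp, w1, endrule = "median"), w2, endrule = "median")
  as.numeric(b[(k + 1):(k + length(samples))])
}

#' Smooth and baseline-correct an ECG
#'
#' Applies the FIR moving-average smoother, then subtracts the
#' median-cascade baseline estimate, centering the isoelectric line at
#' zero. Invariant to additive constants.
#'
#' @inheritParams estimate_baseline
#' @return Corrected signal, same length as the input.
#' @export
correct_baseline <- function(samples, fs, cfg = preprocess_config()) {
  sm <- moving_average(samples, ms_to_samples(cfg$ma_window_ms, fs))
  sm - estimate_baseline(sm, fs, cfg)
}

# RBJ biquad notch coefficients, normalized to a0 = 1.
notch_coefficients <- function(freq, fs, q) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Digital mains notch filter
#'
#' Second-order IIR notch at the mains frequency (default 50 Hz), applied
#' forward and backward (`signal::filtfilt`) for zero phase distortion.
#' Attenuates the mains tone by more than 20 dB while leaving the
#' diagnostic band (<= 40 Hz) essentially untouched.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz (must exceed twice the notch frequency).
#' @param cfg A [preprocess_config()].
#' @return Filtered vector, same length.
#' @export
notch_50hz <- function(samples, fs, cfg = preprocess_config()) {
  if (fs <= 2 * cfg$notch_freq_hz)
    stop("sampling rate too low for the notch frequency")
  co <- notch_coefficients(cfg$notch_freq_hz, fs, cfg$notch_q)
  as.numeric(signal::filtfilt(co$b, co$a, samples))
}

#' Optional diagnostic band-pass
#'
#' Zero-phase Butterworth band-pass with the wearable front-end corners
#' (0.48-41 Hz), for raw synthetic input that has not passed through the
#' analog chain.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param low,high Corner frequencies in Hz.
#' @return Filtered vector, same length.
#' @export
bandpass_ecg <- function(samples, fs, low = 0.48, high = 41) {
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, samples))
}

#' Run the full preprocessing chain on a record
#'
#' Mains notch, FIR smoothing, then baseline-wander subtraction; returns a
#' record whose isoelectric segments sit at zero mV.
#'
#' @param record An [ecg_record()].
#' @param cfg A [preprocess_config()].
#' @return The preprocessed [ecg_record()].
#' @export
preprocess_record <- function(record, cfg = preprocess_config()) {
  x <- notch_50hz(record$samples, record$fs, cfg)
  x <- correct_baseline(x, record$fs, cfg)
  ecg_record(x, fs = record$fs, record_id = record$record_id,
             lead_label = record$lead_label, annotations = record$annotations)
}
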