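#' Linear classifier thresholds
#'
#' ST-deviation thresholds default to 0.10 mV — the clinical 1 mm criterion
#' at standard 10 mm/mV calibration — and the T-inversion threshold to
#' 0.05 mV below the isoelectric line.
#'
#' @param st_elev_mV ST-elevation threshold (mV, > 0).
#' @param st_depr_mV ST-depression threshold (mV, > 0).
#' @param t_inv_mV T-inversion threshold (mV, > 0).
#' @return A `linear_thresholds` object.
#' @export
linear_thresholds <- function(st_elev_mV = 0.10, st_depr_mV = 0.10,
                              t_inv_mV = 0.05) {
  if (any(c(st_elev_mV, st_depr_mV, t_inv_mV) <= 0))
    stop("thresholds must be positive")
  structure(list(st_elev_mV = st_elev_mV, st_depr_mV = st_depr_mV,
                 t_inv_mV = t_inv_mV), class = "linear_thresholds")
}

#' Sliding-window configuration for streaming classification
#'
#' @param window_s Window length in seconds (default 10).
#' @return A `stream_config` object.
#' @export
stream_config <- function(window_s = 10) {
  if (window_s <= 0) stop("window_s must be positive")
  structure(list(window_s = window_s), class = "stream_config")
}

#' Isoelectric, ST and T levels for one beat
#'
#' The isoelectric (ISO) level is the median over the 20 ms PR segment
#' ending at the I point (the HI line); the ST level is the mean over the
#' ST span starting at J — clinically, the first `st_window_ms` after the
#' J point, clipped at K, which by construction ends before the T-peak
#' search region; the T amplitude is the signal at the T peak minus the
#' ISO level. The ST deviation is `st - iso`. With fiducials held fixed,
#' all three are invariant to additive constants.
#'
#' @param samples Baseline-corrected signal in mV.
#' @param fs Sampling rate in Hz.
#' @param fid One row of a [locate_fiducials()] result (needs I, J, K, T).
#' @param st_window_ms ST-measurement span after J in ms (default 80, the
#'   T-search onset margin).
#' @return List with `iso`, `st`, `st_deviation`, `t_amplitude` (all mV).
#' @export
iso_st_levels <- function(samples, fs, fid, st_window_ms = 80) {
  need <- c("I", "J", "K", "T")
  vals <- unlist(fid[need])
  if (any(is.na(vals))) stop("required fiducials (I, J, K, T) absent")
  i1 <- fid$I + 1L; j1 <- fid$J + 1L; k1 <- fid$K + 1L; t1 <- fid$T + 1L
  pr_lo <- max(1L, i1 - ms_to_samples(20, fs))
  iso <- median(samples[pr_lo:i1])
  st_hi <- min(k1, j1 + ms_to_samples(st_window_ms, fs))
  st <- mean(samples[j1:st_hi])
  list(iso = iso, st = st, st_deviation = st - iso,
       t_amplitude = samples[t1] - iso)
}

#' Classify one beat from its ISO/ST/T levels
#'
#' ST states take precedence over the T state: ST elevation if the ST
#' deviation exceeds the elevation threshold, ST depression if it falls
#' below minus the depression threshold, then T inversion if the T
#' amplitude is below minus the T threshold, otherwise normal.
#'
#' @param levels Result of [iso_st_levels()].
#' @param thr A [linear_thresholds()].
#' @return One of [ecg_classes()].
#' @export
classify_beat_linear <- function(levels, thr = linear_thresholds()) {
  dev <- levels$st_deviation
  if (!is.finite(dev) || !is.finite(levels$t_amplitude))
    stop("levels must be finite")
  if (dev > thr$st_elev_mV) return("ST_ELEVATION")
  if (dev < -thr$st_depr_mV) return("ST_DEPRESSION")
  if (levels$t_amplitude < -thr$t_inv_mV) return("T_INVERSION")
  "NORMAL"
}

# Majority label with severity tie-break.
majority_label <- function(labels) {
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  winners[which.max(CLASS_SEVERITY[winners])]
}

#' Linear classification over sliding windows
#'
#' Runs the full linear pipeline on a record: preprocessing, wavelet R-peak
#' detection, fiducial delineation, per-beat ISO/ST comparison, then a
#' decision per 10 s sliding window. Consecutive windows advance by one
#' mean interbeat interval, so successive beat-aligned windows overlap by
#' about half an interval. Each window's label is the majority over the
#' complete beats it contains, ties resolved toward the more severe label.
#'
#' @param record An [ecg_record()] (raw; preprocessing is applied here).
#' @param cfg A [stream_config()].
#' @param thr A [linear_thresholds()].
#' @param dcfg A [delineation_config()].
#' @param pcfg A [preprocess_config()].
#' @return A `linear_decisions` data frame with one row per window:
#'   `start_s`, `end_s`, `iso_level`, `st_level`, `st_deviation`,
#'   `t_amplitude` (window means), `label`, `n_beats`.
#' @export
classify_stream_linear <- function(record, cfg = stream_config(),
                                   thr = linear_thresholds(),
                                   dcfg = delineation_config(),
                                   pcfg = preprocess_config()) {
  dur <- record_duration(record)
  if (dur < cfg$window_s)
    stop("record shorter than one analysis window")
  pre <- preprocess_record(record, pcfg)
  x <- pre$samples
  fs <- pre$fs
  r <- detect_r_peaks(x, fs, dcfg)
  if (length(r) < 2L) stop("no beats detected")
  fid <- locate_fiducials(x, fs, r, dcfg)
  beats <- fid[fid$complete, , drop = FALSE]
  beat_info <- lapply(seq_len(nrow(beats)), function(i) {
    lv <- iso_st_levels(x, fs, beats[i, ])
    c(lv, list(label = classify_beat_linear(lv, thr),
               t_s = beats$R[i] / fs))
  })
  advance <- mean(diff(r)) / fs
  starts <- seq(0, dur - cfg$window_s, by = advance)
  rows <- lapply(starts, function(s0) {
    inw <- Filter(function(b) b$t_s >= s0 & b$t_s < s0 + cfg$window_s,
                  beat_info)
    if (!length(inw)) {
      return(data.frame(start_s = s0, end_s = s0 + cfg$window_s,
                        iso_level = NA_real_, st_level = NA_real_,
                        st_deviation = NA_real_, t_amplitude = NA_real_,
                        label = NA_character_, n_beats = 0L,
                        stringsAsFactors = FALSE))
    }
    data.frame(
      start_s = s0, end_s = s0 + cfg$window_s,
      iso_level = mean(vapply(inw, `[[`, 0, "iso")),
      st_level = mean(vapply(inw, `[[`, 0, "st")),
      st_deviation = mean(vapply(inw, `[[`, 0, "st_deviation")),
      t_amplitude = mean(vapply(inw, `[[`, 0, "t_amplitude")),
      label = majority_label(vapply(inw, `[[`, "", "label")),
      n_beats = length(inw), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("linear_decisions", "data.frame")
  out
}
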