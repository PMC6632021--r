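#' Delineation configuration
#'
#' Timing windows follow standard single-lead delineation practice: the QRS
#' complex spans about 60 ms, Q and S fall within 32 ms of the R peak, the
#' T peak lies between 80 ms after the J point and 400 ms after R, and the
#' K point (ST end) sits 35 ms after the T peak; H and I mirror K and J on
#' the other side of the QRS.
#'
#' @param wavelet_scale Dyadic analysis level (scale `2^level`), default 4.
#' @param r_threshold R-peak detection threshold as a fraction of the
#'   maximum wavelet-coefficient magnitude per analysis window, in (0, 1).
#' @param qrs_ms Nominal QRS duration (ms).
#' @param qs_window_ms Search window for Q and S around R (ms).
#' @param t_from_r_ms Latest T-peak position after R (ms).
#' @param t_after_j_ms Earliest T-peak position after J (ms).
#' @param k_from_t_ms K-point offset after the T peak (ms).
#' @param refractory_ms Minimum separation between detected R peaks (ms).
#' @param zero_band_mV Dead band around zero for the J/I zero-crossing
#'   search on the baseline-corrected signal.
#' @param window_s Analysis-window length (s) used to normalize the
#'   detection threshold.
#' @return A `delineation_config` object.
#' @export
delineation_config <- function(wavelet_scale = 4L, r_threshold = 0.6,
                               qrs_ms = 60, qs_window_ms = 32,
                               t_from_r_ms = 400, t_after_j_ms = 80,
                               k_from_t_ms = 35, refractory_ms = 200,
                               zero_band_mV = 0.02, window_s = 10) {
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("r_threshold must be in (0, 1)")
  if (any(c(qrs_ms, qs_window_ms, t_from_r_ms, t_after_j_ms, k_from_t_ms,
            refractory_ms) <= 0))
    stop("all timing windows must be positive")
  structure(list(wavelet_scale = as.integer(wavelet_scale),
                 r_threshold = r_threshold, qrs_ms = qrs_ms,
                 qs_window_ms = qs_window_ms, t_from_r_ms = t_from_r_ms,
                 t_after_j_ms = t_after_j_ms, k_from_t_ms = k_from_t_ms,
                 refractory_ms = refractory_ms, zero_band_mV = zero_band_mV,
                 window_s = window_s),
            class = "delineation_config")
}

# Quadratic-spline filter pair for the a-trous (undecimated) dyadic
# wavelet transform; the wavelet acts as a smoothed derivative, so a QRS
# maps to a positive/negative coefficient pair straddling the R peak.
DWT_LOWPASS <- c(1, 3, 3, 1) / 8
DWT_HIGHPASS <- c(2, -2)

# Convolve with a filter upsampled by `hole` (zeros inserted), full
# convolution; returns the full-length result. Direct convolution — the
# filters are a handful of taps, so this beats FFT convolution at
# arbitrary (badly factorizable) signal lengths.
atrous_conv <- function(x, filt, hole) {
  f <- rep(0, (length(filt) - 1L) * hole + 1L)
  f[seq(1L, length(f), by = hole)] <- filt
  nf <- length(f)
  xx <- c(rep(0, nf - 1L), x, rep(0, nf - 1L))
  y <- stats::filter(xx, f, method = "convolution", sides = 1L)
  as.numeric(y[nf:(nf + length(x) + nf - 2L)])
}

#' Undecimated dyadic wavelet transform at one scale
#'
#' A-trous implementation with the quadratic-spline filter pair standard in
#' ECG delineation. Returns the coefficients at scale `2^level`, aligned
#' with the input (group delay compensated) and of the same length; edges
#' are reflect-padded. The transform is linear in the input.
#'
#' @param samples Numeric vector.
#' @param level Dyadic level (>= 1); scale is `2^level`.
#' @return Coefficient vector, same length as `samples`.
#' @export
dyadic_wt <- function(samples, level = 4L) {
  if (level < 1L) stop("level must be >= 1")
  n <- length(samples)
  pad <- 2L^(level + 2L)
  if (n < 2L) stop("record too short for the wavelet transform")
  x <- reflect_pad(samples, min(pad, n - 1L))
  padk <- min(pad, n - 1L)
  delay <- 0
  a <- x
  for (k in seq_len(level)) {
    hole <- 2L^(k - 1L)
    if (k < level) {
      a <- atrous_conv(a, DWT_LOWPASS, hole)
      delay <- delay + 1.5 * hole
    } else {
      a <- atrous_conv(a, DWT_HIGHPASS, hole)
      delay <- delay + 0.5 * hole
    }
  }
  # trim pads and compensate cumulative group delay
  start <- padk + 1L + as.integer(round(delay))
  out <- a[start:(start + n - 1L)]
  out[!is.finite(out)] <- 0
  out
}

# Strict local maxima of a vector (interior points).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect R peaks with the dyadic wavelet transform
#'
#' Tompkins-style detection on the scale-`2^level` coefficient magnitudes:
#' within each analysis window the threshold is `r_threshold` times the
#' window's maximum magnitude (making detection invariant to amplitude
#' scaling), candidate local maxima are accepted strongest-first subject to
#' the refractory separation, and each accepted candidate is refined to the
#' raw-signal local maximum within half a QRS duration.
#'
#' @param samples Preprocessed (baseline-corrected) signal in mV.
#' @param fs Sampling rate in Hz.
#' @param cfg A [delineation_config()].
#' @return Ordered integer vector of R-peak sample indices (0-based).
#' @export
detect_r_peaks <- function(samples, fs, cfg = delineation_config()) {
  if (length(samples) == 0L) stop("empty input")
  w <- abs(dyadic_wt(samples, cfg$wavelet_scale))
  n <- length(samples)
  win <- max(1L, as.integer(round(cfg$window_s * fs)))
  refr <- ms_to_samples(cfg$refractory_ms, fs)
  half_qrs <- ms_to_samples(cfg$qrs_ms / 2, fs)
  cand <- local_maxima(w)
  if (!length(cand)) return(integer(0))
  # per-window relative threshold
  win_id <- (cand - 1L) %/% win
  wmax <- vapply(split(seq_along(cand), win_id), function(ii) {
    lo <- (win_id[ii[1]]) * win + 1L
    hi <- min(n, lo + win - 1L)
    max(w[lo:hi])
  }, numeric(1))
  thr <- cfg$r_threshold * wmax[as.character(win_id)]
  cand <- cand[w[cand] >= thr & w[cand] > 0]
  if (!length(cand)) return(integer(0))
  # strongest-first acceptance with refractory separation
  cand <- cand[order(w[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (ci in cand) {
    if (!length(accepted) || all(abs(accepted - ci) >= refr))
      accepted <- c(accepted, ci)
  }
  accepted <- sort(accepted)
  # refine to the raw-signal local maximum near each candidate
  refined <- vapply(accepted, function(ci) {
    lo <- max(1L, ci - half_qrs)
    hi <- min(n, ci + half_qrs)
    lo + which.max(samples[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # merge refinements that collapsed onto nearby maxima
  if (length(refined) > 1L) {
    keep <- c(TRUE, diff(refined) >= refr)
    refined <- refined[keep]
  }
  as.integer(refined - 1L)  # 0-based
}

# First index (1-based) after `from` where the signal re-enters the zero
# dead band, searching up to `limit`; NA if never.
zero_cross_forward <- function(x, from, limit, band) {
  if (from >= limit) return(NA_integer_)
  idx <- (from + 1L):limit
  hit <- which(x[idx] >= -band)
  if (!length(hit)) NA_integer_ else idx[hit[1]]
}

zero_cross_backward <- function(x, from, limit, band) {
  if (from <= limit) return(NA_integer_)
  idx <- (from - 1L):limit
  hit <- which(x[idx] >= -band)
  if (!length(hit)) NA_integer_ else idx[hit[1]]
}

# First index after `from` where the local slope magnitude falls below
# `thr` mV/s — the QRS-end flattening. Needed when the ST level is shifted
# (depression/elevation) and the signal never re-enters the zero band.
flat_forward <- function(x, from, limit, fs, thr = 2) {
  k <- max(2L, as.integer(round(0.01 * fs)))
  hi <- min(limit, length(x) - k)
  if (from + 1L > hi) return(NA_integer_)
  for (i in (from + 1L):hi) {
    if (abs((x[i + k] - x[i]) * fs / k) < thr) return(i)
  }
  NA_integer_
}

flat_backward <- function(x, from, limit, fs, thr = 2) {
  k <- max(2L, as.integer(round(0.01 * fs)))
  lo <- max(limit, k + 1L)
  if (from - 1L < lo) return(NA_integer_)
  for (i in (from - 1L):lo) {
    if (abs((x[i] - x[i - k]) * fs / k) < thr) return(i)
  }
  NA_integer_
}

#' Locate fiducial points for each beat
#'
#' Starting from each R peak: Q is the minimum within 32 ms before R and S
#' the minimum within 32 ms after; J is the first point after S returning
#' to the zero level (corrected baseline, with a small dead band), and the
#' T peak is the largest absolute excursion (so an inverted T is found at
#' its trough) between 80 ms after J and 400 ms after R, with K
#' 35 ms after T. The pre-QRS side is treated symmetrically: I is the first
#' point before Q back at the zero level, P the maximum between 400 ms
#' before R and 80 ms before I, and H sits 35 ms before P. Points whose
#' search windows fall outside the record are reported absent (`NA`) and
#' the beat is flagged incomplete.
#'
#' @param samples Baseline-corrected signal in mV.
#' @param fs Sampling rate in Hz.
#' @param r_indices 0-based R-peak indices from [detect_r_peaks()].
#' @param cfg A [delineation_config()].
#' @return A `fiducial_set` data frame with 0-based index columns
#'   `H, P, I, Q, R, S, J, T, K` and a logical `complete` column, one row
#'   per beat.
#' @export
locate_fiducials <- function(samples, fs, r_indices,
                             cfg = delineation_config()) {
  n <- length(samples)
  ms <- function(v) ms_to_samples(v, fs)
  qs_w <- ms(cfg$qs_window_ms)
  rows <- lapply(r_indices, function(r0) {
    r <- r0 + 1L  # 1-based
    Q <- S <- J <- I <- T_ <- K <- P <- H <- NA_integer_
    if (r - qs_w >= 1L)
      Q <- (r - qs_w) + which.min(samples[(r - qs_w):(r - 1L)]) - 1L
    if (r + qs_w <= n)
      S <- r + which.min(samples[(r + 1L):(r + qs_w)])
    if (!is.na(S)) {
      # the ST level itself may be shifted (elevation/depression), so the
      # QRS-end flattening marks J; the zero-crossing from the negative S
      # is the fallback
      J <- flat_forward(samples, S, min(n, S + ms(160)), fs)
      if (is.na(J))
        J <- zero_cross_forward(samples, S, min(n, S + ms(160)),
                                cfg$zero_band_mV)
    }
    if (!is.na(Q)) {
      # the PR side sits at the true isoelectric level even for ST-shifted
      # beats, so the zero-crossing is authoritative; the flatness rule is
      # only a fallback
      I <- zero_cross_backward(samples, Q, max(1L, Q - ms(160)),
                               cfg$zero_band_mV)
      if (is.na(I))
        I <- flat_backward(samples, Q, max(1L, Q - ms(160)), fs)
    }
    if (!is.na(J)) {
      lo <- J + ms(cfg$t_after_j_ms)
      hi <- r + ms(cfg$t_from_r_ms)
      if (lo <= hi && hi <= n && lo >= 1L)
        T_ <- lo + which.max(abs(samples[lo:hi])) - 1L
    }
    if (!is.na(T_) && T_ + ms(cfg$k_from_t_ms) <= n)
      K <- T_ + ms(cfg$k_from_t_ms)
    if (!is.na(I)) {
      hi <- I - ms(cfg$t_after_j_ms)
      lo <- r - ms(cfg$t_from_r_ms)
      if (lo >= 1L && lo <= hi)
        P <- lo + which.max(samples[lo:hi]) - 1L
    }
    if (!is.na(P) && P - ms(cfg$k_from_t_ms) >= 1L)
      H <- P - ms(cfg$k_from_t_ms)
    out <- c(H = H, P = P, I = I, Q = Q, R = r, S = S, J = J, T = T_, K = K)
    out - 1L  # back to 0-based
  })
  fid <- as.data.frame(do.call(rbind, rows))
  if (nrow(fid) == 0L)
    fid <- as.data.frame(matrix(integer(0), 0, 9,
      dimnames = list(NULL, c("H", "P", "I", "Q", "R", "S", "J", "T", "K"))))
  fid$complete <- stats::complete.cases(fid)
  class(fid) <- c("fiducial_set", "data.frame")
  fid
}

#' Mean heart rate from R-peak indices
#'
#' @param r_indices 0-based R-peak indices (at least two).
#' @param fs Sampling rate in Hz.
#' @return Heart rate in beats per minute, `60 / mean(RR)`.
#' @export
heart_rate <- function(r_indices, fs) {
  if (length(r_indices) < 2L) stop("need at least two R peaks")
  60 / mean(diff(sort(r_indices)) / fs)
}
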