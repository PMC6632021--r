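#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Complex extension of a real signal with (numerically) no
#' negative-frequency content. The real part equals the input. All
#' quadratic time-frequency distributions in the package are computed on
#' the analytic signal, which suppresses cross-terms between positive and
#' negative frequencies.
#'
#' @param x Real numeric vector (length >= 2).
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two samples")
  X <- fft(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2L == 0L) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

new_tfd <- function(values, fs, kind, df) {
  structure(list(values = values, fs = fs, kind = kind,
                 t = (seq_len(nrow(values)) - 1) / fs,
                 f = (seq_len(ncol(values)) - 1) * df),
            class = "tfd_matrix")
}

#' @export
print.tfd_matrix <- function(x, ...) {
  cat(sprintf("<tfd_matrix %s> %d time x %d frequency bins, 0-%.1f Hz\n",
              x$kind, nrow(x$values), ncol(x$values), max(x$f)))
  invisible(x)
}

# Instantaneous autocorrelation K[n, tau] = z[n+tau] * Conj(z[n-tau]) for
# non-negative lags tau = 0..L, stored time x lag; zero outside the valid
# support.
inst_autocorr <- function(z) {
  n <- length(z)
  L <- (n - 1L) %/% 2L
  K <- matrix(0 + 0i, nrow = n, ncol = L + 1L)
  for (tau in 0:L) {
    idx <- (tau + 1L):(n - tau)
    K[idx, tau + 1L] <- z[idx + tau] * Conj(z[idx - tau])
  }
  K
}

# FFT the time x lag kernel over the lag axis into a time x frequency TFD.
# Negative lags are reconstructed from Hermitian symmetry, so the result
# is real up to rounding noise.
lag_fft <- function(K, nfreq) {
  n <- nrow(K)
  L <- ncol(K) - 1L
  M <- matrix(0 + 0i, nrow = nfreq, ncol = n)
  M[1:(L + 1L), ] <- t(K)
  if (L >= 1L)
    M[(nfreq - L + 1L):nfreq, ] <- Conj(t(K[, (L + 1L):2L]))
  t(Re(mvfft(M)))
}

#' Wigner-Ville distribution
#'
#' Discrete WVD of the analytic signal: the instantaneous autocorrelation
#' `K[n, tau] = z[n + tau] * Conj(z[n - tau])` Fourier-transformed over
#' the lag axis. Values are real (up to rounding) and scaled so that
#' `sum(values) * dt * df` equals the signal energy `sum(x^2) / fs`, with
#' `dt = 1/fs` and `df = fs / (2 * nfreq)`; the frequency axis runs from 0
#' to `fs/2`.
#'
#' @param x Real numeric vector.
#' @param fs Sampling rate in Hz.
#' @param nfreq Number of frequency bins; default the next power of two at
#'   or above twice the signal length.
#' @return A `tfd_matrix` (time x frequency).
#' @export
wvd <- function(x, fs = 1, nfreq = NULL) {
  if (!length(x)) stop("empty input")
  z <- analytic_signal(x)
  n <- length(z)
  if (is.null(nfreq)) nfreq <- next_pow2(2L * n)
  K <- inst_autocorr(z)
  vals <- lag_fft(K, nfreq) / fs
  new_tfd(vals, fs, "WVD", df = fs / (2 * nfreq))
}

#' Spectrogram
#'
#' Squared magnitude of the short-time Fourier transform with a
#' unit-energy Hann window, one frame centered at every sample (edges
#' reflect-padded). Computed one-sided from the real signal — the
#' magnitude spectrum of a real frame is symmetric, so folding the
#' negative frequencies is exact and the energy accounting has no
#' leakage. Non-negative everywhere; scaled so that
#' `sum(values) * dt * df` equals the signal energy as for [wvd()], here
#' with `df = fs / nfft`.
#'
#' @param x Real numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_len Analysis window length in samples (forced odd;
#'   default about a quarter of the signal).
#' @param nfft FFT length; default the next power of two at or above twice
#'   the signal length.
#' @return A `tfd_matrix` (time x frequency).
#' @export
spectrogram <- function(x, fs = 1, window_len = NULL, nfft = NULL) {
  n <- length(x)
  if (!n) stop("empty input")
  if (is.null(window_len)) window_len <- max(9L, round(n / 4))
  window_len <- odd_window(window_len)
  if (window_len > n) stop("window longer than the signal")
  if (is.null(nfft)) nfft <- next_pow2(2L * n)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(window_len) / (window_len + 1)))
  w <- w / sqrt(sum(w^2))
  h <- (window_len - 1L) %/% 2L
  if (h >= n) stop("window longer than the signal")
  frames <- matrix(0, nrow = nfft, ncol = n)
  # reflect-pad the edges, then rescale so every original sample carries
  # exactly unit total window coverage across all frames (direct plus
  # mirrored appearances); the correction depends only on the window and
  # the record geometry, making the energy accounting exact
  xp <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  np <- length(xp)
  Wp <- vapply(seq_len(np), function(p) {
    cc <- max(1L, p - window_len + 1L):min(n, p)
    sum(w[p - cc + 1L]^2)
  }, numeric(1))
  orig <- c((h + 1L):2L, seq_len(n), (n - 1L):(n - h))  # zp pos -> sample
  tot <- vapply(seq_len(n), function(m) sum(Wp[orig == m]), numeric(1))
  xp <- xp / sqrt(tot[orig])
  for (c0 in seq_len(n))
    frames[1:window_len, c0] <- xp[c0:(c0 + window_len - 1L)] * w
  S <- mvfft(frames)
  keep <- 1:(nfft %/% 2L + 1L)
  # one-sided fold: double all bins except DC (and Nyquist, if present)
  fold <- rep(2, length(keep))
  fold[1] <- 1
  if (nfft %% 2L == 0L) fold[length(keep)] <- 1
  vals <- t(Mod(S[keep, , drop = FALSE])^2 * fold) / fs
  new_tfd(vals, fs, "SPEC", df = fs / nfft)
}

#' EMBD kernel parameters
#'
#' @param alpha Lag-kernel shape (> 0), default 0.1.
#' @param beta Doppler-kernel shape (> 0), default 0.1.
#' @return An `embd_params` object.
#' @export
embd_params <- function(alpha = 0.1, beta = 0.1) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  structure(list(alpha = alpha, beta = beta), class = "embd_params")
}

# |Gamma(a + i y)|^2 / Gamma(a)^2 for real vector y.
gamma_kernel <- function(a, y) {
  Mod(pracma::gammaz(complex(real = a, imaginary = y)))^2 / gamma(a)^2
}

#' Extended modified B-distribution
#'
#' WVD-style computation with a separable Doppler-lag kernel applied in
#' the ambiguity domain: `G(nu, tau) = g1(nu) * g2(tau)` with
#' `g1(nu) = |Gamma(beta + j*pi*nu)|^2 / Gamma(beta)^2` over normalized
#' Doppler `nu` (cycles/sample, in \[-0.5, 0.5)) and
#' `g2 = |Gamma(alpha + j*pi*w)|^2 / Gamma(alpha)^2` over the normalized
#' lag fraction `w = tau / N`. The kernel satisfies `G(0, 0) = 1`, so the
#' total energy equals the WVD's exactly; small `alpha`, `beta` suppress
#' the oscillatory cross-terms, and in the large-parameter limit the EMBD
#' tends to the WVD. Doppler smoothing is circular in time.
#'
#' @param x Real numeric vector.
#' @param fs Sampling rate in Hz.
#' @param params An [embd_params()].
#' @param nfreq Number of frequency bins, as in [wvd()].
#' @return A `tfd_matrix` (time x frequency).
#' @export
embd <- function(x, fs = 1, params = embd_params(), nfreq = NULL) {
  if (!length(x)) stop("empty input")
  z <- analytic_signal(x)
  n <- length(z)
  if (is.null(nfreq)) nfreq <- next_pow2(2L * n)
  K <- inst_autocorr(z)
  # Doppler-domain smoothing (per lag column, circular in time)
  u <- (seq_len(n) - 1) / n
  u[u >= 0.5] <- u[u >= 0.5] - 1
  g1 <- gamma_kernel(params$beta, pi * u)
  A <- mvfft(K) * g1
  K <- mvfft(A, inverse = TRUE) / n
  # lag windowing
  w <- (seq_len(ncol(K)) - 1) / n
  g2 <- gamma_kernel(params$alpha, pi * w)
  K <- sweep(K, 2L, g2, `*`)
  vals <- lag_fft(K, nfreq) / fs
  new_tfd(vals, fs, "EMBD", df = fs / (2 * nfreq))
}

#' Compute a quadratic time-frequency distribution by kind
#'
#' @param x Real numeric vector.
#' @param fs Sampling rate in Hz.
#' @param kind `"wvd"`, `"spec"` or `"embd"`.
#' @param ... Passed to the specific distribution ([wvd()],
#'   [spectrogram()], [embd()]).
#' @return A `tfd_matrix`.
#' @export
qtfd <- function(x, fs = 1, kind = c("embd", "wvd", "spec"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         wvd = wvd(x, fs, ...),
         spec = spectrogram(x, fs, ...),
         embd = embd(x, fs, ...))
}

#' Total energy represented by a TFD
#'
#' `sum(values) * dt * df`, comparable to `sum(x^2) / fs`.
#'
#' @param tfd A `tfd_matrix`.
#' @return Energy in mV^2 s (for mV input).
#' @export
tfd_energy <- function(tfd) {
  dt <- 1 / tfd$fs
  df <- if (length(tfd$f) > 1L) tfd$f[2] - tfd$f[1] else 1
  sum(tfd$values) * dt * df
}
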