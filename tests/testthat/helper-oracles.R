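# Independent oracles used by both the unit and acceptance suites.

# Brute-force discrete WVD: explicit double sum over lags and frequencies.
brute_wvd <- function(x, fs, nfreq) {
  z <- analytic_signal(x)
  n <- length(z)
  W <- matrix(0, n, nfreq)
  for (ni in seq_len(n)) for (k in seq_len(nfreq)) {
    s <- 0 + 0i
    for (tau in -(n - 1):(n - 1)) {
      if (ni + tau >= 1 && ni + tau <= n && ni - tau >= 1 && ni - tau <= n)
        s <- s + z[ni + tau] * Conj(z[ni - tau]) *
          exp(-2i * pi * (k - 1) * tau / nfreq)
    }
    W[ni, k] <- Re(s) / fs
  }
  W
}

# Pairwise concordance count with half-weight ties.
concordance_auc <- function(p, q) {
  s <- 0
  for (a in p) for (b in q) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(p) * length(q))
}
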