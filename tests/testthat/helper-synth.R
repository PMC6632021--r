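# Shared fixtures: all synthetic, generated in code at test time.

clean_record <- function(label = "NORMAL", n_beats = 20L, seed = 1L, ...) {
  generate_record(label, n_beats = n_beats,
                  noise = noise_preset("none", seed = seed), ...)
}

# Preprocess + detect + delineate in one step.
delineate_record <- function(record) {
  pre <- preprocess_record(record)
  r <- detect_r_peaks(pre$samples, pre$fs)
  fid <- locate_fiducials(pre$samples, pre$fs, r)
  list(pre = pre, r = r, fid = fid)
}

beat_levels <- function(pre, fid) {
  cb <- fid[fid$complete, , drop = FALSE]
  t(vapply(seq_len(nrow(cb)), function(i) {
    lv <- iso_st_levels(pre$samples, pre$fs, cb[i, ])
    c(st_deviation = lv$st_deviation, t_amplitude = lv$t_amplitude)
  }, numeric(2)))
}

# Band-limited zero-mean random trace (spectral content well below
# Nyquist, like an oversampled ECG segment).
bandlimited_trace <- function(n) {
  x <- stats::filter(rnorm(n + 40), rep(1 / 8, 8), sides = 2)
  x <- x[!is.na(x)][seq_len(n)]
  x - mean(x)
}

# Small three-class dataset for classifier tests.
small_dataset <- function(per_subject = 40L, n_beats = 44L, seed = 3L) {
  recs <- lapply(c("NORMAL", "ST_ELEVATION", "T_INVERSION"), function(lab)
    generate_record(lab, n_beats = n_beats,
                    noise = noise_preset("wearable", seed = seed),
                    mean_bpm = 72, rr_jitter = 20,
                    record_id = paste0(lab, "_s", seed)))
  assemble_dataset(recs, dataset_config(trace_len = 350,
                                        per_subject = per_subject,
                                        seed = seed))
}
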