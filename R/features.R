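#' Time-domain statistical features
#'
#' Population (divide-by-N) moments of the trace: mean, variance, skewness,
#' kurtosis (non-excess, `m4 / sigma^4`) and coefficient of variation
#' (`sigma / mean`). When the variance is zero, skewness, kurtosis and CV
#' are undefined and reported as `NA`; CV is also `NA` for a zero mean.
#'
#' @param x Numeric vector (length >= 2).
#' @return Named numeric vector `mean, variance, skewness, kurtosis, cv`.
#' @export
t_features <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two samples")
  m <- sum(x) / n
  d <- x - m
  v <- sum(d^2) / n
  s <- sqrt(v)
  if (v == 0) {
    g <- k <- cv <- NA_real_
  } else {
    g <- sum(d^3) / (n * s^3)
    k <- sum(d^4) / (n * s^4)
    cv <- if (m == 0) NA_real_ else s / m
  }
  c(mean = m, variance = v, skewness = g, kurtosis = k, cv = cv)
}

# Spectral flatness and normalized spectral entropy of a magnitude
# spectrum over K bins.
flatness_entropy <- function(mag) {
  K <- length(mag)
  am <- mean(mag)
  if (am == 0) return(c(flatness = NA_real_, entropy = NA_real_))
  sf <- if (any(mag == 0)) 0 else exp(mean(log(mag))) / am
  p <- mag^2 / sum(mag^2)
  p <- p[p > 0]
  se <- -sum(p * log(p)) / log(K)
  c(flatness = sf, entropy = se)
}

#' Frequency-domain features
#'
#' Over the positive-frequency bins of the trace's magnitude spectrum:
#' spectral flatness (geometric mean over arithmetic mean, 1 for a flat
#' spectrum, near 0 for a single tone), normalized spectral entropy
#' (Shannon entropy of the normalized power spectrum divided by `log K`,
#' in \[0, 1\]), and spectral flux — the mean squared frame-to-frame change
#' of the magnitude spectrum over short frames of a quarter of the trace
#' with 50% overlap (near 0 for a stationary spectrum).
#'
#' @param x Numeric vector (length >= 8).
#' @param fs Sampling rate in Hz (kept for interface symmetry; the
#'   features are rate-free).
#' @return Named numeric vector `spectral_flux, spectral_entropy,
#'   spectral_flatness`.
#' @export
f_features <- function(x, fs = 1) {
  n <- length(x)
  if (n < 8L) stop("trace too short for spectral features")
  mag <- Mod(fft(x))[2:(n %/% 2L + 1L)]
  fe <- flatness_entropy(mag)
  frame <- max(4L, as.integer(round(0.25 * n)))
  hop <- max(1L, frame %/% 2L)
  starts <- seq(1L, n - frame + 1L, by = hop)
  mags <- lapply(starts, function(s0)
    Mod(fft(x[s0:(s0 + frame - 1L)]))[2:(frame %/% 2L + 1L)])
  flux <- if (length(mags) < 2L) 0 else
    mean(vapply(2:length(mags),
                function(i) sum((mags[[i]] - mags[[i - 1L]])^2),
                numeric(1)))
  c(spectral_flux = flux, spectral_entropy = unname(fe["entropy"]),
    spectral_flatness = unname(fe["flatness"]))
}

#' Joint time-frequency features from a TFD
#'
#' Extends the time- and frequency-domain features to the (t,f) plane.
#' The five statistical moments are computed over the flattened TFD
#' magnitudes (so the mean scales with the square of the signal amplitude
#' and skewness/kurtosis/CV are scale-free); the three spectral features
#' are computed on each time slice's magnitude profile and averaged over
#' time, with the flux taken between consecutive time slices.
#'
#' @param tfd A `tfd_matrix` from [qtfd()].
#' @return Named numeric vector of the eight joint features, prefixed
#'   `tf_`.
#' @export
joint_tf_features <- function(tfd) {
  V <- abs(tfd$values)
  if (all(V == 0)) stop("all-zero TFD")
  mom <- t_features(as.numeric(V))
  slice_en <- rowSums(V)
  ok <- which(slice_en > 0)
  fe <- vapply(ok, function(i) flatness_entropy(V[i, ]), numeric(2))
  flux <- if (nrow(V) < 2L) 0 else
    mean(vapply(2:nrow(V), function(i) sum((V[i, ] - V[i - 1L, ])^2),
                numeric(1)))
  c(tf_mean = unname(mom["mean"]), tf_variance = unname(mom["variance"]),
    tf_skewness = unname(mom["skewness"]),
    tf_kurtosis = unname(mom["kurtosis"]), tf_cv = unname(mom["cv"]),
    tf_spectral_flux = flux,
    tf_spectral_entropy = mean(fe["entropy", ], na.rm = TRUE),
    tf_spectral_flatness = mean(fe["flatness", ], na.rm = TRUE))
}

#' Full feature vector for one beat trace
#'
#' Concatenates the five time-domain, three frequency-domain and eight
#' joint (t,f) features (the latter from the requested TFD kind).
#'
#' @param x Numeric trace (mV).
#' @param fs Sampling rate in Hz.
#' @param tfd_kind `"embd"`, `"wvd"` or `"spec"`.
#' @param ... Passed to [qtfd()].
#' @return Named numeric vector of 16 features.
#' @export
trace_features <- function(x, fs, tfd_kind = "embd", ...) {
  c(t_features(x), f_features(x, fs),
    joint_tf_features(qtfd(x, fs, tfd_kind, ...)))
}

#' Feature matrix for a labeled dataset
#'
#' @param dataset A `labeled_dataset` from [assemble_dataset()] (or any
#'   list with `traces`, `label`, `fs`).
#' @param tfd_kind TFD used for the joint features.
#' @param ... Passed to [qtfd()].
#' @return Data frame of 16 feature columns plus a `label` column.
#' @export
extract_features <- function(dataset, tfd_kind = "embd", ...) {
  feats <- t(apply(dataset$traces, 1L, trace_features,
                   fs = dataset$fs, tfd_kind = tfd_kind, ...))
  out <- as.data.frame(feats)
  out$label <- dataset$label
  out
}

#' ROC AUC of one feature (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive value exceeds a randomly
#' chosen negative one, ties counted one half — computed from midranks,
#' identical to the pairwise concordance count.
#'
#' @param values_pos,values_neg Feature values in the positive and
#'   negative groups (both non-empty).
#' @return AUC in \[0, 1\].
#' @export
feature_auc <- function(values_pos, values_neg) {
  n1 <- length(values_pos); n2 <- length(values_neg)
  if (!n1 || !n2) stop("both groups must be non-empty")
  r <- rank(c(values_pos, values_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Screen features by AUC against one abnormality
#'
#' Computes, for every feature column, the raw AUC (abnormal vs normal)
#' and the direction-folded value `max(AUC, 1 - AUC)`, and flags features
#' whose raw AUC meets the inclusive threshold.
#'
#' @param features Feature data frame from [extract_features()] (with a
#'   `label` column).
#' @param positive Abnormal class treated as positive.
#' @param negative Reference class (default `"NORMAL"`).
#' @param min_auc Inclusive selection threshold (default 0.5).
#' @return A `feature_report` data frame: `feature`, `auc`, `auc_folded`,
#'   `selected`.
#' @export
feature_auc_report <- function(features, positive, negative = "NORMAL",
                               min_auc = 0.5) {
  stopifnot("label" %in% names(features))
  pos <- features$label == positive
  neg <- features$label == negative
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  cols <- setdiff(names(features), "label")
  auc <- vapply(cols, function(cn) {
    v <- features[[cn]]
    ok <- is.finite(v)
    feature_auc(v[pos & ok], v[neg & ok])
  }, numeric(1))
  out <- data.frame(feature = cols, auc = auc,
                    auc_folded = pmax(auc, 1 - auc),
                    selected = auc >= min_auc,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("feature_report", "data.frame")
  out
}

#' Select features from an AUC report
#'
#' Keeps the features whose raw AUC meets the inclusive threshold
#' (`>= min_auc`).
#'
#' @param report A [feature_auc_report()] result.
#' @param min_auc Inclusive threshold (default 0.5).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(report, min_auc = 0.5) {
  if (!nrow(report)) stop("empty feature report")
  report$feature[report$auc >= min_auc]
}
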