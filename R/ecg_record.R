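#' Construct a single-lead ECG record
#'
#' An `ecg_record` holds a uniformly sampled single-lead ECG in millivolts
#' together with its sampling rate and optional per-beat annotations. All
#' sample indices in the package are 0-based, so the time of sample `i` is
#' `i / fs` seconds.
#'
#' @param samples Numeric vector of amplitudes in mV; all values must be
#'   finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param record_id Identifier string (also used as subject id downstream).
#' @param lead_label Lead name, e.g. `"I"`.
#' @param annotations `NULL` or a data frame with columns `sample_index`
#'   (0-based integer, strictly increasing, within the record), `label`
#'   (one of [ecg_classes()]) and `source` (`"reference"` or `"predicted"`).
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, record_id = "rec", lead_label = "I",
                       annotations = NULL) {
  samples <- as.numeric(samples)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(samples) < 1L || !all(is.finite(samples)))
    stop("`samples` must be non-empty and finite")
  if (is.null(annotations)) {
    annotations <- data.frame(
      sample_index = integer(0), label = character(0), source = character(0),
      stringsAsFactors = FALSE
    )
  }
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  req <- c("sample_index", "label", "source")
  if (!all(req %in% names(annotations)))
    stop("annotations need columns sample_index, label, source")
  annotations$sample_index <- as.integer(annotations$sample_index)
  if (nrow(annotations)) {
    if (any(diff(annotations$sample_index) <= 0L))
      stop("annotation sample indices must be strictly increasing")
    if (any(annotations$sample_index < 0L) ||
        any(annotations$sample_index >= length(samples)))
      stop("annotation indices outside the record")
    if (!all(annotations$label %in% ECG_CLASSES))
      stop("unknown annotation label")
    if (!all(annotations$source %in% c("reference", "predicted")))
      stop("annotation source must be 'reference' or 'predicted'")
  }
  structure(
    list(record_id = record_id, fs = fs, samples = samples,
         lead_label = lead_label, annotations = annotations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record '%s'> lead %s, %d samples @ %g Hz (%.1f s), %d annotations\n",
    x$record_id, x$lead_label, length(x$samples), x$fs,
    length(x$samples) / x$fs, nrow(x$annotations)
  ))
  invisible(x)
}

#' Record duration in seconds
#' @param record An [ecg_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(record) length(record$samples) / record$fs

ann_path_for <- function(path) paste0(path, ".ann")

#' Read an ECG record from disk
#'
#' The `csv` format is a two-column table `time_s, amplitude_mV` (header
#' optional); the sampling rate is inferred from the median time step. If a
#' sidecar file `<path>.ann` exists (columns `sample_index,label,source`),
#' annotations are read from it. The `wfdb_dialect` format is a plain-text
#' PhysioNet-style layout: `<base>.hea` holds `record_id nsig fs nsamples`
#' on its first line and `gain_adu_per_mV adc_zero` on the second, samples
#' are one ADC integer per line in `<base>.dat.txt`, converted to mV on
#' load, and `<base>.ann` (optional) holds annotations.
#'
#' @param path File path (for `wfdb_dialect`, the `.hea` header path or the
#'   base path without extension).
#' @param format `"csv"` or `"wfdb_dialect"`.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb_dialect")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("empty file: ", path)
    has_header <- grepl("[A-Za-z]", first)
    df <- read.csv(path, header = has_header,
                   col.names = c("time_s", "amplitude_mV"))
    if (nrow(df) < 2L) stop("record needs at least two samples")
    if (!is.numeric(df$time_s) || !is.numeric(df$amplitude_mV) ||
        any(!is.finite(df$time_s)) || any(!is.finite(df$amplitude_mV)))
      stop("non-numeric values in record")
    dt <- diff(df$time_s)
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    fs <- 1 / median(dt)
    ann <- NULL
    ap <- ann_path_for(path)
    if (file.exists(ap)) ann <- read.csv(ap, stringsAsFactors = FALSE)
    rec_id <- sub("\\.[^.]*$", "", basename(path))
    return(ecg_record(df$amplitude_mV, fs = fs, record_id = rec_id,
                      annotations = ann))
  }
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea)
  lines <- readLines(hea)
  h1 <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  h2 <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  fs <- as.numeric(h1[3])
  gain <- as.numeric(h2[1])   # ADC units per mV
  adc_zero <- as.numeric(h2[2])
  codes <- scan(paste0(base, ".dat.txt"), what = numeric(), quiet = TRUE)
  samples <- (codes - adc_zero) / gain
  ann <- NULL
  ap <- paste0(base, ".ann")
  if (file.exists(ap)) ann <- read.csv(ap, stringsAsFactors = FALSE)
  ecg_record(samples, fs = fs, record_id = h1[1], annotations = ann)
}

#' Write an ECG record to disk
#'
#' Writes the two-column CSV dialect read back by [read_record()];
#' annotations (if any) go to a `<path>.ann` sidecar.
#'
#' @param record An [ecg_record()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$samples) == 0L) stop("record has no samples")
  n <- length(record$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / record$fs,
                   amplitude_mV = record$samples)
  write.csv(df, path, row.names = FALSE)
  if (nrow(record$annotations))
    write.csv(record$annotations, ann_path_for(path), row.names = FALSE)
  invisible(path)
}

#' Resample a record to a new sampling rate
#'
#' Polyphase resampling (via `signal::resample`) that preserves the record
#' duration to within one output sample and re-indexes annotations
#' proportionally.
#'
#' @param record An [ecg_record()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return A resampled [ecg_record()].
#' @export
resample_record <- function(record, target_fs) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(target_fs) != 1L || !is.finite(target_fs) || target_fs <= 0)
    stop("`target_fs` must be positive")
  if (isTRUE(all.equal(target_fs, record$fs))) return(record)
  # rational approximation of the rate ratio
  p <- as.integer(round(target_fs * 1000))
  q <- as.integer(round(record$fs * 1000))
  g <- pracma::gcd(p, q)
  p <- p %/% g; q <- q %/% g
  y <- signal::resample(record$samples, p, q)
  n_target <- as.integer(round(length(record$samples) * target_fs / record$fs))
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, rep(y[length(y)], n_target - length(y)))
  ann <- record$annotations
  if (nrow(ann)) {
    ann$sample_index <- pmin(
      n_target - 1L,
      pmax(0L, as.integer(round(ann$sample_index * target_fs / record$fs)))
    )
    ann <- ann[!duplicated(ann$sample_index), , drop = FALSE]
  }
  ecg_record(y, fs = target_fs, record_id = record$record_id,
             lead_label = record$lead_label, annotations = ann)
}
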