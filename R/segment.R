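#' Dataset segmentation configuration
#'
#' @param trace_len Fixed segment length in samples (default 350, i.e.
#'   0.7 s at 500 Hz — enough to span P to T at normal heart rates).
#' @param per_subject Maximum segments kept per subject (default 500).
#' @param seed RNG seed for the deterministic per-subject selection.
#' @return A `dataset_config` object.
#' @export
dataset_config <- function(trace_len = 350L, per_subject = 500L, seed = 1L) {
  if (trace_len < 1) stop("trace_len must be positive")
  structure(list(trace_len = as.integer(trace_len),
                 per_subject = as.integer(per_subject),
                 seed = as.integer(seed)), class = "dataset_config")
}

# Label a detected beat from the nearest reference annotation (within
# half a second), falling back to the record's modal annotation label.
beat_label <- function(r_index, record) {
  ann <- record$annotations
  if (!nrow(ann)) return(NA_character_)
  d <- abs(ann$sample_index - r_index)
  if (min(d) <= record$fs / 2) return(ann$label[which.min(d)])
  names(which.max(table(ann$label)))
}

#' Segment a record into fixed-length beat traces
#'
#' One segment per complete beat (all fiducials present), spanning the
#' H-to-K fiducial range — the P-wave onset side to the ST end — centered
#' on the R peak and zero-padded to `trace_len` samples; spans longer than
#' `trace_len` are center-cropped about R.
#'
#' @param record The (preprocessed) [ecg_record()] the fiducials refer to.
#' @param fiducials A [locate_fiducials()] result for `record`.
#' @param cfg A [dataset_config()].
#' @return A `beat_segments` list with `traces` (matrix, one row per
#'   segment), `label`, `subject_id`, `beat_index`.
#' @export
segment_beats <- function(record, fiducials, cfg = dataset_config()) {
  beats <- which(fiducials$complete)
  if (!length(beats)) stop("no complete beats to segment")
  L <- cfg$trace_len
  center <- L %/% 2L + 1L
  x <- record$samples
  n <- length(x)
  traces <- matrix(0, nrow = length(beats), ncol = L)
  labels <- character(length(beats))
  for (k in seq_along(beats)) {
    b <- fiducials[beats[k], ]
    r1 <- b$R + 1L
    span <- (b$H + 1L):(b$K + 1L)
    pos <- span - r1 + center              # columns where the span lands
    keep <- pos >= 1L & pos <= L & span >= 1L & span <= n
    traces[k, pos[keep]] <- x[span[keep]]
    labels[k] <- beat_label(b$R, record)
  }
  structure(list(traces = traces, label = labels,
                 subject_id = rep(record$record_id, length(beats)),
                 beat_index = beats),
            class = "beat_segments")
}

#' Average traces per class
#'
#' Pointwise mean of the segments in each class — the class-representative
#' trace. Averaging n noisy copies of one beat reduces the residual noise
#' variance by a factor of n.
#'
#' @param traces Numeric matrix, one trace per row.
#' @param labels Character vector of class labels, one per row.
#' @return Named list of mean traces, one per label present.
#' @export
average_class_traces <- function(traces, labels) {
  if (!nrow(traces)) stop("no traces to average")
  groups <- split(seq_len(nrow(traces)), labels)
  lapply(groups, function(ii) colMeans(traces[ii, , drop = FALSE]))
}

#' Assemble a labeled dataset from delineated records
#'
#' Runs preprocessing, R-peak detection, fiducial delineation and
#' segmentation on every record, caps the contribution of each subject at
#' `per_subject` segments (deterministic seeded selection), and pools the
#' result with per-class and per-subject counts.
#'
#' @param records List of [ecg_record()]s, one per subject, each carrying
#'   reference annotations.
#' @param cfg A [dataset_config()].
#' @param dcfg A [delineation_config()].
#' @param pcfg A [preprocess_config()].
#' @return A `labeled_dataset` list with `traces`, `label`, `subject_id`,
#'   `class_counts`, `subject_counts`, `fs`.
#' @export
assemble_dataset <- function(records, cfg = dataset_config(),
                             dcfg = delineation_config(),
                             pcfg = preprocess_config()) {
  stopifnot(length(records) >= 1L)
  pieces <- lapply(records, function(rec) {
    pre <- preprocess_record(rec, pcfg)
    r <- detect_r_peaks(pre$samples, pre$fs, dcfg)
    fid <- locate_fiducials(pre$samples, pre$fs, r, dcfg)
    seg <- segment_beats(pre, fid, cfg)
    if (nrow(seg$traces) > cfg$per_subject) {
      keep <- with_seed(cfg$seed,
                        sort(sample(nrow(seg$traces), cfg$per_subject)))
      seg$traces <- seg$traces[keep, , drop = FALSE]
      seg$label <- seg$label[keep]
      seg$subject_id <- seg$subject_id[keep]
      seg$beat_index <- seg$beat_index[keep]
    }
    seg
  })
  traces <- do.call(rbind, lapply(pieces, `[[`, "traces"))
  label <- unlist(lapply(pieces, `[[`, "label"))
  subject <- unlist(lapply(pieces, `[[`, "subject_id"))
  if (any(is.na(label))) stop("unlabeled segments in dataset")
  counts <- table(label)
  if (any(counts == 0)) stop("a class has zero segments")
  structure(list(traces = traces, label = label, subject_id = subject,
                 class_counts = counts, subject_counts = table(subject),
                 fs = records[[1]]$fs),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d traces x %d samples, %d subjects\n",
              nrow(x$traces), ncol(x$traces), length(x$subject_counts)))
  print(x$class_counts)
  invisible(x)
}
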