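#' Create an alert event
#'
#' @param timestamp Time of the decision (seconds into the stream).
#' @param label Abnormal class label.
#' @param st_deviation Mean ST deviation (mV) from the linear summary.
#' @param confidence Fraction of beats in the buffer voting abnormal.
#' @param location Optional `c(lat, lon)`.
#' @param message Free-text message.
#' @return An `alert_event` list.
#' @export
alert_event <- function(timestamp, label, st_deviation = NA_real_,
                        confidence = NA_real_, location = NULL,
                        message = "possible myocardial infarction") {
  if (!label %in% setdiff(ECG_CLASSES, "NORMAL"))
    stop("alert label must be an abnormal class")
  ev <- list(timestamp = timestamp, label = label,
             st_deviation = st_deviation, confidence = confidence,
             message = message)
  if (!is.null(location)) {
    ev$location <- list(lat = location[1], lon = location[2])
  }
  structure(ev, class = "alert_event")
}

#' Emit an alert to every registered sink
#'
#' Serializes the event to JSON and hands the JSON string to each sink
#' function in turn. A failing sink does not block the others; with no
#' sinks registered this is a no-op.
#'
#' @param event An [alert_event()].
#' @param sinks List of functions taking one JSON string argument.
#' @return Invisibly, a logical vector of per-sink success.
#' @export
emit_alert <- function(event, sinks = list()) {
  payload <- jsonlite::toJSON(unclass(event), auto_unbox = TRUE,
                              digits = NA, null = "null")
  ok <- vapply(sinks, function(sink) {
    tryCatch({ sink(payload); TRUE }, error = function(e) FALSE)
  }, logical(1))
  invisible(ok)
}

#' Console alert sink
#'
#' @return A sink function that prints the alert JSON with [message()].
#' @export
sink_console <- function() function(payload) message("ALERT: ", payload)

#' Collector alert sink (for testing and logging)
#'
#' @return A sink function with an `env$events` character vector
#'   accumulating the JSON payloads (accessible via
#'   `environment(sink)$events`).
#' @export
sink_collector <- function() {
  events <- character(0)
  function(payload) {
    events <<- c(events, payload)
    invisible(payload)
  }
}

#' Buffered real-time decision loop
#'
#' Consumes a recorded stream in complete 10-second buffers. Each buffer
#' is preprocessed, delineated and segmented; EMBD features are extracted
#' per beat and both binary models vote (majority over beats; the STEMI
#' model takes precedence when both fire); the linear classifier supplies
#' the ST-deviation summary. One decision is produced per complete buffer
#' — a trailing partial buffer is discarded with a notice. Alerts are
#' debounced: at most one per contiguous abnormal episode, re-armed by a
#' normal decision.
#'
#' @param record An [ecg_record()] holding the recorded stream.
#' @param models List with `stemi` and `nstemi` [train_model()] models
#'   trained on [trace_features()] columns.
#' @param thr A [linear_thresholds()] for the deviation summary.
#' @param buffer_s Buffer length in seconds (default 10).
#' @param tfd_kind TFD used for the features (default `"embd"`).
#' @param trace_len Segment length in samples; must match the models'
#'   training configuration.
#' @param sinks Alert sinks for [emit_alert()].
#' @param location Optional `c(lat, lon)` provider value attached to
#'   alerts.
#' @return A `stream_result` list with `decisions` (data frame: one row
#'   per buffer) and `alerts` (list of [alert_event()]s).
#' @export
stream_decide <- function(record, models, thr = linear_thresholds(),
                          buffer_s = 10, tfd_kind = "embd",
                          trace_len = 350L, sinks = list(),
                          location = NULL) {
  fs <- record$fs
  buf_n <- as.integer(round(buffer_s * fs))
  n_buf <- length(record$samples) %/% buf_n
  if (length(record$samples) %% buf_n != 0L)
    message("discarding trailing partial buffer (",
            length(record$samples) %% buf_n, " samples)")
  decisions <- list()
  alerts <- list()
  armed <- TRUE
  dcfg <- delineation_config(window_s = buffer_s)
  scfg <- dataset_config(trace_len = trace_len)
  for (bi in seq_len(n_buf)) {
    lo <- (bi - 1L) * buf_n + 1L
    chunk <- record$samples[lo:(lo + buf_n - 1L)]
    t0 <- (lo - 1L) / fs
    x <- correct_baseline(notch_50hz(chunk, fs), fs)
    r <- detect_r_peaks(x, fs, dcfg)
    label <- "NORMAL"; st_dev <- NA_real_; conf <- NA_real_; nb <- 0L
    if (length(r) >= 2L) {
      fid <- locate_fiducials(x, fs, r, dcfg)
      complete <- fid[fid$complete, , drop = FALSE]
      nb <- nrow(complete)
      if (nb > 0L) {
        devs <- vapply(seq_len(nb), function(i)
          iso_st_levels(x, fs, complete[i, ])$st_deviation, numeric(1))
        st_dev <- mean(devs)
        seg <- segment_beats(
          ecg_record(x, fs, record_id = record$record_id), fid, scfg
        )
        fx <- t(apply(seg$traces, 1L, trace_features, fs = fs,
                      tfd_kind = tfd_kind))
        vote <- function(model, abnormal) {
          pred <- predict(model, fx)
          mean(pred == abnormal)
        }
        v_st <- vote(models$stemi, "ST_ELEVATION")
        v_ti <- vote(models$nstemi, "T_INVERSION")
        if (v_st > 0.5) {
          label <- "ST_ELEVATION"; conf <- v_st
        } else if (v_ti > 0.5) {
          label <- "T_INVERSION"; conf <- v_ti
        } else {
          conf <- 1 - max(v_st, v_ti)
        }
      }
    }
    decisions[[bi]] <- data.frame(
      start_s = t0, end_s = t0 + buffer_s, label = label,
      st_deviation = st_dev, confidence = conf, n_beats = nb,
      stringsAsFactors = FALSE
    )
    if (label != "NORMAL") {
      if (armed) {
        ev <- alert_event(t0 + buffer_s, label, st_deviation = st_dev,
                          confidence = conf, location = location)
        emit_alert(ev, sinks)
        alerts[[length(alerts) + 1L]] <- ev
        armed <- FALSE
      }
    } else {
      armed <- TRUE
    }
  }
  structure(list(decisions = do.call(rbind, decisions), alerts = alerts),
            class = "stream_result")
}
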