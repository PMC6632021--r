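# Train a small model pair once for the streaming tests.
stream_models <- local({
  models <- NULL
  function() {
    if (is.null(models)) {
      ds <- small_dataset(per_subject = 40L)
      fx <- extract_features(ds, "embd")
      X <- fx[, setdiff(names(fx), "label")]
      sel_a <- fx$label %in% c("NORMAL", "ST_ELEVATION")
      sel_b <- fx$label %in% c("NORMAL", "T_INVERSION")
      models <<- list(
        stemi = train_model(X[sel_a, ], fx$label[sel_a]),
        nstemi = train_model(X[sel_b, ], fx$label[sel_b])
      )
    }
    models
  }
})

test_that("one decision per complete 10 s buffer, reproducibly", {
  models <- stream_models()
  norm <- generate_record("NORMAL", n_beats = 31, mean_bpm = 62,
                          noise = noise_preset("wearable", seed = 9))
  res <- suppressMessages(stream_decide(norm, models))
  expect_equal(nrow(res$decisions), 3L)
  expect_true(all(res$decisions$label == "NORMAL"))
  expect_length(res$alerts, 0L)

  res2 <- suppressMessages(stream_decide(norm, models))
  expect_identical(res$decisions, res2$decisions)

  short <- generate_record("NORMAL", n_beats = 7,
                           noise = noise_preset("wearable", seed = 9))
  res3 <- suppressMessages(stream_decide(short, models))
  expect_null(res3$decisions)
})

test_that("abnormal stream raises one debounced alert with location", {
  models <- stream_models()
  sink <- sink_collector()
  st <- generate_record("ST_ELEVATION", n_beats = 31, mean_bpm = 62,
                        noise = noise_preset("wearable", seed = 9))
  res <- suppressMessages(
    stream_decide(st, models, sinks = list(sink), location = c(25.3, 51.5)))
  expect_gte(sum(res$decisions$label != "NORMAL"), 1L)
  expect_length(res$alerts, 1L)  # debounced across contiguous abnormality
  payload <- jsonlite::fromJSON(environment(sink)$events[1])
  expect_equal(payload$location$lat, 25.3)
  expect_equal(payload$location$lon, 51.5)
  expect_equal(payload$label, "ST_ELEVATION")
})

test_that("alert re-arms after a normal decision", {
  models <- stream_models()
  st <- generate_record("ST_ELEVATION", n_beats = 11, mean_bpm = 66,
                        noise = noise_preset("wearable", seed = 4))
  norm <- generate_record("NORMAL", n_beats = 11, mean_bpm = 66,
                          noise = noise_preset("wearable", seed = 5))
  combo <- ecg_record(c(st$samples, norm$samples, st$samples), fs = 500,
                      record_id = "episodes")
  res <- suppressMessages(stream_decide(combo, models))
  abn <- res$decisions$label != "NORMAL"
  episodes <- sum(diff(c(FALSE, abn)) == 1)
  expect_length(res$alerts, episodes)
  expect_gte(episodes, 2L)
})

test_that("alert fan-out isolates failing sinks", {
  got <- character(0)
  ok_sink <- function(p) got <<- c(got, p)
  bad_sink <- function(p) stop("sink down")
  ev <- alert_event(12, "T_INVERSION", st_deviation = -0.1)
  status <- emit_alert(ev, list(bad_sink, ok_sink))
  expect_equal(status, c(FALSE, TRUE))
  expect_length(got, 1L)
  expect_silent(emit_alert(ev, list()))  # no sinks: no-op
  expect_error(alert_event(0, "NORMAL"), "abnormal")
})
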