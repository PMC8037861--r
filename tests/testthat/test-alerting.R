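# Command conversion, stimulus emission, connection checks, and the
# monitoring loop.

test_that("command conversion is total and deterministic", {
  expect_equal(convert_command("INATTENTION"), "ALERT")
  expect_equal(convert_command("ATTENTION"), "STAY")
  res <- data.frame(loglik_attention = -5, loglik_inattention = -1,
                    decision = factor("INATTENTION",
                                      levels = attention_levels()))
  expect_equal(convert_command(res), "ALERT")
  expect_error(convert_command("MAYBE"), "decision")
})

test_that("alerts carry both stimuli, STAY emits nothing, sinks never break
           the loop", {
  sink <- log_sink()
  ev <- emit_alert("ALERT", time_s = 3, sinks = list(sink))
  expect_setequal(ev$stimuli, c("VISUAL", "AUDITORY"))
  expect_null(emit_alert("STAY", time_s = 4, sinks = list(sink)))
  store <- attr(sink, "store")
  expect_length(store$events, 1)
  for (i in 1:3) emit_alert("ALERT", time_s = i, sinks = list(sink))
  expect_length(store$events, 4)  # no coalescing

  bad_sink <- function(event) stop("device unplugged")
  expect_warning(ev2 <- emit_alert("ALERT", 1, sinks = list(bad_sink)),
                 "monitoring continues")
  expect_setequal(ev2$stimuli, c("VISUAL", "AUDITORY"))
})

test_that("connection check is fail-safe", {
  expect_equal(check_connection("OK"), "OK")
  expect_equal(check_connection(TRUE), "OK")
  expect_equal(check_connection("POOR"), "POOR")
  expect_equal(check_connection(NA), "POOR")
  expect_equal(check_connection(NULL), "POOR")
})

test_that("monitor replay logs one decision per OK cycle, alerts match
           inattention decisions, and repeats identically", {
  det <- toy_detector(sep = 10)
  set.seed(30)
  # stream: 20 s attention-like then 20 s inattention-like at 6 Hz
  F <- matrix(c(rnorm(120, 0.5), rnorm(120, 10.5)), ncol = 1)
  ms <- run_monitor(F, det)
  expect_equal(ms$n_cycles, (240 - 60) / 6 + 1)
  expect_equal(sum(!is.na(ms$log$decision)), ms$n_cycles)
  expect_equal(nrow(ms$events),
               sum(ms$log$decision == "INATTENTION", na.rm = TRUE))
  # cadence: decisions spaced by step/frame_rate = 1 s
  expect_true(all(diff(ms$log$time_s) == 1))
  ms2 <- run_monitor(F, det)
  expect_identical(ms$log, ms2$log)

  # boundary: exactly w frames -> one cycle
  one <- run_monitor(F[1:60, , drop = FALSE], det)
  expect_equal(one$n_cycles, 1)
  expect_warning(short <- run_monitor(F[1:10, , drop = FALSE], det),
                 "shorter")
  expect_equal(short$n_cycles, 0)
})

test_that("scripted POOR cycles suspend decisions and request adjustment", {
  det <- toy_detector()
  set.seed(31)
  F <- matrix(rnorm(120, 0.5), ncol = 1)
  feed <- rep("OK", 11)
  feed[5:7] <- "POOR"
  ms <- run_monitor(F, det, connection = feed)
  expect_equal(which(ms$log$adjustment_requested), 5:7)
  expect_true(all(is.na(ms$log$decision[5:7])))
  expect_equal(sum(!is.na(ms$log$decision)), 8)

  # missing feed entirely -> all POOR, no decisions
  none <- run_monitor(F, det, connection = NULL)
  expect_true(all(none$log$connection == "POOR"))
  expect_equal(sum(!is.na(none$log$decision)), 0)
  # always-OK feed -> zero adjustment requests
  expect_equal(sum(ms$log$adjustment_requested[-(5:7)]), 0)
})

test_that("monitoring never mutates the detector", {
  det <- toy_detector()
  set.seed(32)
  F <- matrix(rnorm(120, 0.5), ncol = 1)
  before <- unserialize(serialize(det, NULL))
  invisible(run_monitor(F, det))
  expect_identical(det, before)
})

test_that("closed-loop simulant recovers after alerts, shortening lapses", {
  cfg <- quick_sim(duration_s = 480, seed = 33)
  pcfg <- pipeline_config(seed = 33, trim_s = 30,
                          filter = list(type = "none"), sim = cfg)
  res <- run_pipeline(pcfg)
  on <- run_closed_loop(res$detector, cfg, alert_enabled = TRUE,
                        response_latency_s = 2, seed = 34)
  off <- run_closed_loop(res$detector, cfg, alert_enabled = FALSE,
                         response_latency_s = 2, seed = 34)
  expect_length(on$true_state, 480 * 6)
  expect_length(on$telemetry, 480 * 6)
  # alert-enabled runs spend less time inattentive than matched controls
  expect_lt(mean(on$true_state == "INATTENTION"),
            mean(off$true_state == "INATTENTION") + 0.02)
  # determinism of the control condition
  off2 <- run_closed_loop(res$detector, cfg, alert_enabled = FALSE,
                          response_latency_s = 2, seed = 34)
  expect_identical(off$telemetry$altitude_ft, off2$telemetry$altitude_ft)
  expect_identical(off$decisions, off2$decisions)
})
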