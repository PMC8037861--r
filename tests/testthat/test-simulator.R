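# Synthetic session generator: state process, EEG synthesis, telemetry.

test_that("state path respects dwell means, degenerate dwell, and seeding", {
  cfg <- sim_config(duration_s = 600, seed = 1,
                    state_dwell_mean_s = c(attention = 60, inattention = 20))
  # expectation of the alternating renewal process: 20/(60+20) = 25%
  fr <- vapply(1:20, function(s) mean(sample_state_path(cfg, seed = s) ==
                                        "INATTENTION"), numeric(1))
  expect_lt(abs(mean(fr) - 0.25), 0.05)

  inf_cfg <- sim_config(duration_s = 60,
                        state_dwell_mean_s = c(attention = Inf, inattention = 5))
  expect_true(all(sample_state_path(inf_cfg, seed = 2) == "ATTENTION"))

  expect_identical(sample_state_path(cfg, seed = 3),
                   sample_state_path(cfg, seed = 3))
  expect_length(sample_state_path(cfg, seed = 3), 3600L)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(raw_rate = 125, frame_rate = 6), "multiple")
  expect_error(sim_config(theta_gain = 0.5), "theta_gain")
  expect_error(sim_config(telemetry_noise_sd = list(
    attention = c(altitude = 10, velocity = 2),
    inattention = c(altitude = 5, velocity = 5))), "smaller")
  expect_error(sim_config(state_dwell_mean_s = c(attention = -1,
                                                 inattention = 5)), "positive")
})

test_that("EEG synthesis elevates theta during inattention and is seeded", {
  cfg <- sim_config(duration_s = 600, seed = 4, theta_gain = 3)
  st <- sample_state_path(cfg, seed = 4)
  ee <- synthesize_eeg(st, cfg, seed = 5)
  expect_equal(dim(ee$data), c(600 * 120, 14))
  expect_identical(synthesize_eeg(st, cfg, seed = 5)$data, ee$data)

  # oracle: per-channel band-pass around theta, envelope magnitude by state
  bands <- decompose_bands(ee, frame_rate = 6)
  th <- apply(bands$values["theta", , ], 2, mean)
  st_cut <- st[seq_along(th)]
  expect_gt(length(unique(st_cut)), 1)
  per_channel_gap <- vapply(1:14, function(j) {
    v <- bands$values["theta", j, ]
    mean(v[st_cut == "INATTENTION"]) - mean(v[st_cut == "ATTENTION"])
  }, numeric(1))
  expect_true(all(per_channel_gap > 0))
})

test_that("theta gain 1 leaves band power label-independent", {
  cfg <- sim_config(duration_s = 300, seed = 6, theta_gain = 1)
  st <- sample_state_path(cfg, seed = 6)
  ee <- synthesize_eeg(st, cfg, seed = 7)
  bands <- decompose_bands(ee, frame_rate = 6)
  v <- apply(bands$values["theta", , ], 2, mean)
  st_cut <- st[seq_along(v)]
  # subsample every 10 s: frames from overlapping FFT windows are strongly
  # autocorrelated and would invalidate the two-sample test
  keep <- seq(1, length(v), by = 60)
  p <- stats::t.test(v[keep][st_cut[keep] == "INATTENTION"],
                     v[keep][st_cut[keep] == "ATTENTION"])$p.value
  expect_gt(p, 0.01)
})

test_that("increasing theta gain widens the between-state theta gap", {
  gaps <- vapply(c(1, 2, 4), function(g) {
    cfg <- sim_config(duration_s = 300, seed = 8, theta_gain = g)
    st <- sample_state_path(cfg, seed = 8)
    ee <- synthesize_eeg(st, cfg, seed = 9)
    v <- apply(decompose_bands(ee)$values["theta", , ], 2, mean)
    st_cut <- st[seq_along(v)]
    mean(v[st_cut == "INATTENTION"]) - mean(v[st_cut == "ATTENTION"])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("zero amplitudes and zero noise give an all-zero record", {
  cfg <- sim_config(duration_s = 10, seed = 1,
                    band_amplitude_uv = c(delta = 0, theta = 0, alpha = 0, beta = 0),
                    noise_sd_uv = 0)
  st <- sample_state_path(cfg, seed = 1)
  expect_true(all(synthesize_eeg(st, cfg, seed = 2)$data == 0))
})

test_that("telemetry holds targets noiselessly and inflates variance in lapses", {
  cfg0 <- sim_config(duration_s = 60, seed = 1, telemetry_noise_sd = list(
    attention = c(altitude = 0, velocity = 0),
    inattention = c(altitude = 0, velocity = 0)))
  st <- sample_state_path(cfg0, seed = 1)
  tl <- synthesize_telemetry(st, cfg0, seed = 2)
  expect_true(all(tl$altitude_ft == 6500))
  expect_true(all(tl$velocity_kn == 250))

  # SD ratio 10 with pure-state windows: inattention window variance wins
  cfg <- sim_config(duration_s = 20, seed = 1, telemetry_noise_sd = list(
    attention = c(altitude = 1, velocity = 1),
    inattention = c(altitude = 10, velocity = 10)))
  n_win <- 0; n_gt <- 0
  for (s in 1:100) {
    st_a <- factor(rep("ATTENTION", 120), levels = attention_levels())
    st_i <- factor(rep("INATTENTION", 120), levels = attention_levels())
    va <- stats::var(synthesize_telemetry(st_a, cfg, seed = s)$altitude_ft[61:120])
    vi <- stats::var(synthesize_telemetry(st_i, cfg, seed = s + 1000)$altitude_ft[61:120])
    n_win <- n_win + 1
    n_gt <- n_gt + (vi > va)
  }
  expect_gte(n_gt / n_win, 0.95)
  expect_identical(synthesize_telemetry(st, cfg, seed = 3)$altitude_ft,
                   synthesize_telemetry(st, cfg, seed = 3)$altitude_ft)
})

test_that("simulated sessions keep frame bookkeeping consistent", {
  s <- simulate_session(quick_sim(duration_s = 30))
  expect_length(s$true_state, 180L)
  expect_length(s$telemetry, 180L)
  expect_equal(nrow(s$raw_eeg$data), 30 * 120)
  s2 <- simulate_session(quick_sim(duration_s = 30))
  expect_identical(s$raw_eeg$data, s2$raw_eeg$data)
  expect_identical(s$telemetry$altitude_ft, s2$telemetry$altitude_ft)
})
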