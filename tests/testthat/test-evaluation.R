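# Confusion counts, the three detection metrics, label-ratio and band
# diagnostics, and the recovery comparison.

test_that("confusion counts match a manual tally", {
  tr <- c("INATTENTION", "INATTENTION", "ATTENTION", "ATTENTION", "ATTENTION",
          "INATTENTION", "ATTENTION", "ATTENTION", "INATTENTION", "ATTENTION")
  pr <- c("INATTENTION", "ATTENTION", "ATTENTION", "INATTENTION", "ATTENTION",
          "INATTENTION", "INATTENTION", "ATTENTION", "ATTENTION", "ATTENTION")
  cm <- confusion(tr, pr)
  expect_equal(cm[["TP"]], 2)
  expect_equal(cm[["FN"]], 2)
  expect_equal(cm[["FP"]], 2)
  expect_equal(cm[["TN"]], 4)

  perfect <- confusion(tr, tr)
  expect_equal(perfect[["FN"]] + perfect[["FP"]], 0)
  all_att <- confusion(tr, rep("ATTENTION", 10))
  expect_equal(all_att[["TP"]] + all_att[["FP"]], 0)
  expect_error(confusion(tr, pr[1:5]), "equal length")
})

test_that("metrics implement the three ratios with undefined markers", {
  m <- detection_metrics(c(TP = 3, FN = 1, FP = 2, TN = 4))
  expect_equal(m[["accuracy"]], 0.7)
  expect_equal(m[["precision"]], 0.6)
  expect_equal(m[["recall"]], 0.75)

  expect_warning(m0 <- detection_metrics(c(TP = 0, FN = 2, FP = 0, TN = 0)),
                 "precision undefined")
  expect_true(is.na(m0[["precision"]]))
  expect_equal(m0[["accuracy"]], 0)

  # accuracy is the prior-weighted combination of recall and specificity
  set.seed(40)
  for (i in 1:10) {
    c4 <- c(TP = sample(1:20, 1), FN = sample(1:20, 1),
            FP = sample(1:20, 1), TN = sample(1:20, 1))
    m <- detection_metrics(c4)
    n_pos <- c4[["TP"]] + c4[["FN"]]
    n_neg <- c4[["FP"]] + c4[["TN"]]
    spec <- c4[["TN"]] / n_neg
    expect_equal(m[["accuracy"]],
                 (n_pos * m[["recall"]] + n_neg * spec) / (n_pos + n_neg),
                 tolerance = 1e-12)
  }
})

test_that("label-ratio report tracks trim boundary and known state fractions", {
  lw <- toy_labeled(c(rep(9, 4), rep(1, 6)), c(rep(9, 4), rep(1, 6)), w = 6)
  rep0 <- label_ratio_report(lw, trim_s = 0, frame_rate = 6)
  expect_equal(rep0$fraction_whole, rep0$fraction_trimmed)

  all_att <- suppressWarnings(toy_labeled(rep(1, 6), rep(1, 6)))
  r <- label_ratio_report(all_att, trim_s = 0, frame_rate = 6)
  expect_equal(r$fraction_whole, 0)
  expect_true(all(r$curve$fraction == 0))

  # simulator session: the rank-based conjunction rule keeps the labeled
  # fraction inside its structural (0, 0.5] range, and the binned curve is
  # consistent with the overall fraction
  s <- simulate_session(quick_sim(duration_s = 600, seed = 41))
  w <- make_windows(length(s$telemetry), 60, 6)
  lw2 <- label_windows(window_variances(s$telemetry, w),
                       frame_rate = 6)
  rep2 <- label_ratio_report(lw2, trim_s = 0)
  expect_gt(rep2$fraction_whole, 0)
  expect_lte(rep2$fraction_whole, 0.5)
  expect_equal(sum(rep2$curve$fraction * rep2$curve$n_windows) /
                 sum(rep2$curve$n_windows),
               rep2$fraction_whole, tolerance = 1e-12)
})

test_that("band diagnostic flags theta under theta-gain lapses and shrinks
           under label permutation", {
  s <- simulate_session(quick_sim(duration_s = 600, seed = 42, theta_gain = 3))
  bm <- average_channels(decompose_bands(s$raw_eeg))
  T_ <- ncol(bm$values)
  labs <- s$true_state[seq_len(T_)]
  d <- band_label_diagnostic(bm, labs)
  expect_equal(d$flagged, "theta")
  expect_gt(d$table$std_diff[d$table$band == "theta"], 0.2)

  set.seed(43)
  d_perm <- band_label_diagnostic(bm, sample(labs))
  expect_lt(max(abs(d_perm$table$std_diff)),
            max(abs(d$table$std_diff)))

  # gain 1: no band strongly elevated
  s1 <- simulate_session(quick_sim(duration_s = 600, seed = 44, theta_gain = 1))
  bm1 <- average_channels(decompose_bands(s1$raw_eeg))
  labs1 <- s1$true_state[seq_len(ncol(bm1$values))]
  d1 <- band_label_diagnostic(bm1, labs1)
  expect_lt(max(abs(d1$table$std_diff)), 0.2)

  expect_error(band_label_diagnostic(bm, factor(rep("ATTENTION", T_),
                                                levels = attention_levels())),
               "both label classes")
})

test_that("recovery comparison is computed per condition and warns without
           detections", {
  mk_sess <- function(seed, events, alert_enabled) {
    set.seed(seed)
    structure(list(
      telemetry = telemetry_trace(rnorm(600, 6500, 5), rnorm(600, 250, 1), 6),
      true_state = factor(rep("ATTENTION", 600), levels = attention_levels()),
      decisions = data.frame(), events = events,
      alert_enabled = alert_enabled, config = NULL, seed = seed),
      class = "monitored_session")
  }
  ev <- data.frame(frame = c(100, 300), time_s = c(100, 300) / 6)
  r <- recovery_compare(mk_sess(1, ev, TRUE), mk_sess(2, ev, FALSE))
  expect_equal(r$condition, c("alert_enabled", "alert_disabled"))
  expect_true(all(r$n_detections == 2))
  expect_true(all(r$mean_var_alt >= 0))

  none <- mk_sess(3, data.frame(), FALSE)
  expect_warning(r2 <- recovery_compare(mk_sess(1, ev, TRUE), none),
                 "no inattention detections")
  expect_true(is.na(r2$mean_var_alt[2]))

  # identical sessions give identical per-condition rows
  same <- recovery_compare(mk_sess(5, ev, TRUE), mk_sess(5, ev, FALSE))
  expect_equal(same$mean_var_alt[1], same$mean_var_alt[2])
})
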