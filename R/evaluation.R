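# Evaluation: confusion counts with INATTENTION as the positive class,
# accuracy / precision / recall, label-ratio diagnostics, per-band
# amplitude-vs-label diagnostics, and the attention-recovery comparison
# between alert-enabled and alert-disabled monitored sessions.

#' Confusion counts for inattention detection
#'
#' Tallies predictions against reference labels with INATTENTION as the
#' positive class: TP = inattention detected as inattention, FN = missed
#' inattention, FP = false alarm, TN = attention detected as attention.
#'
#' @param truth,predicted Equal-length vectors coercible to the
#'   ATTENTION/INATTENTION factor.
#' @return Object of class `confusion_counts` (named integer vector TP, FN,
#'   FP, TN).
#' @export
confusion <- function(truth, predicted) {
  truth <- as_state_factor(truth)
  predicted <- as_state_factor(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  pos_t <- truth == INATTENTION
  pos_p <- predicted == INATTENTION
  out <- c(TP = sum(pos_t & pos_p), FN = sum(pos_t & !pos_p),
           FP = sum(!pos_t & pos_p), TN = sum(!pos_t & !pos_p))
  structure(as.integer(out), names = names(out), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FN %d  FP %d  TN %d\n",
              x[["TP"]], x[["FN"]], x[["FP"]], x[["TN"]]))
  invisible(x)
}

#' Accuracy, precision, and recall from confusion counts
#'
#' accuracy = (TP+TN)/(TP+FP+FN+TN), recall = TP/(TP+FN),
#' precision = TP/(TP+FP). A metric whose denominator is zero is undefined
#' and reported as `NA` with a warning, never silently as 0.
#'
#' @param counts A [confusion()] result (or named vector with TP/FN/FP/TN).
#' @return Named numeric vector `accuracy`, `precision`, `recall`.
#' @export
detection_metrics <- function(counts) {
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  fp <- counts[["FP"]]; tn <- counts[["TN"]]
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion counts")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    num / den
  }
  c(accuracy = (tp + tn) / total,
    precision = ratio(tp, tp + fp, "precision"),
    recall = ratio(tp, tp + fn, "recall"))
}

#' Inattention label-ratio report
#'
#' Overall inattention fraction among windows before and after discarding a
#' leading trim interval, plus a binned time curve of the inattention
#' fraction, used to inspect how lapses distribute over a flight.
#'
#' @param labeled A `labeled_windows` data frame covering the whole session.
#' @param trim_s Leading seconds whose windows are excluded from the
#'   "after" fraction (a window counts as trimmed when it starts before the
#'   boundary).
#' @param frame_rate Frames per second (default: stored attribute, else 6).
#' @param bin_s Width of the time bins for the curve, seconds (default 60).
#' @return List with `fraction_whole`, `fraction_trimmed`, and `curve`
#'   (data frame `bin_start_s`, `fraction`, `n_windows`).
#' @export
label_ratio_report <- function(labeled, trim_s = 0,
                               frame_rate = attr(labeled, "frame_rate") %||% 6,
                               bin_s = 60) {
  stopifnot(inherits(labeled, "labeled_windows"))
  inatt <- labeled$label == INATTENTION
  start_s <- (labeled$start - 1) / frame_rate
  keep <- start_s >= trim_s
  bins <- floor(start_s / bin_s) * bin_s
  curve <- do.call(rbind, lapply(split(seq_len(nrow(labeled)), bins), function(i)
    data.frame(bin_start_s = bins[i[1]], fraction = mean(inatt[i]),
               n_windows = length(i))))
  rownames(curve) <- NULL
  list(fraction_whole = mean(inatt),
       fraction_trimmed = if (any(keep)) mean(inatt[keep]) else NA_real_,
       curve = curve)
}

#' Band amplitude vs label diagnostic
#'
#' Per-band mean amplitude in each label class and the standardized mean
#' difference (inattention minus attention over the pooled SD), flagging the
#' band with the largest inattention elevation. On sessions where lapses
#' elevate theta, the flagged band should be theta.
#'
#' @param series A `band_means` object (values bands x T).
#' @param labels Per-frame ATTENTION/INATTENTION vector, length T.
#' @return List with `table` (data frame band, mean_attention,
#'   mean_inattention, std_diff) and `flagged` (band name with max
#'   standardized elevation).
#' @export
band_label_diagnostic <- function(series, labels) {
  stopifnot(inherits(series, "band_means"))
  labels <- as_state_factor(labels)
  v <- series$values
  if (ncol(v) != length(labels))
    stop("labels must align with the series frames")
  if (length(unique(labels)) < 2L)
    stop("both label classes must be present")
  inatt <- labels == INATTENTION
  bn <- rownames(v) %||% paste0("band", seq_len(nrow(v)))
  tab <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    m_a <- mean(v[i, !inatt]); m_i <- mean(v[i, inatt])
    s_a <- stats::var(v[i, !inatt]); s_i <- stats::var(v[i, inatt])
    n_a <- sum(!inatt); n_i <- sum(inatt)
    pooled <- sqrt(((n_a - 1) * s_a + (n_i - 1) * s_i) / (n_a + n_i - 2))
    data.frame(band = bn[i], mean_attention = m_a, mean_inattention = m_i,
               std_diff = if (pooled > 0) (m_i - m_a) / pooled else 0)
  }))
  list(table = tab, flagged = tab$band[which.max(tab$std_diff)])
}

#' Compare attention recovery between alert conditions
#'
#' For each INATTENTION detection in a monitored session, takes the
#' telemetry window of `post_window_s` seconds following the detection and
#' computes its altitude and velocity variance; reports the per-condition
#' means. On a responsive simulant, alerts truncate lapses, so the
#' alert-enabled means should be below the alert-disabled ones.
#'
#' @param enabled,disabled `monitored_session` objects from
#'   [run_closed_loop()] with alerts on and off.
#' @param post_window_s Post-detection window length, seconds (default 10,
#'   mirroring the labeling window).
#' @return Object of class `recovery_report`: data frame with one row per
#'   condition (`condition`, `n_detections`, `mean_var_alt`,
#'   `mean_var_vel`).
#' @export
recovery_compare <- function(enabled, disabled, post_window_s = 10) {
  one <- function(sess, condition) {
    fr <- sess$telemetry$frame_rate
    wlen <- as.integer(round(post_window_s * fr))
    n <- length(sess$telemetry)
    det <- sess$events
    if (nrow(det) == 0L) {
      warning(sprintf("no inattention detections in the %s session", condition))
      return(data.frame(condition = condition, n_detections = 0L,
                        mean_var_alt = NA_real_, mean_var_vel = NA_real_))
    }
    va <- vv <- numeric(0)
    for (f in det$frame) {
      if (f + wlen - 1L > n) next
      idx <- f:(f + wlen - 1L)
      va <- c(va, stats::var(sess$telemetry$altitude_ft[idx]))
      vv <- c(vv, stats::var(sess$telemetry$velocity_kn[idx]))
    }
    data.frame(condition = condition, n_detections = length(va),
               mean_var_alt = mean(va), mean_var_vel = mean(vv))
  }
  out <- rbind(one(enabled, "alert_enabled"), one(disabled, "alert_disabled"))
  structure(out, class = c("recovery_report", "data.frame"),
            post_window_s = post_window_s)
}

#' Paired attention-recovery study
#'
#' Runs `n_reps` paired closed-loop simulations (alert-enabled vs disabled,
#' sharing a per-replicate seed so both conditions face the same stochastic
#' regime) and reports how often the enabled condition achieves lower mean
#' post-detection variance, per telemetry channel.
#'
#' @param detector Trained detector with embedded preprocessing state.
#' @param config A [sim_config()] for the simulated sessions.
#' @param n_reps Number of paired replicates.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param response_latency_s Simulant response latency, seconds.
#' @param post_window_s Post-detection variance window, seconds.
#' @return List with `win_fraction_alt`, `win_fraction_vel`, and `reports`
#'   (per-replicate [recovery_compare()] tables).
#' @export
recovery_study <- function(detector, config, n_reps = 50, seed = 1,
                           response_latency_s = 2, post_window_s = 10) {
  wins_a <- wins_v <- logical(0)
  reports <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s_on <- run_closed_loop(detector, config, alert_enabled = TRUE,
                            response_latency_s = response_latency_s,
                            seed = seed + r)
    s_off <- run_closed_loop(detector, config, alert_enabled = FALSE,
                             response_latency_s = response_latency_s,
                             seed = seed + r)
    rep_r <- suppressWarnings(recovery_compare(s_on, s_off, post_window_s))
    reports[[r]] <- rep_r
    if (all(rep_r$n_detections > 0)) {
      wins_a <- c(wins_a, rep_r$mean_var_alt[1] < rep_r$mean_var_alt[2])
      wins_v <- c(wins_v, rep_r$mean_var_vel[1] < rep_r$mean_var_vel[2])
    }
  }
  list(win_fraction_alt = mean(wins_a), win_fraction_vel = mean(wins_v),
       n_compared = length(wins_a), reports = reports)
}
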