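# Alerting and monitoring: the command converter (detection decision ->
# alert/stay), the stimulus generator contract (visual + auditory,
# dispatched to pluggable sinks), per-cycle device-connection checks, the
# replay monitor loop, and a closed-loop monitored simulation in which an
# alerted simulant recovers attention after a response latency.

#' Convert a detection result into an alert/stay command
#'
#' INATTENTION maps to `ALERT`, ATTENTION to `STAY`; the mapping is total
#' and deterministic.
#'
#' @param result A one-row data frame from [classify_window()], or a bare
#'   decision (factor/character).
#' @return `"ALERT"` or `"STAY"`.
#' @export
convert_command <- function(result) {
  decision <- if (is.data.frame(result)) result$decision else result
  decision <- as.character(decision)
  if (length(decision) != 1L || !decision %in% attention_levels())
    stop("result must carry a single ATTENTION/INATTENTION decision")
  if (decision == INATTENTION) "ALERT" else "STAY"
}

#' Stimulus sinks
#'
#' An alert sink is a function taking one alert event. `log_sink()` appends
#' events to an environment (the default, fully testable delivery target);
#' `terminal_sink()` approximates a cockpit alert with a terminal bell and an
#' inverse-video flash line.
#'
#' @param store Environment used by `log_sink` to accumulate `$events`.
#' @return A sink function.
#' @export
log_sink <- function(store = new.env(parent = emptyenv())) {
  store$events <- list()
  f <- function(event) store$events[[length(store$events) + 1L]] <- event
  attr(f, "store") <- store
  f
}

#' @rdname log_sink
#' @export
terminal_sink <- function() {
  function(event) {
    cat(sprintf("\a\033[7m ALERT t=%.1fs stimuli=%s \033[0m\n",
                event$time_s, paste(event$stimuli, collapse = "+")))
  }
}

#' Emit an alert for a command
#'
#' An `ALERT` command produces one alert event carrying both stimuli
#' (visual and auditory, delivered simultaneously) and dispatches it to
#' every sink; `STAY` produces nothing. A failing sink is reported as a
#' warning but never interrupts monitoring.
#'
#' @param command `"ALERT"` or `"STAY"` from [convert_command()].
#' @param time_s Event timestamp in seconds.
#' @param sinks List of sink functions (default: none).
#' @param duration_s Stimulus duration descriptor, seconds.
#' @return The alert event (list with `time_s`, `stimuli`, `duration_s`), or
#'   `NULL` for `STAY`.
#' @export
emit_alert <- function(command, time_s = NA_real_, sinks = list(),
                       duration_s = 1) {
  if (!command %in% c("ALERT", "STAY")) stop("command must be ALERT or STAY")
  if (command == "STAY") return(invisible(NULL))
  event <- list(time_s = time_s, stimuli = c("VISUAL", "AUDITORY"),
                duration_s = duration_s)
  for (s in sinks) {
    tryCatch(s(event), error = function(e)
      warning(sprintf("alert sink failed (%s); monitoring continues",
                      conditionMessage(e))))
  }
  invisible(event)
}

#' Check the acquisition-device connection
#'
#' Normalizes a per-cycle quality value to OK/POOR. A missing value (absent
#' feed) is treated as POOR, the fail-safe choice for a device check.
#'
#' @param status `"OK"`, `"POOR"`, `TRUE`/`FALSE`, or `NA`/`NULL`.
#' @return `"OK"` or `"POOR"`.
#' @export
check_connection <- function(status) {
  if (is.null(status) || length(status) != 1L || is.na(status)) return("POOR")
  if (isTRUE(status) || identical(toupper(as.character(status)), "OK")) "OK" else "POOR"
}

#' Replay a session through the monitoring loop
#'
#' Runs the real-time loop over a recorded feature stream: every cycle (one
#' window step) the device connection is checked; if OK the most recent
#' window of feature vectors is classified, the decision converted to a
#' command, and an alert emitted on INATTENTION. A POOR connection logs a
#' manual-adjustment request instead of a decision. The monitor never
#' mutates the detector, and a replay of the same inputs yields an
#' identical log.
#'
#' @param features Feature matrix (frames x n_p) at `frame_rate`.
#' @param detector A trained [train_detector()] model.
#' @param w,step Window length and cycle step in frames (defaults 60 / 6).
#' @param frame_rate Frames per second (default 6).
#' @param connection Per-cycle quality feed, recycled (`"OK"` default);
#'   `NULL` means no feed at all and every cycle is treated as POOR.
#' @param sinks List of alert sinks (see [log_sink()]).
#' @param refractory_s Minimum seconds between emitted alert events; 0
#'   (default) alerts on every INATTENTION decision.
#' @return Object of class `monitor_state`: list with `log` (one row per
#'   cycle), `events` (alert events data frame), `n_cycles`.
#' @export
run_monitor <- function(features, detector, w = 60, step = 6, frame_rate = 6,
                        connection = "OK", sinks = list(),
                        refractory_s = 0) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < w) {
    warning("stream shorter than one window; empty monitor log")
    return(structure(list(log = data.frame(), events = data.frame(),
                          n_cycles = 0L), class = "monitor_state"))
  }
  ends <- seq.int(w, n, by = step)
  n_cyc <- length(ends)
  feed <- if (is.null(connection)) rep(NA_character_, n_cyc)
          else rep_len(as.character(connection), n_cyc)
  logs <- vector("list", n_cyc)
  events <- list()
  last_alert <- -Inf
  for (k in seq_len(n_cyc)) {
    e <- ends[k]
    t_s <- e / frame_rate
    conn <- check_connection(feed[k])
    if (conn == "POOR") {
      logs[[k]] <- data.frame(cycle = k, time_s = t_s, connection = conn,
                              decision = NA_character_, command = NA_character_,
                              alert = FALSE, adjustment_requested = TRUE)
      next
    }
    res <- classify_window(detector, features[(e - w + 1L):e, , drop = FALSE])
    cmd <- convert_command(res)
    fired <- FALSE
    if (cmd == "ALERT" && t_s - last_alert >= refractory_s) {
      ev <- emit_alert(cmd, time_s = t_s, sinks = sinks)
      events[[length(events) + 1L]] <- data.frame(cycle = k, time_s = t_s,
                                                  stimuli = "VISUAL+AUDITORY")
      last_alert <- t_s
      fired <- TRUE
    }
    logs[[k]] <- data.frame(cycle = k, time_s = t_s, connection = conn,
                            decision = as.character(res$decision),
                            command = cmd, alert = fired,
                            adjustment_requested = FALSE)
  }
  structure(list(log = do.call(rbind, logs),
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(cycle = integer(), time_s = numeric(),
                                          stimuli = character()),
                 n_cycles = n_cyc),
            class = "monitor_state")
}

#' @export
print.monitor_state <- function(x, ...) {
  cat(sprintf("<monitor_state> %d cycles, %d decisions, %d alerts\n",
              x$n_cycles, sum(!is.na(x$log$decision)), nrow(x$events)))
  invisible(x)
}

#' Closed-loop monitored simulation with a responsive simulant
#'
#' Generates a synthetic session frame by frame while running the full
#' detection pipeline on the growing stream: raw EEG is synthesized from the
#' evolving attention state, band amplitudes are computed by the sliding
#' 1 s FFT, normalized with the detector's stored statistics, tracked by the
#' detector's AAR configuration, projected with its PCA model, and the
#' two-HMM detector classifies each window step. When `alert_enabled` and an
#' INATTENTION decision fires, the simulated operator responds: an ongoing
#' inattention episode is truncated `response_latency_s` seconds after the
#' alert. With `alert_enabled = FALSE` the identical machinery runs but
#' alerts have no effect, giving the matched control condition for
#' attention-recovery comparisons.
#'
#' The detector must carry `norm_stats`, `pca`, and `aar` (as produced by
#' [run_pipeline()]). Band-frame `t` is only computable once the raw window
#' starting at frame `t` is complete, so decisions lag the state by about
#' one FFT window.
#'
#' @param detector Trained [train_detector()] with embedded preprocessing.
#' @param config A [sim_config()] describing the session to generate.
#' @param alert_enabled Whether alerts reach the simulant.
#' @param response_latency_s Seconds between an alert and the simulant's
#'   recovery of attention (default 2).
#' @param seed Integer seed for the whole closed loop.
#' @param w,step Window length / cycle step in frames.
#' @param return_internals Keep the generated raw EEG, band means, and
#'   feature stream in the result (for validation).
#' @return Object of class `monitored_session`: `telemetry`, `true_state`,
#'   `decisions` (per-cycle data frame with `frame` = decision frame),
#'   `events` (alerts), `alert_enabled`.
#' @export
run_closed_loop <- function(detector, config, alert_enabled = TRUE,
                            response_latency_s = 2, seed = NULL,
                            w = 60, step = 6, return_internals = FALSE) {
  stopifnot(inherits(detector, "hmm_detector"), inherits(config, "sim_config"))
  if (is.null(detector$norm_stats) || is.null(detector$pca) || is.null(detector$aar))
    stop("detector must embed norm_stats, pca, and aar state for streaming use")
  fr <- config$frame_rate
  fs <- config$raw_rate
  hop <- as.integer(fs / fr)
  win <- fs  # 1 s FFT window
  n_frames <- as.integer(round(config$duration_s * fr))
  n_ch <- length(config$channel_names)
  lat_frames <- as.integer(round(response_latency_s * fr))
  p_exit <- 1 / (config$state_dwell_mean_s * fr)
  centers <- band_centers()
  n_b <- length(centers)
  a1 <- a2 <- amp_sc <- numeric(n_b)
  for (b in seq_len(n_b)) {
    co <- ar2_coeffs(centers[[b]], fs, config$osc_pole_radius)
    a1[b] <- co[["a1"]]; a2[b] <- co[["a2"]]
    amp_sc[b] <- config$band_amplitude_uv[[names(centers)[b]]] /
      ar2_stationary_sd(co[["a1"]], co[["a2"]])
  }
  theta_row <- which(names(centers) == "theta")
  # FFT band bins (same convention as decompose_bands)
  freqs <- (seq_len(win) - 1L) * fs / win
  bin_sets <- lapply(default_bands(), function(b) which(freqs >= b[1] & freqs < b[2]))
  ns <- detector$norm_stats
  aar_cfg <- detector$aar
  n_c <- aar_cfg$n_c
  lam <- aar_cfg$forgetting_factor
  with_seed(seed, {
    # mutable state
    prev1 <- prev2 <- matrix(0, n_b, n_ch)
    raw <- matrix(0, n_frames * hop, n_ch)
    state <- factor(rep(ATTENTION, n_frames), levels = attention_levels())
    cur <- "attention"
    draw_sojourn <- function(s) {
      p <- p_exit[[s]]
      if (p <= 0) .Machine$integer.max else stats::rgeom(1L, p) + 1L
    }
    remain <- draw_sojourn(cur)
    alt <- vel <- numeric(n_frames)
    dev_a <- dev_v <- 0
    phi <- config$telemetry_reversion
    nb <- matrix(NA_real_, n_b, n_frames)       # normalized band means
    rls_c <- matrix(rep(aar_cfg$init_coeffs, n_b), nrow = n_b, byrow = TRUE)
    rls_P <- lapply(seq_len(n_b), function(i) diag(aar_cfg$init_covariance_scale, n_c))
    feats <- matrix(NA_real_, n_frames, detector$pca$n_p)
    decisions <- list()
    events <- list()
    force_at <- NA_integer_
    max_band_frame <- (n_frames * hop - win) %/% hop + 1L
    for (g in seq_len(n_frames)) {
      # simulant state update (alert response may truncate an episode)
      if (!is.na(force_at) && g >= force_at) {
        if (cur == "inattention") {
          cur <- "attention"
          remain <- draw_sojourn(cur)
        }
        force_at <- NA_integer_
      }
      if (remain <= 0L) {
        cur <- if (cur == "attention") "inattention" else "attention"
        remain <- draw_sojourn(cur)
      }
      state[g] <- if (cur == "attention") ATTENTION else INATTENTION
      remain <- remain - 1L
      # telemetry
      sd_set <- config$telemetry_noise_sd[[cur]]
      dev_a <- phi * dev_a + stats::rnorm(1) * sd_set[["altitude"]]
      dev_v <- phi * dev_v + stats::rnorm(1) * sd_set[["velocity"]]
      alt[g] <- config$telemetry_targets[["altitude"]] + dev_a
      vel[g] <- config$telemetry_targets[["velocity"]] + dev_v
      # raw EEG for this frame
      gain <- rep(1, n_b)
      if (cur == "inattention") gain[theta_row] <- config$theta_gain
      base <- (g - 1L) * hop
      for (s in seq_len(hop)) {
        osc <- a1 * prev1 + a2 * prev2 +
          matrix(stats::rnorm(n_b * n_ch), n_b, n_ch)
        prev2 <- prev1
        prev1 <- osc
        raw[base + s, ] <- colSums(osc * (amp_sc * gain)) +
          stats::rnorm(n_ch, sd = config$noise_sd_uv)
      }
      # newest computable band frame
      t_band <- g - (win %/% hop) + 1L
      if (t_band >= 1L && t_band <= max_band_frame) {
        seg <- raw[((t_band - 1L) * hop + 1L):((t_band - 1L) * hop + win), ,
                   drop = FALSE]
        amp <- 2 * Mod(stats::mvfft(seg)) / win
        bm <- vapply(bin_sets, function(bs)
          mean(rowMeans(amp[bs, , drop = FALSE])), numeric(1))
        nb[, t_band] <- (bm - ns$center) / ns$scale
        # AAR step
        frame_c <- numeric(n_b * n_c)
        for (b in seq_len(n_b)) {
          if (t_band > n_c) {
            x <- nb[b, (t_band - 1L):(t_band - n_c)]
            err <- nb[b, t_band] - sum(rls_c[b, ] * x)
            Px <- rls_P[[b]] %*% x
            k <- Px / (lam + sum(x * Px))
            cand_c <- rls_c[b, ] + as.numeric(k) * err
            cand_P <- (rls_P[[b]] + t(rls_P[[b]]) - k %*% t(Px) - Px %*% t(k)) /
              (2 * lam)
            if (all(is.finite(cand_c)) && all(is.finite(cand_P))) {
              rls_c[b, ] <- cand_c
              rls_P[[b]] <- cand_P
            } else {
              rls_P[[b]] <- diag(aar_cfg$init_covariance_scale, n_c)
            }
          }
          frame_c[((b - 1L) * n_c + 1L):(b * n_c)] <- rls_c[b, ]
        }
        feats[t_band, ] <- project_features(detector$pca, frame_c)
        # monitoring cycle on window boundaries
        if (t_band >= w && (t_band - w) %% step == 0L) {
          res <- classify_window(detector,
                                 feats[(t_band - w + 1L):t_band, , drop = FALSE])
          decisions[[length(decisions) + 1L]] <-
            cbind(data.frame(frame = g, band_frame = t_band,
                             time_s = g / fr), res)
          if (res$decision == INATTENTION) {
            events[[length(events) + 1L]] <-
              data.frame(frame = g, time_s = g / fr)
            if (alert_enabled && is.na(force_at))
              force_at <- g + lat_frames
          }
        }
      }
    }
    structure(list(
      telemetry = telemetry_trace(alt, vel, fr),
      true_state = structure(state, frame_rate = fr),
      decisions = if (length(decisions)) do.call(rbind, decisions)
                  else data.frame(),
      events = if (length(events)) do.call(rbind, events) else data.frame(),
      alert_enabled = alert_enabled,
      response_latency_s = response_latency_s,
      config = config, seed = seed,
      internals = if (return_internals)
        list(raw = raw, features = feats, band_means = nb) else NULL),
      class = "monitored_session")
  })
}

#' @export
print.monitored_session <- function(x, ...) {
  cat(sprintf("<monitored_session> %d frames, %d decisions, %d inattention detections, alerts %s\n",
              length(x$true_state), nrow(x$decisions), nrow(x$events),
              if (x$alert_enabled) "ENABLED" else "disabled"))
  invisible(x)
}
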