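# Synthetic session generator: a two-state attention process driving (a) a
# 14-channel EEG-like signal whose theta-band amplitude is elevated during
# inattention and (b) flight telemetry whose variance inflates during
# inattention. Stands in for a headset + flight simulator when no recordings
# are available.

#' Default EEG channel montage
#'
#' The 14 scalp positions of the consumer headset emulated by the simulator,
#' following the international 10-20 layout.
#'
#' @return Character vector of 14 channel labels.
#' @export
default_channels <- function() {
  c("AF3", "AF4", "F3", "F4", "F7", "F8", "FC5", "FC6",
    "P7", "P8", "T7", "T8", "O1", "O2")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-session generator. Defaults encode the
#' emulated study conditions: a 6 Hz frame rate, 14 channels, altitude /
#' velocity targets of 6500 ft and 250 knots, attention dwell ~100 s vs
#' inattention dwell ~25 s (long-run inattention fraction 0.2), a 3x theta
#' amplitude elevation during inattention, and a 5x telemetry noise ratio.
#'
#' @param duration_s Session length in seconds.
#' @param raw_rate Raw EEG sampling rate in Hz; must be an integer multiple of
#'   `frame_rate`. 120 Hz keeps the 6 Hz hop integral (20 samples).
#' @param frame_rate Output frame rate of band amplitudes and telemetry, Hz.
#' @param channel_names EEG channel labels (length defines channel count).
#' @param state_dwell_mean_s Named numeric, mean sojourn seconds for
#'   `attention` and `inattention`; `Inf` pins the process in its start state.
#' @param theta_gain Multiplicative theta-amplitude factor during inattention,
#'   must be >= 1 (1 = no state effect).
#' @param band_amplitude_uv Named numeric, stationary RMS amplitude (micro-
#'   volts) of the delta/theta/alpha/beta oscillators per channel.
#' @param noise_sd_uv SD of additive white measurement noise, microvolts.
#' @param osc_pole_radius AR(2) pole radius of the band oscillators in (0,1);
#'   closer to 1 means narrower band.
#' @param telemetry_targets Named numeric: `altitude` (feet), `velocity`
#'   (knots) the simulated operator tries to hold.
#' @param telemetry_noise_sd List with elements `attention`, `inattention`,
#'   each a named numeric `(altitude, velocity)` of innovation SDs. The
#'   inattention SDs must be at least the attention SDs (degradation built in).
#' @param telemetry_reversion Mean-reversion AR(1) coefficient in [0,1).
#' @param seed Integer master seed used by [simulate_session()].
#' @return Object of class `sim_config` (a validated list).
#' @seealso [simulate_session()], [sample_state_path()]
#' @export
sim_config <- function(duration_s = 1800,
                       raw_rate = 120,
                       frame_rate = 6,
                       channel_names = default_channels(),
                       state_dwell_mean_s = c(attention = 100, inattention = 25),
                       theta_gain = 3,
                       band_amplitude_uv = c(delta = 20, theta = 10, alpha = 15, beta = 8),
                       noise_sd_uv = 5,
                       osc_pole_radius = 0.97,
                       telemetry_targets = c(altitude = 6500, velocity = 250),
                       telemetry_noise_sd = list(
                         attention = c(altitude = 5, velocity = 1),
                         inattention = c(altitude = 25, velocity = 5)),
                       telemetry_reversion = 0.98,
                       seed = NULL) {
  stopifnot_scalar(duration_s, "duration_s")
  stopifnot_scalar(raw_rate, "raw_rate")
  stopifnot_scalar(frame_rate, "frame_rate")
  if (raw_rate %% frame_rate != 0)
    stop("raw_rate must be an integer multiple of frame_rate")
  if (!is.character(channel_names) || length(channel_names) < 1L)
    stop("channel_names must be a non-empty character vector")
  dw <- state_dwell_mean_s
  if (!all(c("attention", "inattention") %in% names(dw)))
    stop("state_dwell_mean_s needs named entries 'attention' and 'inattention'")
  if (any(dw <= 0)) stop("dwell means must be positive")
  if (!is.numeric(theta_gain) || theta_gain < 1)
    stop("theta_gain must be >= 1")
  if (!all(c("delta", "theta", "alpha", "beta") %in% names(band_amplitude_uv)))
    stop("band_amplitude_uv needs delta/theta/alpha/beta entries")
  if (any(band_amplitude_uv < 0) || noise_sd_uv < 0)
    stop("amplitudes and noise SD must be non-negative")
  if (osc_pole_radius <= 0 || osc_pole_radius >= 1)
    stop("osc_pole_radius must lie in (0,1)")
  att <- telemetry_noise_sd$attention
  ina <- telemetry_noise_sd$inattention
  if (is.null(att) || is.null(ina) ||
      !all(c("altitude", "velocity") %in% names(att)) ||
      !all(c("altitude", "velocity") %in% names(ina)))
    stop("telemetry_noise_sd needs $attention and $inattention, each with altitude and velocity")
  if (any(att < 0) || any(ina < 0)) stop("telemetry noise SDs must be non-negative")
  if (any(ina[c("altitude", "velocity")] < att[c("altitude", "velocity")]))
    stop("inattention telemetry noise SDs must not be smaller than attention SDs")
  if (telemetry_reversion < 0 || telemetry_reversion >= 1)
    stop("telemetry_reversion must lie in [0,1)")
  structure(list(
    duration_s = duration_s, raw_rate = raw_rate, frame_rate = frame_rate,
    channel_names = channel_names, state_dwell_mean_s = dw,
    theta_gain = theta_gain, band_amplitude_uv = band_amplitude_uv,
    noise_sd_uv = noise_sd_uv, osc_pole_radius = osc_pole_radius,
    telemetry_targets = telemetry_targets, telemetry_noise_sd = telemetry_noise_sd,
    telemetry_reversion = telemetry_reversion, seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %gs @ %g Hz frames (%g Hz raw), %d channels\n",
              x$duration_s, x$frame_rate, x$raw_rate, length(x$channel_names)))
  cat(sprintf("  dwell att/inatt: %g/%g s; theta_gain %g; telem SD ratio %g (alt)\n",
              x$state_dwell_mean_s[["attention"]], x$state_dwell_mean_s[["inattention"]],
              x$theta_gain,
              x$telemetry_noise_sd$inattention[["altitude"]] /
                max(x$telemetry_noise_sd$attention[["altitude"]], .Machine$double.eps)))
  invisible(x)
}

#' Sample an attention/inattention state path
#'
#' Draws an alternating-renewal sequence at the frame rate. Sojourn lengths in
#' each state are geometric with mean `dwell_s * frame_rate` frames, i.e. the
#' path is a two-state first-order Markov chain. The path starts in ATTENTION.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (NULL = use current RNG stream).
#' @return Factor of length `duration_s * frame_rate` with levels
#'   `ATTENTION`, `INATTENTION` and attribute `frame_rate`.
#' @export
sample_state_path <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(round(config$duration_s * config$frame_rate))
  if (n < 1L) stop("duration too short for one frame")
  # per-frame exit probability of each state; Inf dwell -> absorbing
  p_exit <- 1 / (config$state_dwell_mean_s * config$frame_rate)
  with_seed(seed, {
    states <- character(n)
    cur <- "attention"
    t <- 1L
    while (t <= n) {
      p <- p_exit[[cur]]
      len <- if (p <= 0) n - t + 1L else stats::rgeom(1L, p) + 1L
      len <- min(len, n - t + 1L)
      states[t:(t + len - 1L)] <- if (cur == "attention") ATTENTION else INATTENTION
      t <- t + len
      cur <- if (cur == "attention") "inattention" else "attention"
    }
    structure(factor(states, levels = attention_levels()),
              frame_rate = config$frame_rate)
  })
}

# Closed-form stationary SD of an AR(2) process with unit-variance innovations.
ar2_stationary_sd <- function(a1, a2) {
  g0 <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  sqrt(g0)
}

# AR(2) coefficients for a resonator at f0 Hz sampled at fs with pole radius r.
ar2_coeffs <- function(f0, fs, r) {
  th <- 2 * pi * f0 / fs
  c(a1 = 2 * r * cos(th), a2 = -r^2)
}

# Center frequencies of the four conventional bands (midpoints of the
# default Hz ranges used by decompose_bands()).
band_centers <- function() c(delta = 3, theta = 6, alpha = 10.5, beta = 21.5)

#' Synthesize raw multichannel EEG for a given state path
#'
#' Each channel is the sum of four band-limited stochastic oscillations
#' (AR(2) resonators at the delta/theta/alpha/beta center frequencies, scaled
#' to the configured stationary RMS amplitude) plus white measurement noise.
#' During INATTENTION frames the theta oscillation is multiplied by
#' `theta_gain`, emulating the theta-band elevation that accompanies lapses
#' of attention; the other bands are state-independent.
#'
#' @param state_path Factor from [sample_state_path()] at the frame rate.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A [raw_eeg()] record at `config$raw_rate` Hz, units microvolts.
#' @export
synthesize_eeg <- function(state_path, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_frames <- length(state_path)
  hop <- config$raw_rate / config$frame_rate
  n_raw <- n_frames * hop
  n_ch <- length(config$channel_names)
  centers <- band_centers()
  amps <- config$band_amplitude_uv[names(centers)]
  r <- config$osc_pole_radius
  # theta modulation mask at raw rate
  gain_raw <- rep(ifelse(state_path == INATTENTION, config$theta_gain, 1),
                  each = hop)
  with_seed(seed, {
    data <- matrix(0, nrow = n_raw, ncol = n_ch)
    for (j in seq_len(n_ch)) {
      x <- numeric(n_raw)
      for (b in names(centers)) {
        a <- ar2_coeffs(centers[[b]], config$raw_rate, r)
        innov <- stats::rnorm(n_raw)
        osc <- stats::filter(innov, filter = a, method = "recursive")
        osc <- as.numeric(osc) / ar2_stationary_sd(a[["a1"]], a[["a2"]])
        osc <- osc * amps[[b]]
        if (b == "theta") osc <- osc * gain_raw
        x <- x + osc
      }
      if (config$noise_sd_uv > 0)
        x <- x + stats::rnorm(n_raw, sd = config$noise_sd_uv)
      data[, j] <- x
    }
    raw_eeg(data, sample_rate = config$raw_rate,
            channel_names = config$channel_names)
  })
}

#' Synthesize flight telemetry for a given state path
#'
#' Altitude and velocity follow mean-reverting AR(1) walks around the targets
#' (6500 ft / 250 kn by default) whose innovation SD switches with the
#' attention state, so windowed telemetry variance is stochastically larger
#' in inattention stretches.
#'
#' @inheritParams synthesize_eeg
#' @return A [telemetry_trace()] at the frame rate.
#' @export
synthesize_telemetry <- function(state_path, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(state_path)
  phi <- config$telemetry_reversion
  tg <- config$telemetry_targets
  sd_att <- config$telemetry_noise_sd$attention
  sd_ina <- config$telemetry_noise_sd$inattention
  inatt <- state_path == INATTENTION
  with_seed(seed, {
    out <- list()
    for (ch in c("altitude", "velocity")) {
      sds <- ifelse(inatt, sd_ina[[ch]], sd_att[[ch]])
      eps <- stats::rnorm(n) * sds
      x <- numeric(n)
      dev <- 0
      for (t in seq_len(n)) {
        dev <- phi * dev + eps[t]
        x[t] <- tg[[ch]] + dev
      }
      out[[ch]] <- x
    }
    telemetry_trace(out$altitude, out$velocity, frame_rate = config$frame_rate)
  })
}

#' Simulate a complete synthetic session
#'
#' Draws the state path, raw EEG, and telemetry from one seeded RNG stream.
#'
#' @param config A [sim_config()]; its `seed` (or the `seed` argument) makes
#'   the whole session reproducible.
#' @param seed Optional override of `config$seed`.
#' @return Object of class `synthetic_session`: list with `raw_eeg`,
#'   `telemetry`, `true_state`, and `config`.
#' @examples
#' s <- simulate_session(sim_config(duration_s = 30, seed = 1))
#' table(s$true_state)
#' @export
simulate_session <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  with_seed(seed, {
    st <- sample_state_path(config)
    ee <- synthesize_eeg(st, config)
    tl <- synthesize_telemetry(st, config)
    structure(list(raw_eeg = ee, telemetry = tl, true_state = st,
                   config = config),
              class = "synthetic_session")
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d frames @ %g Hz, %d raw samples, inattention %.1f%%\n",
              length(x$true_state), x$config$frame_rate, nrow(x$raw_eeg$data),
              100 * mean(x$true_state == INATTENTION)))
  invisible(x)
}
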