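# Signal processing: raw multichannel EEG -> band-pass -> sliding-window FFT
# band amplitudes e[i,j,t] -> channel means -> per-band normalization ->
# start-trimming. The 4 bands x 14 channels give the 56 per-frame properties
# the detector pipeline is built on.

#' Raw EEG record
#'
#' @param data Numeric matrix, time x channel, microvolts.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_names Channel labels, one per column.
#' @param start_time Time of the first sample, seconds.
#' @return Object of class `raw_eeg`.
#' @export
raw_eeg <- function(data, sample_rate, channel_names = colnames(data),
                    start_time = 0) {
  data <- as.matrix(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(data)))
  if (ncol(data) != length(channel_names))
    stop("data must have exactly one column per channel name")
  stopifnot_scalar(sample_rate, "sample_rate")
  colnames(data) <- channel_names
  structure(list(data = data, sample_rate = sample_rate,
                 channel_names = channel_names, start_time = start_time),
            class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate))
  invisible(x)
}

#' Flight telemetry trace
#'
#' Altitude (feet) and velocity (knots) sampled at the EEG frame rate; the
#' "performance values" whose windowed variance defines inattention labels.
#'
#' @param altitude_ft,velocity_kn Equal-length numeric vectors.
#' @param frame_rate Sampling rate in Hz.
#' @return Object of class `telemetry_trace`.
#' @export
telemetry_trace <- function(altitude_ft, velocity_kn, frame_rate) {
  if (length(altitude_ft) != length(velocity_kn))
    stop("altitude and velocity must have equal length")
  if (!all(is.finite(altitude_ft)) || !all(is.finite(velocity_kn)))
    stop("telemetry values must be finite")
  structure(list(altitude_ft = as.numeric(altitude_ft),
                 velocity_kn = as.numeric(velocity_kn),
                 frame_rate = frame_rate),
            class = "telemetry_trace")
}

#' @export
length.telemetry_trace <- function(x) length(x$altitude_ft)

#' @export
print.telemetry_trace <- function(x, ...) {
  cat(sprintf("<telemetry_trace> %d frames @ %g Hz; alt %.0f+-%.1f ft, vel %.0f+-%.1f kn\n",
              length(x), x$frame_rate,
              mean(x$altitude_ft), stats::sd(x$altitude_ft),
              mean(x$velocity_kn), stats::sd(x$velocity_kn)))
  invisible(x)
}

#' Conventional EEG band ranges
#'
#' Hz ranges used to pool FFT bins into the four band amplitudes, clipped to
#' the 2-42 Hz analysis pass-band: delta 2-4, theta 4-8, alpha 8-13,
#' beta 13-30. Bins are assigned half-open, `low <= f < high`.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
default_bands <- function() {
  list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Band-pass filter a raw EEG record
#'
#' Zero-phase (forward-backward) Butterworth band-pass, applied per channel.
#' Removes DC and out-of-band content before band decomposition.
#'
#' @param raw A [raw_eeg()] record.
#' @param low,high Band edges in Hz (defaults 2 and 42).
#' @param order Butterworth prototype order (the band-pass doubles it).
#' @return Filtered [raw_eeg()] of the same shape.
#' @export
bandpass_eeg <- function(raw, low = 2, high = 42, order = 4) {
  stopifnot(inherits(raw, "raw_eeg"))
  nyq <- raw$sample_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < sample_rate/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- apply(raw$data, 2, function(x) signal::filtfilt(bf, x))
  raw_eeg(out, raw$sample_rate, raw$channel_names, raw$start_time)
}

#' Decompose raw EEG into per-band, per-channel amplitudes
#'
#' Sliding-window FFT: a rectangular window of `window_s` seconds advances by
#' `sample_rate / frame_rate` samples; within each window the single-sided
#' amplitude spectrum (2|X_k|/N, microvolts) is averaged over the bins falling
#' in each band's Hz range. Produces the band tensor `e[i, j, t]` (band x
#' channel x frame) at the frame rate.
#'
#' @param raw A [raw_eeg()] record (normally already band-passed).
#' @param frame_rate Output frame rate, Hz; must divide `sample_rate`.
#' @param window_s FFT window length in seconds (default 1).
#' @param bands Named list of Hz ranges, see [default_bands()].
#' @return Object of class `band_series`: list with `values` (4 x channels x
#'   T array), `frame_rate`, `bands`.
#' @export
decompose_bands <- function(raw, frame_rate = 6, window_s = 1,
                            bands = default_bands()) {
  stopifnot(inherits(raw, "raw_eeg"))
  fs <- raw$sample_rate
  if (fs %% frame_rate != 0) stop("sample_rate must be divisible by frame_rate")
  win <- as.integer(round(window_s * fs))
  hop <- as.integer(fs / frame_rate)
  n <- nrow(raw$data)
  if (n < win) stop("record shorter than one FFT window; no frames to emit")
  n_frames <- (n - win) %/% hop + 1L
  freqs <- (seq_len(win) - 1L) * fs / win
  bin_sets <- lapply(bands, function(b) which(freqs >= b[1] & freqs < b[2]))
  if (any(vapply(bin_sets, length, 1L) == 0L))
    stop("a band contains no FFT bins at this window length")
  vals <- array(0, dim = c(length(bands), ncol(raw$data), n_frames),
                dimnames = list(names(bands), raw$channel_names, NULL))
  for (t in seq_len(n_frames)) {
    seg <- raw$data[((t - 1L) * hop + 1L):((t - 1L) * hop + win), , drop = FALSE]
    amp <- 2 * Mod(stats::mvfft(seg)) / win
    for (i in seq_along(bin_sets)) {
      bs <- bin_sets[[i]]
      vals[i, , t] <- if (length(bs) == 1L) amp[bs, ] else colMeans(amp[bs, , drop = FALSE])
    }
  }
  structure(list(values = vals, frame_rate = frame_rate, bands = bands),
            class = "band_series")
}

#' @export
print.band_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<band_series> %d bands x %d channels x %d frames @ %g Hz (%d properties/frame)\n",
              d[1], d[2], d[3], x$frame_rate, d[1] * d[2]))
  invisible(x)
}

#' Average band amplitudes across channels
#'
#' Collapses the band tensor to one value per band and frame by the
#' arithmetic mean over channels, yielding the channel-mean series the AAR
#' features are computed from.
#'
#' @param bands A `band_series` from [decompose_bands()].
#' @return Object of class `band_means`: list with `values` (bands x T
#'   matrix), `frame_rate`, and `stats` (NULL until [normalize_bands()]).
#' @export
average_channels <- function(bands) {
  stopifnot(inherits(bands, "band_series"))
  vals <- apply(bands$values, c(1, 3), mean)
  structure(list(values = vals, frame_rate = bands$frame_rate, stats = NULL),
            class = "band_means")
}

#' @export
print.band_means <- function(x, ...) {
  cat(sprintf("<band_means> %d bands x %d frames @ %g Hz%s\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              if (is.null(x$stats)) "" else " (normalized)"))
  invisible(x)
}

#' Per-band z-score normalization
#'
#' Standardizes each band row to mean 0 / SD 1 (sample SD). When `stats` is
#' omitted they are computed from `series` and stored in the result for reuse,
#' so a model fitted on training data can be applied to held-out or streaming
#' data without peeking at its statistics (train-fit, test-apply contract).
#'
#' @param series A `band_means` object.
#' @param stats Optional list with `center` and `scale` (named per band), as
#'   returned in a previous result's `$stats`.
#' @return Normalized `band_means` with `$stats` filled in.
#' @export
normalize_bands <- function(series, stats = NULL) {
  stopifnot(inherits(series, "band_means"))
  v <- series$values
  bn <- rownames(v) %||% paste0("band", seq_len(nrow(v)))
  rownames(v) <- bn
  if (is.null(stats)) {
    ctr <- apply(v, 1, mean)
    scl <- apply(v, 1, stats::sd)
    if (any(scl == 0)) {
      bad <- bn[scl == 0]
      stop(sprintf("band(s) %s have zero variance; cannot normalize",
                   paste(bad, collapse = ", ")))
    }
    stats <- list(center = ctr, scale = scl)
  } else {
    if (is.null(stats$center) || is.null(stats$scale))
      stop("stats must contain 'center' and 'scale'")
    if (length(stats$center) != nrow(v) || length(stats$scale) != nrow(v))
      stop("stats must provide one center/scale per band")
  }
  # align by band name when names are present, else by position
  ctr <- if (is.null(names(stats$center))) stats$center else stats$center[bn]
  scl <- if (is.null(names(stats$scale))) stats$scale else stats$scale[bn]
  out <- (v - ctr) / scl
  structure(list(values = out, frame_rate = series$frame_rate, stats = stats),
            class = "band_means")
}

#' Trim the unstable start of a session
#'
#' Drops the first `trim_s` seconds of frames. Telemetry fluctuates strongly
#' at the beginning of a flight for reasons unrelated to attention, so the
#' opening stretch of EEG frames, telemetry, and label sequences is removed
#' consistently before labeling.
#'
#' @param x A `band_means`, `band_series`, `telemetry_trace`, or a plain
#'   vector/factor (then `frame_rate` is required, or taken from the
#'   `frame_rate` attribute).
#' @param trim_s Seconds to drop (>= 0).
#' @param ... Passed to methods.
#' @return Object of the same type, shortened.
#' @export
trim_start <- function(x, trim_s, ...) UseMethod("trim_start")

trim_frames <- function(n_total, trim_s, frame_rate) {
  if (trim_s < 0) stop("trim_s must be >= 0")
  n_drop <- as.integer(round(trim_s * frame_rate))
  if (n_drop >= n_total)
    stop(sprintf("trim of %g s removes all %d frames", trim_s, n_total))
  n_drop
}

#' @rdname trim_start
#' @export
trim_start.band_means <- function(x, trim_s, ...) {
  nd <- trim_frames(ncol(x$values), trim_s, x$frame_rate)
  if (nd == 0L) return(x)
  x$values <- x$values[, -(seq_len(nd)), drop = FALSE]
  x
}

#' @rdname trim_start
#' @export
trim_start.band_series <- function(x, trim_s, ...) {
  nd <- trim_frames(dim(x$values)[3], trim_s, x$frame_rate)
  if (nd == 0L) return(x)
  x$values <- x$values[, , -(seq_len(nd)), drop = FALSE]
  x
}

#' @rdname trim_start
#' @export
trim_start.telemetry_trace <- function(x, trim_s, ...) {
  nd <- trim_frames(length(x), trim_s, x$frame_rate)
  if (nd == 0L) return(x)
  telemetry_trace(x$altitude_ft[-seq_len(nd)], x$velocity_kn[-seq_len(nd)],
                  x$frame_rate)
}

#' @rdname trim_start
#' @param frame_rate Frames per second of `x` (default methods only).
#' @export
trim_start.default <- function(x, trim_s, frame_rate = attr(x, "frame_rate"), ...) {
  if (is.null(frame_rate)) stop("frame_rate required to trim a plain vector")
  nd <- trim_frames(length(x), trim_s, frame_rate)
  if (nd == 0L) return(x)
  out <- x[-seq_len(nd)]
  attr(out, "frame_rate") <- frame_rate
  out
}
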