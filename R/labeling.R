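# Window labeling from telemetry variance: sliding windows over the frame
# axis, per-window sample variances of altitude and velocity, and the
# 50th-percentile rule (a window is INATTENTION when its variance exceeds the
# session median on both channels), plus training-set construction
# (train/test split and inattention oversampling).

#' Build a sliding window index
#'
#' Half-open frame windows `[start, start + w)` with starts
#' `1, 1 + step, 1 + 2 step, ...` while the window fits: count =
#' `floor((T - w) / step) + 1`. Defaults are 60-frame (10 s at 6 Hz) windows
#' advancing by 6 frames (1 s).
#'
#' @param n_frames Total frame count T.
#' @param w Window length in frames (default 60).
#' @param step Step between window starts in frames (default 6).
#' @return Data frame of class `window_index` with columns `start`, `end`
#'   (1-based, `end` exclusive).
#' @export
make_windows <- function(n_frames, w = 60, step = 6) {
  if (w < 1 || step < 1) stop("w and step must be positive")
  if (w > n_frames)
    stop(sprintf("window length %d exceeds the %d available frames", w, n_frames))
  starts <- seq.int(1L, n_frames - w + 1L, by = step)
  structure(data.frame(start = starts, end = starts + w),
            class = c("window_index", "data.frame"), w = w, step = step)
}

window_rows <- function(win) seq.int(win[["start"]], win[["end"]] - 1L)

#' Per-window telemetry variances
#'
#' Sample variance of altitude and velocity within each window.
#'
#' @param trace A [telemetry_trace()].
#' @param windows A [make_windows()] index; must lie within the trace.
#' @return Data frame with columns `start`, `end`, `var_alt` (ft^2),
#'   `var_vel` (kn^2).
#' @export
window_variances <- function(trace, windows) {
  stopifnot(inherits(trace, "telemetry_trace"))
  if (max(windows$end) - 1L > length(trace))
    stop("windows extend past the end of the telemetry trace")
  va <- vapply(seq_len(nrow(windows)), function(i)
    stats::var(trace$altitude_ft[window_rows(windows[i, ])]), numeric(1))
  vv <- vapply(seq_len(nrow(windows)), function(i)
    stats::var(trace$velocity_kn[window_rows(windows[i, ])]), numeric(1))
  data.frame(start = windows$start, end = windows$end, var_alt = va, var_vel = vv)
}

#' Label windows by the variance-percentile rule
#'
#' Computes the 50th percentile (median) of `var_alt` and of `var_vel` over
#' all windows. Under the default `"both"` rule a window is INATTENTION iff
#' its altitude variance AND velocity variance both strictly exceed their
#' medians; `"either"` requires only one. Strict inequality means that with
#' all-identical variances every window is ATTENTION (with a warning).
#'
#' @param variances Data frame from [window_variances()] (needs `var_alt`,
#'   `var_vel`; `start`/`end` carried through if present).
#' @param rule `"both"` (default) or `"either"`.
#' @param frame_rate Optional frame rate stored on the result (used by
#'   downstream reports).
#' @return Data frame of class `labeled_windows` with the variance columns
#'   plus `label` (factor ATTENTION/INATTENTION); attribute `role` is unset
#'   until [split_train_test()].
#' @export
label_windows <- function(variances, rule = c("both", "either"),
                          frame_rate = NULL) {
  rule <- match.arg(rule)
  if (nrow(variances) < 2L) stop("need at least two windows to take a percentile")
  med_a <- stats::median(variances$var_alt)
  med_v <- stats::median(variances$var_vel)
  hi_a <- variances$var_alt > med_a
  hi_v <- variances$var_vel > med_v
  inatt <- if (rule == "both") hi_a & hi_v else hi_a | hi_v
  if (!any(hi_a) && !any(hi_v))
    warning("all window variances are identical; labeling everything ATTENTION")
  out <- variances
  out$label <- factor(ifelse(inatt, INATTENTION, ATTENTION),
                      levels = attention_levels())
  structure(out, class = c("labeled_windows", "data.frame"),
            rule = rule, frame_rate = frame_rate)
}

#' @export
print.labeled_windows <- function(x, ...) {
  cat(sprintf("<labeled_windows> %d windows, %.1f%% inattention (rule '%s'%s)\n",
              nrow(x), 100 * mean(x$label == INATTENTION), attr(x, "rule"),
              if (is.null(attr(x, "role"))) "" else paste0(", role ", attr(x, "role"))))
  invisible(x)
}

#' Random train/test split of labeled windows
#'
#' Partitions windows at the given ratio (train size = `floor(ratio * n)`),
#' uniformly at random under the seed. Oversampling is applied after
#' splitting and only to the training part.
#'
#' @param labeled A `labeled_windows` data frame.
#' @param ratio Training fraction (default 0.8).
#' @param seed Optional integer seed.
#' @return List with `train` and `test`, each a `labeled_windows` with
#'   attribute `role` set to `"train"` / `"test"`.
#' @export
split_train_test <- function(labeled, ratio = 0.8, seed = NULL) {
  stopifnot(inherits(labeled, "labeled_windows"))
  n <- nrow(labeled)
  if (n < 2L) stop("need at least two windows to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0,1)")
  n_train <- floor(ratio * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  mk <- function(d, role) {
    attr(d, "role") <- role
    attr(d, "rule") <- attr(labeled, "rule")
    attr(d, "frame_rate") <- attr(labeled, "frame_rate")
    class(d) <- class(labeled)
    d
  }
  list(train = mk(labeled[sort(idx), , drop = FALSE], "train"),
       test = mk(labeled[sort(setdiff(seq_len(n), idx)), , drop = FALSE], "test"))
}

#' Oversample inattention windows for training
#'
#' Inattention occurrences are rare, so each INATTENTION window is duplicated
#' `factor - 1` additional times and the result is shuffled. Training-time
#' only: applying it to a test split is a misuse and raises an error.
#'
#' @param labeled A `labeled_windows` data frame (role must not be "test").
#' @param factor Integer >= 1; 2 doubles the inattention windows (default).
#' @param seed Optional integer seed for the shuffle.
#' @return A `labeled_windows` with duplicated inattention rows.
#' @export
oversample_inattention <- function(labeled, factor = 2, seed = NULL) {
  stopifnot(inherits(labeled, "labeled_windows"))
  if (!is.numeric(factor) || factor < 1 || factor != round(factor))
    stop("factor must be an integer >= 1")
  if (identical(attr(labeled, "role"), "test"))
    stop("oversampling a test split is forbidden: it would leak duplicated evaluation windows")
  if (factor == 1) return(labeled)
  in_idx <- which(labeled$label == INATTENTION)
  idx <- c(seq_len(nrow(labeled)), rep(in_idx, times = factor - 1))
  idx <- with_seed(seed, sample(idx))
  out <- labeled[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("role", "rule", "frame_rate")) attr(out, a) <- attr(labeled, a)
  class(out) <- class(labeled)
  out
}

#' Majority ground-truth state per window
#'
#' Convenience for validating telemetry-derived labels against simulator
#' truth: the majority true state inside each window, plus whether the window
#' is pure (single-state).
#'
#' @param true_state Per-frame state factor (e.g. `session$true_state`).
#' @param windows A window index or `labeled_windows`.
#' @return Data frame with `majority` (factor) and `pure` (logical).
#' @export
window_true_state <- function(true_state, windows) {
  maj <- character(nrow(windows))
  pure <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    s <- true_state[window_rows(windows[i, ])]
    fr <- mean(s == INATTENTION)
    maj[i] <- if (fr > 0.5) INATTENTION else ATTENTION
    pure[i] <- fr %in% c(0, 1)
  }
  data.frame(majority = factor(maj, levels = attention_levels()), pure = pure)
}
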