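# Configuration, session/detector serialization, and the end-to-end
# pipeline: simulate/load -> filter -> band decomposition -> channel means
# -> trim -> variance labeling -> split -> normalize -> AAR -> PCA -> two-HMM
# training -> test-set classification -> evaluation reports.

#' Pipeline configuration
#'
#' Every tunable of the processing and detection pipeline with its default:
#' 6 Hz frames, 1 s FFT window, 2-42 Hz Butterworth band-pass, 60 s start
#' trim, 60-frame windows stepped by 6, conjunction ("both") labeling rule,
#' 8:2 split, inattention oversampling factor 2, n_c = n_p = 10, 3 hidden
#' states.
#'
#' @param frame_rate Band-frame rate, Hz.
#' @param window_s FFT window, seconds.
#' @param bands Named list of band Hz ranges ([default_bands()]).
#' @param filter List `type` ("butterworth" or "none"), `low`, `high`,
#'   `order`.
#' @param trim_s Leading seconds removed before labeling.
#' @param w,step Labeling window length and step, frames.
#' @param label_rule `"both"` or `"either"` (see [label_windows()]).
#' @param split_ratio Training fraction.
#' @param oversample_factor Duplication factor for inattention training
#'   windows.
#' @param n_c AAR order per band; `n_p` PCA components; `n_states` hidden
#'   states per HMM.
#' @param n_p,n_states See above.
#' @param n_restarts,tol,max_iter Baum-Welch settings.
#' @param seed Master seed; stage seeds are derived from it.
#' @param sim Optional [sim_config()] used when no session is supplied.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(frame_rate = 6, window_s = 1,
                            bands = default_bands(),
                            filter = list(type = "butterworth", low = 2,
                                          high = 42, order = 4),
                            trim_s = 60, w = 60, step = 6,
                            label_rule = "both", split_ratio = 0.8,
                            oversample_factor = 2, n_c = 10, n_p = 10,
                            n_states = 3, n_restarts = 5, tol = 1e-4,
                            max_iter = 200, seed = NULL, sim = NULL) {
  stopifnot_scalar(frame_rate, "frame_rate")
  stopifnot_scalar(window_s, "window_s")
  if (!label_rule %in% c("both", "either")) stop("label_rule must be 'both' or 'either'")
  if (!is.list(filter) || is.null(filter$type)) stop("filter must be a list with $type")
  if (!filter$type %in% c("butterworth", "none"))
    stop("filter$type must be 'butterworth' or 'none'")
  if (n_c < 1 || n_c != round(n_c)) stop("n_c must be a positive integer")
  if (n_p < 1 || n_p != round(n_p)) stop("n_p must be a positive integer")
  if (n_p > 4 * n_c) stop("n_p cannot exceed the 4*n_c AAR features")
  if (n_states < 1) stop("n_states must be >= 1")
  if (split_ratio <= 0 || split_ratio >= 1) stop("split_ratio must lie in (0,1)")
  if (oversample_factor < 1 || oversample_factor != round(oversample_factor))
    stop("oversample_factor must be an integer >= 1")
  if (trim_s < 0) stop("trim_s must be >= 0")
  if (w < 1 || step < 1) stop("w and step must be positive")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(frame_rate = frame_rate, window_s = window_s, bands = bands,
                 filter = filter, trim_s = trim_s, w = w, step = step,
                 label_rule = label_rule, split_ratio = split_ratio,
                 oversample_factor = oversample_factor,
                 n_c = as.integer(n_c), n_p = as.integer(n_p),
                 n_states = as.integer(n_states), n_restarts = n_restarts,
                 tol = tol, max_iter = max_iter, seed = seed, sim = sim),
            class = "pipeline_config")
}

#' Load / save a pipeline configuration
#'
#' YAML round-trip of [pipeline_config()]. An empty or absent file yields
#' all defaults; unknown keys are rejected by name.
#'
#' @param path YAML file path.
#' @return For `load_config`, a validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(pipeline_config())
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  if (!is.null(vals$sim) && !inherits(vals$sim, "sim_config"))
    vals$sim <- do.call(sim_config, vals$sim)
  if (!is.null(vals$bands)) vals$bands <- lapply(vals$bands, as.numeric)
  do.call(pipeline_config, vals)
}

#' @rdname load_config
#' @param config A `pipeline_config` to write.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- unclass(config)
  if (!is.null(plain$sim)) plain$sim <- unclass(plain$sim)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Write a session to a directory of CSV files
#'
#' Canonical plain-text interchange: `eeg.csv` (time_s + one microvolt
#' column per channel), `telemetry.csv` (time_s, altitude_ft, velocity_kn),
#' and, when ground truth exists, `state.csv` (time_s, state). Numeric state
#' export uses 1 = INATTENTION (stated in the column name).
#'
#' @param session A `synthetic_session` (or compatible list).
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ee <- session$raw_eeg
  df <- data.frame(time_s = (seq_len(nrow(ee$data)) - 1) / ee$sample_rate +
                     ee$start_time)
  df <- cbind(df, as.data.frame(ee$data))
  utils::write.csv(df, file.path(dir, "eeg.csv"), row.names = FALSE)
  tl <- session$telemetry
  utils::write.csv(data.frame(
    time_s = (seq_len(length(tl)) - 1) / tl$frame_rate,
    altitude_ft = tl$altitude_ft, velocity_kn = tl$velocity_kn),
    file.path(dir, "telemetry.csv"), row.names = FALSE)
  if (!is.null(session$true_state)) {
    st <- session$true_state
    utils::write.csv(data.frame(
      time_s = (seq_len(length(st)) - 1) / tl$frame_rate,
      state = as.character(st),
      inattention_1 = as.integer(st == INATTENTION)),
      file.path(dir, "state.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session directory
#'
#' Inverse of [write_session()]. Validates that the EEG and telemetry cover
#' the same duration; a mismatch raises an alignment error.
#'
#' @param dir Directory containing `eeg.csv` and `telemetry.csv`
#'   (optionally `state.csv`).
#' @return List of class `synthetic_session` with `raw_eeg`, `telemetry`,
#'   and `true_state` (NULL when absent); `config` is NULL.
#' @export
read_session <- function(dir) {
  eeg <- utils::read.csv(file.path(dir, "eeg.csv"), check.names = FALSE)
  tel <- utils::read.csv(file.path(dir, "telemetry.csv"))
  sr <- 1 / stats::median(diff(eeg$time_s))
  fr <- 1 / stats::median(diff(tel$time_s))
  sr <- round(sr); fr <- round(fr)
  raw <- raw_eeg(as.matrix(eeg[, setdiff(names(eeg), "time_s"), drop = FALSE]),
                 sample_rate = sr, start_time = eeg$time_s[1])
  if (abs(nrow(raw$data) / sr - nrow(tel) / fr) > 1 / fr + 1e-9)
    stop(sprintf("alignment error: EEG covers %.3f s but telemetry %.3f s",
                 nrow(raw$data) / sr, nrow(tel) / fr))
  trace <- telemetry_trace(tel$altitude_ft, tel$velocity_kn, fr)
  st <- NULL
  sp <- file.path(dir, "state.csv")
  if (file.exists(sp)) {
    sd_ <- utils::read.csv(sp)
    st <- structure(factor(sd_$state, levels = attention_levels()),
                    frame_rate = fr)
  }
  structure(list(raw_eeg = raw, telemetry = trace, true_state = st,
                 config = NULL),
            class = "synthetic_session")
}

#' Serialize / restore a trained detector
#'
#' Writes the full detector (both HMMs, PCA model, normalization statistics,
#' AAR configuration, metadata) as one JSON document with 17 significant
#' digits, so numeric parameters round-trip exactly.
#'
#' @param detector An [train_detector()] result.
#' @param path JSON file path.
#' @return `write_detector`: the path, invisibly. `read_detector`: the
#'   restored `hmm_detector`.
#' @export
write_detector <- function(detector, path) {
  stopifnot(inherits(detector, "hmm_detector"))
  as_plain_hmm <- function(h) list(
    n_states = h$n_states, init_probs = h$init_probs, trans = h$trans,
    means = h$means, vars = h$vars, var_floor = h$var_floor)
  doc <- list(
    attention_hmm = as_plain_hmm(detector$attention_hmm),
    inattention_hmm = as_plain_hmm(detector$inattention_hmm),
    pca = if (is.null(detector$pca)) NULL else unclass(detector$pca),
    # named vectors serialize as JSON objects only when passed as lists
    norm_stats = if (is.null(detector$norm_stats)) NULL else
      list(center = as.list(detector$norm_stats$center),
           scale = as.list(detector$norm_stats$scale)),
    aar = if (is.null(detector$aar)) NULL else unclass(detector$aar),
    metadata = detector$metadata)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_detector
#' @export
read_detector <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk_hmm <- function(h) gaussian_hmm(h$init_probs, as.matrix(h$trans),
                                     as.matrix(h$means), as.matrix(h$vars),
                                     h$var_floor)
  pca <- NULL
  if (!is.null(doc$pca)) {
    pca <- structure(list(center = doc$pca$center,
                          components = as.matrix(doc$pca$components),
                          explained = doc$pca$explained,
                          n_p = as.integer(doc$pca$n_p)),
                     class = "pca_model")
  }
  ns <- doc$norm_stats
  if (!is.null(ns)) ns <- list(center = unlist(ns$center), scale = unlist(ns$scale))
  aar <- NULL
  if (!is.null(doc$aar))
    aar <- aar_config(doc$aar$n_c, doc$aar$forgetting_factor,
                      doc$aar$init_coeffs, doc$aar$init_covariance_scale)
  structure(list(attention_hmm = mk_hmm(doc$attention_hmm),
                 inattention_hmm = mk_hmm(doc$inattention_hmm),
                 pca = pca, norm_stats = ns, aar = aar,
                 metadata = doc$metadata),
            class = "hmm_detector")
}

#' Export labeled windows as CSV
#'
#' Columns: window start/end frame, variances, label, and the numeric
#' convention `label_1_is_inattention` (1 = INATTENTION).
#'
#' @param labeled A `labeled_windows` data frame.
#' @param path CSV file path.
#' @export
write_labeled_windows <- function(labeled, path) {
  stopifnot(inherits(labeled, "labeled_windows"))
  out <- data.frame(window_start_frame = labeled$start,
                    window_end_frame = labeled$end,
                    var_alt = labeled$var_alt, var_vel = labeled$var_vel,
                    label = as.character(labeled$label),
                    label_1_is_inattention =
                      as.integer(labeled$label == INATTENTION))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Per-frame expansion of window labels: a frame is INATTENTION when more
# than half of the windows covering it are labeled INATTENTION.
frame_labels <- function(labeled, n_frames) {
  hits <- numeric(n_frames)
  cover <- numeric(n_frames)
  for (i in seq_len(nrow(labeled))) {
    idx <- window_rows(labeled[i, ])
    cover[idx] <- cover[idx] + 1
    if (labeled$label[i] == INATTENTION) hits[idx] <- hits[idx] + 1
  }
  lab <- ifelse(cover > 0 & hits / pmax(cover, 1) > 0.5, INATTENTION, ATTENTION)
  factor(lab, levels = attention_levels())
}

#' Run the full pipeline on one session
#'
#' End-to-end convenience: simulate (or accept) a session, filter and
#' decompose the EEG, average channels, trim the start, label windows from
#' telemetry variance, split, normalize and extract AAR + PCA features with
#' statistics fitted on the training part only, train the two-HMM detector
#' and the SVM baseline, classify the held-out windows, and assemble the
#' evaluation reports. Deterministic under `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param session Optional session (e.g. [simulate_session()] output or
#'   [read_session()]); when NULL one is simulated from `config$sim` (or a
#'   default [sim_config()] seeded with `config$seed`).
#' @return Object of class `pipeline_result`; see Details.
#' @details The result contains `detector`, `features` (frames x n_p),
#'   `windows` (`$train`, `$train_os`, `$test`), `results_test`
#'   (per-window decisions), `metrics` (`$hmm`, `$svm` named vectors),
#'   `confusion` (`$hmm`, `$svm`), `label_report`, `band_diag`,
#'   `truth_agreement` (fraction of pure-truth windows whose label matches,
#'   NA without ground truth), `config`, and `n_frames`.
#' @export
run_pipeline <- function(config = pipeline_config(), session = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  dseed <- function(k) if (is.null(seed)) NULL else seed + k
  if (is.null(session)) {
    simc <- config$sim %||% sim_config(seed = seed)
    session <- simulate_session(simc, seed = simc$seed %||% seed)
  }
  raw <- session$raw_eeg
  if (identical(config$filter$type, "butterworth"))
    raw <- bandpass_eeg(raw, config$filter$low %||% 2,
                        config$filter$high %||% 42,
                        config$filter$order %||% 4)
  bands <- decompose_bands(raw, frame_rate = config$frame_rate,
                           window_s = config$window_s, bands = config$bands)
  bm <- average_channels(bands)
  T_b <- ncol(bm$values)
  # telemetry/truth aligned to band frames (band frame t = raw window
  # starting at frame t), then trimmed consistently
  tel <- session$telemetry
  tel <- telemetry_trace(tel$altitude_ft[seq_len(T_b)],
                         tel$velocity_kn[seq_len(T_b)], tel$frame_rate)
  truth <- session$true_state
  if (!is.null(truth)) truth <- truth[seq_len(T_b)]
  # whole-session labels (pre-trim) for the ratio report
  win_whole <- make_windows(T_b, config$w, config$step)
  lw_whole <- label_windows(window_variances(tel, win_whole),
                            rule = config$label_rule,
                            frame_rate = config$frame_rate)
  bm_t <- trim_start(bm, config$trim_s)
  tel_t <- trim_start(tel, config$trim_s)
  n_drop <- T_b - ncol(bm_t$values)
  truth_t <- if (is.null(truth)) NULL else truth[-seq_len(n_drop)]
  T_ <- ncol(bm_t$values)
  windows <- make_windows(T_, config$w, config$step)
  labeled <- label_windows(window_variances(tel_t, windows),
                           rule = config$label_rule,
                           frame_rate = config$frame_rate)
  split <- split_train_test(labeled, ratio = config$split_ratio,
                            seed = dseed(1))
  # train-fit statistics: frames covered by training windows only
  train_frames <- sort(unique(unlist(lapply(
    seq_len(nrow(split$train)), function(i) window_rows(split$train[i, ])))))
  tv <- bm_t$values[, train_frames, drop = FALSE]
  scl <- apply(tv, 1, stats::sd)
  if (any(scl == 0))
    stop(sprintf("band(s) %s constant on training frames; cannot normalize",
                 paste(rownames(tv)[scl == 0], collapse = ", ")))
  norm_stats <- list(center = apply(tv, 1, mean), scale = scl)
  norm <- normalize_bands(bm_t, norm_stats)
  aar_cfg <- aar_config(n_c = config$n_c)
  aar <- estimate_aar(norm, aar_cfg)
  pca <- fit_pca(aar$values[train_frames, , drop = FALSE], n_p = config$n_p)
  features <- project_features(pca, aar$values)
  train_os <- oversample_inattention(split$train,
                                     factor = config$oversample_factor,
                                     seed = dseed(2))
  detector <- train_detector(features, train_os, n_states = config$n_states,
                             seed = dseed(3), pca = pca,
                             norm_stats = norm_stats, aar = aar_cfg,
                             tol = config$tol, max_iter = config$max_iter,
                             n_restarts = config$n_restarts)
  results <- classify_windows(detector, features, split$test)
  cm_hmm <- confusion(split$test$label, results$decision)
  svm <- train_baseline(features, train_os, seed = dseed(4))
  svm_pred <- classify_baseline(svm, features, split$test)
  cm_svm <- confusion(split$test$label, svm_pred)
  diag_labels <- frame_labels(labeled, T_)
  band_diag <- if (length(unique(diag_labels)) > 1L)
    band_label_diagnostic(bm_t, diag_labels) else NULL
  truth_agreement <- NA_real_
  if (!is.null(truth_t)) {
    ts <- window_true_state(truth_t, labeled)
    pure <- ts$pure
    if (any(pure))
      truth_agreement <- mean(labeled$label[pure] == ts$majority[pure])
  }
  structure(list(
    detector = detector, features = features,
    windows = list(train = split$train, train_os = train_os,
                   test = split$test, whole = lw_whole),
    results_test = results,
    metrics = list(hmm = suppressWarnings(detection_metrics(cm_hmm)),
                   svm = suppressWarnings(detection_metrics(cm_svm))),
    confusion = list(hmm = cm_hmm, svm = cm_svm),
    label_report = label_ratio_report(lw_whole, trim_s = config$trim_s,
                                      frame_rate = config$frame_rate),
    band_diag = band_diag, truth_agreement = truth_agreement,
    config = config, n_frames = T_),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$metrics
  cat("<pipeline_result>\n")
  cat(sprintf("  windows: %d train (+%d oversampled) / %d test; inattention %.1f%%\n",
              nrow(x$windows$train),
              nrow(x$windows$train_os) - nrow(x$windows$train),
              nrow(x$windows$test),
              100 * mean(x$windows$whole$label == INATTENTION)))
  cat(sprintf("  HMM  accuracy %.3f  precision %.3f  recall %.3f\n",
              m$hmm[["accuracy"]], m$hmm[["precision"]], m$hmm[["recall"]]))
  cat(sprintf("  SVM  accuracy %.3f  precision %.3f  recall %.3f\n",
              m$svm[["accuracy"]], m$svm[["precision"]], m$svm[["recall"]]))
  if (!is.null(x$band_diag))
    cat(sprintf("  most elevated band under inattention: %s\n", x$band_diag$flagged))
  if (!is.na(x$truth_agreement))
    cat(sprintf("  label/truth agreement on pure windows: %.1f%%\n",
                100 * x$truth_agreement))
  invisible(x)
}
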