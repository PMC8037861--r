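# Feature extraction: adaptive autoregressive (AAR) coefficients tracked per
# band with recursive least squares, flattened band-major to 4*n_c values per
# frame, then reduced to n_p dimensions by PCA fitted on training frames only.

#' AAR estimation configuration
#'
#' @param n_c AR model order = number of coefficients tracked per band
#'   (default 10).
#' @param forgetting_factor RLS forgetting factor in (0,1); the default 0.998
#'   gives an effective memory of ~500 frames (~83 s at 6 Hz), chosen because
#'   band-amplitude frames from overlapping FFT windows are strongly
#'   collinear and faster forgetting inflates coefficient variance.
#' @param init_coeffs Initial coefficient vector (default zeros).
#' @param init_covariance_scale Initial inverse-information scale; the RLS
#'   covariance starts at `init_covariance_scale * I`.
#' @return Object of class `aar_config`.
#' @export
aar_config <- function(n_c = 10, forgetting_factor = 0.998,
                       init_coeffs = NULL, init_covariance_scale = 100) {
  if (!is.numeric(n_c) || n_c < 1 || n_c != round(n_c))
    stop("n_c must be a positive integer")
  if (forgetting_factor <= 0 || forgetting_factor >= 1)
    stop("forgetting_factor must lie in (0,1)")
  stopifnot_scalar(init_covariance_scale, "init_covariance_scale")
  init_coeffs <- init_coeffs %||% numeric(n_c)
  if (length(init_coeffs) != n_c) stop("init_coeffs must have length n_c")
  structure(list(n_c = as.integer(n_c), forgetting_factor = forgetting_factor,
                 init_coeffs = init_coeffs,
                 init_covariance_scale = init_covariance_scale),
            class = "aar_config")
}

# RLS tracker for a single series. Returns T x n_c coefficient matrix; the
# first n_c frames carry the initialization values (warm-up), preserving
# frame alignment with labels.
rls_track <- function(y, config) {
  n_c <- config$n_c
  lam <- config$forgetting_factor
  T_ <- length(y)
  if (T_ <= n_c) stop("series length must exceed n_c")
  coef <- matrix(rep(config$init_coeffs, each = T_), nrow = T_)
  cvec <- config$init_coeffs
  P <- diag(config$init_covariance_scale, n_c)
  n_resets <- 0L
  for (t in (n_c + 1L):T_) {
    x <- y[(t - 1L):(t - n_c)]
    err <- y[t] - sum(cvec * x)
    Px <- P %*% x
    denom <- lam + sum(x * Px)
    k <- Px / denom
    cvec_new <- cvec + as.numeric(k) * err
    # symmetrized update: plain (P - k Px')/lam loses symmetry in floating
    # point and diverges over long runs
    P_new <- (P + t(P) - k %*% t(Px) - Px %*% t(k)) / (2 * lam)
    if (!all(is.finite(cvec_new)) || !all(is.finite(P_new))) {
      # numerically singular update: reset the covariance, keep coefficients
      P <- diag(config$init_covariance_scale, n_c)
      n_resets <- n_resets + 1L
    } else {
      cvec <- cvec_new
      P <- P_new
    }
    coef[t, ] <- cvec
  }
  if (n_resets > 0L)
    warning(sprintf("RLS covariance reset %d time(s) after singular update", n_resets))
  coef
}

#' Track adaptive AR coefficients per band
#'
#' Runs a recursive-least-squares AR(`n_c`) tracker independently on each
#' band row of the (normalized) channel-mean series. At each frame the
#' coefficients are updated from the one-step prediction error against the
#' previous `n_c` values; the first `n_c` frames are warm-up and carry the
#' initialization coefficients.
#'
#' @param series A `band_means` object (normally normalized).
#' @param config An [aar_config()].
#' @return Object of class `aar_series`: list with `values` (T x 4*n_c
#'   matrix, columns band-major: delta c1..c_nc, theta c1..c_nc, ...),
#'   `config`, `frame_rate`.
#' @export
estimate_aar <- function(series, config = aar_config()) {
  stopifnot(inherits(series, "band_means"), inherits(config, "aar_config"))
  v <- series$values
  bn <- rownames(v) %||% paste0("band", seq_len(nrow(v)))
  per_band <- lapply(seq_len(nrow(v)), function(i) rls_track(v[i, ], config))
  vals <- do.call(cbind, per_band)
  colnames(vals) <- unlist(lapply(bn, function(b) paste0(b, "_c", seq_len(config$n_c))))
  structure(list(values = vals, config = config, frame_rate = series$frame_rate),
            class = "aar_series")
}

#' @export
print.aar_series <- function(x, ...) {
  cat(sprintf("<aar_series> %d frames x %d coefficients (n_c = %d per band)\n",
              nrow(x$values), ncol(x$values), x$config$n_c))
  invisible(x)
}

#' Fit a PCA model on training feature frames
#'
#' Centers the training matrix and keeps the top `n_p` principal components
#' by explained variance. Component signs are fixed deterministically: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param training Numeric matrix (frames x features), e.g.
#'   `aar_series$values` restricted to training rows.
#' @param n_p Number of components to keep (default 10).
#' @return Object of class `pca_model`: `center` (length d), `components`
#'   (n_p x d, orthonormal rows), `explained` (length n_p fractions of total
#'   variance), `n_p`.
#' @export
fit_pca <- function(training, n_p = 10) {
  training <- as.matrix(training)
  if (nrow(training) < 2L) stop("need at least two frames to fit PCA")
  if (n_p < 1 || n_p > ncol(training))
    stop("n_p must lie in [1, number of features]")
  ctr <- colMeans(training)
  Xc <- sweep(training, 2, ctr)
  rk <- qr(Xc)$rank
  if (rk < n_p)
    stop(sprintf("training data has rank %d < n_p = %d", rk, n_p))
  p <- stats::prcomp(training, center = TRUE, scale. = FALSE)
  comp <- unname(t(p$rotation[, seq_len(n_p), drop = FALSE]))
  for (i in seq_len(n_p)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  frac <- p$sdev^2 / sum(p$sdev^2)
  structure(list(center = ctr, components = comp,
                 explained = frac[seq_len(n_p)], n_p = as.integer(n_p)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components of %d features; %.1f%% variance kept\n",
              x$n_p, length(x$center), 100 * sum(x$explained)))
  invisible(x)
}

#' Project feature frames onto a fitted PCA model
#'
#' Computes `f = components %*% (x - center)` for one frame or for each row
#' of a frame matrix.
#'
#' @param model A [fit_pca()] model.
#' @param frames Numeric vector of length d, or a frames x d matrix.
#' @return Length-`n_p` vector, or a frames x `n_p` matrix.
#' @export
project_features <- function(model, frames) {
  stopifnot(inherits(model, "pca_model"))
  d <- length(model$center)
  if (is.null(dim(frames))) {
    if (length(frames) != d)
      stop(sprintf("frame has length %d, expected %d", length(frames), d))
    return(as.numeric(model$components %*% (frames - model$center)))
  }
  frames <- as.matrix(frames)
  if (ncol(frames) != d)
    stop(sprintf("frames have %d columns, expected %d", ncol(frames), d))
  sweep(frames, 2, model$center) %*% t(model$components)
}
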