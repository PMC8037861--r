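# Two-model HMM detection: a Gaussian hidden Markov model per attention
# class, fitted by Baum-Welch EM; a window of feature vectors is classified
# by comparing the forward log-likelihoods of the two models. An SVM on
# window-mean features is kept as a static baseline.

#' Construct a Gaussian HMM
#'
#' Hidden Markov model with diagonal-covariance Gaussian emissions. Diagonal
#' covariances keep the parameter count manageable for 10-dimensional
#' features fitted from limited per-class data.
#'
#' @param init_probs Initial state distribution, length `n_states`, sums to 1.
#' @param trans Transition matrix, rows sum to 1.
#' @param means State means, `n_states x d` matrix.
#' @param vars State variances (diagonal), `n_states x d`, entries >= floor.
#' @param var_floor Minimum admissible variance (default 1e-6).
#' @return Object of class `gaussian_hmm`.
#' @export
gaussian_hmm <- function(init_probs, trans, means, vars, var_floor = 1e-6) {
  means <- unname(as.matrix(means))
  vars <- unname(as.matrix(vars))
  trans <- unname(as.matrix(trans))
  S <- length(init_probs)
  if (!isTRUE(all.equal(sum(init_probs), 1, tolerance = 1e-8)))
    stop("init_probs must sum to 1")
  if (nrow(trans) != S || ncol(trans) != S)
    stop("trans must be n_states x n_states")
  if (any(abs(rowSums(trans) - 1) > 1e-8))
    stop("each row of trans must sum to 1")
  if (nrow(means) != S || nrow(vars) != S || ncol(means) != ncol(vars))
    stop("means and vars must be n_states x d")
  if (any(vars < var_floor))
    stop(sprintf("variances must be >= the floor %g", var_floor))
  structure(list(n_states = S, init_probs = as.numeric(init_probs),
                 trans = trans, means = means, vars = vars,
                 var_floor = var_floor),
            class = "gaussian_hmm")
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf("<gaussian_hmm> %d states, %d-dim diagonal Gaussian emissions\n",
              x$n_states, ncol(x$means)))
  if (!is.null(attr(x, "loglik")))
    cat(sprintf("  fitted: loglik %.3f after %d EM iterations\n",
                attr(x, "loglik"), length(attr(x, "loglik_trace"))))
  invisible(x)
}

# N x S matrix of per-frame log emission densities.
emission_logdens <- function(hmm, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(hmm$means))
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(X), ncol(hmm$means)))
  S <- hmm$n_states
  out <- matrix(0, nrow(X), S)
  for (s in seq_len(S)) {
    v <- hmm$vars[s, ]
    const <- -0.5 * sum(log(2 * pi * v))
    D <- sweep(X, 2, hmm$means[s, ])
    out[, s] <- const - 0.5 * rowSums(sweep(D^2, 2, v, "/"))
  }
  out
}

#' Forward-algorithm log-likelihood of a feature sequence
#'
#' Computes `log P(sequence | hmm)` with the log-space forward recursion
#' (numerically stable for long windows).
#'
#' @param hmm A [gaussian_hmm()].
#' @param sequence Feature matrix, frames x d (a vector is taken as one
#'   frame per element for d = 1).
#' @return Scalar log-likelihood.
#' @export
forward_loglik <- function(hmm, sequence) {
  stopifnot(inherits(hmm, "gaussian_hmm"))
  if (is.null(dim(sequence))) sequence <- matrix(sequence, ncol = 1)
  if (nrow(sequence) < 1L) stop("sequence must contain at least one frame")
  logB <- emission_logdens(hmm, sequence)
  logA <- log(hmm$trans)
  la <- log(hmm$init_probs) + logB[1, ]
  T_ <- nrow(sequence)
  if (T_ > 1L) {
    for (t in 2:T_) {
      la <- logB[t, ] + vapply(seq_len(hmm$n_states),
                               function(j) logsumexp(la + logA[, j]),
                               numeric(1))
    }
  }
  logsumexp(la)
}

# Batched scaled forward-backward over equal-length sequences.
# X_all: stacked frames (sequence-major), n sequences of length T_.
# Returns loglik total and E-step sufficient statistics.
fb_batch <- function(hmm, X_all, n, T_) {
  S <- hmm$n_states
  d <- ncol(hmm$means)
  A <- hmm$trans
  tA <- t(A)
  logB <- emission_logdens(hmm, X_all)
  base <- T_ * (seq_len(n) - 1L)
  LBt <- lapply(seq_len(T_), function(t) logB[base + t, , drop = FALSE])
  Xt <- lapply(seq_len(T_), function(t) X_all[base + t, , drop = FALSE])
  rowmax <- function(m) {
    r <- m[, 1]
    if (S > 1L) for (s in 2:S) r <- pmax(r, m[, s])
    r
  }
  # scaled forward: per-step max-shifted emissions, row-normalized alpha
  alpha <- vector("list", T_)
  Bt <- vector("list", T_)
  ct <- vector("list", T_)
  loglik <- 0
  for (t in seq_len(T_)) {
    mt <- rowmax(LBt[[t]])
    B <- exp(LBt[[t]] - mt)
    a <- if (t == 1L) B * rep(hmm$init_probs, each = n)
         else (alpha[[t - 1L]] %*% A) * B
    cc <- rowSums(a)
    cc[cc == 0] <- .Machine$double.xmin
    alpha[[t]] <- a / cc
    Bt[[t]] <- B
    ct[[t]] <- cc
    loglik <- loglik + sum(log(cc) + mt)
  }
  # scaled backward with accumulation of E-step statistics
  beta <- matrix(1, n, S)
  gamma_sum <- numeric(S)
  mean_num <- matrix(0, S, d)
  sq_num <- matrix(0, S, d)
  xi_sum <- matrix(0, S, S)
  gamma1_sum <- NULL
  g <- alpha[[T_]]
  for (t in T_:1) {
    if (t < T_) {
      w <- (Bt[[t + 1L]] * beta) / ct[[t + 1L]]
      xi_sum <- xi_sum + A * crossprod(alpha[[t]], w)
      beta <- w %*% tA
      g <- alpha[[t]] * beta
      g <- g / rowSums(g)
    }
    gamma_sum <- gamma_sum + colSums(g)
    mean_num <- mean_num + crossprod(g, Xt[[t]])
    sq_num <- sq_num + crossprod(g, Xt[[t]]^2)
    if (t == 1L) gamma1_sum <- colSums(g)
  }
  list(loglik = loglik, gamma_sum = gamma_sum, mean_num = mean_num,
       sq_num = sq_num, xi_sum = xi_sum, gamma1_sum = gamma1_sum,
       n_seq = n)
}

# One E step over a list of variable-length sequences (grouped by length).
estep <- function(hmm, sequences) {
  lens <- vapply(sequences, nrow, 1L)
  groups <- split(seq_along(sequences), lens)
  agg <- NULL
  for (g in groups) {
    T_ <- nrow(sequences[[g[1]]])
    X_all <- do.call(rbind, sequences[g])
    st <- fb_batch(hmm, X_all, length(g), T_)
    if (is.null(agg)) agg <- st
    else {
      agg$loglik <- agg$loglik + st$loglik
      agg$gamma_sum <- agg$gamma_sum + st$gamma_sum
      agg$mean_num <- agg$mean_num + st$mean_num
      agg$sq_num <- agg$sq_num + st$sq_num
      agg$xi_sum <- agg$xi_sum + st$xi_sum
      agg$gamma1_sum <- agg$gamma1_sum + st$gamma1_sum
      agg$n_seq <- agg$n_seq + st$n_seq
    }
  }
  agg
}

random_hmm_init <- function(X_all, n_states, var_floor) {
  d <- ncol(X_all)
  pi0 <- stats::runif(n_states) + 0.1
  pi0 <- pi0 / sum(pi0)
  A <- matrix(stats::runif(n_states^2) + 0.1, n_states)
  A <- A / rowSums(A)
  cm <- colMeans(X_all)
  cv <- pmax(apply(X_all, 2, stats::var), var_floor)
  idx <- sample.int(nrow(X_all), n_states, replace = nrow(X_all) < n_states)
  means <- X_all[idx, , drop = FALSE] +
    matrix(stats::rnorm(n_states * d, sd = 0.1 * sqrt(cv)), n_states,
           byrow = TRUE)
  vars <- matrix(cv, n_states, d, byrow = TRUE)
  gaussian_hmm(pi0, A, means, vars, var_floor)
}

#' Fit a Gaussian HMM by Baum-Welch EM
#'
#' Expectation-maximization over one or more observation sequences. The
#' log-likelihood is non-decreasing across iterations; the fit stops when
#' the improvement drops below `tol` or after `max_iter` iterations. Several
#' random restarts are run (random initialization is multimodal) and the
#' restart with the best final log-likelihood is returned; everything is
#' deterministic under the seed.
#'
#' @param sequences A feature matrix (one sequence) or list of matrices,
#'   all with the same column count.
#' @param n_states Number of hidden states (default 3).
#' @param seed Optional integer seed.
#' @param tol Absolute log-likelihood improvement below which EM stops.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Random restarts (ignored when `init` is given).
#' @param var_floor Variance floor applied at every M step.
#' @param init Optional `gaussian_hmm` to start from (single run).
#' @return A fitted [gaussian_hmm()] with attributes `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `seed`.
#' @export
fit_hmm <- function(sequences, n_states = 3, seed = NULL, tol = 1e-4,
                    max_iter = 200, n_restarts = 5, var_floor = 1e-6,
                    init = NULL) {
  if (is.matrix(sequences) || is.data.frame(sequences))
    sequences <- list(as.matrix(sequences))
  sequences <- lapply(sequences, as.matrix)
  X_all <- do.call(rbind, sequences)
  if (nrow(X_all) < n_states)
    stop("need at least n_states total frames")
  run_em <- function(hmm0) {
    hmm <- hmm0
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      st <- estep(hmm, sequences)
      if (!is.finite(st$loglik)) stop("EM log-likelihood became non-finite")
      trace <- c(trace, st$loglik)
      if (it > 1L && st$loglik - trace[it - 1L] < tol) {
        converged <- TRUE
        break
      }
      # M step
      pi_new <- st$gamma1_sum / st$n_seq
      pi_new <- pi_new / sum(pi_new)
      A_new <- st$xi_sum
      rs <- rowSums(A_new)
      dead <- rs <= 0 | st$gamma_sum < 1e-10
      if (any(dead))
        warning("degenerate HMM state(s) with vanishing responsibility; parameters frozen")
      A_new[rs > 0, ] <- A_new[rs > 0, , drop = FALSE] / rs[rs > 0]
      A_new[rs <= 0, ] <- hmm$trans[rs <= 0, , drop = FALSE]
      gs <- pmax(st$gamma_sum, 1e-300)
      means_new <- st$mean_num / gs
      vars_new <- pmax(st$sq_num / gs - means_new^2, var_floor)
      means_new[dead, ] <- hmm$means[dead, , drop = FALSE]
      vars_new[dead, ] <- hmm$vars[dead, , drop = FALSE]
      hmm <- gaussian_hmm(pi_new, A_new, means_new, vars_new, var_floor)
    }
    attr(hmm, "loglik") <- trace[length(trace)]
    attr(hmm, "loglik_trace") <- trace
    attr(hmm, "n_iter") <- length(trace)
    attr(hmm, "converged") <- converged
    hmm
  }
  with_seed(seed, {
    if (!is.null(init)) {
      stopifnot(inherits(init, "gaussian_hmm"))
      best <- run_em(init)
    } else {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- run_em(random_hmm_init(X_all, n_states, var_floor))
        if (is.null(best) || attr(fit, "loglik") > attr(best, "loglik"))
          best <- fit
      }
    }
    attr(best, "seed") <- seed
    best
  })
}

#' Train the two-HMM inattention detector
#'
#' Fits the attention HMM on the feature sequences of ATTENTION-labeled
#' windows and the inattention HMM on INATTENTION-labeled windows (normally
#' after oversampling), producing the subject-dependent detector. The PCA
#' model, normalization statistics, and AAR configuration captured from the
#' same training data may be attached so the detector is self-contained for
#' streaming use.
#'
#' @param features Feature matrix for the whole session (frames x n_p),
#'   aligned with the frame indices in `windows`.
#' @param windows A `labeled_windows` training set (both classes present).
#' @param n_states Hidden states per HMM (default 3).
#' @param seed Optional integer seed (the inattention fit uses `seed + 1`).
#' @param pca,norm_stats,aar Optional fitted preprocessing state to embed.
#' @param ... Passed to [fit_hmm()] (tol, max_iter, n_restarts, ...).
#' @return Object of class `hmm_detector`.
#' @export
train_detector <- function(features, windows, n_states = 3, seed = NULL,
                           pca = NULL, norm_stats = NULL, aar = NULL, ...) {
  stopifnot(inherits(windows, "labeled_windows"))
  features <- as.matrix(features)
  seqs <- lapply(seq_len(nrow(windows)), function(i)
    features[window_rows(windows[i, ]), , drop = FALSE])
  is_in <- windows$label == INATTENTION
  for (cls in attention_levels()) {
    if (!any(windows$label == cls))
      stop(sprintf("training set contains no %s windows", cls))
  }
  att <- fit_hmm(seqs[!is_in], n_states = n_states, seed = seed, ...)
  ina <- fit_hmm(seqs[is_in], n_states = n_states,
                 seed = if (is.null(seed)) NULL else seed + 1L, ...)
  structure(list(
    attention_hmm = att, inattention_hmm = ina,
    pca = pca, norm_stats = norm_stats, aar = aar,
    metadata = list(seed = seed, n_states = n_states,
                    n_train = nrow(windows),
                    n_iter = c(attention = attr(att, "n_iter"),
                               inattention = attr(ina, "n_iter")),
                    final_loglik = c(attention = attr(att, "loglik"),
                                     inattention = attr(ina, "loglik")))),
    class = "hmm_detector")
}

#' @export
print.hmm_detector <- function(x, ...) {
  cat(sprintf("<hmm_detector> two %d-state Gaussian HMMs (trained on %d windows)\n",
              x$metadata$n_states, x$metadata$n_train))
  invisible(x)
}

#' Classify one window of feature vectors
#'
#' Computes the forward log-likelihood of the sequence under both HMMs and
#' decides INATTENTION iff the inattention log-likelihood is greater than or
#' equal to the attention one. Ties go to INATTENTION: in an alerting system
#' the costlier error is a missed lapse.
#'
#' @param detector An [train_detector()] result.
#' @param sequence Feature matrix, frames x n_p.
#' @return One-row data frame: `loglik_attention`, `loglik_inattention`,
#'   `decision` (factor).
#' @export
classify_window <- function(detector, sequence) {
  stopifnot(inherits(detector, "hmm_detector"))
  ll_a <- forward_loglik(detector$attention_hmm, sequence)
  ll_i <- forward_loglik(detector$inattention_hmm, sequence)
  data.frame(loglik_attention = ll_a, loglik_inattention = ll_i,
             decision = factor(if (ll_i >= ll_a) INATTENTION else ATTENTION,
                               levels = attention_levels()))
}

#' Classify every window of a session
#'
#' @param detector An [train_detector()] result.
#' @param features Session feature matrix (frames x n_p).
#' @param windows A window index or `labeled_windows`.
#' @return Data frame with `start`, `end`, both log-likelihoods, `decision`.
#' @export
classify_windows <- function(detector, features, windows) {
  features <- as.matrix(features)
  out <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i)
    classify_window(detector, features[window_rows(windows[i, ]), , drop = FALSE])))
  cbind(data.frame(start = windows$start, end = windows$end), out)
}

#' SVM baseline on window-mean features
#'
#' Radial-kernel support-vector classifier with default hyperparameters on
#' the per-window mean feature vector; a static (sequence-blind) reference
#' point for the two-HMM detector.
#'
#' @param features Session feature matrix (frames x n_p).
#' @param windows A `labeled_windows` training set.
#' @param seed Optional integer seed.
#' @return Object of class `svm_baseline`.
#' @export
train_baseline <- function(features, windows, seed = NULL) {
  stopifnot(inherits(windows, "labeled_windows"))
  if (length(unique(windows$label)) < 2L)
    stop("baseline training needs both classes present")
  features <- as.matrix(features)
  X <- t(vapply(seq_len(nrow(windows)), function(i)
    colMeans(features[window_rows(windows[i, ]), , drop = FALSE]),
    numeric(ncol(features))))
  y <- factor(windows$label, levels = attention_levels())
  fit <- with_seed(seed, e1071::svm(X, y, kernel = "radial"))
  structure(list(svm = fit, n_p = ncol(features)), class = "svm_baseline")
}

#' @rdname train_baseline
#' @param model A fitted `svm_baseline`.
#' @return For `classify_baseline`: factor of decisions, one per window.
#' @export
classify_baseline <- function(model, features, windows) {
  stopifnot(inherits(model, "svm_baseline"))
  features <- as.matrix(features)
  X <- t(vapply(seq_len(nrow(windows)), function(i)
    colMeans(features[window_rows(windows[i, ]), , drop = FALSE]),
    numeric(ncol(features))))
  factor(as.character(stats::predict(model$svm, X)), levels = attention_levels())
}
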