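# Shared fixtures: small deterministic sessions and toy models, built in
# code at test time.

quick_sim <- function(duration_s = 120, seed = 11, theta_gain = 3, ...) {
  sim_config(duration_s = duration_s, seed = seed, theta_gain = theta_gain, ...)
}

# Small band_means object with known values.
toy_band_means <- function(values, frame_rate = 6) {
  rownames(values) <- c("delta", "theta", "alpha", "beta")[seq_len(nrow(values))]
  structure(list(values = values, frame_rate = frame_rate, stats = NULL),
            class = "band_means")
}

# A well-separated pair of 1-D Gaussian HMMs for detector-level tests.
toy_detector <- function(sep = 10) {
  h_att <- gaussian_hmm(c(1, 0), matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
                        means = matrix(c(0, 1), 2, 1),
                        vars = matrix(1, 2, 1))
  h_in <- gaussian_hmm(c(1, 0), matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
                       means = matrix(c(sep, sep + 1), 2, 1),
                       vars = matrix(1, 2, 1))
  structure(list(attention_hmm = h_att, inattention_hmm = h_in,
                 pca = NULL, norm_stats = NULL, aar = NULL,
                 metadata = list(n_states = 2, n_train = 0)),
            class = "hmm_detector")
}

# Sample an observation sequence from a Gaussian HMM (independent oracle
# for classification tests).
sample_hmm <- function(hmm, T_) {
  S <- hmm$n_states
  s <- numeric(T_)
  s[1] <- sample.int(S, 1, prob = hmm$init_probs)
  if (T_ > 1) for (t in 2:T_)
    s[t] <- sample.int(S, 1, prob = hmm$trans[s[t - 1], ])
  d <- ncol(hmm$means)
  X <- matrix(0, T_, d)
  for (t in seq_len(T_))
    X[t, ] <- stats::rnorm(d, hmm$means[s[t], ], sqrt(hmm$vars[s[t], ]))
  X
}

# Brute-force forward likelihood by enumeration over all state paths
# (oracle; only feasible for tiny state counts / lengths).
enum_loglik <- function(hmm, X) {
  X <- as.matrix(X)
  S <- hmm$n_states
  T_ <- nrow(X)
  dens <- matrix(0, T_, S)
  for (s in seq_len(S))
    dens[, s] <- vapply(seq_len(T_), function(t)
      prod(stats::dnorm(X[t, ], hmm$means[s, ], sqrt(hmm$vars[s, ]))),
      numeric(1))
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  total <- 0
  for (p in seq_len(nrow(paths))) {
    path <- paths[p, ]
    pr <- hmm$init_probs[path[1]] * dens[1, path[1]]
    if (T_ > 1) for (t in 2:T_)
      pr <- pr * hmm$trans[path[t - 1], path[t]] * dens[t, path[t]]
    total <- total + pr
  }
  log(total)
}

# Labeled-window fixture with prescribed variances.
toy_labeled <- function(var_alt, var_vel, w = 3, rule = "both") {
  n <- length(var_alt)
  starts <- seq(1, by = w, length.out = n)
  label_windows(data.frame(start = starts, end = starts + w,
                           var_alt = var_alt, var_vel = var_vel),
                rule = rule)
}
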