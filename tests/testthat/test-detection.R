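# Gaussian HMM forward algorithm, Baum-Welch EM, the two-model detector,
# and the SVM baseline.

test_that("forward log-likelihood collapses correctly in closed-form cases", {
  set.seed(20)
  # single state: sum of per-frame Gaussian log-densities
  h1 <- gaussian_hmm(1, matrix(1), matrix(c(0.5, -1), 1, 2),
                     matrix(c(1, 2), 1, 2))
  X <- matrix(rnorm(10), 5, 2)
  direct <- sum(stats::dnorm(X[, 1], 0.5, 1, log = TRUE)) +
    sum(stats::dnorm(X[, 2], -1, sqrt(2), log = TRUE))
  expect_equal(forward_loglik(h1, X), direct, tolerance = 1e-10)

  # length-1 sequence: log sum_s pi_s N(f; mu_s, var_s)
  h2 <- gaussian_hmm(c(0.3, 0.7), matrix(0.5, 2, 2),
                     matrix(c(0, 3), 2, 1), matrix(c(1, 4), 2, 1))
  f <- 1.7
  expected <- log(0.3 * stats::dnorm(f, 0, 1) + 0.7 * stats::dnorm(f, 3, 2))
  expect_equal(forward_loglik(h2, matrix(f, 1, 1)), expected, tolerance = 1e-10)
})

test_that("forward algorithm matches exhaustive path enumeration", {
  set.seed(21)
  for (S in 2:3) for (T_ in c(2, 4, 6)) {
    pi0 <- runif(S); pi0 <- pi0 / sum(pi0)
    A <- matrix(runif(S * S), S); A <- A / rowSums(A)
    hmm <- gaussian_hmm(pi0, A, matrix(rnorm(S * 2), S, 2),
                        matrix(runif(S * 2, 0.5, 2), S, 2))
    X <- matrix(rnorm(T_ * 2), T_, 2)
    expect_equal(forward_loglik(hmm, X), enum_loglik(hmm, X),
                 tolerance = 1e-8)
  }
})

test_that("Baum-Welch log-likelihood is monotone and converges to a fixed point", {
  set.seed(22)
  gen <- gaussian_hmm(c(0.5, 0.5), matrix(c(.9, .1, .2, .8), 2, byrow = TRUE),
                      matrix(c(0, 10), 2, 1), matrix(1, 2, 1))
  seqs <- lapply(1:20, function(i) sample_hmm(gen, 100))
  fit <- fit_hmm(seqs, n_states = 2, seed = 1, n_restarts = 3)
  trace <- attr(fit, "loglik_trace")
  expect_true(all(diff(trace) > -1e-6))
  # refit from the returned parameters barely moves
  refit <- fit_hmm(seqs, n_states = 2, init = fit, tol = 1e-4)
  tr2 <- attr(refit, "loglik_trace")
  expect_lt(abs(tr2[length(tr2)] - attr(fit, "loglik")), 1e-3)
})

test_that("EM recovers well-separated generating parameters", {
  set.seed(23)
  gen <- gaussian_hmm(c(0.5, 0.5), matrix(c(.95, .05, .05, .95), 2, byrow = TRUE),
                      matrix(c(0, 10), 2, 1), matrix(1, 2, 1))
  seqs <- lapply(1:20, function(i) sample_hmm(gen, 100))
  fit <- fit_hmm(seqs, n_states = 2, seed = 2)
  mu <- sort(as.numeric(fit$means))
  expect_lt(abs(mu[1] - 0), 0.5)
  expect_lt(abs(mu[2] - 10), 0.5)
  # determinism under the seed
  fit2 <- fit_hmm(seqs, n_states = 2, seed = 2)
  expect_identical(fit$means, fit2$means)
})

test_that("constructor validates stochastic constraints", {
  expect_error(gaussian_hmm(c(0.5, 0.6), diag(2), matrix(0, 2, 1),
                            matrix(1, 2, 1)), "sum to 1")
  expect_error(gaussian_hmm(c(0.5, 0.5), matrix(c(1, 1, 0, 1), 2),
                            matrix(0, 2, 1), matrix(1, 2, 1)), "row")
  expect_error(gaussian_hmm(c(0.5, 0.5), diag(2), matrix(0, 2, 1),
                            matrix(1e-9, 2, 1)), "floor")
})

test_that("window classification follows the log-likelihood order with ties
           to inattention", {
  det <- toy_detector(sep = 10)
  set.seed(24)
  X_att <- matrix(rnorm(60, 0.5), 60, 1)
  res <- classify_window(det, X_att)
  expect_equal(as.character(res$decision), "ATTENTION")
  expect_true(is.finite(res$loglik_attention) && is.finite(res$loglik_inattention))
  expect_equal(res$decision == "INATTENTION",
               res$loglik_inattention >= res$loglik_attention)

  # identical models: every window ties -> INATTENTION
  tied <- det
  tied$inattention_hmm <- det$attention_hmm
  expect_equal(as.character(classify_window(tied, X_att)$decision),
               "INATTENTION")
})

test_that("windows drawn from each model's own generative law are assigned to it", {
  det <- toy_detector(sep = 8)
  set.seed(25)
  hits <- replicate(200, {
    X <- sample_hmm(det$attention_hmm, 30)
    as.character(classify_window(det, X)$decision) == "ATTENTION"
  })
  expect_gt(mean(hits), 0.95)
})

test_that("detector training needs both classes and swapping labels inverts
           decisions", {
  set.seed(26)
  n_win <- 30
  F <- rbind(matrix(rnorm(15 * 10 * 5, 0), 15 * 10, 5),
             matrix(rnorm(15 * 10 * 5, 6), 15 * 10, 5))
  starts <- seq(1, 300 - 9, by = 10)
  lw <- structure(data.frame(start = starts, end = starts + 10,
                             var_alt = 1, var_vel = 1,
                             label = factor(rep(c("ATTENTION", "INATTENTION"),
                                                each = 15),
                                            levels = attention_levels())),
                  class = c("labeled_windows", "data.frame"))
  only_in <- lw[lw$label == "INATTENTION", ]
  class(only_in) <- class(lw)
  expect_error(train_detector(F, only_in, seed = 1), "no ATTENTION")

  det <- train_detector(F, lw, n_states = 2, seed = 1, n_restarts = 2)
  swapped <- lw
  swapped$label <- factor(ifelse(lw$label == "ATTENTION", "INATTENTION",
                                 "ATTENTION"), levels = attention_levels())
  class(swapped) <- class(lw)
  det_sw <- train_detector(F, swapped, n_states = 2, seed = 1, n_restarts = 2)
  r1 <- classify_windows(det, F, lw)
  r2 <- classify_windows(det_sw, F, lw)
  expect_gt(mean(r1$decision != r2$decision), 0.9)
})

test_that("SVM baseline separates a toy problem and is seed-deterministic", {
  set.seed(27)
  F <- rbind(matrix(rnorm(200, 0, 0.3), 100, 2),
             matrix(rnorm(200, 4, 0.3), 100, 2))
  starts <- seq(1, 200 - 4, by = 5)
  lw <- structure(data.frame(start = starts, end = starts + 5,
                             var_alt = 1, var_vel = 1,
                             label = factor(rep(c("ATTENTION", "INATTENTION"),
                                                each = 20),
                                            levels = attention_levels())),
                  class = c("labeled_windows", "data.frame"))
  clf <- train_baseline(F, lw, seed = 1)
  pred <- classify_baseline(clf, F, lw)
  expect_equal(mean(pred == lw$label), 1)
  clf2 <- train_baseline(F, lw, seed = 1)
  expect_identical(classify_baseline(clf2, F, lw), pred)
  one_class <- lw[lw$label == "ATTENTION", ]
  class(one_class) <- class(lw)
  expect_error(train_baseline(F, one_class), "both classes")
})
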