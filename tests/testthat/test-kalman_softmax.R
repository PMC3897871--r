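test_that("beliefs initialize to the shared prior", {
  b <- init_beliefs(model_params(), 4L)
  expect_equal(b$pre_mean, rep(67.78, 4))
  expect_equal(b$pre_var, rep(8.18, 4))
  expect_equal(init_beliefs(model_params(mu0_pre = 0), 4L)$pre_mean, rep(0, 4))
  expect_error(init_beliefs(model_params(), 1L), "at least 2")
})

test_that("kalman_update implements the gain, correction and diffusion steps", {
  # zero observation noise: gain 1, posterior mean jumps to the reward
  p0 <- model_params(sigma_o_hat = 0, lambda_hat = 1, sigma_d_hat = 0)
  b <- new_belief <- init_beliefs(p0, 4L)
  nb <- kalman_update(b, 2L, 91, p0)
  expect_equal(nb$pre_mean[2], 91)
  expect_equal(nb$pre_var[2], 0)
  expect_equal(nb$pre_mean[-2], b$pre_mean[-2])

  # equal precision: gain 1/2, posterior mean halfway between prior and reward
  pe <- model_params(sigma_o_hat = 3, var0_pre = 9, lambda_hat = 1,
                     sigma_d_hat = 0)
  nb <- kalman_update(init_beliefs(pe, 4L), 1L, 100, pe)
  expect_equal(nb$pre_mean[1], (67.78 + 100) / 2)
  expect_equal(nb$pre_var[1], 9 / 2)

  # diffusion of an unchosen arm at the default parameters, evaluated by hand
  pd <- model_params()
  nb <- kalman_update(init_beliefs(pd, 4L), 1L, 67.78, pd)
  expect_equal(nb$pre_mean[3], 0.8941 * 67.78 + (1 - 0.8941) * 54.77,
               tolerance = 1e-12)
  expect_equal(nb$pre_var[3], 0.8941^2 * 8.18 + 6.32^2, tolerance = 1e-12)

  expect_error(kalman_update(new_belief_state(c(1, 1), c(-1, 1)), 1L, 5,
                             model_params()), "negative")
  expect_error(kalman_update(init_beliefs(pd, 4L), 9L, 5, pd), "out of range")
})

test_that("the Kalman gain stays in [0, 1] and never inflates the chosen arm", {
  set.seed(31)
  p <- model_params(sigma_o_hat = 4, var0_pre = 8.18)
  b <- init_beliefs(p, 4L)
  for (i in 1:50) {
    a <- sample.int(4, 1)
    k <- b$pre_var[a] / (b$pre_var[a] + p$sigma_o_hat^2)
    expect_gte(k, 0); expect_lte(k, 1)
    nb <- kalman_update(b, a, runif(1, 1, 100), p)
    # posterior variance of the chosen arm cannot exceed its prior variance
    post_var <- (1 - k) * b$pre_var[a]
    expect_lte(post_var, b$pre_var[a] + 1e-12)
    expect_true(all(nb$pre_var >= 0))
    b <- nb
  }
})

test_that("repeated observation drives uncertainty to zero when nothing drifts", {
  p <- model_params(sigma_d_hat = 0, lambda_hat = 1, sigma_o_hat = 4)
  b <- init_beliefs(p, 4L)
  vars <- numeric(100)
  for (i in 1:100) {
    b <- kalman_update(b, 1L, 50, p)
    vars[i] <- b$pre_var[1]
  }
  # harmonic shrinkage: v_k is about sigma_o^2 / k
  expect_true(all(diff(vars) < 0))
  expect_lt(vars[100], 0.3)
})

test_that("softmax probabilities are normalized, ordered and overflow-safe", {
  b <- new_belief_state(c(60, 50, 50, 50), rep(1, 4))
  expect_equal(choice_probabilities(b, 0), rep(0.25, 4))
  p <- choice_probabilities(b, 0.18)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[1], exp(0.18 * 60) / (exp(0.18 * 60) + 3 * exp(0.18 * 50)),
               tolerance = 1e-12)
  # greedy limit concentrates on the argmax
  expect_gt(choice_probabilities(b, 50)[1], 1 - 1e-12)
  # products beta * mean far beyond exp() range must not overflow
  bb <- new_belief_state(c(5000, 4000, 3000, 2000), rep(1, 4))
  p <- choice_probabilities(bb, 1)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(choice_probabilities(b, -1), "beta")
})

test_that("a uniform chooser has the closed-form likelihood N * log(4)", {
  sch <- generate_schedule(task_config(), seed = 21)
  s <- play_session(sch, softmax_policy(0.3), seed = 22, miss_rate = 0.05)
  n_resp <- sum(!s$missed)
  expect_equal(session_nll(s, model_params(beta = 0)), n_resp * log(4),
               tolerance = 1e-9 / (n_resp * log(4)))
})

test_that("session_nll matches the stepwise naive oracle on random sessions", {
  set.seed(77)
  for (rep in 1:80) {
    n <- sample(5:40, 1)
    missed <- runif(n) < 0.15
    s <- make_session(choices = sample.int(4, n, replace = TRUE),
                      rewards = sample.int(100, n, replace = TRUE),
                      missed = missed)
    p <- model_params(lambda_hat = runif(1, 0.5, 1),
                      theta_hat = runif(1, 20, 80),
                      sigma_d_hat = runif(1, 0, 10),
                      sigma_o_hat = sample(c(0, runif(1, 0.5, 8)), 1),
                      mu0_pre = runif(1, 0, 100),
                      var0_pre = runif(1, 0, 20),
                      beta = runif(1, 0, 0.5))
    expect_equal(session_nll(s, p), naive_session_nll(s, p), tolerance = 1e-9)
  }
})

test_that("likelihood decreases in beta when choices are greedy on the beliefs", {
  sch <- generate_schedule(task_config(), seed = 23)
  greedy <- function(b) {
    p <- numeric(length(b$pre_mean)); p[which.max(b$pre_mean)] <- 1; p
  }
  s <- play_session(sch, greedy, seed = 24)
  p0 <- session_nll(s, model_params(beta = 0))
  p_small <- session_nll(s, model_params(beta = 0.01))
  expect_lt(p_small, p0)
})

test_that("missed trials advance beliefs but add no likelihood", {
  p <- model_params(beta = 0.2)
  s_resp <- make_session(choices = c(1L, 2L), rewards = c(90, 10))
  # same second trial, but the first trial is missed
  s_miss <- make_session(choices = c(1L, 2L), rewards = c(0, 10),
                         missed = c(TRUE, FALSE))
  # with a missed first trial the second-trial beliefs are the diffused prior
  nll_direct <- -log(choice_probabilities(
    diffuse_beliefs(init_beliefs(p, 4L), p), p$beta)[2])
  expect_equal(session_nll(s_miss, p), nll_direct, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(session_nll(s_miss, p),
                                session_nll(s_resp, p))))
})

test_that("model parameters round-trip through JSON", {
  p <- model_params(beta = 0.123, sigma_o_hat = 2.5)
  path <- file.path(withr::local_tempdir(), "params.json")
  write_model_params(p, path)
  expect_equal(read_model_params(path), p)
})
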