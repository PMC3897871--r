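#' Kalman-softmax learner parameters
#'
#' Parameters of the choice model: a per-arm Kalman filter tracks a Gaussian
#' belief (mean, variance) over each slot machine's payoff under the same
#' AR(1) diffusion prior that generates the task, and a softmax over the
#' pre-choice belief means produces choice probabilities,
#' `P(i) = exp(beta * m_i) / sum_j exp(beta * m_j)`.
#'
#' Defaults are the best-fitting maximum-likelihood values for this task
#' family: `lambda_hat = 0.8941`, `theta_hat = 54.77`, `sigma_d_hat = 6.32`,
#' `sigma_o_hat = 0`, prior mean `mu0_pre = 67.78`, prior variance
#' `var0_pre = 8.18`. `beta` is the inverse temperature in 1/points; 0 is a
#' uniform chooser, large values approach the greedy chooser. Note that with
#' `sigma_o_hat = 0` the Kalman gain is 1 and the belief mean jumps to each
#' observed reward before diffusing.
#'
#' @param lambda_hat Belief decay parameter, in (0, 1].
#' @param theta_hat Belief decay center, points.
#' @param sigma_d_hat Belief diffusion SD, points; >= 0.
#' @param sigma_o_hat Assumed observation noise SD, points; >= 0.
#' @param mu0_pre Initial prior mean shared by all arms, points.
#' @param var0_pre Initial prior variance shared by all arms, points^2.
#' @param beta Softmax inverse temperature, 1/points; >= 0.
#' @return An object of class `model_params`.
#' @export
model_params <- function(lambda_hat = 0.8941, theta_hat = 54.77,
                         sigma_d_hat = 6.32, sigma_o_hat = 0,
                         mu0_pre = 67.78, var0_pre = 8.18, beta = 0.18) {
  p <- list(lambda_hat = lambda_hat, theta_hat = theta_hat,
            sigma_d_hat = sigma_d_hat, sigma_o_hat = sigma_o_hat,
            mu0_pre = mu0_pre, var0_pre = var0_pre, beta = beta)
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (!(p$lambda_hat > 0 && p$lambda_hat <= 1))
    stop("model_params: lambda_hat must lie in (0, 1]", call. = FALSE)
  if (p$sigma_d_hat < 0 || p$sigma_o_hat < 0)
    stop("model_params: noise SDs must be >= 0", call. = FALSE)
  if (p$var0_pre < 0)
    stop("model_params: var0_pre must be >= 0", call. = FALSE)
  if (p$beta < 0)
    stop("model_params: beta must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Kalman-softmax model parameters\n")
  cat(sprintf("  learning: lambda = %.4f, theta = %.2f, sigma_d = %.2f, sigma_o = %.2f\n",
              x$lambda_hat, x$theta_hat, x$sigma_d_hat, x$sigma_o_hat))
  cat(sprintf("  prior: mu0 = %.2f, var0 = %.2f; softmax beta = %.4f /point\n",
              x$mu0_pre, x$var0_pre, x$beta))
  invisible(x)
}

#' Serialize / deserialize model parameters as flat JSON
#' @param params A [model_params()].
#' @param path JSON file path.
#' @return `read_model_params` returns a `model_params`; `write_model_params`
#'   invisibly returns `path`.
#' @export
write_model_params <- function(params, path) {
  validate_model_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  do.call(model_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

new_belief_state <- function(pre_mean, pre_var, trial = 1L) {
  structure(list(pre_mean = pre_mean, pre_var = pre_var,
                 trial = as.integer(trial)),
            class = "belief_state")
}

#' Initialize per-arm beliefs
#'
#' All arms start from the same prior: mean `mu0_pre`, variance `var0_pre`.
#'
#' @param params A [model_params()].
#' @param n_arms Number of arms (>= 2).
#' @return A `belief_state`: list with `pre_mean`, `pre_var` (length
#'   `n_arms`) and the trial index.
#' @export
init_beliefs <- function(params, n_arms = 4L) {
  validate_model_params(params)
  if (n_arms < 2L) stop("init_beliefs: need at least 2 arms", call. = FALSE)
  new_belief_state(rep(params$mu0_pre, n_arms), rep(params$var0_pre, n_arms))
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("Belief state at trial %d\n", x$trial))
  cat("  pre-choice means:    ", paste(sprintf("%.2f", x$pre_mean), collapse = " "), "\n")
  cat("  pre-choice variances:", paste(sprintf("%.2f", x$pre_var), collapse = " "), "\n")
  invisible(x)
}

## Kalman gain with the 0/0 limit (pre_var = sigma_o = 0) defined as 1.
kalman_gain <- function(pre_var, sigma_o) {
  denom <- pre_var + sigma_o^2
  ifelse(denom < 1e-12, 1, pre_var / denom)
}

#' One Kalman belief update plus diffusion
#'
#' Observation step on the chosen arm — gain
#' `k = v_c / (v_c + sigma_o^2)` (defined as 1 in the 0/0 limit), posterior
#' mean `m_c + k * (reward - m_c)`, posterior variance `(1 - k) * v_c`;
#' unchosen arms keep their prior as posterior — followed by the diffusion
#' step for every arm: next pre-mean `lambda * m + (1 - lambda) * theta`,
#' next pre-variance `lambda^2 * v + sigma_d^2`.
#'
#' @param belief A `belief_state` (see [init_beliefs()]).
#' @param chosen Index of the chosen arm.
#' @param reward Observed payoff, points.
#' @param params A [model_params()].
#' @return The next trial's `belief_state`.
#' @export
kalman_update <- function(belief, chosen, reward, params) {
  validate_model_params(params)
  m <- belief$pre_mean; v <- belief$pre_var
  if (any(v < 0)) stop("kalman_update: negative prior variance", call. = FALSE)
  if (chosen < 1L || chosen > length(m))
    stop("kalman_update: chosen arm out of range", call. = FALSE)
  if (!is.finite(reward)) stop("kalman_update: reward must be finite", call. = FALSE)
  k <- kalman_gain(v[chosen], params$sigma_o_hat)
  m[chosen] <- m[chosen] + k * (reward - m[chosen])
  v[chosen] <- (1 - k) * v[chosen]
  new_belief_state(params$lambda_hat * m + (1 - params$lambda_hat) * params$theta_hat,
                   params$lambda_hat^2 * v + params$sigma_d_hat^2,
                   belief$trial + 1L)
}

## Diffusion-only step (missed trial: time passes, nothing observed).
diffuse_beliefs <- function(belief, params) {
  new_belief_state(params$lambda_hat * belief$pre_mean +
                     (1 - params$lambda_hat) * params$theta_hat,
                   params$lambda_hat^2 * belief$pre_var + params$sigma_d_hat^2,
                   belief$trial + 1L)
}

#' Softmax choice probabilities over belief means
#'
#' `P(i) = exp(beta * m_i) / sum_j exp(beta * m_j)`, computed with max
#' subtraction so large `beta * m` products cannot overflow. `beta = 0`
#' gives the uniform distribution; as `beta` grows the mass concentrates on
#' the arm with the highest believed mean.
#'
#' @param belief A `belief_state`.
#' @param beta Inverse temperature, 1/points; >= 0.
#' @return Probability vector over arms (sums to 1).
#' @examples
#' b <- init_beliefs(model_params())
#' choice_probabilities(b, beta = 0)     # uniform
#' @export
choice_probabilities <- function(belief, beta) {
  if (beta < 0) stop("choice_probabilities: beta must be >= 0", call. = FALSE)
  z <- beta * belief$pre_mean
  e <- exp(z - max(z))
  e / sum(e)
}

#' A softmax policy closure for [play_session()]
#' @param beta Inverse temperature, 1/points.
#' @return Function mapping a `belief_state` to choice probabilities.
#' @export
softmax_policy <- function(beta) {
  force(beta)
  function(belief) choice_probabilities(belief, beta)
}

#' Negative log-likelihood of a session under the Kalman-softmax model
#'
#' Walks the session in trial order, accumulating `-log P(chosen | beliefs,
#' beta)` over responded trials. Beliefs are advanced by the full Kalman
#' update after each responded trial and by the diffusion-only step after
#' each missed trial; missed trials contribute nothing to the likelihood.
#' Choice probabilities use the pre-choice (prior) means — the belief held
#' before the trial's reward is seen.
#'
#' @param session A `session_record`.
#' @param params A [model_params()] (its `beta` is the softmax parameter
#'   used).
#' @param n_arms Number of arms; defaults to the largest chosen index, at
#'   least 2.
#' @return Negative log-likelihood in nats (scalar).
#' @examples
#' sch <- generate_schedule(task_config(), seed = 1)
#' s <- play_session(sch, softmax_policy(0), seed = 2)
#' session_nll(s, model_params(beta = 0))  # = 300 * log(4)
#' @export
session_nll <- function(session, params, n_arms = NULL) {
  stopifnot(inherits(session, "session_record"))
  validate_model_params(params)
  if (is.null(n_arms)) n_arms <- max(4L, session$choice, na.rm = TRUE)
  ord <- order(session$trial)
  choices <- session$choice[ord]; rewards <- session$reward[ord]
  missed <- session$missed[ord]
  nll <- cpp_session_nll(ifelse(missed, -1L, choices - 1L), rewards,
                         as.integer(n_arms),
                         params$lambda_hat, params$theta_hat,
                         params$sigma_d_hat, params$sigma_o_hat,
                         params$mu0_pre, params$var0_pre, params$beta)
  if (!is.finite(nll))
    stop("session_nll: non-finite log-likelihood encountered", call. = FALSE)
  nll
}

#' Pre-choice belief means for every trial of a session
#'
#' The belief trajectory used by both the likelihood and the explore/exploit
#' labelling: row `t` holds the per-arm prior means immediately before trial
#' `t`'s choice, with beliefs advanced exactly as in [session_nll()].
#'
#' @inheritParams session_nll
#' @return Numeric matrix, trials x arms.
#' @export
prechoice_means <- function(session, params, n_arms = NULL) {
  stopifnot(inherits(session, "session_record"))
  validate_model_params(params)
  if (is.null(n_arms)) n_arms <- max(4L, session$choice, na.rm = TRUE)
  ord <- order(session$trial)
  cpp_prechoice_means(ifelse(session$missed[ord], -1L, session$choice[ord] - 1L),
                      session$reward[ord], as.integer(n_arms),
                      params$lambda_hat, params$theta_hat,
                      params$sigma_d_hat, params$sigma_o_hat,
                      params$mu0_pre, params$var0_pre)
}
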