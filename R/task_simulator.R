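#' Task configuration for the restless four-armed bandit
#'
#' Bundles the generating-process parameters of the restless bandit task:
#' per-arm latent mean payoffs diffuse in a decaying Gaussian random walk,
#' mu[t+1] = lambda * mu[t] + (1 - lambda) * theta + nu, and the payoff shown
#' on a trial is a Gaussian draw around the arm's latent mean, rounded to the
#' nearest integer and kept inside the payoff bounds.
#'
#' Defaults are the task's generating values: decay `lambda_gen = 0.9836`
#' toward center `theta_gen = 50`, diffusion noise SD `sigma_d_gen = 2.8`,
#' payoff noise SD `sigma_o_gen = 4`, payoffs in 1..100 points, 300 trials in
#' 4 runs, and a 1.5 s response window.
#'
#' @param n_arms Number of slot machines.
#' @param n_trials Total trials; must be divisible by `n_runs`.
#' @param n_runs Number of runs the trials are split into.
#' @param lambda_gen Decay parameter of the mean process, in (0, 1].
#' @param theta_gen Decay center of the mean process, points.
#' @param sigma_d_gen Diffusion noise SD, points; >= 0.
#' @param sigma_o_gen Payoff (observation) noise SD, points; >= 0.
#' @param payoff_min,payoff_max Integer payoff bounds, points.
#' @param boundary_mode How draws outside the payoff bounds are handled:
#'   `"reflect"` (default; folded back at the bounds before rounding, which
#'   avoids probability mass piling up at 1 and 100) or `"clamp"`.
#' @param choice_window Response window, seconds.
#' @param seed Optional integer seed recorded with the config and used by
#'   [generate_schedule()] when no explicit seed is passed there.
#'
#' @return An object of class `task_config` (a validated list).
#' @seealso [generate_schedule()], [step_means()]
#' @export
task_config <- function(n_arms = 4L, n_trials = 300L, n_runs = 4L,
                        lambda_gen = 0.9836, theta_gen = 50,
                        sigma_d_gen = 2.8, sigma_o_gen = 4,
                        payoff_min = 1L, payoff_max = 100L,
                        boundary_mode = c("reflect", "clamp"),
                        choice_window = 1.5, seed = NULL) {
  boundary_mode <- match.arg(boundary_mode)
  cfg <- list(
    n_arms = as.integer(n_arms), n_trials = as.integer(n_trials),
    n_runs = as.integer(n_runs), lambda_gen = lambda_gen,
    theta_gen = theta_gen, sigma_d_gen = sigma_d_gen,
    sigma_o_gen = sigma_o_gen, payoff_min = as.integer(payoff_min),
    payoff_max = as.integer(payoff_max), boundary_mode = boundary_mode,
    choice_window = choice_window,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$n_arms < 2L) stop("task_config: need at least 2 arms", call. = FALSE)
  if (cfg$n_trials < 1L) stop("task_config: n_trials must be positive", call. = FALSE)
  if (cfg$n_trials %% cfg$n_runs != 0L)
    stop("task_config: n_trials must be a multiple of n_runs", call. = FALSE)
  if (!(cfg$lambda_gen > 0 && cfg$lambda_gen <= 1))
    stop("task_config: lambda_gen must lie in (0, 1]", call. = FALSE)
  if (cfg$sigma_d_gen < 0 || cfg$sigma_o_gen < 0)
    stop("task_config: noise SDs must be >= 0", call. = FALSE)
  if (cfg$payoff_min >= cfg$payoff_max)
    stop("task_config: payoff_min must be < payoff_max", call. = FALSE)
  if (cfg$choice_window <= 0)
    stop("task_config: choice_window must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Restless bandit task configuration\n")
  cat(sprintf("  %d arms, %d trials in %d runs of %d\n",
              x$n_arms, x$n_trials, x$n_runs, x$n_trials %/% x$n_runs))
  cat(sprintf("  mean process: lambda = %.4f, theta = %g, sigma_d = %g\n",
              x$lambda_gen, x$theta_gen, x$sigma_d_gen))
  cat(sprintf("  payoffs: Gaussian(mu, %g), integers in [%d, %d], %s at bounds\n",
              x$sigma_o_gen, x$payoff_min, x$payoff_max, x$boundary_mode))
  cat(sprintf("  choice window: %g s\n", x$choice_window))
  invisible(x)
}

#' Advance the latent mean payoffs by one trial
#'
#' One step of the decaying Gaussian random walk that drives the bandit:
#' `lambda * mu + (1 - lambda) * theta + noise`, elementwise per arm. The
#' latent means are unbounded; only realized payoffs are kept inside the
#' payoff bounds.
#'
#' @param mu Numeric vector of current latent means, one per arm.
#' @param config A [task_config()].
#' @param noise The realized diffusion draw `nu` (vector recycled to
#'   `length(mu)`). Supplying it explicitly makes the step deterministic for
#'   testing; the default draws `N(0, sigma_d_gen)` per arm.
#' @return Numeric vector of next-trial latent means.
#' @examples
#' cfg <- task_config()
#' step_means(rep(50, 4), cfg, noise = 0)  # 50 is the fixed point
#' @export
step_means <- function(mu, config, noise = NULL) {
  validate_task_config(config)
  if (length(mu) != config$n_arms)
    stop(sprintf("step_means: mu has %d entries, config expects %d arms",
                 length(mu), config$n_arms), call. = FALSE)
  if (is.null(noise)) {
    noise <- stats::rnorm(length(mu), 0, config$sigma_d_gen)
  } else if (!(length(noise) %in% c(1L, length(mu)))) {
    stop("step_means: noise must have length 1 or n_arms", call. = FALSE)
  }
  config$lambda_gen * mu + (1 - config$lambda_gen) * config$theta_gen + noise
}

## Stationary moments of the AR(1) mean process; used for the default
## initializer and exposed for tests.
stationary_mean_var <- function(config) {
  if (config$lambda_gen >= 1)
    return(c(mean = config$theta_gen, var = Inf))
  c(mean = config$theta_gen,
    var = config$sigma_d_gen^2 / (1 - config$lambda_gen^2))
}

## Fold values back into [lo, hi] by repeated reflection at the bounds.
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  r <- (x - lo) %% (2 * w)
  lo + ifelse(r > w, 2 * w - r, r)
}

#' Generate a payoff schedule for the restless bandit
#'
#' Evolves each arm's latent mean by the decaying Gaussian random walk and
#' draws the integer payoff shown on each trial: `round(N(mu[i, t],
#' sigma_o))`, kept inside `[payoff_min, payoff_max]` by reflection (default)
#' or clamping. Initial means are drawn per arm from the stationary
#' distribution of the mean process (Gaussian with mean `theta` and variance
#' `sigma_d^2 / (1 - lambda^2)`) so that early trials are statistically
#' typical; pass `init_means` to override.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; defaults to the seed stored in `config`. The
#'   schedule is fully reproducible from it.
#' @param init_means Optional numeric vector of starting latent means.
#' @return An object of class `payoff_schedule`: list with `means` and
#'   `payoffs` matrices (`n_trials` x `n_arms`), the `config`, and the `seed`
#'   used.
#' @examples
#' sch <- generate_schedule(task_config(), seed = 1)
#' range(sch$payoffs)
#' @export
generate_schedule <- function(config = task_config(), seed = config$seed,
                              init_means = NULL) {
  validate_task_config(config)
  if (!is.null(seed)) local_seed(seed)
  nt <- config$n_trials; na <- config$n_arms
  lam <- config$lambda_gen; theta <- config$theta_gen

  if (is.null(init_means)) {
    sv <- stationary_mean_var(config)
    init_means <- if (is.finite(sv["var"])) {
      stats::rnorm(na, sv["mean"], sqrt(sv["var"]))
    } else rep(theta, na)  # pure random walk: start at the center
  }
  if (length(init_means) != na)
    stop("generate_schedule: init_means must have one entry per arm", call. = FALSE)

  ## AR(1) recursion vectorized per arm via stats::filter.
  means <- matrix(NA_real_, nt, na)
  means[1L, ] <- init_means
  if (nt > 1L) {
    drive <- matrix((1 - lam) * theta +
                      stats::rnorm((nt - 1L) * na, 0, config$sigma_d_gen),
                    nt - 1L, na)
    for (a in seq_len(na)) {
      means[-1L, a] <- stats::filter(drive[, a], lam, method = "recursive",
                                     init = init_means[a])
    }
  }

  raw <- means + stats::rnorm(nt * na, 0, config$sigma_o_gen)
  payoffs <- switch(config$boundary_mode,
    reflect = round(reflect_into(raw, config$payoff_min, config$payoff_max)),
    clamp   = pmin(pmax(round(raw), config$payoff_min), config$payoff_max)
  )
  storage.mode(payoffs) <- "integer"

  structure(list(means = means, payoffs = payoffs, config = config,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "payoff_schedule")
}

#' @export
print.payoff_schedule <- function(x, ...) {
  cat(sprintf("Payoff schedule: %d trials x %d arms (seed %s)\n",
              nrow(x$payoffs), ncol(x$payoffs),
              ifelse(is.na(x$seed), "unset", x$seed)))
  cat(sprintf("  payoff range observed: [%d, %d]; latent means in [%.1f, %.1f]\n",
              min(x$payoffs), max(x$payoffs), min(x$means), max(x$means)))
  invisible(x)
}

#' Play one session of the bandit against a choice policy
#'
#' Runs an agent through a payoff schedule trial by trial. On each trial the
#' agent either misses (with probability `miss_rate`: no choice, zero reward,
#' no response time — a red X trial) or samples an arm from the policy's
#' choice probabilities, collects the scheduled payoff, and draws a response
#' time from `rt_sampler` truncated to `(0, choice_window]`. Beliefs are
#' advanced by the Kalman update after responded trials and by the
#' diffusion-only step after missed trials.
#'
#' @param schedule A [generate_schedule()] result.
#' @param policy Function taking a `belief_state` and returning a probability
#'   vector over arms (e.g. [softmax_policy()]).
#' @param params [model_params()] governing the agent's belief updates.
#' @param rt_sampler Function `n -> n response times (seconds)`; draws outside
#'   `(0, choice_window]` are resampled. Default: uniform on (0.2, 0.6).
#' @param miss_rate Probability a trial is missed, in [0, 1].
#' @param seed Optional integer seed.
#' @param subject,group Identifier and group label stored on the record.
#' @return A `session_record`: data.frame with columns `trial`, `run`,
#'   `choice` (NA when missed), `reward`, `rt`, `missed`, carrying `subject`
#'   and `group` attributes.
#' @export
play_session <- function(schedule, policy, params = model_params(),
                         rt_sampler = function(n) stats::runif(n, 0.2, 0.6),
                         miss_rate = 0, seed = NULL,
                         subject = "s1", group = NA_character_) {
  stopifnot(inherits(schedule, "payoff_schedule"))
  if (miss_rate < 0 || miss_rate >= 1 + 1e-12)
    stop("play_session: miss_rate must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) local_seed(seed)
  cfg <- schedule$config
  nt <- cfg$n_trials; na <- cfg$n_arms
  validate_model_params(params)

  missed <- stats::runif(nt) < miss_rate
  choice <- rep(NA_integer_, nt)
  reward <- integer(nt)
  rt <- rep(NA_real_, nt)

  m <- rep(params$mu0_pre, na)
  v <- rep(params$var0_pre, na)
  for (t in seq_len(nt)) {
    if (!missed[t]) {
      p <- policy(new_belief_state(m, v, t))
      if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
        stop("play_session: policy returned a non-normalized probability vector",
             call. = FALSE)
      a <- sample.int(na, 1L, prob = p)
      choice[t] <- a
      reward[t] <- schedule$payoffs[t, a]
      repeat {
        r <- rt_sampler(1L)
        if (r > 0 && r <= cfg$choice_window) break
      }
      rt[t] <- r
      ## chosen-arm Kalman correction, then diffusion for every arm
      k <- kalman_gain(v[a], params$sigma_o_hat)
      m[a] <- m[a] + k * (reward[t] - m[a])
      v[a] <- (1 - k) * v[a]
    }
    m <- params$lambda_hat * m + (1 - params$lambda_hat) * params$theta_hat
    v <- params$lambda_hat^2 * v + params$sigma_d_hat^2
  }

  session_record(trial = seq_len(nt),
                 run = rep(seq_len(cfg$n_runs), each = nt %/% cfg$n_runs),
                 choice = choice, reward = reward, rt = rt, missed = missed,
                 subject = subject, group = group)
}

#' Construct a session record
#'
#' A session record is one subject's trial log: the trial and run indices,
#' the chosen arm (NA on missed trials), the reward collected, the response
#' time in seconds, and the missed flag, with the subject id and group label
#' attached as attributes.
#'
#' @param trial,run,choice,reward,rt,missed Per-trial columns.
#' @param subject Subject identifier.
#' @param group Group label (e.g. `"entrepreneur"` / `"manager"`).
#' @return A data.frame of class `session_record`.
#' @export
session_record <- function(trial, run, choice, reward, rt, missed,
                           subject = "s1", group = NA_character_) {
  d <- data.frame(trial = as.integer(trial), run = as.integer(run),
                  choice = as.integer(choice), reward = as.numeric(reward),
                  rt = as.numeric(rt), missed = as.logical(missed))
  if (any(d$missed & !is.na(d$choice)))
    stop("session_record: missed trials cannot carry a choice", call. = FALSE)
  if (any(!d$missed & is.na(d$choice)))
    stop("session_record: responded trials need a choice", call. = FALSE)
  if (any(!d$missed & (is.na(d$rt) | d$rt <= 0)))
    stop("session_record: responded trials need a positive response time",
         call. = FALSE)
  attr(d, "subject") <- as.character(subject)
  attr(d, "group") <- as.character(group)
  class(d) <- c("session_record", "data.frame")
  d
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Session %s (group %s): %d trials, %d responded, total payoff %g\n",
              attr(x, "subject"), attr(x, "group"), nrow(x),
              sum(!x$missed), sum(x$reward[!x$missed])))
  NextMethod()
}

#' Write / read a payoff schedule as CSV
#'
#' Long format with columns `trial`, `arm`, `latent_mean`, `payoff`; the task
#' configuration is echoed to a JSON sidecar (`<path>.json`) so a schedule
#' round-trips completely.
#'
#' @param schedule A `payoff_schedule`.
#' @param path CSV path.
#' @return `write_schedule` invisibly returns `path`; `read_schedule` returns
#'   the reconstructed `payoff_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "payoff_schedule"))
  nt <- nrow(schedule$payoffs); na <- ncol(schedule$payoffs)
  long <- data.frame(trial = rep(seq_len(nt), na),
                     arm = rep(seq_len(na), each = nt),
                     latent_mean = as.vector(schedule$means),
                     payoff = as.vector(schedule$payoffs))
  write_csv_full(long, path)
  cfg <- schedule$config
  cfg_out <- unclass(cfg)
  cfg_out$schedule_seed <- schedule$seed
  jsonlite::write_json(cfg_out, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_schedule
#' @param path CSV path written by [write_schedule()].
#' @export
read_schedule <- function(path) {
  long <- utils::read.csv(path)
  stopifnot(all(c("trial", "arm", "latent_mean", "payoff") %in% names(long)))
  cfg_json <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  seed_used <- cfg_json$schedule_seed
  cfg_json$schedule_seed <- NULL
  cfg <- do.call(task_config, cfg_json[!vapply(cfg_json, is.null, logical(1))])
  nt <- max(long$trial); na <- max(long$arm)
  means <- matrix(NA_real_, nt, na)
  payoffs <- matrix(NA_integer_, nt, na)
  means[cbind(long$trial, long$arm)] <- long$latent_mean
  payoffs[cbind(long$trial, long$arm)] <- long$payoff
  structure(list(means = means, payoffs = payoffs, config = cfg,
                 seed = if (is.null(seed_used)) NA_integer_ else as.integer(seed_used)),
            class = "payoff_schedule")
}

## Seed handling: set the RNG for the calling function's scope and restore
## the previous state when that scope exits.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  restore <- function() {
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
  assign(".rb_seed_restore", restore, envir = env)
  do.call(on.exit, list(quote(.rb_seed_restore()), add = TRUE), envir = env)
  invisible(seed)
}
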