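#' Configuration of the synthetic study cohort
#'
#' Describes the simulated two-group study the pipeline is exercised on:
#' group A is "entrepreneur-like" (24 subjects), group B "manager-like"
#' (26 subjects), every subject plays 300 trials of the restless bandit
#' through a Kalman-softmax agent. Per-subject inverse temperatures are
#' drawn from group Gaussians (means 0.19 / 0.17, SDs 0.08 / 0.09,
#' truncated at 0). Response times are hierarchical lognormals: each
#' subject's mean RT is drawn from a lognormal moment-matched to the group's
#' across-subject target mean and SD (0.389 s, 0.043 s vs 0.454 s, 0.095 s),
#' and trial RTs scatter lognormally around the subject mean with
#' within-subject SD `rt_trial_sd`. ROI activity tables are generated with
#' planted explore/exploit condition effects, a planted choice-by-group
#' interaction in the switching-study FPC sphere, and an efficiency-coupled
#' component.
#'
#' @param n_group_A,n_group_B Group sizes (entrepreneur-like, manager-like).
#' @param beta_mean,beta_sd Length-2 vectors (A, B) of softmax inverse
#'   temperature means and SDs, 1/points.
#' @param rt_mean,rt_sd Length-2 vectors (A, B): across-subject mean and SD
#'   of per-subject mean RTs, seconds.
#' @param rt_trial_sd Within-subject trial-to-trial RT SD, seconds.
#' @param miss_rate Per-trial miss probability.
#' @param learning_params [model_params()] shared by all simulated agents.
#' @param task [task_config()] of the bandit the cohort plays.
#' @param share_schedule Reuse one fixed-seed payoff schedule for all
#'   subjects (default, matching a study where everyone faces the same
#'   payoff structure); `FALSE` regenerates per subject.
#' @param roi_effects ROI generator settings; see [roi_effect_defaults()].
#' @param seed Master seed; every derived draw is reproducible from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_group_A = 24L, n_group_B = 26L,
                          beta_mean = c(0.19, 0.17),
                          beta_sd = c(0.08, 0.09),
                          rt_mean = c(0.389, 0.454),
                          rt_sd = c(0.043, 0.095),
                          rt_trial_sd = 0.08, miss_rate = 0.01,
                          learning_params = model_params(),
                          task = task_config(),
                          share_schedule = TRUE,
                          roi_effects = roi_effect_defaults(),
                          seed = 1L) {
  cfg <- list(n_group_A = as.integer(n_group_A),
              n_group_B = as.integer(n_group_B),
              beta_mean = beta_mean, beta_sd = beta_sd,
              rt_mean = rt_mean, rt_sd = rt_sd, rt_trial_sd = rt_trial_sd,
              miss_rate = miss_rate, learning_params = learning_params,
              task = task, share_schedule = isTRUE(share_schedule),
              roi_effects = roi_effects, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_group_A < 2L || cfg$n_group_B < 2L)
    stop("cohort_config: each group needs at least 2 subjects", call. = FALSE)
  stopifnot(length(cfg$beta_mean) == 2L, length(cfg$beta_sd) == 2L,
            length(cfg$rt_mean) == 2L, length(cfg$rt_sd) == 2L)
  if (any(cfg$beta_sd < 0) || any(cfg$rt_sd < 0) || cfg$rt_trial_sd < 0)
    stop("cohort_config: SDs must be >= 0", call. = FALSE)
  if (any(cfg$rt_mean <= 0) || any(cfg$rt_mean >= cfg$task$choice_window))
    stop("cohort_config: rt_mean must lie in (0, choice_window)", call. = FALSE)
  if (cfg$miss_rate < 0 || cfg$miss_rate >= 1)
    stop("cohort_config: miss_rate must lie in [0, 1)", call. = FALSE)
  validate_model_params(cfg$learning_params)
  validate_task_config(cfg$task)
  invisible(cfg)
}

#' Default planted ROI effect structure
#'
#' Condition effects are per-subject explore-minus-exploit mean shifts in
#' estimate units: positive (explore > exploit) in the fronto-parietal,
#' dACC and LC spheres, negative (exploit > explore) in vmPFC. The
#' switching-study FPC sphere instead carries a planted choice-by-group
#' interaction: each subject's explore-exploit difference is drawn from a
#' group Gaussian (A: mean 0.67, SD 1.60; B: mean -0.15, SD 1.18).
#' `eff_coupling` adds `coupling * z(efficiency)` (z-scored within group, so
#' the planted group structure is untouched) to the named
#' ROI-by-condition estimates so that the efficiency regression has signal;
#' `noise_sd` is the per-condition estimate noise.
#'
#' @param cond_effect Named explore-minus-exploit effects per ROI.
#' @param interaction_roi ROI carrying the planted interaction.
#' @param interaction_mean,interaction_sd Length-2 (A, B) mean and SD of the
#'   per-subject explore-exploit difference in `interaction_roi`.
#' @param eff_coupling Named vector, names `"<roi>_<condition>"`.
#' @param noise_sd Estimate noise SD.
#' @param baseline Baseline activity level.
#' @return List of generator settings.
#' @export
roi_effect_defaults <- function(
    cond_effect = c(vmPFC = -1.02, L_FPC = 0.41, R_FPC = 0.53, L_IPS = 0.81,
                    R_IPS = 1.24, dACC = 0.90, LC_left = 0.33,
                    LC_right = 0.33),
    interaction_roi = "R_FPC_switch",
    interaction_mean = c(0.67, -0.15),
    interaction_sd = c(1.60, 1.18),
    eff_coupling = c(R_FPC_switch_exploit = 0.5, vmPFC_explore = -0.3,
                     dACC_exploit = 0.3),
    noise_sd = 1, baseline = 0) {
  list(cond_effect = cond_effect, interaction_roi = interaction_roi,
       interaction_mean = interaction_mean, interaction_sd = interaction_sd,
       eff_coupling = eff_coupling, noise_sd = noise_sd, baseline = baseline)
}

## Lognormal meanlog/sdlog matching a target mean m and SD s by moments.
lognormal_from_moments <- function(m, s) {
  m <- unname(m); s <- unname(s)
  if (s <= 0) return(c(meanlog = log(m), sdlog = 0))
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a full synthetic cohort of bandit sessions
#'
#' Draws each subject's inverse temperature and mean response time from the
#' group distributions in the config, then simulates the subject's 300-trial
#' session with a Kalman-softmax agent on the (by default shared) payoff
#' schedule, applying the miss rate. Reproducible from the master seed:
#' per-subject seeds are derived from it, so the same config and seed give
#' identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed override; defaults to `config$seed`.
#' @return A `cohort` list: `sessions` (list of `session_record`),
#'   `groups` (named subject-to-group vector), `betas` and `rt_subject_mean`
#'   (named true generating values), `schedule`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  local_seed(seed)
  nA <- config$n_group_A; nB <- config$n_group_B
  n <- nA + nB
  ids <- c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB)))
  grp <- stats::setNames(rep(c("entrepreneur_like", "manager_like"),
                             c(nA, nB)), ids)
  gi <- rep(1:2, c(nA, nB))  # group index into the length-2 config vectors

  ## truncated-at-zero Gaussian betas
  betas <- stats::setNames(numeric(n), ids)
  for (i in seq_len(n)) {
    repeat {
      b <- stats::rnorm(1, config$beta_mean[gi[i]], config$beta_sd[gi[i]])
      if (b >= 0) break
    }
    betas[i] <- b
  }

  ## per-subject mean RTs from the group's across-subject lognormal
  rt_mu <- stats::setNames(numeric(n), ids)
  for (g in 1:2) {
    par <- lognormal_from_moments(config$rt_mean[g], config$rt_sd[g])
    k <- which(gi == g)
    repeat {
      rt_mu[k] <- stats::rlnorm(length(k), par["meanlog"], par["sdlog"])
      if (all(rt_mu[k] < config$task$choice_window)) break
    }
  }

  shared <- if (config$share_schedule)
    generate_schedule(config$task, seed = sample.int(2^31 - 1L, 1L)) else NULL

  subject_seeds <- sample.int(2^31 - 1L, n)
  schedule_seeds <- sample.int(2^31 - 1L, n)
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    sch <- if (config$share_schedule) shared else
      generate_schedule(config$task, seed = schedule_seeds[i])
    par <- lognormal_from_moments(rt_mu[i], config$rt_trial_sd)
    sampler <- local({
      ml <- par[["meanlog"]]; sl <- par[["sdlog"]]
      function(nn) stats::rlnorm(nn, ml, sl)
    })
    sessions[[i]] <- play_session(sch, softmax_policy(betas[i]),
                                  params = config$learning_params,
                                  rt_sampler = sampler,
                                  miss_rate = config$miss_rate,
                                  seed = subject_seeds[i],
                                  subject = ids[i], group = grp[i])
  }
  names(sessions) <- ids
  structure(list(sessions = sessions, groups = grp, betas = betas,
                 rt_subject_mean = rt_mu, schedule = shared, config = config,
                 seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s)\n", length(x$sessions),
              paste(sprintf("%d %s", table(x$groups),
                            names(table(x$groups))), collapse = ", ")))
  cat(sprintf("  %d trials/session, miss rate %.3f, %s schedule\n",
              x$config$task$n_trials, x$config$miss_rate,
              if (x$config$share_schedule) "shared" else "per-subject"))
  invisible(x)
}

#' Generate a synthetic ROI activity table for a cohort
#'
#' Each subject x ROI x condition estimate is built as
#' `baseline + subject-level intercept + condition effect +
#'  efficiency-coupled component + noise`. Non-interaction ROIs get half the
#' planted explore-exploit effect added to the explore estimate and
#' subtracted from the exploit estimate, plus independent condition noise.
#' The interaction ROI instead draws each subject's whole explore-exploit
#' difference from its group Gaussian (so the realized difference SD is the
#' configured one) on top of a subject-level intercept. The
#' efficiency-coupled component adds `coupling * z(efficiency)`, with
#' efficiency z-scored within group, to the configured ROI-condition cells,
#' linking activity to behavior for the regression stage without altering
#' the planted group contrasts.
#'
#' @param cohort A [generate_cohort()] result (or a list with `sessions` and
#'   `groups`).
#' @param config Cohort config; defaults to `cohort$config`.
#' @param seed Seed for the ROI noise; defaults to the cohort's realized
#'   seed plus one.
#' @return An [roi_beta_table()].
#' @export
generate_roi_table <- function(cohort, config = cohort$config,
                               seed = cohort$seed + 1L) {
  validate_cohort_config(config)
  eff <- vapply(cohort$sessions, subject_efficiency, numeric(1))
  ## standardize within group so the coupling adds efficiency signal without
  ## disturbing the planted group/condition structure
  grp_mean <- tapply(eff, cohort$groups[names(eff)], mean)
  resid <- eff - grp_mean[cohort$groups[names(eff)]]
  z_eff <- as.numeric(resid / stats::sd(resid))
  ids <- names(cohort$sessions)
  grp <- cohort$groups[ids]
  gi <- ifelse(grp == "entrepreneur_like", 1L, 2L)
  re <- config$roi_effects
  local_seed(seed)

  registry <- roi_registry()
  rows <- list()
  for (r in registry$roi) {
    n <- length(ids)
    subj_int <- stats::rnorm(n, 0, re$noise_sd)  # shared across conditions
    if (identical(r, re$interaction_roi)) {
      ## realized explore-exploit difference must have the configured SD,
      ## so the part contributed by the efficiency coupling is discounted
      cpl <- function(key) if (key %in% names(re$eff_coupling))
        re$eff_coupling[[key]] else 0
      cvar <- (cpl(paste0(r, "_explore")) - cpl(paste0(r, "_exploit")))^2
      sd_draw <- sqrt(pmax(re$interaction_sd[gi]^2 - cvar, 0.01))
      diff_s <- stats::rnorm(n, re$interaction_mean[gi], sd_draw)
      est_explore <- re$baseline + subj_int + diff_s / 2
      est_exploit <- re$baseline + subj_int - diff_s / 2
    } else {
      ce <- if (r %in% names(re$cond_effect)) re$cond_effect[[r]] else 0
      est_explore <- re$baseline + subj_int + ce / 2 +
        stats::rnorm(n, 0, re$noise_sd)
      est_exploit <- re$baseline + subj_int - ce / 2 +
        stats::rnorm(n, 0, re$noise_sd)
    }
    ck_ex <- paste0(r, "_explore"); ck_xp <- paste0(r, "_exploit")
    if (ck_ex %in% names(re$eff_coupling))
      est_explore <- est_explore + re$eff_coupling[[ck_ex]] * z_eff
    if (ck_xp %in% names(re$eff_coupling))
      est_exploit <- est_exploit + re$eff_coupling[[ck_xp]] * z_eff
    rows[[length(rows) + 1L]] <-
      data.frame(subject = rep(ids, 2L), group = rep(unname(grp), 2L),
                 roi = r,
                 condition = rep(c("explore", "exploit"), each = n),
                 estimate = c(est_explore, est_exploit))
  }
  roi_beta_table(do.call(rbind, rows), registry = registry)
}
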