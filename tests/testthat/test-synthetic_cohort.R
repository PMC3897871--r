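small_cohort_config <- function(...) {
  # trimmed sizes keep the generator checks fast; structure is unchanged
  cohort_config(n_group_A = 6L, n_group_B = 7L,
                task = task_config(n_trials = 100L, n_runs = 2L), ...)
}

test_that("generated cohorts have the configured shape", {
  co <- generate_cohort(cohort_config(), seed = 301)
  expect_length(co$sessions, 50L)
  expect_equal(unname(table(co$groups)[c("entrepreneur_like",
                                         "manager_like")]), c(24L, 26L),
               ignore_attr = TRUE)
  s <- co$sessions[[1]]
  expect_equal(nrow(s), 300L)
  expect_equal(unname(table(s$run)), rep(75L, 4), ignore_attr = TRUE)
  expect_true(all(co$betas >= 0))
  # shared schedule: every subject faces identical payoffs
  expect_identical(co$schedule$payoffs[cbind(s$trial[!s$missed],
                                             s$choice[!s$missed])],
                   as.integer(s$reward[!s$missed]))
})

test_that("missed proportion tracks the configured miss rate", {
  co <- generate_cohort(cohort_config(miss_rate = 0.05), seed = 302)
  miss <- mean(vapply(co$sessions, function(s) mean(s$missed), 1))
  expect_equal(miss, 0.05, tolerance = 0.2)
  co0 <- generate_cohort(small_cohort_config(miss_rate = 0), seed = 303)
  expect_true(all(!vapply(co0$sessions, function(s) any(s$missed), TRUE)))
})

test_that("identical master seeds give identical cohorts, different seeds differ", {
  c1 <- generate_cohort(small_cohort_config(), seed = 304)
  c2 <- generate_cohort(small_cohort_config(), seed = 304)
  c3 <- generate_cohort(small_cohort_config(), seed = 305)
  expect_identical(c1$betas, c2$betas)
  expect_identical(lapply(c1$sessions, as.data.frame),
                   lapply(c2$sessions, as.data.frame))
  expect_false(identical(c1$betas, c3$betas))
  r1 <- generate_roi_table(c1)
  r2 <- generate_roi_table(c2)
  r3 <- generate_roi_table(c3)
  expect_identical(r1$estimate, r2$estimate)
  expect_false(identical(r1$estimate, r3$estimate))
})

test_that("group RT means concentrate on the configured targets", {
  means <- sapply(1:6, function(i) {
    co <- generate_cohort(cohort_config(), seed = 310 + i)
    rts <- vapply(co$sessions, function(s) mean(s$rt[!s$missed]), 1)
    tapply(rts, co$groups, mean)
  })
  avg <- rowMeans(means)
  # Monte-Carlo SE of the replicate average is about 0.004-0.008 s
  expect_equal(unname(avg["entrepreneur_like"]), 0.389, tolerance = 0.02)
  expect_equal(unname(avg["manager_like"]), 0.454, tolerance = 0.02)
})

test_that("sessions round-trip bit-identically through CSV", {
  co <- generate_cohort(small_cohort_config(miss_rate = 0.05), seed = 320)
  dir <- withr::local_tempdir()
  write_sessions(co, file.path(dir, "sessions.csv"))
  back <- read_sessions(file.path(dir, "sessions.csv"))
  expect_identical(names(back), names(co$sessions))
  for (id in names(back)) {
    expect_identical(as.data.frame(back[[id]]),
                     as.data.frame(co$sessions[[id]]),
                     info = id)
    expect_identical(attr(back[[id]], "group"),
                     attr(co$sessions[[id]], "group"))
  }
  expect_identical(session_groups(back), co$groups)
})

test_that("ROI tables carry the planted condition effects", {
  co <- generate_cohort(cohort_config(), seed = 330)
  roi <- generate_roi_table(co)
  # explore > exploit planted in right IPS, reversed in vmPFC
  expect_gt(roi_contrast(roi, "R_IPS")$t, 0)
  expect_lt(roi_contrast(roi, "vmPFC")$t, 0)
  # zero effects and zero noise collapse everything onto the baseline
  null_cfg <- cohort_config(roi_effects = roi_effect_defaults(
    cond_effect = c(vmPFC = 0), interaction_mean = c(0, 0),
    interaction_sd = c(0.1, 0.1), eff_coupling = c(vmPFC_explore = 0),
    noise_sd = 1e-9, baseline = 3))
  co0 <- generate_cohort(small_cohort_config(), seed = 331)
  co0$config <- null_cfg
  roi0 <- generate_roi_table(co0, config = null_cfg, seed = 332)
  expect_equal(mean(abs(roi0$estimate[roi0$roi == "vmPFC"] - 3)), 0,
               tolerance = 0.05)
})

test_that("the efficiency coupling drives the regression toward R^2 = 1", {
  co <- generate_cohort(cohort_config(), seed = 340)
  labs <- label_cohort(co$sessions, co$config$learning_params)
  et <- efficiency_table(co$sessions, labs)
  strong <- cohort_config(roi_effects = roi_effect_defaults(
    eff_coupling = c(R_FPC_switch_exploit = 50), noise_sd = 1e-6))
  roi_strong <- generate_roi_table(co, config = strong, seed = 341)
  res <- efficiency_regression(roi_strong, et)
  expect_gt(res$r_squared, 0.999)
})

test_that("planted regression signal recovers the headline coefficient signs", {
  hits_group <- 0; hits_fpc <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    co <- generate_cohort(cohort_config(), seed = 400 + i)
    labs <- label_cohort(co$sessions, co$config$learning_params)
    et <- efficiency_table(co$sessions, labs)
    roi <- generate_roi_table(co)
    res <- efficiency_regression(roi, et,
                                 group_indicator = "entrepreneur_like")
    cf <- res$coefficients
    if (cf$estimate[cf$term == "group"] > 0) hits_group <- hits_group + 1
    if (cf$estimate[cf$term == "R_FPC_switch_exploit"] > 0)
      hits_fpc <- hits_fpc + 1
  }
  expect_gte(hits_group / n_rep, 0.9)
  expect_gte(hits_fpc / n_rep, 0.9)
})

test_that("the planted FPC interaction is detected at its analytic power", {
  # planted per-subject explore-exploit differences: means 0.67 / -0.15,
  # SDs 1.60 / 1.18 at n = 24 / 26 -> noncentral-F rejection probability
  sp2 <- (23 * 1.60^2 + 25 * 1.18^2) / 48
  ncp <- (0.67 - (-0.15))^2 / (sp2 * (1 / 24 + 1 / 26))
  power <- 1 - pf(qf(0.95, 1, 48), 1, 48, ncp = ncp)
  n_rep <- 40
  rej <- 0
  for (i in seq_len(n_rep)) {
    co <- generate_cohort(cohort_config(), seed = 600 + i)
    roi <- generate_roi_table(co)
    if (roi_mixed_anova(roi, "R_FPC_switch")$p[3] < 0.05) rej <- rej + 1
  }
  # empirical rate within the 99.9% binomial envelope of the analytic power,
  # and clearly above the 5% null rate
  env <- qbinom(c(0.0005, 0.9995), n_rep, power)
  expect_gte(rej, max(env[1], 6))
  expect_lte(rej, env[2])
})

test_that("equal group beta distributions give a null group comparison", {
  cfg <- small_cohort_config(beta_mean = c(0.18, 0.18), beta_sd = c(0, 0))
  co <- generate_cohort(cfg, seed = 350)
  expect_true(all(abs(co$betas - 0.18) < 1e-12))
})

test_that("config validation catches impossible settings", {
  expect_error(cohort_config(n_group_A = 1), "at least 2")
  expect_error(cohort_config(rt_mean = c(0.4, 2.0)), "choice_window")
  expect_error(cohort_config(miss_rate = 1), "miss_rate")
  expect_error(cohort_config(beta_sd = c(-0.1, 0.1)), "SDs")
})
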