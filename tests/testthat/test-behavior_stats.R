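make_labelled_session <- function(choices, rewards, rts, params, ...) {
  s <- make_session(choices, rewards, rts = rts, ...)
  list(session = s, labels = label_trials(s, params))
}

test_that("overall efficiency is payoff over mean response time", {
  s <- make_session(rep(1L, 4), c(50, 40, 60, 30), rts = rep(0.45, 4))
  expect_equal(subject_efficiency(s), 180 / 0.45)
  # doubling every RT halves efficiency
  s2 <- make_session(rep(1L, 4), c(50, 40, 60, 30), rts = rep(0.9, 4))
  expect_equal(subject_efficiency(s2), subject_efficiency(s) / 2)
  # a subject at the printed group-level means
  n <- 300
  s3 <- make_session(rep(1L, n), rep(18049.18 / n, n),
                     rts = rep(0.422822, n))
  expect_equal(subject_efficiency(s3), 18049.18 / 0.422822, tolerance = 1e-9)
  # missed trials stay out of both numerator and denominator
  sm <- make_session(c(1L, 1L, 1L), c(50, 0, 70), rts = c(0.4, NA, 0.6),
                     missed = c(FALSE, TRUE, FALSE))
  expect_equal(subject_efficiency(sm), 120 / 0.5)
  all_miss <- make_session(1L, 0, rts = NA_real_, missed = TRUE)
  expect_error(subject_efficiency(all_miss), "no responded trials")
})

test_that("efficiency is invariant under trial reordering", {
  set.seed(5)
  n <- 40
  s <- make_session(sample.int(4, n, TRUE), sample.int(100, n, TRUE),
                    rts = runif(n, 0.2, 0.8))
  perm <- s[sample.int(n), ]
  attr(perm, "subject") <- attr(s, "subject")
  class(perm) <- class(s)
  expect_equal(subject_efficiency(perm), subject_efficiency(s))
})

# Labels fixed by hand so the cell arithmetic is fully controlled.
hand_labels <- function(label, subject = "s1") {
  out <- data.frame(trial = seq_along(label),
                    label = factor(label,
                                   levels = c("exploit", "explore", "missed")))
  attr(out, "subject") <- subject
  class(out) <- c("trial_labels", "data.frame")
  out
}

test_that("cell efficiencies follow the configured definition", {
  p <- staging_params(beta = 1)
  ch <- c(1L, 2L, 3L, 4L, rep(4L, 3L), 1L)
  rw <- c(10, 20, 30, 40, rep(40, 3), 10)
  s <- make_session(ch, rw, rts = rep(0.5, 8))
  lab <- label_trials(s, p)

  cells <- efficiency_by_type(s, lab, cell = "total")
  expect_equal(cells$efficiency, cells$payoff / cells$mean_rt)
  per <- efficiency_by_type(s, lab, cell = "per_trial")
  expect_equal(per$efficiency, (per$payoff / per$n) / per$mean_rt)
  # the two variants differ exactly by the cell trial count
  expect_equal(cells$eff_total, cells$eff_per_trial * cells$n)

  # equal per-trial payoff and RT in both classes, 3x the exploit trials:
  # total-based cell efficiency scales 3x, per-trial cells are equal
  s2 <- make_session(rep(c(4L, 1L), c(6L, 2L)), rep(60, 8),
                     rts = rep(0.4, 8))
  lab2 <- hand_labels(rep(c("exploit", "explore"), c(6L, 2L)))
  tot2 <- efficiency_by_type(s2, lab2, cell = "total")
  per2 <- efficiency_by_type(s2, lab2, cell = "per_trial")
  expect_equal(tot2$efficiency[tot2$choice_type == "exploit"] /
                 tot2$efficiency[tot2$choice_type == "explore"], 3)
  expect_equal(per2$efficiency[1], per2$efficiency[2])
})

test_that("a session with one label class flags the other cell missing", {
  p <- staging_params(beta = 1)
  s <- make_session(rep(1L, 5), rep(50, 5), rts = rep(0.5, 5))
  lab <- label_trials(s, p)  # arm 1 always the believed best -> all exploit
  cells <- efficiency_by_type(s, lab)
  expect_equal(cells$n[cells$choice_type == "explore"], 0L)
  expect_true(is.na(cells$efficiency[cells$choice_type == "explore"]))
  expect_equal(cells$efficiency[cells$choice_type == "exploit"],
               subject_efficiency(s))
})

test_that("mixed_anova reports df (1, n-2) and matches the textbook oracle", {
  set.seed(88)
  for (sizes in list(c(4, 4), c(3, 5), c(24, 26), c(6, 9))) {
    d <- random_mixed_data(sizes[1], sizes[2])
    res <- mixed_anova(d)
    expect_equal(res$df1, rep(1L, 3))
    expect_equal(res$df2, rep(sum(sizes) - 2L, 3))
    oracle <- oracle_mixed_anova(d)
    expect_equal(res$F, unname(oracle[c("condition", "group", "interaction")]),
                 tolerance = 1e-8)
  }
})

test_that("mixed_anova agrees with aov's Error() strata in the balanced case", {
  set.seed(89)
  d <- random_mixed_data(10, 10)
  res <- mixed_anova(d)
  a <- summary(aov(value ~ group * condition + Error(subject / condition),
                   data = transform(d, subject = factor(subject),
                                    group = factor(group),
                                    condition = factor(condition))))
  f_group <- a[["Error: subject"]][[1]]["group", "F value"]
  f_cond <- a[["Error: subject:condition"]][[1]]["condition", "F value"]
  f_int <- a[["Error: subject:condition"]][[1]]["group:condition", "F value"]
  expect_equal(res$F[res$effect == "group"], f_group, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "condition"], f_cond, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "interaction"], f_int, tolerance = 1e-10)
})

test_that("degenerate within-subject data give a zero condition F", {
  d <- random_mixed_data(5, 6)
  # make both conditions identical within every subject
  d$value <- rep(d$value[1:11], 2)
  res <- mixed_anova(d)
  expect_equal(res$F[res$effect == "condition"], 0)
  expect_equal(res$F[res$effect == "interaction"], 0)
})

test_that("mixed_anova rejects incomplete subjects by name", {
  d <- random_mixed_data(3, 3)
  d <- d[!(d$subject == "s02" & d$condition == "c2"), ]
  expect_error(mixed_anova(d), "s02")
})

test_that("group-label permutations give uniform group-effect p-values under the null", {
  set.seed(90)
  d <- random_mixed_data(12, 13)   # no group structure in the generator
  subj <- unique(d$subject)
  pvals <- replicate(400, {
    newg <- sample(rep(c("g1", "g2"), c(12, 13)))
    d$group <- newg[match(d$subject, subj)]
    mixed_anova(d)$p[2]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("cohort_summary reports n-1 SDs overall and per group", {
  p <- staging_params(beta = 1)
  sessions <- lapply(1:4, function(i)
    make_session(c(1L, 2L, 3L, 4L, 4L), c(10, 20, 30, 40, 40),
                 rts = rep(0.4 + 0.05 * i, 5),
                 subject = sprintf("s%d", i),
                 group = ifelse(i <= 2, "gA", "gB")))
  labs <- lapply(sessions, label_trials, params = p)
  tab <- efficiency_table(sessions, labs)
  sm <- cohort_summary(tab)
  eff_all <- sm[sm$variable == "efficiency" & sm$scope == "all", ]
  expect_equal(eff_all$n, 4)
  expect_equal(eff_all$mean, mean(tab$efficiency))
  expect_equal(eff_all$sd, stats::sd(tab$efficiency))
  expect_equal(eff_all$min, min(tab$efficiency))
  rt_gA <- sm[sm$variable == "response_time" & sm$scope == "gA", ]
  expect_equal(rt_gA$n, 2)
  expect_equal(rt_gA$mean, mean(tab$mean_rt[tab$group == "gA"]))

  # single subject: SD is undefined, mean = min = max
  one <- cohort_summary(efficiency_table(sessions[1], labs[1]))
  expect_true(all(is.na(one$sd)))
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
})
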