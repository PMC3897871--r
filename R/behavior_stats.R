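#' Overall decision efficiency of a session
#'
#' The speed-accuracy statistic of the pipeline: total payoff over responded
#' trials divided by the mean response time over responded trials, in points
#' per second. Missed trials contribute no payoff and do not enter the RT
#' denominator.
#'
#' @param session A `session_record`.
#' @return Efficiency in points/second (scalar).
#' @examples
#' # 18000 points at a mean RT of 0.45 s -> 40000 points/s
#' @export
subject_efficiency <- function(session) {
  stopifnot(inherits(session, "session_record"))
  resp <- !session$missed
  if (!any(resp))
    stop("subject_efficiency: session has no responded trials", call. = FALSE)
  sum(session$reward[resp]) / mean(session$rt[resp])
}

#' Per-choice-type efficiency cells
#'
#' Splits a session's responded trials by their explore/exploit label and
#' computes each cell's payoff, trial count, mean RT, and efficiency. Two
#' cell definitions are reported: `eff_total` = cell payoff TOTAL divided by
#' cell mean RT (the default, the literal reading of payoff-over-time; it
#' scales with the number of trials in the cell) and `eff_per_trial` = cell
#' mean payoff divided by cell mean RT. The `efficiency` column repeats the
#' one selected by `cell`.
#'
#' @param session A `session_record`.
#' @param labels Matching `trial_labels` from [label_trials()].
#' @param cell Which definition feeds downstream ANOVAs: `"total"` (default)
#'   or `"per_trial"`.
#' @return Data.frame with one row per choice type (`exploit`, `explore`)
#'   and columns `n`, `payoff`, `mean_rt`, `eff_total`, `eff_per_trial`,
#'   `efficiency`; cells with zero trials carry NA.
#' @export
efficiency_by_type <- function(session, labels, cell = c("total", "per_trial")) {
  cell <- match.arg(cell)
  stopifnot(inherits(session, "session_record"),
            inherits(labels, "trial_labels"))
  ord <- order(session$trial)
  s <- session[ord, ]
  lab <- labels$label[match(s$trial, labels$trial)]
  out <- do.call(rbind, lapply(c("exploit", "explore"), function(ct) {
    sel <- !s$missed & lab == ct
    if (!any(sel))
      return(data.frame(choice_type = ct, n = 0L, payoff = NA_real_,
                        mean_rt = NA_real_, eff_total = NA_real_,
                        eff_per_trial = NA_real_))
    pay <- sum(s$reward[sel]); mrt <- mean(s$rt[sel])
    data.frame(choice_type = ct, n = sum(sel), payoff = pay, mean_rt = mrt,
               eff_total = pay / mrt, eff_per_trial = (pay / sum(sel)) / mrt)
  }))
  out$efficiency <- if (cell == "total") out$eff_total else out$eff_per_trial
  out
}

#' Per-subject efficiency table for a cohort
#'
#' One row per subject with the overall payoff, mean RT and efficiency plus
#' the explore/exploit cells from [efficiency_by_type()].
#'
#' @param sessions List of `session_record`s.
#' @param labels List of matching `trial_labels` (see [label_cohort()]).
#' @param cell Cell-efficiency definition, see [efficiency_by_type()].
#' @return An `efficiency_table` data.frame with columns `subject`, `group`,
#'   `n_responded`, `payoff`, `mean_rt`, `efficiency`, and
#'   `<type>_{n,payoff,mean_rt,eff_total,eff_per_trial,efficiency}` for both
#'   choice types.
#' @export
efficiency_table <- function(sessions, labels, cell = c("total", "per_trial")) {
  cell <- match.arg(cell)
  stopifnot(length(sessions) == length(labels))
  rows <- Map(function(s, l) {
    stopifnot(identical(attr(s, "subject"), attr(l, "subject")))
    resp <- !s$missed
    base <- data.frame(subject = attr(s, "subject"), group = attr(s, "group"),
                       n_responded = sum(resp),
                       payoff = sum(s$reward[resp]),
                       mean_rt = mean(s$rt[resp]),
                       efficiency = subject_efficiency(s))
    cells <- efficiency_by_type(s, l, cell = cell)
    for (i in seq_len(nrow(cells))) {
      ct <- cells$choice_type[i]
      for (col in c("n", "payoff", "mean_rt", "eff_total", "eff_per_trial",
                    "efficiency"))
        base[[paste0(ct, "_", col)]] <- cells[[col]][i]
    }
    base
  }, sessions, labels)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cell") <- cell
  class(out) <- c("efficiency_table", "data.frame")
  out
}

#' Reshape an efficiency table for the choice-type ANOVAs
#'
#' @param table An [efficiency_table()].
#' @param measure Which per-cell measure becomes the ANOVA dependent
#'   variable: `"efficiency"` (configured cell definition), `"payoff"`, or
#'   `"mean_rt"`.
#' @param drop_incomplete Drop subjects with an empty explore or exploit
#'   cell (default). Such subjects carry no within-subject contrast and
#'   cannot enter the mixed ANOVA; with `FALSE` their NA cells are kept and
#'   [mixed_anova()] raises an error naming them.
#' @return Long data.frame with columns `subject`, `group`, `condition`
#'   (exploit/explore), `value` — the input shape of [mixed_anova()].
#' @export
choice_type_long <- function(table, measure = c("efficiency", "payoff",
                                                "mean_rt"),
                             drop_incomplete = TRUE) {
  measure <- match.arg(measure)
  stopifnot(inherits(table, "efficiency_table"))
  out <- do.call(rbind, lapply(c("exploit", "explore"), function(ct)
    data.frame(subject = table$subject, group = table$group, condition = ct,
               value = table[[paste0(ct, "_", measure)]])))
  if (drop_incomplete) {
    bad <- unique(out$subject[!is.finite(out$value)])
    out <- out[!(out$subject %in% bad), ]
  }
  out
}

#' Two-by-two mixed-design ANOVA
#'
#' ANOVA with one two-level within-subject factor (`condition`) and one
#' two-level between-subject factor (`group`), allowing unbalanced group
#' sizes. The partition is the standard mixed-design one: the group main
#' effect is tested against the between-subject error (one-way ANOVA on the
#' subject means over conditions), while the condition main effect and the
#' condition-by-group interaction are tested against the subject-by-condition
#' error, computed from the per-subject condition differences with
#' sum-to-zero group coding (Type-III-equivalent in this 2x2 layout: the
#' condition effect is the unweighted mean of the group-wise difference
#' means). All three tests have df (1, n - 2) for n subjects.
#'
#' @param data Long data.frame with columns `subject`, `group`, `condition`,
#'   `value`: exactly one value per subject x condition, two conditions, two
#'   groups.
#' @return A `mixed_anova_result` data.frame with columns `effect`
#'   (`condition`, `group`, `interaction`), `F`, `df1`, `df2`, `p`.
#' @export
mixed_anova <- function(data) {
  stopifnot(all(c("subject", "group", "condition", "value") %in% names(data)))
  if (any(!is.finite(data$value)))
    stop("mixed_anova: non-finite values for subject(s) ",
         paste(unique(data$subject[!is.finite(data$value)]), collapse = ", "),
         call. = FALSE)
  conds <- sort(unique(as.character(data$condition)))
  if (length(conds) != 2L)
    stop("mixed_anova: exactly two conditions required", call. = FALSE)
  wide <- stats::reshape(
    data.frame(subject = as.character(data$subject),
               group = as.character(data$group),
               condition = as.character(data$condition),
               value = data$value),
    idvar = c("subject", "group"), timevar = "condition",
    direction = "wide")
  y1 <- wide[[paste0("value.", conds[1L])]]
  y2 <- wide[[paste0("value.", conds[2L])]]
  bad <- is.na(y1) | is.na(y2)
  if (any(bad))
    stop("mixed_anova: subject(s) missing a condition: ",
         paste(wide$subject[bad], collapse = ", "), call. = FALSE)
  g <- factor(wide$group)
  if (nlevels(g) != 2L)
    stop("mixed_anova: exactly two groups required", call. = FALSE)
  n <- nrow(wide)
  if (any(table(g) < 2L))
    stop("mixed_anova: each group needs at least 2 subjects", call. = FALSE)

  ## between-subject stratum: subject means across conditions
  s <- (y1 + y2) / 2
  sbar_g <- tapply(s, g, mean)
  ss_between_err <- sum((s - sbar_g[g])^2) * 2       # cell-scale SS
  ss_group <- 2 * sum(tapply(s, g, length) * (sbar_g - mean(s))^2)
  ## the factor 2 puts subject-mean SS on the per-cell scale; it cancels in F
  F_group <- (ss_group / 1) / (ss_between_err / (n - 2L))

  ## within-subject stratum: per-subject condition differences
  d <- y1 - y2
  dbar_g <- tapply(d, g, mean)
  n_g <- tapply(d, g, length)
  mse_d <- sum((d - dbar_g[g])^2) / (n - 2L)
  w <- sum(1 / n_g)                                   # 1/nA + 1/nB
  cond_est <- mean(dbar_g)                            # unweighted across groups
  int_est <- diff(dbar_g)
  ## zero numerator with zero error is a degenerate no-effect case, F = 0
  safe_F <- function(num, denom) if (num == 0) 0 else num / denom
  F_cond <- safe_F(cond_est^2, mse_d / 4 * w)
  F_int <- safe_F(int_est^2, mse_d * w)

  out <- data.frame(effect = c("condition", "group", "interaction"),
                    F = c(F_cond, F_group, F_int),
                    df1 = 1L, df2 = n - 2L)
  out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  class(out) <- c("mixed_anova_result", "data.frame")
  out
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat("2x2 mixed-design ANOVA (within: condition, between: group)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-11s F(%d, %d) = %8.4f, p = %.4g\n", x$effect[i],
                x$df1[i], x$df2[i], x$F[i], x$p[i]))
  invisible(x)
}

#' Descriptive cohort summary of efficiency, payoff and response time
#'
#' N, mean, SD (n - 1 denominator), min and max for each behavioral measure,
#' overall and per group. With a single subject the SD is reported as NA.
#'
#' @param table An [efficiency_table()].
#' @return Data.frame with columns `variable`, `scope` (`all` or a group
#'   label), `n`, `mean`, `sd`, `min`, `max`.
#' @export
cohort_summary <- function(table) {
  stopifnot(inherits(table, "efficiency_table"), nrow(table) >= 1L)
  vars <- c(efficiency = "efficiency", payoff = "payoff",
            response_time = "mean_rt")
  scopes <- c(list(all = rep(TRUE, nrow(table))),
              lapply(stats::setNames(nm = unique(table$group)),
                     function(gr) table$group == gr))
  rows <- list()
  for (v in names(vars)) for (sc in names(scopes)) {
    x <- table[[vars[[v]]]][scopes[[sc]]]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, scope = sc, n = length(x), mean = mean(x),
      sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
      min = min(x), max = max(x))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the three choice-type-by-group ANOVAs of the behavioral analysis
#'
#' Convenience wrapper applying [mixed_anova()] to cell efficiency, cell
#' payoff and cell mean RT in turn.
#'
#' @param table An [efficiency_table()].
#' @return Named list of `mixed_anova_result`s: `efficiency`, `payoff`,
#'   `response_time`.
#' @export
behavior_anovas <- function(table) {
  list(efficiency = mixed_anova(choice_type_long(table, "efficiency")),
       payoff = mixed_anova(choice_type_long(table, "payoff")),
       response_time = mixed_anova(choice_type_long(table, "mean_rt")))
}
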