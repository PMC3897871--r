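#' Registry of the analysis regions of interest
#'
#' The spherical ROIs (8 mm radius, MNI centers in mm) whose per-subject,
#' per-choice-type activity estimates enter the second-level statistics:
#' vmPFC, bilateral frontopolar cortex (FPC) and bilateral intraparietal
#' sulcus (IPS) from an explore/exploit value-tracking study, a right FPC
#' sphere from a behavioral-switching study, a dACC sphere from a foraging
#' study, and left/right locus coeruleus (LC) spheres from a neuromelanin
#' localization study. The seven non-LC regions (`in_regression = TRUE`) are
#' the regressor set of [efficiency_regression()].
#'
#' @return Data.frame with columns `roi`, `x`, `y`, `z` (MNI mm),
#'   `radius_mm`, `source`, `in_regression`.
#' @export
roi_registry <- function() {
  data.frame(
    roi = c("vmPFC", "L_FPC", "R_FPC", "L_IPS", "R_IPS", "R_FPC_switch",
            "dACC", "LC_left", "LC_right"),
    x = c(-3, -27, 27, -29, 39, 36, -2, -4, 5),
    y = c(33, 48, 57, -33, -36, 54, 21, -37, -37),
    z = c(-6, 4, 6, 45, 42, 0, 34, -23, -23),
    radius_mm = 8,
    source = c(rep("explore-exploit value study", 5),
               "behavioral-switching study", "foraging dACC study",
               rep("neuromelanin LC study", 2)),
    in_regression = c(rep(TRUE, 7), FALSE, FALSE))
}

#' Write the ROI registry as JSON
#' @param path JSON path.
#' @param registry ROI registry data.frame.
#' @return Invisibly, `path`.
#' @export
write_roi_registry <- function(path, registry = roi_registry()) {
  jsonlite::write_json(registry, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct / validate an ROI activity table
#'
#' Tabular per-subject, per-ROI, per-choice-type activity estimates (BOLD
#' parameter-estimate units). Sphere extraction from images happens upstream;
#' this package starts from the table.
#'
#' @param data Data.frame with columns `subject`, `group`, `roi`,
#'   `condition` (`explore` / `exploit`), `estimate`.
#' @param registry ROI registry the table's `roi` values must come from.
#' @return The validated data.frame with class `roi_beta_table`.
#' @export
roi_beta_table <- function(data, registry = roi_registry()) {
  need <- c("subject", "group", "roi", "condition", "estimate")
  if (!all(need %in% names(data)))
    stop("roi_beta_table: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(data$roi), registry$roi)
  if (length(bad))
    stop("roi_beta_table: unknown ROI(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(data$condition %in% c("explore", "exploit")))
    stop("roi_beta_table: condition must be 'explore' or 'exploit'",
         call. = FALSE)
  tab <- table(data$subject, data$roi, data$condition)
  if (any(tab != 1L))
    stop("roi_beta_table: every subject needs exactly one estimate per ",
         "ROI x condition", call. = FALSE)
  out <- as.data.frame(data)[, need]
  attr(out, "registry") <- registry
  class(out) <- c("roi_beta_table", "data.frame")
  out
}

roi_slice <- function(table, roi) {
  stopifnot(inherits(table, "roi_beta_table"))
  d <- table[table$roi == roi, ]
  if (nrow(d) == 0L)
    stop("no estimates for ROI '", roi, "'", call. = FALSE)
  d
}

#' Explore-vs-exploit contrast in one ROI
#'
#' Compares the n explore estimates with the n exploit estimates across
#' subjects. The default pools them as two independent samples
#' (pooled-variance t, df = 2n - 2, the convention of the reference ROI
#' table); `paired = TRUE` gives the within-subject alternative (df = n - 1).
#' Two-sided p by default.
#'
#' @param table An [roi_beta_table()].
#' @param roi ROI name from the registry.
#' @param direction `"explore_vs_exploit"` (t > 0 when explore is higher) or
#'   `"exploit_vs_explore"`.
#' @param paired Use the paired t-test variant.
#' @return List with `roi`, `direction`, `t`, `df`, `p`, and the per-condition
#'   means.
#' @export
roi_contrast <- function(table, roi,
                         direction = c("explore_vs_exploit",
                                       "exploit_vs_explore"),
                         paired = FALSE) {
  direction <- match.arg(direction)
  d <- roi_slice(table, roi)
  wide <- merge(d[d$condition == "explore", c("subject", "estimate")],
                d[d$condition == "exploit", c("subject", "estimate")],
                by = "subject", suffixes = c("_explore", "_exploit"))
  x <- wide$estimate_explore; y <- wide$estimate_exploit
  if (direction == "exploit_vs_explore") { tmp <- x; x <- y; y <- tmp }
  tt <- if (paired) stats::t.test(x, y, paired = TRUE) else
    stats::t.test(x, y, var.equal = TRUE)
  list(roi = roi, direction = direction, paired = paired,
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_explore = mean(wide$estimate_explore),
       mean_exploit = mean(wide$estimate_exploit))
}

#' Choice-type by group mixed ANOVA on one ROI
#'
#' Delegates to [mixed_anova()] on the ROI's per-subject condition
#' estimates; the interaction row is the test of whether the
#' explore-exploit activity difference differs between groups.
#'
#' @param table An [roi_beta_table()].
#' @param roi ROI name.
#' @param groups Optional named subject-to-group map overriding the table's
#'   `group` column.
#' @return A `mixed_anova_result` (see [mixed_anova()]).
#' @export
roi_mixed_anova <- function(table, roi, groups = NULL) {
  d <- roi_slice(table, roi)
  grp <- if (is.null(groups)) d$group else unname(groups[as.character(d$subject)])
  mixed_anova(data.frame(subject = d$subject, group = grp,
                         condition = d$condition, value = d$estimate))
}

#' Multiple regression of decision efficiency on ROI activity
#'
#' Ordinary least squares of per-subject efficiency on an intercept, a group
#' indicator, and one regressor per ROI x choice type (by default the 7
#' registry ROIs with `in_regression = TRUE`, i.e. 14 activity regressors,
#' 15 regressors in all). Regressors are raw activity estimates;
#' `standardize = TRUE` z-scores them first.
#'
#' @param table An [roi_beta_table()].
#' @param efficiency Named per-subject efficiency vector (points/second), or
#'   an [efficiency_table()].
#' @param group_indicator Group label coded 1 (others 0); defaults to the
#'   first group label in alphabetical order.
#' @param rois ROIs to include; default the registry's regression set.
#' @param standardize Z-score the activity regressors before fitting.
#' @return A `roi_regression` list: `coefficients` data.frame (`term`,
#'   `estimate`, `std_error`, `t`, `p`), `r_squared`, `adj_r_squared`,
#'   `f_statistic`, `df1`, `df2`, `p_value`, `n`.
#' @export
efficiency_regression <- function(table, efficiency, group_indicator = NULL,
                                  rois = NULL, standardize = FALSE) {
  stopifnot(inherits(table, "roi_beta_table"))
  if (inherits(efficiency, "efficiency_table"))
    efficiency <- stats::setNames(efficiency$efficiency, efficiency$subject)
  reg <- attr(table, "registry")
  if (is.null(rois)) rois <- reg$roi[reg$in_regression]

  subjects <- sort(unique(as.character(table$subject)))
  if (!all(subjects %in% names(efficiency)))
    stop("efficiency_regression: efficiency missing for subject(s): ",
         paste(setdiff(subjects, names(efficiency)), collapse = ", "),
         call. = FALSE)
  grp <- table$group[match(subjects, table$subject)]
  if (is.null(group_indicator)) group_indicator <- sort(unique(grp))[1L]

  X <- data.frame(row.names = subjects)
  X$group <- as.numeric(grp == group_indicator)
  for (r in rois) for (cond in c("explore", "exploit")) {
    d <- table[table$roi == r & table$condition == cond, ]
    v <- d$estimate[match(subjects, d$subject)]
    if (any(is.na(v)))
      stop("efficiency_regression: missing ", r, "-", cond, " estimates",
           call. = FALSE)
    X[[paste0(r, "_", cond)]] <- if (standardize) as.numeric(scale(v)) else v
  }
  X$.efficiency <- efficiency[subjects]

  fit <- stats::lm(.efficiency ~ ., data = X)
  if (any(is.na(stats::coef(fit))))
    stop("efficiency_regression: rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  out <- list(
    coefficients = data.frame(term = rownames(ct), estimate = ct[, 1L],
                              std_error = ct[, 2L], t = ct[, 3L],
                              p = ct[, 4L], row.names = NULL),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(sm$fstatistic[1L]),
    df1 = unname(sm$fstatistic[2L]), df2 = unname(sm$fstatistic[3L]),
    n = length(subjects), group_indicator = group_indicator)
  out$p_value <- stats::pf(out$f_statistic, out$df1, out$df2,
                           lower.tail = FALSE)
  class(out) <- "roi_regression"
  out
}

#' @export
print.roi_regression <- function(x, ...) {
  cat(sprintf("Efficiency ~ group + ROI activity (n = %d)\n", x$n))
  cat(sprintf("  R^2 = %.3f, adjusted R^2 = %.3f, F(%d, %d) = %.3f, p = %.4g\n",
              x$r_squared, x$adj_r_squared, x$df1, x$df2, x$f_statistic,
              x$p_value))
  sig <- x$coefficients[x$coefficients$p < 0.1 &
                          x$coefficients$term != "(Intercept)", ]
  if (nrow(sig)) {
    cat("  terms with p < 0.1:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %-24s %10.2f (p = %.4g)\n", sig$term[i],
                  sig$estimate[i], sig$p[i]))
  }
  invisible(x)
}

#' Write / read an ROI activity table as CSV
#' @param table An [roi_beta_table()].
#' @param path CSV path.
#' @return `write_betas` invisibly returns `path`; `read_betas` returns an
#'   `roi_beta_table`.
#' @export
write_betas <- function(table, path) {
  stopifnot(inherits(table, "roi_beta_table"))
  write_csv_full(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_betas
#' @export
read_betas <- function(path) {
  roi_beta_table(utils::read.csv(path))
}
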