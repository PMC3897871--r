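## Shared-parameter names, in the order the optimizer sees them.
.shared_names <- c("lambda_hat", "theta_hat", "sigma_d_hat", "sigma_o_hat",
                   "mu0_pre", "var0_pre")

.default_bounds <- function() {
  rbind(lambda_hat = c(1e-4, 1),
        theta_hat = c(0, 100),
        sigma_d_hat = c(0, 50),
        sigma_o_hat = c(0, 50),   # lower bound exactly 0: the boundary is a legitimate optimum
        mu0_pre = c(0, 100),
        var0_pre = c(0, 1000))
}

#' Maximum-likelihood fit of the Kalman-softmax model to a cohort
#'
#' Estimates one set of learning parameters (`lambda_hat`, `theta_hat`,
#' `sigma_d_hat`, `sigma_o_hat`, `mu0_pre`, `var0_pre`) shared by all
#' subjects, with a per-subject softmax inverse temperature `beta`. For any
#' candidate set of shared parameters each subject's `beta` is profiled out
#' by one-dimensional minimization of that subject's negative log-likelihood;
#' the shared parameters are then minimized by bounded quasi-Newton search
#' (L-BFGS-B) from `restarts` seeded starting points, and the best local
#' optimum is returned. The likelihood surface is smooth but can be
#' multimodal in (`lambda_hat`, `theta_hat`), hence the multistart.
#'
#' With `sigma_o_hat = 0` the Kalman gain is 1, beliefs track rewards
#' exactly, and `sigma_d_hat` / `var0_pre` drop out of the choice likelihood
#' (flat directions); the optimizer simply leaves them near their starting
#' values in that regime. A `fixed` mask can pin any subset of the shared
#' parameters.
#'
#' @param sessions List of `session_record`s (e.g. from
#'   [generate_cohort()]`$sessions`).
#' @param start A [model_params()] giving the first starting point (its
#'   `beta` is ignored; beta is profiled).
#' @param bounds 6 x 2 matrix of box constraints, rows named as the shared
#'   parameters; default box keeps `lambda_hat` in (0, 1] and all SDs and
#'   variances nonnegative, with `sigma_o_hat` allowed to sit exactly at 0.
#' @param fixed Character vector of shared-parameter names to hold at their
#'   `start` values.
#' @param restarts Number of starting points (>= 1); the first is `start`,
#'   the rest are drawn uniformly inside the bounds from `seed`.
#' @param beta_max Upper bound of the per-subject beta search, 1/points.
#' @param seed Integer seed making the whole fit deterministic.
#' @param n_arms Number of arms.
#' @return A `fit_result`: list with `params` (fitted `model_params`),
#'   `betas` (named per-subject vector), `subject_nll`, `total_nll`,
#'   `group_nll` (when sessions carry group labels), and `diagnostics`
#'   (per-restart convergence codes, iterations, objective values).
#' @export
fit_bandit_model <- function(sessions, start = model_params(),
                             bounds = .default_bounds(), fixed = character(),
                             restarts = 5L, beta_max = 2, seed = 1L,
                             n_arms = 4L) {
  stopifnot(length(sessions) >= 1L)
  lapply(sessions, function(s) stopifnot(inherits(s, "session_record")))
  validate_model_params(start)
  if (!all(.shared_names %in% rownames(bounds)))
    stop("fit_bandit_model: bounds must have one named row per shared parameter",
         call. = FALSE)
  bounds <- bounds[.shared_names, , drop = FALSE]
  if (any(!is.finite(bounds))) stop("fit_bandit_model: bounds must be finite",
                                    call. = FALSE)
  bad <- setdiff(fixed, .shared_names)
  if (length(bad)) stop("fit_bandit_model: unknown parameter in `fixed`: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  restarts <- max(1L, as.integer(restarts))

  choices <- lapply(sessions, function(s) {
    ord <- order(s$trial)
    as.integer(ifelse(s$missed[ord], -1L, s$choice[ord] - 1L))
  })
  rewards <- lapply(sessions, function(s) as.numeric(s$reward[order(s$trial)]))

  full <- unlist(unclass(start)[.shared_names])
  free <- setdiff(.shared_names, fixed)

  objective <- function(x_free) {
    p <- full
    p[free] <- x_free
    cpp_cohort_profile_nll(choices, rewards, as.integer(n_arms),
                           p["lambda_hat"], p["theta_hat"], p["sigma_d_hat"],
                           p["sigma_o_hat"], p["mu0_pre"], p["var0_pre"],
                           0, beta_max, 1e-7)$total_nll
  }

  local_seed(seed)
  starts <- matrix(NA_real_, restarts, length(free),
                   dimnames = list(NULL, free))
  if (length(free)) {
    starts[1L, ] <- pmin(pmax(full[free], bounds[free, 1L]), bounds[free, 2L])
    if (restarts > 1L) {
      for (r in 2:restarts)
        starts[r, ] <- stats::runif(length(free), bounds[free, 1L],
                                    bounds[free, 2L])
    }
  }

  diag_rows <- vector("list", restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    if (length(free) == 0L) {
      fit <- list(par = numeric(0), value = objective(numeric(0)),
                  convergence = 0L, counts = c(`function` = 1L, gradient = 0L))
    } else {
      fit <- tryCatch(
        stats::optim(starts[r, ], objective, method = "L-BFGS-B",
                     lower = bounds[free, 1L], upper = bounds[free, 2L],
                     control = list(maxit = 300L)),
        error = function(e) NULL)
    }
    if (is.null(fit)) {
      diag_rows[[r]] <- data.frame(restart = r, converged = FALSE,
                                   evaluations = NA_integer_, nll = NA_real_)
      next
    }
    diag_rows[[r]] <- data.frame(restart = r, converged = fit$convergence == 0L,
                                 evaluations = unname(fit$counts[1L]),
                                 nll = fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  diagnostics <- do.call(rbind, diag_rows)
  if (is.null(best))
    stop("fit_bandit_model: all restarts failed; diagnostics:\n",
         paste(utils::capture.output(print(diagnostics)), collapse = "\n"),
         call. = FALSE)

  full[free] <- best$par
  prof <- cpp_cohort_profile_nll(choices, rewards, as.integer(n_arms),
                                 full["lambda_hat"], full["theta_hat"],
                                 full["sigma_d_hat"], full["sigma_o_hat"],
                                 full["mu0_pre"], full["var0_pre"],
                                 0, beta_max, 1e-8)
  ids <- vapply(sessions, function(s) attr(s, "subject"), character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  betas <- stats::setNames(prof$betas, ids)
  subject_nll <- stats::setNames(prof$nlls, ids)
  groups <- vapply(sessions, function(s) attr(s, "group"), character(1))
  group_nll <- if (all(is.na(groups))) NULL else
    tapply(subject_nll, groups, sum)

  params <- model_params(lambda_hat = full[["lambda_hat"]],
                         theta_hat = full[["theta_hat"]],
                         sigma_d_hat = full[["sigma_d_hat"]],
                         sigma_o_hat = full[["sigma_o_hat"]],
                         mu0_pre = full[["mu0_pre"]],
                         var0_pre = full[["var0_pre"]],
                         beta = mean(betas))
  structure(list(params = params, betas = betas, subject_nll = subject_nll,
                 total_nll = prof$total_nll, group_nll = group_nll,
                 groups = stats::setNames(groups, ids),
                 converged = any(diagnostics$converged),
                 diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Kalman-softmax maximum-likelihood fit\n")
  cat(sprintf("  %d subjects, total NLL = %.2f nats%s\n", length(x$betas),
              x$total_nll,
              if (x$converged) "" else " (no restart converged)"))
  p <- x$params
  cat(sprintf("  shared: lambda = %.4f, theta = %.2f, sigma_d = %.3f, sigma_o = %.3f, mu0 = %.2f, var0 = %.2f\n",
              p$lambda_hat, p$theta_hat, p$sigma_d_hat, p$sigma_o_hat,
              p$mu0_pre, p$var0_pre))
  cat(sprintf("  per-subject beta: mean %.4f, range [%.4f, %.4f]\n",
              mean(x$betas), min(x$betas), max(x$betas)))
  if (!is.null(x$group_nll)) {
    cat("  group NLL:", paste(sprintf("%s = %.1f", names(x$group_nll),
                                      x$group_nll), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a fit result as a JSON report
#' @param fit A `fit_result`.
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(params = unclass(fit$params),
              betas = as.list(fit$betas),
              subject_nll = as.list(fit$subject_nll),
              total_nll = fit$total_nll,
              group_nll = if (is.null(fit$group_nll)) NULL else
                as.list(fit$group_nll),
              converged = fit$converged,
              diagnostics = fit$diagnostics)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Compare per-subject softmax parameters between two groups
#'
#' Pooled-variance two-sample t-test on the fitted per-subject inverse
#' temperatures, df = n1 + n2 - 2.
#'
#' @param fit A `fit_result` from [fit_bandit_model()], or a named numeric
#'   vector of per-subject betas.
#' @param groups Named vector mapping subject id to group label; defaults to
#'   the groups stored in the fit.
#' @return List with `t`, `df`, `p`, and the per-group means.
#' @export
compare_group_betas <- function(fit, groups = NULL) {
  betas <- if (inherits(fit, "fit_result")) fit$betas else fit
  if (is.null(groups) && inherits(fit, "fit_result")) groups <- fit$groups
  if (is.null(groups)) stop("compare_group_betas: no group labels available",
                            call. = FALSE)
  groups <- groups[names(betas)]
  lv <- unique(stats::na.omit(groups))
  if (length(lv) != 2L)
    stop("compare_group_betas: exactly two groups required", call. = FALSE)
  x <- betas[groups == lv[1L]]; y <- betas[groups == lv[2L]]
  if (length(x) < 2L || length(y) < 2L)
    stop("compare_group_betas: each group needs at least 2 subjects",
         call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * stats::var(x) + (n2 - 1L) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mean(x) - mean(y)
  tstat <- if (se == 0) { if (diff == 0) 0 else sign(diff) * Inf } else
    diff / se
  list(t = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df),
       group_means = stats::setNames(c(mean(x), mean(y)), lv))
}
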