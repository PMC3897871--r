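#' Label trials as explorative or exploitative from model beliefs
#'
#' Walks a session with the Kalman filter at fixed parameters (typically the
#' cohort maximum-likelihood fit) and labels each responded trial:
#' *exploit* when the chosen arm's pre-choice belief mean is within
#' `tie_tol` of the maximum over arms, *explore* when a strictly
#' lower-valued arm was chosen, *missed* otherwise. Ties count as exploit:
#' an explorative choice is one of an arm believed strictly inferior to the
#' best. On trial 1 all arms share the prior mean, so the first responded
#' trial is a tie and labels exploit.
#'
#' @param session A `session_record`.
#' @param params A [model_params()] (beliefs advanced exactly as in
#'   [session_nll()]).
#' @param tie_tol Tie tolerance in points for "believed best".
#' @param n_arms Number of arms.
#' @return A `trial_labels` object: data.frame with columns `trial`, `label`
#'   (factor exploit/explore/missed), plus `counts` and `proportions`
#'   (over responded trials) attributes.
#' @export
label_trials <- function(session, params, tie_tol = 1e-9, n_arms = NULL) {
  stopifnot(inherits(session, "session_record"))
  M <- prechoice_means(session, params, n_arms = n_arms)
  ord <- order(session$trial)
  choice <- session$choice[ord]; missed <- session$missed[ord]
  best <- apply(M, 1L, max)
  chosen_mean <- M[cbind(seq_len(nrow(M)), ifelse(missed, 1L, choice))]
  lab <- ifelse(missed, "missed",
                ifelse(chosen_mean >= best - tie_tol, "exploit", "explore"))
  lab <- factor(lab, levels = c("exploit", "explore", "missed"))
  counts <- table(lab)
  responded <- sum(counts[c("exploit", "explore")])
  props <- if (responded > 0)
    counts[c("exploit", "explore")] / responded else
    stats::setNames(c(NA_real_, NA_real_), c("exploit", "explore"))
  out <- data.frame(trial = session$trial[ord], label = lab)
  attr(out, "counts") <- counts
  attr(out, "proportions") <- props
  attr(out, "subject") <- attr(session, "subject")
  class(out) <- c("trial_labels", "data.frame")
  out
}

#' @export
print.trial_labels <- function(x, ...) {
  ct <- attr(x, "counts")
  cat(sprintf("Trial labels for %s: %d exploit, %d explore, %d missed\n",
              attr(x, "subject"), ct[["exploit"]], ct[["explore"]],
              ct[["missed"]]))
  invisible(x)
}

#' Label every session of a cohort
#'
#' @param sessions List of `session_record`s.
#' @param params A [model_params()], typically `fit$params` from
#'   [fit_bandit_model()].
#' @param ... Passed to [label_trials()].
#' @return Named list of `trial_labels`, one per session.
#' @export
label_cohort <- function(sessions, params, ...) {
  out <- lapply(sessions, label_trials, params = params, ...)
  names(out) <- vapply(sessions, function(s) attr(s, "subject"), character(1))
  out
}

#' Write / read trial labels as CSV
#'
#' Long format with columns `subject`, `trial`, `label`.
#'
#' @param labels A `trial_labels` or a list of them (see [label_cohort()]).
#' @param path CSV path.
#' @return `write_labels` invisibly returns `path`; `read_labels` returns a
#'   named list of `trial_labels`.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "trial_labels")) labels <- list(labels)
  long <- do.call(rbind, lapply(labels, function(l)
    data.frame(subject = attr(l, "subject"), trial = l$trial,
               label = as.character(l$label))))
  write_csv_full(long, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  long <- utils::read.csv(path)
  stopifnot(all(c("subject", "trial", "label") %in% names(long)))
  lapply(split(long, long$subject), function(d) {
    d <- d[order(d$trial), ]
    lab <- factor(d$label, levels = c("exploit", "explore", "missed"))
    out <- data.frame(trial = d$trial, label = lab)
    counts <- table(lab)
    responded <- sum(counts[c("exploit", "explore")])
    attr(out, "counts") <- counts
    attr(out, "proportions") <- if (responded > 0)
      counts[c("exploit", "explore")] / responded else
      stats::setNames(c(NA_real_, NA_real_), c("exploit", "explore"))
    attr(out, "subject") <- as.character(d$subject[1L])
    class(out) <- c("trial_labels", "data.frame")
    out
  })
}
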