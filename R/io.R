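## Write a data.frame as CSV with doubles at full (round-trip) precision.
write_csv_full <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- sprintf("%.17g", df[[j]])
      x[is.na(df[[j]])] <- NA_character_
      df[[j]] <- x
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write / read cohort sessions as CSV
#'
#' Long trial-level format with columns `subject`, `group`, `run`, `trial`,
#' `choice`, `reward`, `rt`, `missed` — the on-disk interchange form of a
#' cohort's session records. Round-trips bit-identically through
#' `read_sessions()`.
#'
#' @param sessions List of `session_record`s (or a `cohort`, whose
#'   `$sessions` are used).
#' @param path CSV path.
#' @return `write_sessions` invisibly returns `path`; `read_sessions`
#'   returns a named list of `session_record`s.
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "cohort")) sessions <- sessions$sessions
  long <- do.call(rbind, lapply(sessions, function(s)
    data.frame(subject = attr(s, "subject"), group = attr(s, "group"),
               run = s$run, trial = s$trial, choice = s$choice,
               reward = s$reward, rt = s$rt, missed = s$missed)))
  write_csv_full(long, path)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  long <- utils::read.csv(path)
  need <- c("subject", "group", "run", "trial", "choice", "reward", "rt",
            "missed")
  if (!all(need %in% names(long)))
    stop("read_sessions: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(long, long$subject), function(d) {
    d <- d[order(d$trial), ]
    session_record(trial = d$trial, run = d$run, choice = d$choice,
                   reward = d$reward, rt = d$rt, missed = d$missed,
                   subject = d$subject[1L], group = d$group[1L])
  })
  out[unique(long$subject)]
}

#' Group map of a session list
#' @param sessions List of `session_record`s.
#' @return Named character vector, subject id to group label.
#' @export
session_groups <- function(sessions) {
  if (inherits(sessions, "cohort")) return(sessions$groups)
  stats::setNames(vapply(sessions, function(s) attr(s, "group"), character(1)),
                  vapply(sessions, function(s) attr(s, "subject"), character(1)))
}
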