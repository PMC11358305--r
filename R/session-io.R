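trial_cols <- c("session_id", "subject", "task", "treatment", "trial",
                "stim_left", "stim_right", "reward_left", "reward_right",
                "choice", "reward_obtained", "pattern", "post_reversal",
                "reversal_boundary")

#' Validate a trial tibble
#'
#' Checks the structural invariants of the trial-log data model: required
#' columns present; trial indices contiguous from 1 within each session;
#' distinct stimuli and rewards within a pair; the delivered reward equal to
#' the in-force map's reward for the chosen side; the pattern changing only
#' at reversal boundaries; and exactly one reversal in NOVEL sessions.
#'
#' @param trials Trial tibble (see [sim_novel_session()] for the columns).
#' @return `trials`, invisibly; errors describe the offending session and
#'   trial.
#' @export
validate_sessions <- function(trials) {
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing) > 0L) {
    abort(paste0("trial log is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  fail <- function(sid, trial, msg) {
    abort(sprintf("invalid trial log (session %s, trial %s): %s", sid, trial, msg))
  }
  by_session <- split(seq_len(nrow(trials)), trials$session_id)
  for (sid in names(by_session)) {
    s <- trials[by_session[[sid]], ]
    if (!identical(as.integer(s$trial), seq_len(nrow(s)))) {
      fail(sid, s$trial[1], "trial indices must be contiguous from 1")
    }
    bad <- which(s$stim_left == s$stim_right)
    if (length(bad)) fail(sid, bad[1], "identical stimuli offered")
    bad <- which(!(s$choice == s$stim_left | s$choice == s$stim_right))
    if (length(bad)) fail(sid, bad[1], "choice is not one of the offered stimuli")
    chosen_reward <- ifelse(s$choice == s$stim_left, s$reward_left, s$reward_right)
    bad <- which(s$reward_obtained != chosen_reward)
    if (length(bad)) fail(sid, bad[1], "reward_obtained differs from the chosen side's reward")
    for (p in c("A", "B")) {
      rows <- which(s$pattern == p)
      if (!length(rows)) next
      m <- reward_map(p)
      bad <- rows[m[s$stim_left[rows]] != s$reward_left[rows] |
                  m[s$stim_right[rows]] != s$reward_right[rows]]
      if (length(bad)) fail(sid, bad[1], paste0("rewards inconsistent with pattern ", p))
    }
    switches <- which(s$pattern != dplyr::lag(s$pattern, default = s$pattern[1]))
    bad <- setdiff(switches, which(s$reversal_boundary))
    if (length(bad)) fail(sid, bad[1], "pattern changed without a reversal boundary")
    if (s$task[1] == "NOVEL" && sum(s$reversal_boundary) != 1L) {
      fail(sid, NA, "NOVEL sessions must contain exactly one reversal")
    }
  }
  invisible(trials)
}

#' Write a trial log to tidy CSV
#'
#' One row per trial, canonical column order, all session metadata carried
#' as columns; writing the same trials twice produces byte-identical files.
#'
#' @param trials Trial tibble; validated before writing.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(trials, path) {
  if (nrow(trials) > 0L) validate_sessions(trials)
  extra <- setdiff(names(trials), trial_cols)
  ordered <- trials[, c(intersect(trial_cols, names(trials)), extra)]
  readr::write_csv(ordered, path, progress = FALSE)
  invisible(path)
}

#' Read a trial log from tidy CSV
#'
#' @param path CSV written by [write_sessions()] (or any file with the same
#'   header). Extra columns are passed through untouched.
#' @return Validated trial tibble, ordered by session then trial.
#' @export
read_sessions <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing) > 0L) {
    abort(paste0("trial log is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(trials) == 0L) return(trials)
  trials <- trials |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("trial", "reward_left", "reward_right",
                                                "reward_obtained")), as.integer),
                  dplyr::across(dplyr::all_of(c("post_reversal", "reversal_boundary")),
                                as.logical)) |>
    dplyr::arrange(match(.data$session_id, unique(.data$session_id)), .data$trial)
  validate_sessions(trials)
  trials
}
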