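#' Optimal-choice indicator
#'
#' A choice is optimal when the chosen stimulus carries the larger reward of
#' the offered pair under the map currently in force — immediately after a
#' reversal, choosing the formerly better stimulus therefore counts as
#' non-optimal.
#'
#' @param trials Trial tibble.
#' @return Integer 0/1 vector, one entry per row.
#' @export
optimal_choice_indicator <- function(trials) {
  as.integer(trials$reward_obtained == pmax(trials$reward_left, trials$reward_right))
}

#' Block-averaged optimal-choice rate
#'
#' Mean optimal-choice rate over consecutive blocks of trials (default 10,
#' matching the round-robin schedule, so each block offers every pair
#' once). Trailing partial blocks are dropped.
#'
#' @param trials Trial tibble.
#' @param block Block length in trials.
#' @return Tibble with `session_id`, `block` (1-based), `rate`.
#' @export
block_optimal_rate <- function(trials, block = 10L) {
  trials |>
    dplyr::mutate(optimal = optimal_choice_indicator(trials)) |>
    dplyr::group_by(.data$session_id) |>
    dplyr::mutate(block = (.data$trial - 1L) %/% block + 1L,
                  .complete = dplyr::n() %/% !!block) |>
    dplyr::filter(.data$block <= .data$.complete) |>
    dplyr::group_by(.data$session_id, .data$block) |>
    dplyr::summarise(rate = mean(.data$optimal), .groups = "drop")
}

# Phase windows for one session: list of per-reversal window index lists.
phase_windows <- function(s) {
  b <- s$trial[s$reversal_boundary]
  if (length(b) == 0L) abort(sprintf("session %s has no reversal", s$session_id[1]))
  n <- nrow(s)
  if (s$task[1] == "NOVEL") {
    list(list(pre = seq_len(b - 1L),
              poe = seq(b, min(b + 99L, n)),
              pol = if (b + 100L <= n) seq(b + 100L, min(b + 209L, n)) else integer()))
  } else {
    purrr::map(seq_along(b), function(i) {
      lo <- if (i == 1L) 1L else b[i - 1L] + 10L  # keep clear of the previous PoL
      pre <- seq2(max(b[i] - 10L, lo), b[i] - 1L)
      if (length(pre) < 10L) {
        warn(sprintf("session %s: Pre window at reversal %d truncated to %d trials",
                     s$session_id[1], i, length(pre)))
      }
      hi <- if (i == length(b)) n else b[i + 1L] - 1L
      list(pre = pre,
           poe = seq2(b[i], min(b[i] + 4L, hi)),
           pol = seq2(b[i] + 5L, min(b[i] + 9L, hi)))
    })
  }
}

seq2 <- function(from, to) if (from > to) integer() else seq(from, to)

#' Phase-wise optimal-choice rates
#'
#' NOVEL sessions are split at their single reversal into Pre (the 90
#' trials before it), PoE (the first 100 trials after it) and PoL (the next
#' 110). FAMILIAR sessions use per-reversal windows — Pre: 10 trials before,
#' PoE: first 5 after, PoL: next 5 — computed per reversal and then averaged
#' across reversals (never pooled). Windows are truncated at session edges
#' and never overlap a neighboring reversal's windows.
#'
#' @param trials Trial tibble (any mix of sessions with `>= 1` reversal).
#' @return Tibble with `session_id`, `subject`, `task`, `treatment`,
#'   `phase` (`Pre`/`PoE`/`PoL`), `rate`.
#' @export
phase_rates <- function(trials) {
  purrr::map(split(trials, trials$session_id), function(s) {
    s <- dplyr::arrange(s, .data$trial)
    opt <- optimal_choice_indicator(s)
    per_rev <- purrr::map(phase_windows(s), function(wnd) {
      c(Pre = mean(opt[wnd$pre]), PoE = mean(opt[wnd$poe]), PoL = mean(opt[wnd$pol]))
    })
    rates <- colMeans(do.call(rbind, per_rev), na.rm = TRUE)
    tibble::tibble(session_id = s$session_id[1], subject = s$subject[1],
                   task = s$task[1], treatment = s$treatment[1],
                   phase = factor(names(rates), levels = c("Pre", "PoE", "PoL")),
                   rate = unname(rates))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(match(.data$session_id, unique(trials$session_id)), .data$phase)
}

#' Extract unpredicted-experience events and their evaluation trials
#'
#' Within the early post-reversal (PoE) phase of a NOVEL-like session, an
#' unpredicted positive experience is the first choice of a high-valued
#' option (4 or 5 drops under the in-force map) whose most recent earlier
#' presentation had that option offered, carrying the pair's larger reward,
#' and yet not chosen; a negative experience is defined symmetrically for
#' low-valued options (1 or 2 drops) — the first suboptimal choice of such
#' an option (taken although it carried the pair's smaller reward) whose
#' most recent earlier presentation had it offered and not chosen. In both
#' cases the defining error is suboptimal behavior, so an agent that always
#' takes the better option of each pair generates no events. The evaluation
#' trial is the next presentation of that option after the event; one event
#' is extracted per option per session.
#'
#' @param trials Trial tibble; sessions without a reversal are skipped.
#' @param sign `"positive"` or `"negative"`.
#' @param within `"poe"` (default) restricts the whole
#'   non-choice/event/evaluation chain to the PoE window; `"post"` uses the
#'   full post-reversal period.
#' @return Tibble with one row per extracted event: `session_id`, `sign`,
#'   `option`, `nonchoice_trial`, `event_trial`, `eval_trial`,
#'   `eval_optimal` (0/1 indicator at the evaluation trial).
#' @export
experience_events <- function(trials, sign = c("positive", "negative"),
                              within = c("poe", "post")) {
  sign <- match.arg(sign)
  within <- match.arg(within)
  purrr::map(split(trials, trials$session_id), function(s) {
    s <- dplyr::arrange(s, .data$trial)
    b <- s$trial[s$reversal_boundary]
    if (length(b) == 0L) return(NULL)
    b <- min(b)
    hi <- if (within == "poe") min(b + 99L, nrow(s)) else nrow(s)
    idx <- seq(b, hi)
    map <- reward_map(s$pattern[b])
    wanted <- if (sign == "positive") c(4L, 5L) else c(1L, 2L)
    options <- names(map)[map %in% wanted]
    opt <- optimal_choice_indicator(s)
    purrr::map(options, function(o) {
      pres <- idx[s$stim_left[idx] == o | s$stim_right[idx] == o]
      if (length(pres) < 3L) return(NULL)
      took <- s$choice[pres] == o
      was_best <- map[[o]] == pmax(s$reward_left[pres], s$reward_right[pres])
      ev <- if (sign == "positive") {
        # chosen right after failing to take it when it was the better option
        which(took & !dplyr::lag(took, default = TRUE) &
                dplyr::lag(was_best, default = FALSE))[1]
      } else {
        # taken although it was the worse option, after an unchosen presentation
        which(took & !was_best & !dplyr::lag(took, default = TRUE))[1]
      }
      if (is.na(ev) || ev == length(pres)) return(NULL)
      tibble::tibble(session_id = s$session_id[1], sign = sign, option = o,
                     nonchoice_trial = pres[ev - 1L], event_trial = pres[ev],
                     eval_trial = pres[ev + 1L],
                     eval_optimal = opt[pres[ev + 1L]])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Extract inference trials after each FAMILIAR reversal
#'
#' The 1st trial of a reversal is the first trial played under the new map.
#' The inference trial is the earliest later trial (before the next
#' reversal) whose offered pair shares no stimulus with the 1st trial's
#' pair: an optimal choice there cannot rest on direct experience with
#' either option since the reversal.
#'
#' @param trials Trial tibble of FAMILIAR sessions; reversal-free sessions
#'   contribute nothing, as do reversals with no disjoint pair before the
#'   next reversal.
#' @return Tibble with one row per reversal: `session_id`, `first_trial`,
#'   `inference_trial`, `first_optimal`, `inference_optimal` (0/1
#'   indicators).
#' @export
inference_trials <- function(trials) {
  purrr::map(split(trials, trials$session_id), function(s) {
    s <- dplyr::arrange(s, .data$trial)
    b <- s$trial[s$reversal_boundary]
    if (length(b) == 0L) return(NULL)
    opt <- optimal_choice_indicator(s)
    nxt <- c(b[-1L] - 1L, nrow(s))
    purrr::map2(b, nxt, function(bi, hi) {
      pair0 <- c(s$stim_left[bi], s$stim_right[bi])
      cand <- seq2(bi + 1L, hi)
      disjoint <- !(s$stim_left[cand] %in% pair0 | s$stim_right[cand] %in% pair0)
      if (!any(disjoint)) return(NULL)
      it <- cand[which(disjoint)[1]]
      tibble::tibble(session_id = s$session_id[1], first_trial = bi,
                     inference_trial = it,
                     first_optimal = opt[bi], inference_optimal = opt[it])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Devaluation proportion-shifted index
#'
#' Summarizes how much choice shifts away from objects whose associated
#' food was devalued:
#' `((F1N - F1D) + (F2N - F2D)) / (F1N + F2N)`,
#' where `F1`/`F2` count choices associated with the two food types and
#' `N`/`D` index the baseline and devaluation tests. Equal counts give 0; a
#' complete shift (no devalued-object choices) gives 1.
#'
#' @param f1n,f1d,f2n,f2d Nonnegative choice counts (baseline and
#'   devaluation days for foods 1 and 2).
#' @return The proportion shifted.
#' @examples
#' proportion_shifted(20, 10, 20, 5)  # 0.625
#' @export
proportion_shifted <- function(f1n, f1d, f2n, f2d) {
  counts <- c(f1n, f1d, f2n, f2d)
  if (any(!is.finite(counts) | counts < 0)) abort("counts must be nonnegative")
  if (f1n + f2n == 0) abort("baseline counts must sum to a positive number")
  ((f1n - f1d) + (f2n - f2d)) / (f1n + f2n)
}
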