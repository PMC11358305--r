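#' Run the full synthetic analysis chain
#'
#' Generates a synthetic cohort from a preset design, fits the task-matched
#' modified models (EXP on NOVEL, INF on FAMILIAR) and both basic models,
#' compares models per session by BIC posterior, computes phase-wise
#' optimal-choice rates, experience-event and inference-trial statistics,
#' and reports treated-vs-control contrasts of the fitted post-reversal
#' learning rate and inverse temperature with permutation p-values. The
#' whole report is a pure function of `(preset arguments, seed)`.
#'
#' @inheritParams cohort_design
#' @param seed Master seed for cohort generation, fitting starts, and
#'   permutation tests.
#' @param out_dir If non-`NULL`, a directory where the sessions, ground
#'   truth, fits, posteriors, phase rates and contrasts are written as CSV.
#' @param n_perm Permutations for the group contrasts.
#' @param n_starts Optimizer starts per fit.
#' @param ... Further arguments to [cohort_design()] (e.g. `effect`,
#'   `n_novel`).
#' @return An `rl_report` list: `design`, `sessions`, `ground_truth`,
#'   `fits`, `posteriors`, `phase`, `recovery`, `events`, `inference`,
#'   `provenance`. `glance()` condenses it to one row.
#' @examples
#' \donttest{
#' rep <- run_pipeline("rmcd", seed = 42, n_perm = 500)
#' glance(rep)
#' }
#' @export
run_pipeline <- function(preset = c("ofc", "rmcd", "mdm"), seed = 1L,
                         out_dir = NULL, n_perm = 2000L, n_starts = 10L, ...) {
  preset <- match.arg(preset)
  design <- cohort_design(preset, ...)
  cohort <- generate_cohort(design, seed = seed)
  sessions <- cohort$sessions
  novel <- dplyr::filter(sessions, .data$task == "NOVEL")
  familiar <- dplyr::filter(sessions, .data$task == "FAMILIAR")

  fits <- dplyr::bind_rows(
    fit_sessions(novel, models = "exp", variants = "modified",
                 n_starts = n_starts, seed = seed),
    fit_sessions(familiar, models = "inf", variants = "modified",
                 n_starts = n_starts, seed = seed),
    fit_sessions(sessions, models = c("exp", "inf"), variants = "basic",
                 n_starts = n_starts, seed = seed)
  )
  posteriors <- compare_models(fits, variant = "basic")
  phase <- phase_rates(sessions) |>
    dplyr::group_by(.data$task, .data$treatment, .data$phase) |>
    dplyr::summarise(mean_rate = mean(.data$rate),
                     sem = sd(.data$rate) / sqrt(dplyr::n()),
                     n_sessions = dplyr::n(), .groups = "drop")
  recovery <- recovery_report(fits, cohort$ground_truth,
                              n_perm = n_perm, seed = seed)
  events <- dplyr::bind_rows(experience_events(novel, "positive"),
                             experience_events(novel, "negative")) |>
    dplyr::left_join(dplyr::distinct(sessions, .data$session_id, .data$treatment),
                     by = "session_id") |>
    dplyr::group_by(.data$sign, .data$treatment) |>
    dplyr::summarise(rate = mean(.data$eval_optimal), n_events = dplyr::n(),
                     .groups = "drop")
  inference <- inference_trials(familiar) |>
    dplyr::left_join(dplyr::distinct(sessions, .data$session_id, .data$treatment),
                     by = "session_id") |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(first_rate = mean(.data$first_optimal),
                     inference_rate = mean(.data$inference_optimal),
                     n_reversals = dplyr::n(), .groups = "drop")

  report <- structure(list(
    design = design, sessions = sessions, ground_truth = cohort$ground_truth,
    fits = fits, posteriors = posteriors, phase = phase, recovery = recovery,
    events = events, inference = inference,
    provenance = list(
      preset = preset, seed = seed, n_perm = n_perm, n_starts = n_starts,
      design_hash = rlang::hash(design),
      package_version = as.character(utils::packageVersion("revalr"))
    )
  ), class = "rl_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sessions(sessions, file.path(out_dir, "sessions.csv"))
    readr::write_csv(cohort$ground_truth, file.path(out_dir, "ground_truth.csv"))
    readr::write_csv(fits, file.path(out_dir, "fits.csv"))
    readr::write_csv(posteriors, file.path(out_dir, "posteriors.csv"))
    readr::write_csv(phase, file.path(out_dir, "phase_rates.csv"))
    readr::write_csv(recovery$contrasts, file.path(out_dir, "contrasts.csv"))
  }
  report
}

matched_posterior <- function(report) {
  report$posteriors |>
    dplyr::filter(.data$model == ifelse(.data$task == "NOVEL", "EXP", "INF")) |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(mean_posterior = mean(.data$posterior),
                     prop_favored = mean(.data$posterior > 0.5),
                     .groups = "drop")
}

#' @export
print.rl_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<rl_report> preset '%s', seed %d, %d sessions\n",
              p$preset, p$seed, length(unique(x$sessions$session_id))))
  cat("\nPhase-wise optimal-choice rate (mean +/- sem):\n")
  print(as.data.frame(x$phase), row.names = FALSE, digits = 3)
  cat("\nTreated-vs-control contrasts of fitted parameters:\n")
  print(as.data.frame(x$recovery$contrasts), row.names = FALSE, digits = 3)
  cat("\nTask-matched model support (BIC posterior, basic variants):\n")
  print(as.data.frame(matched_posterior(x)), row.names = FALSE, digits = 3)
  cat("\nFAMILIAR 1st-trial vs inference-trial optimal rate:\n")
  print(as.data.frame(x$inference), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `rl_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.rl_report <- function(x, ...) {
  ctr <- x$recovery$contrasts
  pick <- function(task, par, col) {
    v <- ctr[[col]][ctr$task == task & ctr$parameter == par]
    if (length(v)) v else NA_real_
  }
  poe <- tidyr::pivot_wider(dplyr::filter(x$phase, .data$phase == "PoE"),
                            id_cols = "task", names_from = "treatment",
                            values_from = "mean_rate")
  arms <- unique(x$design$treatment)  # c(control, treated), design order
  tibble::tibble(
    preset = x$provenance$preset, seed = x$provenance$seed,
    novel_poe_deficit = poe[[arms[1]]][poe$task == "NOVEL"] -
      poe[[arms[2]]][poe$task == "NOVEL"],
    familiar_poe_deficit = poe[[arms[1]]][poe$task == "FAMILIAR"] -
      poe[[arms[2]]][poe$task == "FAMILIAR"],
    novel_alpha_post_diff = pick("NOVEL", "alpha_post", "difference"),
    novel_alpha_post_p = pick("NOVEL", "alpha_post", "p_value"),
    familiar_alpha_post_diff = pick("FAMILIAR", "alpha_post", "difference"),
    familiar_alpha_post_p = pick("FAMILIAR", "alpha_post", "p_value"),
    novel_beta_p = pick("NOVEL", "beta", "p_value"),
    familiar_beta_p = pick("FAMILIAR", "beta", "p_value")
  )
}
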