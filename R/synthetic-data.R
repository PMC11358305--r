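#' Design a synthetic cohort
#'
#' Lays out a study-shaped cohort: two subjects, a control and a treated
#' arm, NOVEL sessions generated by the EXP agent and FAMILIAR sessions by
#' the INF agent. Under the treated condition the post-reversal learning
#' rate is multiplied by `effect` (the model-level account of chemogenetic
#' silencing); the inverse temperature is never altered. Presets:
#'
#' * `"ofc"` — effect in both tasks; 7 NOVEL and 6 FAMILIAR sessions per
#'   treatment per subject.
#' * `"rmcd"` — effect in NOVEL only; 5 sessions per task/treatment/subject.
#' * `"mdm"` — effect in FAMILIAR only; 5 sessions per task/treatment/subject.
#'
#' @param preset `"ofc"`, `"rmcd"`, or `"mdm"`.
#' @param effect Multiplier in (0, 1\] applied to the post-reversal learning
#'   rate in the treated arm of affected tasks; 1 means no effect.
#' @param subjects Two subject labels; the second runs 400-trial FAMILIAR
#'   sessions, the first 300-trial ones.
#' @param treatments Two treatment labels, `c(control, treated)`.
#' @param n_novel,n_familiar Sessions per treatment per subject; `NULL`
#'   takes the preset's value.
#' @param exp_alpha,exp_beta,inf_alpha,inf_beta Generating parameters of
#'   the EXP (NOVEL) and INF (FAMILIAR) agents.
#' @return Design tibble, one row per planned session, carrying the
#'   generating model and parameters (`alpha_post` already includes the
#'   effect where it applies).
#' @export
cohort_design <- function(preset = c("ofc", "rmcd", "mdm"), effect = 0.5,
                          subjects = c("Mk1", "Mk2"),
                          treatments = c("vehicle", "DCZ"),
                          n_novel = NULL, n_familiar = NULL,
                          exp_alpha = 0.15, exp_beta = 1.5,
                          inf_alpha = 0.05, inf_beta = 1.5) {
  preset <- match.arg(preset)
  stopifnot(effect > 0, effect <= 1,
            length(subjects) == 2L, length(treatments) == 2L)
  n_novel <- n_novel %||% if (preset == "ofc") 7L else 5L
  n_familiar <- n_familiar %||% if (preset == "ofc") 6L else 5L
  affected <- switch(preset,
                     ofc = c("NOVEL", "FAMILIAR"),
                     rmcd = "NOVEL",
                     mdm = "FAMILIAR")
  design <- dplyr::bind_rows(
    tidyr::expand_grid(subject = subjects, treatment = treatments,
                       task = "NOVEL", session = seq_len(n_novel)),
    tidyr::expand_grid(subject = subjects, treatment = treatments,
                       task = "FAMILIAR", session = seq_len(n_familiar))
  )
  design |>
    dplyr::mutate(
      session_id = paste(.data$subject, .data$treatment,
                         tolower(.data$task), .data$session, sep = "-"),
      model = ifelse(.data$task == "NOVEL", "exp", "inf"),
      alpha = ifelse(.data$task == "NOVEL", exp_alpha, inf_alpha),
      beta = ifelse(.data$task == "NOVEL", exp_beta, inf_beta),
      silenced = .data$treatment == treatments[2] & .data$task %in% affected,
      alpha_post = .data$alpha * ifelse(.data$silenced, effect, 1),
      n_trials = ifelse(.data$task == "NOVEL", 300L,
                        ifelse(.data$subject == subjects[2], 400L, 300L)),
      preset = preset, effect = effect
    )
}

#' Generate a synthetic cohort with ground truth
#'
#' Simulates every session planned by a [cohort_design()], deriving one
#' sub-seed per session from the master seed, so the whole cohort is a pure
#' function of `(design, seed)`. The returned ground truth records the
#' generating model, parameters and seeds; it is never consumed by the
#' fitting functions.
#'
#' @param design Design tibble from [cohort_design()].
#' @param seed Master seed.
#' @return List with `sessions` (trial tibble over all sessions) and
#'   `ground_truth` (the design plus per-session seeds).
#' @export
generate_cohort <- function(design, seed = 1L) {
  truth <- design
  truth$seed <- withr::with_seed(seed, sample.int(2147483646L, nrow(design)))
  sessions <- purrr::pmap(
    truth[, c("session_id", "subject", "task", "treatment", "model",
              "alpha", "beta", "alpha_post", "n_trials", "seed")],
    function(session_id, subject, task, treatment, model,
             alpha, beta, alpha_post, n_trials, seed) {
      if (task == "NOVEL") {
        sim_novel_session(model, alpha = alpha, beta = beta,
                          alpha_post = alpha_post,
                          n_acquisition = 90L, n_post = n_trials - 90L,
                          session_id = session_id, subject = subject,
                          treatment = treatment, seed = seed)
      } else {
        sim_familiar_session(model, alpha = alpha, beta = beta,
                             alpha_post = alpha_post, n_trials = n_trials,
                             session_id = session_id, subject = subject,
                             treatment = treatment, seed = seed)
      }
    }
  ) |> dplyr::bind_rows()
  list(sessions = sessions, ground_truth = truth)
}

#' Permutation test for a difference in group means
#'
#' Shuffles group labels `n_perm` times and compares the observed
#' `mean(x) - mean(y)` with the permutation distribution; the p-value uses
#' the add-one estimator `(1 + #{as extreme}) / (n_perm + 1)`.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"less"` (`mean(x) < mean(y)`), or
#'   `"greater"`.
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutations.
#' @return Tibble with `estimate` (observed difference) and `p_value`.
#' @export
permutation_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                             n_perm = 2000L, seed = 1L) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  nx <- length(x)
  perm <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), nx)
      mean(pooled[idx]) - mean(pooled[-idx])
    })
  })
  extreme <- switch(alternative,
                    two.sided = sum(abs(perm) >= abs(obs)),
                    less = sum(perm <= obs),
                    greater = sum(perm >= obs))
  tibble::tibble(estimate = obs, p_value = (1 + extreme) / (n_perm + 1))
}

#' Parameter-recovery report for a fitted synthetic cohort
#'
#' Joins per-session fits to the cohort's ground truth and summarizes, per
#' task and treatment arm, the recovery of the post-reversal learning rate
#' and the inverse temperature, plus the treated-vs-control contrasts with
#' permutation p-values (one-sided for the learning rate, whose silencing
#' effect is directional; two-sided for the inverse temperature).
#'
#' @param fits Fit tibble from [fit_sessions()]; modified-variant rows of
#'   the task-matched model (EXP for NOVEL, INF for FAMILIAR) are used.
#' @param truth Ground-truth tibble from [generate_cohort()].
#' @param n_perm,seed Passed to [permutation_test()].
#' @return List with `by_arm` (per task x treatment recovery summaries) and
#'   `contrasts` (per task x parameter treated-minus-control differences).
#' @export
recovery_report <- function(fits, truth, n_perm = 2000L, seed = 1L) {
  matched <- fits |>
    dplyr::filter(.data$variant == "modified",
                  .data$model == ifelse(.data$task == "NOVEL", "EXP", "INF"))
  if (!all(matched$session_id %in% truth$session_id)) {
    abort("fits contain session ids absent from the ground truth")
  }
  joined <- dplyr::inner_join(
    matched,
    dplyr::select(truth, "session_id", true_alpha_post = "alpha_post",
                  true_beta = "beta", "silenced"),
    by = "session_id"
  )
  by_arm <- joined |>
    dplyr::group_by(.data$task, .data$treatment) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      alpha_post_mean = mean(.data$alpha_post),
      alpha_post_bias = mean(.data$alpha_post - .data$true_alpha_post),
      alpha_post_mae = mean(abs(.data$alpha_post - .data$true_alpha_post)),
      beta_mean = mean(.data$beta),
      beta_bias = mean(.data$beta - .data$true_beta),
      .groups = "drop"
    )
  treated_label <- unique(joined$treatment[joined$silenced])
  if (length(treated_label) == 0L) {
    # effect multiplier 1: fall back to the arm labelled last in the design
    treated_label <- dplyr::last(unique(truth$treatment))
  }
  contrasts <- joined |>
    dplyr::group_by(.data$task) |>
    dplyr::group_modify(function(g, key) {
      tr <- g[g$treatment == treated_label, ]
      ct <- g[g$treatment != treated_label, ]
      purrr::map2(c("alpha_post", "beta"), c("less", "two.sided"),
                  function(par, alt) {
                    pt <- permutation_test(tr[[par]], ct[[par]], alternative = alt,
                                           n_perm = n_perm, seed = seed)
                    tibble::tibble(parameter = par,
                                   control_mean = mean(ct[[par]]),
                                   treated_mean = mean(tr[[par]]),
                                   difference = pt$estimate,
                                   alternative = alt, p_value = pt$p_value)
                  }) |> dplyr::bind_rows()
    }) |>
    dplyr::ungroup()
  list(by_arm = by_arm, contrasts = contrasts)
}
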