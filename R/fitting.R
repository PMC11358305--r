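#' Post-reversal trial mask
#'
#' The post-reversal period — the trials whose value updates the modified
#' model variant assigns a separate learning rate — is every trial from the
#' reversal onward in a NOVEL session, and the 5 trials from each reversal
#' onward in a FAMILIAR session (truncated at session end).
#'
#' @param trials Trial tibble (one or more sessions).
#' @return Logical vector, one entry per row of `trials`.
#' @export
post_reversal_mask <- function(trials) {
  unsplit(lapply(split(trials, trials$session_id), function(s) {
    b <- s$trial[s$reversal_boundary]
    if (length(b) == 0L) return(rep(FALSE, nrow(s)))
    if (s$task[1] == "NOVEL") {
      s$trial >= min(b)
    } else {
      Reduce(`|`, lapply(b, function(bi) s$trial >= bi & s$trial <= bi + 4L))
    }
  }), trials$session_id)
}

session_arrays <- function(s) {
  chosen <- stim_index(s$choice)
  left <- stim_index(s$stim_left)
  right <- stim_index(s$stim_right)
  list(chosen = chosen,
       other = ifelse(chosen == left, right, left),
       reward = as.integer(s$reward_obtained),
       post = post_reversal_mask(s))
}

one_session <- function(trials) {
  if (length(unique(trials$session_id)) != 1L) {
    abort("expected a single session; use fit_sessions() for many")
  }
  trials
}

#' Session negative log-likelihood
#'
#' Sum over trials of `-log P(observed choice)` under the EXP or INF model,
#' with the latent state evolved by the delivered rewards. The probability
#' of the choice at trial `t` uses the state before trial `t`'s update. The
#' `"modified"` variant applies `alpha_post` to updates on post-reversal
#' trials (see [post_reversal_mask()]) and `alpha_other` elsewhere; the
#' `"basic"` variant uses a single `alpha` throughout.
#'
#' @param trials Trial tibble for one session.
#' @param model `"exp"` or `"inf"`.
#' @param variant `"basic"` or `"modified"`.
#' @param pars Named numeric vector: `alpha`, `beta` for `"basic"`;
#'   `alpha_post`, `alpha_other`, `beta` for `"modified"`.
#' @return Total negative log-likelihood (a nonnegative number).
#' @examples
#' s <- sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 1)
#' negloglik(s, "exp", "basic", c(alpha = 0.15, beta = 1.5))
#' @export
negloglik <- function(trials, model = c("exp", "inf"),
                      variant = c("basic", "modified"), pars) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  trials <- one_session(trials)
  arr <- session_arrays(trials)
  alpha_vec <- if (variant == "basic") {
    rep(pars[["alpha"]], nrow(trials))
  } else {
    ifelse(arr$post, pars[["alpha_post"]], pars[["alpha_other"]])
  }
  check_beta(pars[["beta"]])
  fn <- if (model == "exp") nll_exp_cpp else nll_inf_cpp
  fn(arr$chosen, arr$other, arr$reward, alpha_vec, pars[["beta"]])
}

default_bounds <- function() list(alpha = c(0, 1), beta = c(0, 10))

par_names <- function(variant) {
  if (variant == "basic") c("alpha", "beta") else c("alpha_post", "alpha_other", "beta")
}

#' Fit one session by multi-start maximum likelihood
#'
#' Minimizes [negloglik()] with bounded L-BFGS-B from `n_starts` starting
#' points drawn from a seeded Latin hypercube over the parameter bounds,
#' and returns the best converged start. Deterministic given `seed`.
#'
#' @inheritParams negloglik
#' @param n_starts Number of optimizer starts.
#' @param bounds List with elements `alpha` and `beta`, each `c(lower,
#'   upper)`; the `alpha` bounds apply to both learning rates of the
#'   modified variant.
#' @param seed Seed for the start-point design.
#' @return An object of class `rl_fit`: parameter estimates, maximized
#'   log-likelihood, trial count, and optimizer diagnostics. Use [tidy()]
#'   and [glance()] to extract tibbles.
#' @examples
#' s <- sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 1)
#' fit <- fit_session(s, "exp", "basic")
#' tidy(fit)
#' glance(fit)
#' @export
fit_session <- function(trials, model = c("exp", "inf"),
                        variant = c("basic", "modified"),
                        n_starts = 10L, bounds = default_bounds(), seed = 1L) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  trials <- one_session(trials)
  arr <- session_arrays(trials)
  if (variant == "modified" && !any(arr$post)) {
    abort("modified variant needs at least one post-reversal trial")
  }
  nms <- par_names(variant)
  k <- length(nms)
  lower <- c(rep(bounds$alpha[1], k - 1L), bounds$beta[1])
  upper <- c(rep(bounds$alpha[2], k - 1L), bounds$beta[2])
  fn_cpp <- if (model == "exp") nll_exp_cpp else nll_inf_cpp
  objective <- function(p) {
    alpha_vec <- if (variant == "basic") {
      rep(p[1], length(arr$chosen))
    } else {
      ifelse(arr$post, p[1], p[2])
    }
    fn_cpp(arr$chosen, arr$other, arr$reward, alpha_vec, p[k])
  }
  starts <- withr::with_seed(seed, lhs::randomLHS(n_starts, k))
  starts <- sweep(sweep(starts, 2L, upper - lower, `*`), 2L, lower, `+`)
  runs <- purrr::map(seq_len(n_starts), function(i) {
    tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL
    )
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0L) {
    abort(sprintf("all %d optimizer starts failed for session %s",
                  n_starts, trials$session_id[1]))
  }
  values <- purrr::map_dbl(runs, "value")
  best <- runs[[which.min(values)]]
  estimates <- setNames(best$par, nms)
  structure(list(
    session_id = trials$session_id[1], subject = trials$subject[1],
    task = trials$task[1], treatment = trials$treatment[1],
    model = toupper(model), variant = variant,
    estimates = estimates, logLik = -best$value,
    n_trials = nrow(trials), k = k,
    n_starts = n_starts, n_converged = sum(purrr::map_dbl(runs, "convergence") == 0),
    convergence = best$convergence,
    flat = estimates[["beta"]] < 1e-6,
    start_values = values
  ), class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("<rl_fit> %s/%s  session %s (%s, %s, %d trials)\n",
              x$model, x$variant, x$session_id, x$task, x$treatment, x$n_trials))
  cat("  estimates:", paste(sprintf("%s = %.4f", names(x$estimates), x$estimates),
                            collapse = ", "), "\n")
  cat(sprintf("  logLik = %.3f  (%d/%d starts converged)\n",
              x$logLik, x$n_converged, x$n_starts))
  if (x$flat) cat("  note: beta ~ 0; learning rate(s) unidentifiable\n")
  invisible(x)
}

#' @rdname fit_session
#' @param x An `rl_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @rdname fit_session
#' @exportS3Method generics::glance
glance.rl_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, df = x$k, nobs = x$n_trials,
                 BIC = bic(x$logLik, x$k, x$n_trials),
                 n_converged = x$n_converged, flat = x$flat)
}

#' Fit every session of a trial log
#'
#' Maps [fit_session()] over the sessions of a (possibly multi-session)
#' trial tibble and over the requested model/variant combinations.
#'
#' @inheritParams fit_session
#' @param models,variants Character vectors of models and variants to fit.
#' @return Tibble with one row per session x model x variant: metadata,
#'   estimates (`alpha` for basic fits, `alpha_post`/`alpha_other` for
#'   modified fits, `beta` always), `logLik`, `df`, `n_trials`, `bic`, and
#'   diagnostics.
#' @export
fit_sessions <- function(trials, models = c("exp", "inf"),
                         variants = c("basic", "modified"),
                         n_starts = 10L, bounds = default_bounds(), seed = 1L) {
  sessions <- split(trials, trials$session_id)
  grid <- tidyr::expand_grid(session = names(sessions),
                             model = models, variant = variants)
  purrr::pmap(grid, function(session, model, variant) {
    f <- fit_session(sessions[[session]], model, variant,
                     n_starts = n_starts, bounds = bounds, seed = seed)
    est <- as.list(f$estimates)
    tibble::tibble(
      session_id = f$session_id, subject = f$subject, task = f$task,
      treatment = f$treatment, model = f$model, variant = f$variant,
      alpha = est$alpha %||% NA_real_,
      alpha_post = est$alpha_post %||% NA_real_,
      alpha_other = est$alpha_other %||% NA_real_,
      beta = est$beta,
      logLik = f$logLik, df = f$k, n_trials = f$n_trials,
      bic = bic(f$logLik, f$k, f$n_trials),
      n_converged = f$n_converged, flat = f$flat
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(match(.data$session_id, unique(trials$session_id)),
                   .data$model, .data$variant)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
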