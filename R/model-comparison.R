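#' Bayesian information criterion
#'
#' `BIC = k log(n) - 2 logL`, with `n` the number of completed trials in
#' the session and `k` the number of fitted parameters (2 for the basic
#' model variants, 3 for the modified variants).
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (trials).
#' @return BIC value (vectorized over the inputs).
#' @export
bic <- function(logLik, k, n) {
  stopifnot(all(n >= 1), all(k >= 0))
  k * log(n) - 2 * logLik
}

#' Posterior model probabilities from BIC values
#'
#' Under the BIC approximation to the model evidence,
#' `posterior_m \propto prior_m exp(-BIC_m / 2)`; computed with a max-shift
#' so that arbitrarily large BIC values do not underflow.
#'
#' @param bics Named or unnamed numeric vector of per-model BIC values.
#' @param prior Prior model probabilities (default uniform).
#' @return Numeric vector of posterior probabilities summing to 1.
#' @examples
#' bic_posteriors(c(exp = 100, inf = 102))  # ~ (0.731, 0.269)
#' @export
bic_posteriors <- function(bics, prior = NULL) {
  if (length(bics) < 2L) abort("need BIC values for at least two models")
  if (any(!is.finite(bics))) abort("BIC values must be finite")
  if (is.null(prior)) prior <- rep(1 / length(bics), length(bics))
  stopifnot(length(prior) == length(bics), all(prior >= 0), sum(prior) > 0)
  l <- -bics / 2
  u <- exp(l - max(l)) * prior
  setNames(u / sum(u), names(bics))
}

#' Per-session Bayesian model comparison
#'
#' Compares the EXP and INF accounts of each session via their BIC values,
#' as fitted by [fit_sessions()]. By default the basic (2-parameter)
#' variants are compared per session; `method = "summed"` instead sums BIC
#' over sessions within each `session group x model` and reports one
#' posterior per group.
#'
#' @param fits Fit tibble from [fit_sessions()] containing both models.
#' @param variant Which variant's fits to compare.
#' @param prior Prior probability vector over models (default uniform).
#' @param method `"per_session"` (default) or `"summed"`.
#' @return Tibble in long format: one row per session (or per group) and
#'   model, with columns `bic` and `posterior`.
#' @export
compare_models <- function(fits, variant = "basic", prior = NULL,
                           method = c("per_session", "summed")) {
  method <- match.arg(method)
  f <- dplyr::filter(fits, .data$variant == !!variant)
  if (method == "summed") {
    f <- f |>
      dplyr::group_by(.data$subject, .data$task, .data$treatment, .data$model) |>
      dplyr::summarise(bic = sum(.data$bic), n_sessions = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(session_id = paste(.data$subject, .data$task,
                                       .data$treatment, sep = "/"))
  }
  groups <- split(f, f$session_id)
  purrr::map(groups, function(g) {
    if (length(unique(g$model)) < 2L) {
      abort(sprintf("session %s lacks fits for two models", g$session_id[1]))
    }
    g$posterior <- unname(bic_posteriors(setNames(g$bic, g$model), prior = prior))
    g
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(match(.data$session_id, unique(f$session_id)), .data$model)
}
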