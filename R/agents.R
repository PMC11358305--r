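#' EXP model: softmax choice probability
#'
#' The EXP (experience-based) learner holds a subjective value `V[i]` for
#' each stimulus, in drops-of-juice units, and chooses between the two
#' offered stimuli through a softmax with inverse temperature `beta`:
#' `P(S_i) = exp(beta V_i) / (exp(beta V_i) + exp(beta V_j))`.
#'
#' @param v Numeric vector of 5 subjective values, named by stimulus id
#'   (see [exp_init()]).
#' @param pair Character vector of two distinct stimulus ids; the
#'   probability returned is that of choosing `pair[1]`.
#' @param beta Inverse temperature, `>= 0`. `beta = 0` gives uniform choice.
#' @return Probability in (0, 1) of choosing `pair[1]`.
#' @examples
#' v <- exp_init()
#' v[c("S1", "S2")] <- c(3, 1)
#' exp_choice_prob(v, c("S1", "S2"), beta = 1)  # 1 / (1 + exp(-2))
#' @export
exp_choice_prob <- function(v, pair, beta) {
  check_beta(beta)
  check_pair(pair)
  # logistic of the scaled value difference: overflow-safe for any beta
  stats::plogis(beta * (v[[pair[1]]] - v[[pair[2]]]))
}

#' EXP model: Rescorla-Wagner value update
#'
#' After choosing stimulus `chosen` and receiving `r_obs` drops, only the
#' chosen stimulus's value moves toward the observed reward:
#' `V_i <- V_i - alpha (V_i - r_obs)`.
#'
#' @param v Named value vector as in [exp_choice_prob()].
#' @param chosen Stimulus id that was chosen.
#' @param r_obs Observed reward (drops).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value vector.
#' @export
exp_update <- function(v, chosen, r_obs, alpha) {
  check_alpha(alpha)
  v[[chosen]] <- v[[chosen]] - alpha * (v[[chosen]] - r_obs)
  v
}

#' Initial EXP state
#'
#' All subjective values start at zero at the beginning of a session.
#'
#' @return Named numeric vector of five zeros.
#' @export
exp_init <- function() setNames(numeric(5L), stimuli())

#' Fixed value tables of the INF model
#'
#' The INF (inference-based) learner knows the association takes one of two
#' patterns: under pattern A stimulus `Si` is worth `i` drops
#' (`V_A[i] = i`), under pattern B it is worth `6 - i` (`V_B[i] = 6 - i`).
#'
#' @return List with named numeric vectors `A` and `B` (`A + B = 6`
#'   elementwise).
#' @export
inf_values <- function() {
  list(A = setNames(as.numeric(1:5), stimuli()),
       B = setNames(as.numeric(6 - 1:5), stimuli()))
}

#' INF model: mixture-of-softmax choice probability
#'
#' The learner's confidence that pattern A is in force is a weight
#' `w` in \[0, 1\]; choice follows the `w`-mixture of the two softmax
#' distributions induced by the fixed tables `V_A` and `V_B`.
#'
#' @param w Confidence weight in \[0, 1\] that pattern A is in force.
#' @param pair Character vector of two distinct stimulus ids; the
#'   probability returned is that of choosing `pair[1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability in (0, 1) of choosing `pair[1]`.
#' @examples
#' inf_choice_prob(w = 0.7, c("S1", "S3"), beta = 1)
#' @export
inf_choice_prob <- function(w, pair, beta) {
  check_beta(beta)
  check_pair(pair)
  if (!is.finite(w) || w < 0 || w > 1) {
    abort("confidence weight `w` must lie in [0, 1]")
  }
  # V_B = 6 - V_A, so the two softmax terms reflect each other and the
  # balanced mixture is exactly 1/2 for every pair
  if (w == 0.5) return(0.5)
  vals <- inf_values()
  p_a <- stats::plogis(beta * (vals$A[[pair[1]]] - vals$A[[pair[2]]]))
  p_b <- stats::plogis(beta * (vals$B[[pair[1]]] - vals$B[[pair[2]]]))
  w * p_a + (1 - w) * p_b
}

#' INF model: confidence-weight update
#'
#' Gradient step on the squared error between the mixture-expected reward of
#' the chosen stimulus and the observed reward:
#' `w <- w - alpha * ((w V_A[i] + (1-w) V_B[i]) - r_obs) * (V_A[i] - V_B[i])`,
#' clipped to \[0, 1\].
#'
#' @param w Current confidence weight.
#' @param chosen Stimulus id that was chosen.
#' @param r_obs Observed reward (drops).
#' @param alpha Learning rate, `>= 0`.
#' @return Updated weight in \[0, 1\].
#' @examples
#' inf_update(w = 0.5, chosen = "S1", r_obs = 5, alpha = 0.05)  # 0.1
#' @export
inf_update <- function(w, chosen, r_obs, alpha) {
  if (!is.finite(alpha) || alpha < 0) abort("`alpha` must be >= 0")
  vals <- inf_values()
  va <- vals$A[[chosen]]
  vb <- vals$B[[chosen]]
  w_new <- w - alpha * ((w * va + (1 - w) * vb) - r_obs) * (va - vb)
  min(1, max(0, w_new))
}

check_beta <- function(beta) {
  if (!is.finite(beta) || beta < 0) abort("inverse temperature `beta` must be >= 0")
  invisible(beta)
}

check_alpha <- function(alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    abort("learning rate `alpha` must lie in [0, 1]")
  }
  invisible(alpha)
}

check_pair <- function(pair) {
  if (length(pair) != 2L || pair[1] == pair[2]) {
    abort("`pair` must be two distinct stimulus ids")
  }
  stim_index(pair)
  invisible(pair)
}
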