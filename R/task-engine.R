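#' Round-robin pair schedule
#'
#' Stimulus pairs are scheduled so that each of the `choose(5, 2) = 10`
#' unordered pairs appears exactly once in every consecutive 10-trial block,
#' in an independently shuffled order per block, with the left/right screen
#' position randomized per trial. Draws from the current RNG state; wrap in
#' [withr::with_seed()] for a reproducible schedule.
#'
#' @param n_blocks Number of 10-trial blocks.
#' @return Tibble with columns `trial`, `stim_left`, `stim_right`
#'   (`10 * n_blocks` rows).
#' @export
round_robin_pairs <- function(n_blocks = 1L) {
  stopifnot(n_blocks >= 1L)
  pairs <- utils::combn(stimuli(), 2L)  # 2 x 10, lexicographic
  blocks <- purrr::map(seq_len(n_blocks), function(b) {
    ord <- sample.int(10L)
    flip <- sample(c(TRUE, FALSE), 10L, replace = TRUE)
    a <- pairs[1L, ord]
    z <- pairs[2L, ord]
    tibble::tibble(stim_left = ifelse(flip, z, a),
                   stim_right = ifelse(flip, a, z))
  })
  dplyr::bind_rows(blocks) |>
    dplyr::mutate(trial = dplyr::row_number(), .before = 1L)
}

#' Simulate a NOVEL-task session
#'
#' A NOVEL session has `n_acquisition` trials (default 90) under reward
#' pattern A, a single forced reversal, and `n_post` trials (default 210)
#' under pattern B. A generative EXP or INF agent chooses on every trial and
#' updates its state with the delivered reward. On post-reversal trials the
#' agent updates with `alpha_post` (defaults to `alpha`), which is how a
#' silencing manipulation is represented in synthetic cohorts.
#'
#' @param model `"exp"` or `"inf"`.
#' @param alpha Learning rate on non-post-reversal trials.
#' @param beta Inverse temperature.
#' @param alpha_post Learning rate on post-reversal trials; default `alpha`.
#' @param n_acquisition,n_post Phase lengths in trials; both must be
#'   multiples of 10 (the round-robin block length).
#' @param session_id,subject,treatment Metadata carried into the output.
#' @param seed Integer seed governing the schedule and the agent's choices.
#' @param keep_state If `TRUE`, record the agent's pre-choice latent state
#'   per trial (columns `V_S1..V_S5` for EXP, `w` for INF).
#' @return Trial tibble (one row per trial) with columns `session_id`,
#'   `subject`, `task`, `treatment`, `trial`, `stim_left`, `stim_right`,
#'   `reward_left`, `reward_right`, `choice`, `reward_obtained`, `pattern`,
#'   `post_reversal`, `reversal_boundary`.
#' @examples
#' s <- sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 1)
#' table(s$pattern)
#' @export
sim_novel_session <- function(model = c("exp", "inf"), alpha, beta,
                              alpha_post = alpha,
                              n_acquisition = 90L, n_post = 210L,
                              session_id = "novel-1", subject = "Mk1",
                              treatment = "vehicle", seed = 1L,
                              keep_state = FALSE) {
  model <- match.arg(model)
  stopifnot(n_acquisition %% 10L == 0L, n_post %% 10L == 0L,
            n_acquisition >= 10L, n_post >= 10L)
  n_trials <- n_acquisition + n_post
  withr::with_seed(seed, {
    schedule <- round_robin_pairs(n_trials / 10L)
    run_session_loop(
      schedule = schedule, model = model, alpha = alpha, beta = beta,
      alpha_post = alpha_post, task = "NOVEL",
      first_pattern = "A", forced_reversal_at = n_acquisition + 1L,
      session_id = session_id, subject = subject, treatment = treatment,
      keep_state = keep_state
    )
  })
}

#' Simulate a FAMILIAR-task session
#'
#' A FAMILIAR session uses a fixed stimulus set whose reward map alternates
#' between the two known patterns. Whenever the optimal-choice rate over the
#' trailing `criterion_window` completed trials strictly exceeds
#' `criterion_rate` (with the defaults: at least 23 of 30 optimal), the map
#' is reversed before the next trial. The trailing window never spans a
#' reversal, so consecutive reversals are at least `criterion_window` trials
#' apart. The post-reversal period is the 5 trials after each reversal;
#' those trials use `alpha_post`.
#'
#' @inheritParams sim_novel_session
#' @param n_trials Session length; a multiple of 10 (300 or 400 in the
#'   study design).
#' @param criterion_window,criterion_rate Trailing-window reversal
#'   criterion: reverse when `> criterion_rate` of the last
#'   `criterion_window` trials were optimal.
#' @param first_pattern `"A"`, `"B"`, or `NULL` for a coin flip.
#' @return Trial tibble as in [sim_novel_session()].
#' @export
sim_familiar_session <- function(model = c("exp", "inf"), alpha, beta,
                                 alpha_post = alpha, n_trials = 300L,
                                 criterion_window = 30L, criterion_rate = 0.76,
                                 first_pattern = NULL,
                                 session_id = "familiar-1", subject = "Mk1",
                                 treatment = "vehicle", seed = 1L,
                                 keep_state = FALSE) {
  model <- match.arg(model)
  stopifnot(n_trials %% 10L == 0L, n_trials >= criterion_window,
            criterion_window >= 1L, criterion_rate > 0, criterion_rate < 1)
  withr::with_seed(seed, {
    if (is.null(first_pattern)) {
      first_pattern <- sample(c("A", "B"), 1L)
    }
    schedule <- round_robin_pairs(n_trials / 10L)
    run_session_loop(
      schedule = schedule, model = model, alpha = alpha, beta = beta,
      alpha_post = alpha_post, task = "FAMILIAR",
      first_pattern = first_pattern, forced_reversal_at = NA_integer_,
      criterion_window = criterion_window, criterion_rate = criterion_rate,
      session_id = session_id, subject = subject, treatment = treatment,
      keep_state = keep_state
    )
  })
}

# Closed-loop trial loop shared by both tasks. Draws from the current RNG.
# forced_reversal_at = NA means criterion-triggered reversals (FAMILIAR);
# otherwise a single forced reversal before that trial (NOVEL).
run_session_loop <- function(schedule, model, alpha, beta, alpha_post, task,
                             first_pattern, forced_reversal_at,
                             criterion_window = NULL, criterion_rate = NULL,
                             session_id, subject, treatment, keep_state) {
  n <- nrow(schedule)
  map <- reward_map(first_pattern)
  crit_thresh <- if (!is.null(criterion_window)) {
    floor(criterion_rate * criterion_window) + 1L  # smallest count strictly past the rate
  }
  v <- exp_init()
  w <- 0.5
  post_left <- 0L      # FAMILIAR: trials remaining in the post-reversal period
  since_rev <- 0L      # completed trials since the last reversal
  opt_hist <- integer(n)

  choice <- character(n)
  reward_obtained <- integer(n)
  reward_left <- integer(n)
  reward_right <- integer(n)
  pattern <- character(n)
  post_reversal <- logical(n)
  reversal_boundary <- logical(n)
  if (keep_state) {
    state_v <- matrix(NA_real_, n, 5L, dimnames = list(NULL, paste0("V_", stimuli())))
    state_w <- rep(NA_real_, n)
  }

  for (t in seq_len(n)) {
    boundary <- FALSE
    if (!is.na(forced_reversal_at)) {
      if (t == forced_reversal_at) boundary <- TRUE
    } else if (t > 1L && since_rev >= criterion_window &&
               sum(opt_hist[(t - criterion_window):(t - 1L)]) >= crit_thresh) {
      boundary <- TRUE
    }
    if (boundary) {
      map <- reverse_map(map)
      since_rev <- 0L
      post_left <- 5L
    }
    is_post <- if (!is.na(forced_reversal_at)) t >= forced_reversal_at else post_left > 0L

    pair <- c(schedule$stim_left[t], schedule$stim_right[t])
    if (keep_state) {
      state_v[t, ] <- v
      state_w[t] <- w
    }
    p_left <- if (model == "exp") {
      stats::plogis(beta * (v[[pair[1]]] - v[[pair[2]]]))
    } else {
      inf_choice_prob(w, pair, beta)
    }
    chosen <- if (stats::runif(1) < p_left) pair[1] else pair[2]
    r_obs <- map[[chosen]]
    a_t <- if (is_post) alpha_post else alpha
    if (model == "exp") {
      v[[chosen]] <- v[[chosen]] - a_t * (v[[chosen]] - r_obs)
    } else {
      w <- inf_update(w, chosen, r_obs, a_t)
    }

    choice[t] <- chosen
    reward_obtained[t] <- r_obs
    reward_left[t] <- map[[pair[1]]]
    reward_right[t] <- map[[pair[2]]]
    pattern[t] <- attr(map, "pattern")
    post_reversal[t] <- is_post
    reversal_boundary[t] <- boundary
    opt_hist[t] <- as.integer(r_obs == max(reward_left[t], reward_right[t]))
    since_rev <- since_rev + 1L
    if (post_left > 0L) post_left <- post_left - 1L
  }

  out <- tibble::tibble(
    session_id = session_id, subject = subject, task = task,
    treatment = treatment, trial = seq_len(n),
    stim_left = schedule$stim_left, stim_right = schedule$stim_right,
    reward_left = reward_left, reward_right = reward_right,
    choice = choice, reward_obtained = reward_obtained,
    pattern = pattern, post_reversal = post_reversal,
    reversal_boundary = reversal_boundary
  )
  if (keep_state) {
    if (model == "exp") {
      out <- dplyr::bind_cols(out, tibble::as_tibble(state_v))
    } else {
      out$w <- state_w
    }
  }
  out
}
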