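# Step-by-step likelihood oracle, written independently of the package's
# likelihood code: plain loops, textbook softmax, no shared helpers. Used to
# cross-check negloglik() trial by trial.
oracle_nll <- function(trials, model, variant, pars) {
  n <- nrow(trials)
  drop_id <- function(s) as.integer(sub("S", "", s))
  # post-reversal mask re-derived from the reversal markers
  bounds <- trials$trial[trials$reversal_boundary]
  post <- rep(FALSE, n)
  if (length(bounds) > 0) {
    if (trials$task[1] == "NOVEL") {
      post <- trials$trial >= min(bounds)
    } else {
      for (b in bounds) post <- post | (trials$trial >= b & trials$trial <= b + 4)
    }
  }
  v <- rep(0, 5)
  w <- 0.5
  va <- 1:5
  vb <- 6 - (1:5)
  nll <- 0
  for (t in seq_len(n)) {
    i <- drop_id(trials$choice[t])
    l <- drop_id(trials$stim_left[t])
    r <- drop_id(trials$stim_right[t])
    j <- if (i == l) r else l
    if (model == "exp") {
      p <- exp(pars[["beta"]] * v[i]) /
        (exp(pars[["beta"]] * v[i]) + exp(pars[["beta"]] * v[j]))
    } else {
      pa <- exp(pars[["beta"]] * va[i]) /
        (exp(pars[["beta"]] * va[i]) + exp(pars[["beta"]] * va[j]))
      pb <- exp(pars[["beta"]] * vb[i]) /
        (exp(pars[["beta"]] * vb[i]) + exp(pars[["beta"]] * vb[j]))
      p <- w * pa + (1 - w) * pb
    }
    nll <- nll - log(p)
    a <- if (variant == "modified") {
      if (post[t]) pars[["alpha_post"]] else pars[["alpha_other"]]
    } else {
      pars[["alpha"]]
    }
    r_obs <- trials$reward_obtained[t]
    if (model == "exp") {
      v[i] <- v[i] - a * (v[i] - r_obs)
    } else {
      w <- w - a * ((w * va[i] + (1 - w) * vb[i]) - r_obs) * (va[i] - vb[i])
      w <- min(1, max(0, w))
    }
  }
  nll
}

# Build a scripted session from explicit pair and choice sequences.
# pairs: list of c(left, right); choices: character vector; boundary_at:
# trial numbers at which the reward pattern flips.
make_session <- function(pairs, choices, task = "NOVEL", boundary_at = integer(),
                         first_pattern = "A", session_id = "fix-1",
                         subject = "MkX", treatment = "vehicle") {
  n <- length(choices)
  stopifnot(length(pairs) == n)
  boundary <- seq_len(n) %in% boundary_at
  flip <- cumsum(boundary) %% 2 == 1
  pattern <- ifelse(xor(first_pattern == "B", flip), "B", "A")
  post <- rep(FALSE, n)
  if (length(boundary_at) > 0) {
    if (task == "NOVEL") {
      post <- seq_len(n) >= min(boundary_at)
    } else {
      for (b in boundary_at) post <- post | (seq_len(n) >= b & seq_len(n) <= b + 4)
    }
  }
  left <- vapply(pairs, `[`, "", 1)
  right <- vapply(pairs, `[`, "", 2)
  maps <- list(A = revalr::reward_map("A"), B = revalr::reward_map("B"))
  rl <- mapply(function(s, p) maps[[p]][[s]], left, pattern)
  rr <- mapply(function(s, p) maps[[p]][[s]], right, pattern)
  ro <- ifelse(choices == left, rl, rr)
  tibble::tibble(
    session_id = session_id, subject = subject, task = task,
    treatment = treatment, trial = seq_len(n),
    stim_left = left, stim_right = right,
    reward_left = as.integer(rl), reward_right = as.integer(rr),
    choice = choices, reward_obtained = as.integer(ro),
    pattern = pattern, post_reversal = post, reversal_boundary = boundary
  )
}

# Short random-but-valid session for likelihood cross-checks: random pairs,
# random choices, reversal halfway, rewards from the in-force map.
random_fixture <- function(n = 20, seed = 1, task = "NOVEL") {
  withr::with_seed(seed, {
    pairs <- replicate(n, sample(revalr::stimuli(), 2), simplify = FALSE)
    choices <- vapply(pairs, function(p) sample(p, 1), "")
    make_session(pairs, choices, task = task, boundary_at = n %/% 2 + 1,
                 session_id = paste0("rand-", seed))
  })
}

# Brute-force re-derivation of criterion-triggered reversal positions from an
# optimal-choice indicator sequence: scan trial by trial, fire when the 30
# trials since the last reversal contain >= 23 optimal choices.
oracle_reversals <- function(opt) {
  fired <- integer(0)
  last_rev <- 0L
  for (t in seq_along(opt)) {
    if (t - last_rev > 30L && sum(opt[(t - 30L):(t - 1L)]) >= 23L) {
      fired <- c(fired, t)
      last_rev <- t - 1L
    }
  }
  fired
}
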