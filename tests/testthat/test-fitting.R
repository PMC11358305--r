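test_that("the post-reversal mask covers the right trials in each task", {
  nov <- sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 1)
  expect_identical(sum(post_reversal_mask(nov)), 210L)
  expect_identical(post_reversal_mask(nov), nov$trial >= 91L)

  fam <- sim_familiar_session("inf", alpha = 0.05, beta = 1.5, seed = 2)
  m <- post_reversal_mask(fam)
  b <- fam$trial[fam$reversal_boundary]
  expect_identical(sum(m), length(b) * 5L)  # no reversal within 5 of session end here
  expect_true(all(fam$trial[m] %in% as.vector(outer(b, 0:4, `+`))))

  none <- sim_familiar_session("exp", alpha = 0, beta = 5, seed = 42)
  expect_false(any(post_reversal_mask(none)))
})

test_that("negloglik agrees with a step-by-step oracle on random fixtures", {
  withr::with_seed(51, {
    for (i in 1:10) {
      s <- random_fixture(n = 20, seed = 100 + i,
                          task = sample(c("NOVEL", "FAMILIAR"), 1))
      pars_b <- c(alpha = runif(1), beta = runif(1, 0, 4))
      pars_m <- c(alpha_post = runif(1), alpha_other = runif(1),
                  beta = runif(1, 0, 4))
      for (model in c("exp", "inf")) {
        expect_equal(negloglik(s, model, "basic", pars_b),
                     oracle_nll(s, model, "basic", pars_b), tolerance = 1e-12)
        expect_equal(negloglik(s, model, "modified", pars_m),
                     oracle_nll(s, model, "modified", pars_m), tolerance = 1e-12)
      }
    }
  })
})

test_that("beta = 0 gives the uniform-choice likelihood exactly", {
  s <- random_fixture(n = 20, seed = 52)
  expect_equal(negloglik(s, "exp", "basic", c(alpha = 0.3, beta = 0)),
               20 * log(2), tolerance = 1e-14)
})

test_that("the modified variant nests the basic one", {
  s <- sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 53)
  pars <- c(alpha_post = 0.22, alpha_other = 0.22, beta = 1.1)
  expect_equal(negloglik(s, "exp", "modified", pars),
               negloglik(s, "exp", "basic", c(alpha = 0.22, beta = 1.1)))
  # and its optimum can only improve on the basic optimum
  fb <- fit_session(s, "exp", "basic", seed = 2)
  fm <- fit_session(s, "exp", "modified", seed = 2)
  expect_lte(-fm$logLik, -fb$logLik + 1e-6)
})

test_that("negloglik is invariant to relabeling the stimulus ids", {
  s <- sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 54)
  perm <- setNames(c("S3", "S5", "S1", "S2", "S4"), stimuli())
  # relabeling breaks the id->drops convention, so bypass full validation and
  # compare likelihoods directly (rewards travel with the trials)
  s2 <- s |>
    dplyr::mutate(stim_left = unname(perm[stim_left]),
                  stim_right = unname(perm[stim_right]),
                  choice = unname(perm[choice]))
  pars <- c(alpha = 0.2, beta = 1.4)
  expect_equal(negloglik(s2, "exp", "basic", pars),
               negloglik(s, "exp", "basic", pars), tolerance = 1e-12)
})

test_that("the MLE beats the generating parameters and recovers them in aggregate", {
  fits <- purrr::map(1:6, function(i) {
    s <- sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 60 + i)
    f <- fit_session(s, "exp", "basic", seed = 1)
    expect_lte(-f$logLik,
               negloglik(s, "exp", "basic", c(alpha = 0.15, beta = 1.5)) + 1e-8)
    f$estimates
  })
  est <- do.call(rbind, fits)
  expect_lt(median(abs(est[, "alpha"] - 0.15)), 0.05)
  expect_lt(median(abs(est[, "beta"] - 1.5)) / 1.5, 0.3)
})

test_that("fit_sessions tabulates fits per session x model x variant", {
  trials <- dplyr::bind_rows(
    sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 71, session_id = "a"),
    sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 72, session_id = "b")
  )
  tab <- fit_sessions(trials, models = "exp", variants = c("basic", "modified"),
                      seed = 1)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$df, ifelse(tab$variant == "basic", 2L, 3L))
  expect_true(all(is.na(tab$alpha_post[tab$variant == "basic"])))
  expect_true(all(is.na(tab$alpha[tab$variant == "modified"])))
  expect_equal(tab$bic, tab$df * log(tab$n_trials) - 2 * tab$logLik)
})

test_that("tidy and glance expose estimates and fit summaries", {
  s <- sim_novel_session("exp", alpha = 0.15, beta = 1.5, seed = 73)
  f <- fit_session(s, "exp", "modified", seed = 1)
  td <- tidy(f)
  expect_identical(td$term, c("alpha_post", "alpha_other", "beta"))
  gl <- glance(f)
  expect_identical(gl$nobs, 300L)
  expect_equal(gl$BIC, 3 * log(300) - 2 * gl$logLik)
})

test_that("degenerate sessions are flagged or refused", {
  s <- sim_familiar_session("exp", alpha = 0, beta = 5, seed = 42)  # no reversal
  expect_error(fit_session(s, "exp", "modified"), "post-reversal")
  # a coin-flipping session can drive beta onto the zero bound, where the
  # learning rate is unidentifiable and the fit is flagged
  flat <- random_fixture(n = 60, seed = 76)
  f <- fit_session(flat, "exp", "basic", seed = 1)
  expect_identical(f$estimates[["beta"]], 0)
  expect_true(f$flat)
})
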