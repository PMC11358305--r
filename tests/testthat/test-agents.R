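test_that("EXP softmax matches hand-computed values and limits", {
  v <- exp_init()
  v[c("S1", "S2")] <- c(3, 1)
  expect_equal(exp_choice_prob(v, c("S1", "S2"), beta = 1), 1 / (1 + exp(-2)))
  expect_equal(exp_choice_prob(v, c("S2", "S1"), beta = 1), 1 / (1 + exp(2)))
  # uniform limit and equal-value symmetry are exactly 1/2
  expect_identical(exp_choice_prob(v, c("S1", "S2"), beta = 0), 0.5)
  v2 <- exp_init(); v2[c("S3", "S4")] <- c(2.2, 2.2)
  expect_identical(exp_choice_prob(v2, c("S3", "S4"), beta = 7), 0.5)
  expect_error(exp_choice_prob(v, c("S1", "S2"), beta = -1), "beta")
  expect_error(exp_choice_prob(v, c("S1", "S1"), beta = 1), "distinct")
})

test_that("EXP choice probabilities are complementary and stable at extreme beta", {
  withr::with_seed(11, {
    for (i in 1:25) {
      v <- setNames(runif(5, -2, 8), stimuli())
      pair <- sample(stimuli(), 2)
      beta <- runif(1, 0, 3)
      p <- exp_choice_prob(v, pair, beta)
      q <- exp_choice_prob(v, rev(pair), beta)
      expect_true(p > 0 && p < 1)
      expect_equal(p + q, 1)
      # extreme beta saturates in floating point but never overflows
      p_hot <- exp_choice_prob(v, pair, beta * 1000)
      expect_true(is.finite(p_hot) && p_hot >= 0 && p_hot <= 1)
    }
  })
})

test_that("Rescorla-Wagner update moves only the chosen value, contracting toward the reward", {
  v <- exp_init()
  expect_equal(exp_update(v, "S2", 5, alpha = 0.1)[["S2"]], 0.5)
  expect_identical(exp_update(v, "S2", 5, alpha = 0), v)
  v[["S4"]] <- 3
  expect_identical(exp_update(v, "S4", 3, alpha = 0.7), v)  # zero prediction error
  withr::with_seed(12, {
    for (i in 1:20) {
      v <- setNames(runif(5, 0, 5), stimuli())
      a <- runif(1)
      s <- sample(stimuli(), 1)
      r <- sample(1:5, 1)
      v2 <- exp_update(v, s, r, a)
      expect_equal(abs(v2[[s]] - r), (1 - a) * abs(v[[s]] - r))
      expect_identical(v2[setdiff(stimuli(), s)], v[setdiff(stimuli(), s)])
    }
  })
})

test_that("INF mixture probability matches hand evaluation and degenerate cases", {
  # w = 0.7, beta = 1, pair (S1, S3): 0.7 plogis(-2) + 0.3 plogis(2)
  expect_equal(inf_choice_prob(0.7, c("S1", "S3"), beta = 1),
               0.7 / (1 + exp(2)) + 0.3 / (1 + exp(-2)))
  # (S1, S5) at w = 0.5 is exactly 1/2 by A/B symmetry
  expect_identical(inf_choice_prob(0.5, c("S1", "S5"), beta = 3.7), 0.5)
  # w = 1 degenerates to the EXP softmax on the pattern-A table
  va <- inf_values()$A
  withr::with_seed(13, {
    for (i in 1:20) {
      pair <- sample(stimuli(), 2)
      beta <- runif(1, 0, 5)
      expect_equal(inf_choice_prob(1, pair, beta),
                   exp_choice_prob(va, pair, beta))
    }
  })
  expect_error(inf_choice_prob(1.2, c("S1", "S2"), beta = 1), "\\[0, 1\\]")
})

test_that("INF weight update follows the gradient rule and clips to [0, 1]", {
  # w = 0.5, alpha = 0.05, chosen S1, r = 5: expected 3, step -0.05*(-2)*(-4)
  expect_equal(inf_update(0.5, "S1", 5, alpha = 0.05), 0.1)
  # S3 is worth 3 under both patterns: zero gradient factor
  expect_identical(inf_update(0.31, "S3", 5, alpha = 0.9), 0.31)
  # overshooting updates land exactly on the bounds
  expect_identical(inf_update(0.5, "S1", 5, alpha = 0.2), 0)
  expect_identical(inf_update(0.5, "S5", 5, alpha = 0.2), 1)
  withr::with_seed(14, {
    w <- 0.5
    for (i in 1:200) {
      w <- inf_update(w, sample(stimuli(), 1), sample(1:5, 1), runif(1, 0, 0.4))
      expect_true(w >= 0 && w <= 1)
    }
  })
})
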