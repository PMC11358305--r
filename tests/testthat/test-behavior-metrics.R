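test_that("optimality is judged against the map in force", {
  s <- make_session(list(c("S3", "S5"), c("S3", "S5"), c("S3", "S5")),
                    c("S5", "S3", "S3"), boundary_at = 3)
  # pattern A: S5 = 5 > S3 = 3; after reversal S3 = 3 > S5 = 1
  expect_identical(optimal_choice_indicator(s), c(1L, 0L, 1L))
})

test_that("block rates average the indicator per 10-trial block", {
  s <- experience_fixture()
  br <- block_optimal_rate(s)
  expect_identical(nrow(br), 12L)
  opt <- optimal_choice_indicator(s)
  expect_equal(br$rate, colMeans(matrix(opt, nrow = 10)))
  # trailing partial blocks are dropped
  expect_identical(nrow(block_optimal_rate(s[1:95, ])), 9L)
})

test_that("NOVEL phase windows are Pre 1-90, PoE 91-190, PoL 191-300", {
  s <- sim_novel_session("exp", alpha = 0.2, beta = 2, seed = 101)
  pr <- phase_rates(s)
  opt <- optimal_choice_indicator(s)
  expect_equal(pr$rate, c(mean(opt[1:90]), mean(opt[91:190]), mean(opt[191:300])))
  expect_identical(as.character(pr$phase), c("Pre", "PoE", "PoL"))
})

test_that("FAMILIAR phase rates average per-reversal windows, not pooled trials", {
  # two reversals with hand-computable windows
  pairs <- replicate(80, c("S1", "S2"), simplify = FALSE)
  choices <- rep("S1", 80)
  s <- make_session(pairs, choices, task = "FAMILIAR", boundary_at = c(31, 66),
                    session_id = "fam-fix")
  opt <- optimal_choice_indicator(s)
  pr <- phase_rates(s)
  expected <- c(
    Pre = mean(c(mean(opt[21:30]), mean(opt[56:65]))),
    PoE = mean(c(mean(opt[31:35]), mean(opt[66:70]))),
    PoL = mean(c(mean(opt[36:40]), mean(opt[71:75])))
  )
  expect_equal(pr$rate, unname(expected))
  expect_error(phase_rates(make_session(pairs[1:10], choices[1:10],
                                        task = "FAMILIAR")), "no reversal")
})

test_that("worked experience-event chains are extracted exactly", {
  s <- experience_fixture()
  pos <- experience_events(s, "positive")
  expect_identical(pos$option, c("S1", "S2"))
  expect_identical(pos$nonchoice_trial, c(93L, 104L))
  expect_identical(pos$event_trial, c(96L, 105L))
  expect_identical(pos$eval_trial, c(99L, 108L))
  expect_identical(pos$eval_optimal, c(1L, 1L))

  neg <- experience_events(s, "negative")
  expect_identical(neg$option, "S5")
  expect_identical(neg$nonchoice_trial, 101L)
  expect_identical(neg$event_trial, 104L)
  expect_identical(neg$eval_trial, 107L)
  expect_identical(neg$eval_optimal, 1L)
})

test_that("an always-optimal chooser generates no experience events", {
  pairs <- withr::with_seed(102, replicate(200, sample(stimuli(), 2),
                                           simplify = FALSE))
  maps <- list(A = reward_map("A"), B = reward_map("B"))
  pattern <- rep(c("A", "B"), each = 100)
  choices <- mapply(function(p, pat) p[which.max(maps[[pat]][p])],
                    pairs, pattern)
  s <- make_session(pairs, choices, task = "NOVEL", boundary_at = 101,
                    session_id = "opt-1")
  expect_identical(nrow(experience_events(s, "positive")), 0L)
  expect_identical(nrow(experience_events(s, "negative")), 0L)
})

test_that("inference trials are the first pair-disjoint trials after each reversal", {
  pairs <- list(
    c("S1", "S2"), c("S1", "S3"), c("S2", "S3"), c("S1", "S2"), c("S4", "S5"),
    c("S1", "S2"), c("S1", "S3"), c("S2", "S3"), c("S1", "S2"), c("S4", "S5"),
    c("S2", "S4"),                 # 11: boundary, 1st trial offers {S2, S4}
    c("S2", "S5"),                 # 12: shares S2 -> excluded
    c("S4", "S1"),                 # 13: shares S4 -> excluded
    c("S3", "S5"),                 # 14: disjoint -> inference trial
    c("S1", "S5"),                 # 15: later disjoint trials are ignored
    c("S1", "S2"), c("S2", "S3"), c("S1", "S3"), c("S2", "S3"), c("S1", "S2"),
    c("S3", "S4"),                 # 21: second boundary, {S3, S4}
    c("S3", "S5"), c("S4", "S2"), c("S3", "S1"), c("S4", "S5")  # all overlap
  )
  choices <- vapply(pairs, `[`, "", 1)
  s <- make_session(pairs, choices, task = "FAMILIAR", boundary_at = c(11, 21),
                    session_id = "inf-fix")
  it <- inference_trials(s)
  expect_identical(nrow(it), 1L)  # second reversal has no disjoint trial
  expect_identical(it$first_trial, 11L)
  expect_identical(it$inference_trial, 14L)
  expect_identical(it$first_optimal,
                   optimal_choice_indicator(s)[11])
  expect_identical(it$inference_optimal,
                   optimal_choice_indicator(s)[14])
})

test_that("proportion shifted matches the closed form", {
  expect_identical(proportion_shifted(12, 12, 9, 9), 0)
  expect_identical(proportion_shifted(20, 0, 15, 0), 1)
  expect_identical(proportion_shifted(20, 10, 20, 5), 0.625)
  expect_error(proportion_shifted(0, 0, 0, 0), "positive")
  expect_error(proportion_shifted(-1, 0, 2, 0), "nonnegative")
})

test_that("an inference agent outperforms chance on inference trials relative to 1st trials", {
  trials <- dplyr::bind_rows(purrr::map(1:6, function(i) {
    sim_familiar_session("inf", alpha = 0.05, beta = 1.5, seed = 300 + i,
                         session_id = paste0("inf-", i))
  }))
  it <- inference_trials(trials)
  expect_gt(mean(it$inference_optimal), mean(it$first_optimal))
})
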