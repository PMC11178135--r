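test_that("compiled and reference engines are bit-identical", {
  cases <- list(
    list(p = agent_params(0.7, 0.3, 0.6), eps = 0),
    list(p = agent_params(0.1, 0.9, 0.1), eps = 0),
    list(p = agent_params(0.9, 0.1, 0.9, decision_rule = "softmax",
                          temperature = 0.3), eps = 0),
    list(p = agent_params(0.5, 0.5, 0.5), eps = 0.2),
    list(p = agent_params(0.8, 0.4, 0.4, decay_unchosen = TRUE), eps = 0)
  )
  for (cs in cases) {
    for (seed in c(1, 99, 12345)) {
      a <- run_agent(cs$p, std_task, seed = seed, epsilon = cs$eps,
                     engine = "cpp")
      b <- run_agent(cs$p, std_task, seed = seed, epsilon = cs$eps,
                     engine = "r")
      expect_identical(a$trials, b$trials)
      expect_identical(a$block_preferences, b$block_preferences)
    }
  }
})

test_that("simulation is deterministic given a seed and logs are consistent", {
  p <- agent_params(0.6, 0.4, 0.7)
  a <- run_agent(p, std_task, seed = 11)
  b <- run_agent(p, std_task, seed = 11)
  expect_identical(a$trials, b$trials)
  # accumulated money equals the running sum of (gain - loss)
  expect_equal(sum(a$trials$gain - a$trials$loss),
               sum(a$trials$gain) - sum(a$trials$loss))
  # probabilities logged on each trial form a simplex
  pr <- as.matrix(a$trials[, c("pA", "pB", "pC", "pD")])
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  # overall preference is the mean of block preferences
  expect_equal(a$overall_preference, mean(a$block_preferences))
})

test_that("a full-memory agent never learns and starts uniform", {
  sim <- run_agent(agent_params(1, 0.5, 0.5), std_task, seed = 21)
  expect_equal(unname(sim$initial_values), rep(0.25, 4))
  vals <- as.matrix(sim$trials[, c("vA", "vB", "vC", "vD")])
  expect_true(all(vals == 0.25))
  expect_equal(unlist(sim$trials[1, c("pA", "pB", "pC", "pD")]),
               c(pA = 0.25, pB = 0.25, pC = 0.25, pD = 0.25))
})

test_that("memoryless agent on a single deck tracks the per-trial net gain", {
  # deck C alone, normalizer 100: Gn is 0.45 on unpunished cards and
  # 0.45 - 0.05 = 0.40 on punished ones; with M = 0 the deck's value after
  # each trial equals that trial's Gn exactly (hand-derived).
  sim <- run_agent(agent_params(0, 0.9, 0.1), deck_c_task(20), seed = 31)
  v <- sim$trials$vC
  expect_true(all(v %in% c(0.45, 0.40)))
  expect_equal(v, ifelse(sim$trials$loss > 0, 0.40, 0.45))
  expect_equal(sim$trials$net_gain, v)
})

test_that("optional decay shrinks unchosen values toward zero", {
  # default: an unchosen deck's value never moves off 0.25; with decay it
  # contracts by M per trial regardless of choice
  p0 <- agent_params(0.5, 0.5, 0.5)
  pd <- agent_params(0.5, 0.5, 0.5, decay_unchosen = TRUE)
  s0 <- run_agent(p0, std_task, seed = 61)
  sd_ <- run_agent(pd, std_task, seed = 61)
  vals0 <- as.matrix(s0$trials[, c("vA", "vB", "vC", "vD")])
  # under the default, any deck not yet chosen still sits at 0.25
  unchosen_first <- setdiff(c("A", "B", "C", "D"), s0$trials$deck[1])
  expect_true(all(vals0[1, paste0("v", unchosen_first)] == 0.25))
  # with decay, after trial 1 the unchosen decks sit at M * 0.25
  valsd <- as.matrix(sd_$trials[, c("vA", "vB", "vC", "vD")])
  unchosen_d <- setdiff(c("A", "B", "C", "D"), sd_$trials$deck[1])
  expect_true(all(valsd[1, paste0("v", unchosen_d)] == 0.5 * 0.25))
})

test_that("relative preference counts advantageous choices per block", {
  expect_equal(relative_preference(rep("A", 20)), 1)
  expect_equal(relative_preference(rep("C", 20)), 0)
  expect_equal(relative_preference(c(rep("A", 10), rep("C", 5), rep("D", 5))),
               0.5)
  expect_equal(relative_preference(c(rep("B", 20), rep("D", 20))), c(1, 0))
  expect_error(relative_preference(rep("A", 30), block_size = 20),
               "multiple")
})

test_that("trial log CSV has the documented header", {
  sim <- run_agent(agent_params(0.5, 0.5, 0.5), std_task, seed = 41)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(sim, tmp)
  expect_equal(readLines(tmp, n = 1),
               "trial,deck,gain,loss,net_gain,vA,vB,vC,vD,pA,pB,pC,pD")
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 100)
  expect_equal(back$deck, sim$trials$deck)
})
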