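# Shared fixtures, built in code.

std_task <- task_config()

# A single-deck task used for hand-checkable value dynamics: deck C only,
# normalizer 100 so gain_n = loss_n = 0.5.
deck_c_task <- function(n_trials = 20) {
  task_config(decks = deck_spec("C", 50, 50, 0.5, FALSE),
              n_trials = n_trials, block_size = n_trials, normalizer = 100)
}

# Target whose trajectory came from a known agent.
target_from_agent <- function(params, seed, task = std_task, id = "syn") {
  sim <- run_agent(params, task, seed = seed)
  fit_target(id, sim$block_preferences)
}

# 3-sigma binomial half-width for a proportion.
binom3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
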