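# Pure-R reference engine. Mirrors src/run_agent.cpp draw for draw:
# [lapse draw if epsilon > 0] -> choice draw -> loss draw. Kept as an
# independent route so the compiled engine can be checked bit-for-bit.
run_agent_engine_r <- function(gain, loss_mag, loss_prob, memory, gs, ls,
                               n_trials, rule, temperature, value_floor,
                               epsilon, v_init, decay_unchosen) {
  k <- length(gain)
  v <- rep(v_init, k)
  choice <- integer(n_trials)
  gain_out <- loss_out <- gn_out <- numeric(n_trials)
  values <- matrix(0, n_trials, k)
  probs <- matrix(0, n_trials, k)
  for (t in seq_len(n_trials)) {
    p <- if (rule == 0L) {
      w <- pmax(v, value_floor)
      w / sum(w)
    } else {
      w <- exp((v - max(v)) / temperature)
      w / sum(w)
    }
    lapse <- if (epsilon > 0) runif(1) < epsilon else FALSE
    u <- runif(1)
    deck <- if (lapse) min(floor(u * k) + 1L, k)
            else min(sum(u >= cumsum(p)) + 1L, k)
    loss <- if (runif(1) < loss_prob[deck]) loss_mag[deck] else 0
    gn <- gain[deck] * gs - loss * ls
    if (decay_unchosen) v[-deck] <- memory * v[-deck]
    v[deck] <- memory * v[deck] + (1 - memory) * gn
    choice[t] <- deck
    gain_out[t] <- gain[deck]
    loss_out[t] <- loss
    gn_out[t] <- gn
    values[t, ] <- v
    probs[t, ] <- p
  }
  list(choice = choice, gain = gain_out, loss = loss_out, net_gain = gn_out,
       values = values, probs = probs)
}

# Shared argument marshalling for both engines.
run_agent_raw <- function(params, task, epsilon = 0, engine = "cpp") {
  dn <- normalize_deck(task$decks, task$normalizer)
  rule <- if (params$decision_rule == "softmax") 1L else 0L
  f <- if (engine == "cpp") .run_agent_cpp else run_agent_engine_r
  f(dn$gain, dn$loss_magnitude, dn$loss_prob, params$memory,
    params$gain_sensitivity, params$loss_sensitivity, task$n_trials, rule,
    params$temperature, params$value_floor, epsilon, 0.25,
    isTRUE(params$decay_unchosen))
}

#' Simulate one agent through the task
#'
#' Runs the choose -> draw outcome -> net gain -> value update cycle for
#' `task$n_trials` trials. All alternatives start at value 0.25, so the
#' first choice is uniform. Learning operates on payoffs normalized by
#' `task$normalizer`; the trial log reports raw currency alongside the
#' normalized net gain. Deterministic given `seed`.
#'
#' @param params an [agent_params()] object.
#' @param task an [task_config()] object.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param epsilon lapse probability in \[0, 1\]: with probability `epsilon`
#'   a trial's choice is replaced by a uniformly random deck (used by the
#'   synthetic-cohort generator; 0 for a pure model agent).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference). The two
#'   produce bit-identical logs under the same seed.
#' @return an `igt_simulation`: a list with `trials` (data frame with
#'   columns `trial`, `deck`, `gain`, `loss`, `net_gain`, `vA`..`vD`,
#'   `pA`..`pD`), `block_preferences`, `overall_preference`,
#'   `initial_values`, `params`, `seed`.
#' @seealso [relative_preference()], [parameter_sweep()]
#' @export
#' @examples
#' sim <- run_agent(agent_params(0.9, 0.1, 0.5), seed = 1)
#' sim$block_preferences
run_agent <- function(params, task = task_config(), seed = NULL,
                      epsilon = 0, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "igt_agent_params"), inherits(task, "igt_task"))
  if (epsilon < 0 || epsilon > 1)
    stop("`epsilon` must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- run_agent_raw(params, task, epsilon, engine)
  lab <- task$decks$label
  trials <- data.frame(trial = seq_len(task$n_trials),
                       deck = lab[res$choice],
                       gain = res$gain * task$normalizer,
                       loss = res$loss * task$normalizer,
                       net_gain = res$net_gain,
                       stringsAsFactors = FALSE)
  vals <- as.data.frame(res$values)
  names(vals) <- paste0("v", lab)
  prb <- as.data.frame(res$probs)
  names(prb) <- paste0("p", lab)
  trials <- cbind(trials, vals, prb)
  bp <- relative_preference(trials, task$block_size,
                            advantageous = lab[task$decks$advantageous])
  structure(list(trials = trials, block_preferences = bp,
                 overall_preference = mean(trials$deck %in%
                                             lab[task$decks$advantageous]),
                 initial_values = setNames(rep(0.25, nrow(task$decks)), lab),
                 params = params, task = task, seed = seed,
                 epsilon = epsilon, engine = engine),
            class = "igt_simulation")
}

#' @export
print.igt_simulation <- function(x, ...) {
  cat(sprintf("IGT simulation: %d trials, M = %.3g, Gs = %.3g, Ls = %.3g\n",
              nrow(x$trials), x$params$memory, x$params$gain_sensitivity,
              x$params$loss_sensitivity))
  cat("block preferences:",
      paste(sprintf("%.2f", x$block_preferences), collapse = " "), "\n")
  invisible(x)
}

#' Block-wise relative preference for advantageous choices
#'
#' Per block of `block_size` consecutive trials, the fraction of choices
#' that fall on the advantageous decks: (#A + #B) / block_size under the
#' default labeling.
#'
#' @param trials an `igt_simulation`, its `trials` data frame, or a
#'   character vector of chosen deck labels.
#' @param block_size trials per block (default 20).
#' @param advantageous labels counted as advantageous (default `c("A", "B")`).
#' @return a numeric vector of per-block proportions.
#' @export
#' @examples
#' relative_preference(rep(c("A", "C"), 10), block_size = 20)  # 0.5
relative_preference <- function(trials, block_size = 20,
                                advantageous = c("A", "B")) {
  deck <- if (inherits(trials, "igt_simulation")) trials$trials$deck
          else if (is.data.frame(trials)) trials$deck
          else trials
  n <- length(deck)
  if (n < 1 || n %% block_size != 0)
    stop("trial count must be a positive multiple of `block_size`",
         call. = FALSE)
  adv <- as.numeric(deck %in% advantageous)
  as.vector(tapply(adv, rep(seq_len(n %/% block_size), each = block_size),
                   mean))
}

#' Write a trial log to CSV
#'
#' Header: `trial,deck,gain,loss,net_gain,vA,vB,vC,vD,pA,pB,pC,pD`.
#'
#' @param sim an `igt_simulation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(sim, path) {
  write.csv(sim$trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
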