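# Fast path used by the sweep and the fitting loops: one compiled agent
# run, returning only the per-block advantageous-choice proportions.
agent_block_prefs <- function(task_norm, M, Gs, Ls, seed, value_floor = 0.001,
                              rule = 0L, temperature = 1, epsilon = 0,
                              decay_unchosen = FALSE) {
  set.seed(seed)
  res <- .run_agent_cpp(task_norm$gain, task_norm$loss_magnitude,
                        task_norm$loss_prob, M, Gs, Ls, task_norm$n_trials,
                        rule, temperature, value_floor, epsilon, 0.25,
                        decay_unchosen)
  adv <- res$choice %in% task_norm$adv_idx
  as.vector(tapply(adv, task_norm$block_id, mean))
}

# Pre-marshal a task for agent_block_prefs().
task_norm_spec <- function(task) {
  dn <- normalize_deck(task$decks, task$normalizer)
  list(gain = dn$gain, loss_magnitude = dn$loss_magnitude,
       loss_prob = dn$loss_prob, n_trials = task$n_trials,
       adv_idx = which(task$decks$advantageous),
       block_id = rep(seq_len(task$n_trials %/% task$block_size),
                      each = task$block_size))
}

#' Parametric sweep over memory and sensitivity grids
#'
#' For every combination of memory factor, gain sensitivity, and loss
#' sensitivity, runs `n_agents` independent agents and records the mean and
#' SD over agents of the overall (all-trials) relative preference for the
#' advantageous decks. The default 0.1-step grids give 9 x 9 x 9 = 729
#' combinations of 50 agents each. Per-agent seeds are derived from `seed`
#' by a counter, so any agent is re-runnable in isolation via
#' [agent_seed()].
#'
#' @param m_grid,gs_grid,ls_grid grids for M, Gs, Ls (defaults
#'   `seq(0.1, 0.9, by = 0.1)`).
#' @param n_agents agents per combination (default 50).
#' @param task an [task_config()].
#' @param seed master seed.
#' @param value_floor matching rectification floor passed to every agent.
#' @return an `igt_sweep`: list with `table` (one row per combination:
#'   `M`, `Gs`, `Ls`, `mean_preference`, `sd_preference`, `n_agents`),
#'   `argmax_combo`, `argmin_combo`, `grand_mean_combo` (the combination
#'   whose mean is closest to the grand mean), and `grand_mean`.
#' @export
#' @examples
#' sw <- parameter_sweep(m_grid = c(0.1, 0.9), gs_grid = 0.5, ls_grid = 0.5,
#'                       n_agents = 5, seed = 1)
#' sw$table
parameter_sweep <- function(m_grid = seq(0.1, 0.9, by = 0.1),
                            gs_grid = seq(0.1, 0.9, by = 0.1),
                            ls_grid = seq(0.1, 0.9, by = 0.1),
                            n_agents = 50, task = task_config(), seed = 1,
                            value_floor = 0.001) {
  stopifnot(length(m_grid) >= 1, length(gs_grid) >= 1, length(ls_grid) >= 1,
            n_agents >= 1)
  grid <- expand.grid(M = m_grid, Gs = gs_grid, Ls = ls_grid,
                      KEEP.OUT.ATTRS = FALSE)
  tn <- task_norm_spec(task)
  nc <- nrow(grid)
  mean_pref <- sd_pref <- numeric(nc)
  for (i in seq_len(nc)) {
    prefs <- vapply(seq_len(n_agents), function(a) {
      mean(agent_block_prefs(tn, grid$M[i], grid$Gs[i], grid$Ls[i],
                             agent_seed(seed, (i - 1) * n_agents + a),
                             value_floor))
    }, numeric(1))
    mean_pref[i] <- mean(prefs)
    sd_pref[i] <- sd(prefs)
  }
  tab <- cbind(grid, mean_preference = mean_pref, sd_preference = sd_pref,
               n_agents = n_agents)
  gm <- mean(tab$mean_preference)
  combo <- function(i) unlist(tab[i, c("M", "Gs", "Ls", "mean_preference")])
  structure(list(table = tab,
                 argmax_combo = combo(which.max(tab$mean_preference)),
                 argmin_combo = combo(which.min(tab$mean_preference)),
                 grand_mean_combo =
                   combo(which.min(abs(tab$mean_preference - gm))),
                 grand_mean = gm, seed = seed, n_agents = n_agents),
            class = "igt_sweep")
}

#' @export
print.igt_sweep <- function(x, ...) {
  cat(sprintf("IGT parameter sweep: %d combinations x %d agents\n",
              nrow(x$table), x$n_agents))
  cat(sprintf("  max  preference %.3f at M = %.2g, Gs = %.2g, Ls = %.2g\n",
              x$argmax_combo[["mean_preference"]], x$argmax_combo[["M"]],
              x$argmax_combo[["Gs"]], x$argmax_combo[["Ls"]]))
  cat(sprintf("  min  preference %.3f at M = %.2g, Gs = %.2g, Ls = %.2g\n",
              x$argmin_combo[["mean_preference"]], x$argmin_combo[["M"]],
              x$argmin_combo[["Gs"]], x$argmin_combo[["Ls"]]))
  cat(sprintf("  grand mean %.3f (closest combo M = %.2g, Gs = %.2g, Ls = %.2g)\n",
              x$grand_mean, x$grand_mean_combo[["M"]],
              x$grand_mean_combo[["Gs"]], x$grand_mean_combo[["Ls"]]))
  invisible(x)
}

#' Write a sweep table to CSV
#'
#' @param sweep an `igt_sweep`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  write.csv(sweep$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
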