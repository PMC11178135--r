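#' Construct a fitting target
#'
#' A target is one subject's block-wise relative-preference trajectory
#' (5 proportions under the default task) plus identifiers.
#'
#' @param subject_id identifier.
#' @param block_preferences numeric vector of per-block proportions in
#'   \[0, 1\].
#' @param group optional group label (e.g. `"control"`).
#' @return a list with class `igt_fit_target`.
#' @export
#' @examples
#' fit_target("s1", c(0.45, 0.55, 0.6, 0.7, 0.75), group = "control")
fit_target <- function(subject_id, block_preferences, group = NA_character_) {
  if (!is.numeric(block_preferences) || length(block_preferences) < 1 ||
      any(block_preferences < 0 | block_preferences > 1))
    stop("`block_preferences` must be proportions in [0, 1]", call. = FALSE)
  structure(list(subject_id = subject_id,
                 block_preferences = as.numeric(block_preferences),
                 group = group),
            class = "igt_fit_target")
}

new_fit_result <- function(params, achieved_block5, iterations, converged,
                           objective_value, method, seed) {
  structure(list(params = params, achieved_block5 = achieved_block5,
                 iterations = as.integer(iterations), converged = converged,
                 objective_value = objective_value, method = method,
                 seed = seed),
            class = "igt_fit")
}

#' @export
print.igt_fit <- function(x, ...) {
  cat(sprintf(
    "IGT fit (%s): M = %.3f, Gs = %.3f, Ls = %.3f | objective %.4g, %d iterations, %sconverged\n",
    x$method, x$params$memory, x$params$gain_sensitivity,
    x$params$loss_sensitivity, x$objective_value, x$iterations,
    if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Rejection-sampling parameter recovery on the final block
#'
#' Repeatedly draws (M, Gs, Ls) uniformly on `param_range`, runs a single
#' agent, and accepts the first run whose final-block preference is within
#' `tolerance` of the target's final block (0.01 by default, the published
#' acceptance rule). One agent per target: the aim is a set of initial
#' traits that reproduces the subject's end-of-task preference, with the
#' earlier blocks left free to be compared against the subject's learning
#' curve. Returns the best draw so far with `converged = FALSE` if no draw
#' is accepted within `max_iterations`.
#'
#' The accepted agent's seed is stored in the result, so the acceptance can
#' be audited by re-simulation: `run_agent(fit$params, task, fit$seed)`.
#'
#' @param target an [fit_target()].
#' @param tolerance maximum absolute deviation on the final block
#'   (default 0.01).
#' @param max_iterations cap on candidate draws (default 10000, > 0).
#' @param task an [task_config()].
#' @param seed master seed; candidate parameters and agent seeds are both
#'   derived from it by counters.
#' @param param_range sampling interval for all three parameters
#'   (default `c(0.01, 0.99)`).
#' @return an `igt_fit` with fields `params`, `achieved_block5`,
#'   `iterations`, `converged`, `objective_value` (absolute final-block
#'   deviation), `method = "rejection"`, and the accepted agent `seed`.
#' @export
#' @examples
#' tgt <- fit_target("s1", c(0.4, 0.5, 0.6, 0.7, 0.75))
#' fit_rejection(tgt, tolerance = 0.05, seed = 1)
fit_rejection <- function(target, tolerance = 0.01, max_iterations = 10000,
                          task = task_config(), seed = NULL,
                          param_range = c(0.01, 0.99)) {
  stopifnot(inherits(target, "igt_fit_target"))
  if (tolerance <= 0) stop("`tolerance` must be positive", call. = FALSE)
  if (max_iterations <= 0)
    stop("`max_iterations` must be positive", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  tn <- task_norm_spec(task)
  target5 <- target$block_preferences[length(target$block_preferences)]
  best <- NULL
  best_dev <- Inf
  for (i in seq_len(max_iterations)) {
    set.seed(agent_seed(seed, 2 * i - 1))
    p <- runif(3, param_range[1], param_range[2])
    s <- agent_seed(seed, 2 * i)
    bp <- agent_block_prefs(tn, p[1], p[2], p[3], s)
    dev <- abs(bp[length(bp)] - target5)
    if (dev < best_dev) {
      best_dev <- dev
      best <- list(p = p, s = s, b5 = bp[length(bp)], i = i)
    }
    if (dev <= tolerance) break
  }
  new_fit_result(agent_params(best$p[1], best$p[2], best$p[3]),
                 achieved_block5 = best$b5, iterations = i,
                 converged = best_dev <= tolerance,
                 objective_value = best_dev, method = "rejection",
                 seed = best$s)
}

# Box transform used by the Nelder-Mead fit: R -> (lo, hi).
to_box <- function(theta, lo, hi) lo + (hi - lo) / (1 + exp(-theta))
from_box <- function(p, lo, hi) {
  q <- (p - lo) / (hi - lo)
  q <- pmin(pmax(q, 1e-6), 1 - 1e-6)
  log(q / (1 - q))
}

# SSE between a target trajectory and the mean trajectory of n_eval_agents
# agents at the candidate parameters, with common random numbers: the same
# per-agent seeds for every candidate, making the objective a deterministic
# function of the parameters.
nm_objective <- function(p, target_bp, tn, eval_seeds) {
  bp <- rowMeans(vapply(eval_seeds,
                        function(s) agent_block_prefs(tn, p[1], p[2], p[3], s),
                        numeric(length(target_bp))))
  sum((target_bp - bp)^2)
}

#' Nelder-Mead parameter recovery on the full trajectory
#'
#' Minimizes the sum over all blocks of the squared deviation between the
#' target's block preferences and the mean block preferences of
#' `n_eval_agents` simulated agents at the candidate parameters. The same
#' per-agent seeds are reused for every candidate (common random numbers),
#' so the objective is deterministic and the simplex search is well
#' behaved. Parameters are box-constrained to `param_range` through a
#' logistic transform.
#'
#' @inheritParams fit_rejection
#' @param n_eval_agents agents averaged per objective evaluation
#'   (default 20).
#' @param start starting values for (M, Gs, Ls) (default mid-range).
#' @param maxit maximum simplex evaluations (default 500).
#' @return an `igt_fit` with `objective_value` the achieved SSE and
#'   `method = "nelder-mead"`; `seed` is the master seed the evaluation
#'   seeds derive from.
#' @export
fit_nelder_mead <- function(target, n_eval_agents = 20, task = task_config(),
                            seed = NULL, param_range = c(0.01, 0.99),
                            start = c(0.5, 0.5, 0.5), maxit = 500) {
  stopifnot(inherits(target, "igt_fit_target"))
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  tn <- task_norm_spec(task)
  eval_seeds <- vapply(seq_len(n_eval_agents),
                       function(j) agent_seed(seed, j), integer(1))
  lo <- param_range[1]; hi <- param_range[2]
  fn <- function(theta)
    nm_objective(to_box(theta, lo, hi), target$block_preferences, tn,
                 eval_seeds)
  opt <- optim(from_box(start, lo, hi), fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  p <- to_box(opt$par, lo, hi)
  bp <- rowMeans(vapply(eval_seeds,
                        function(s) agent_block_prefs(tn, p[1], p[2], p[3], s),
                        numeric(length(target$block_preferences))))
  new_fit_result(agent_params(p[1], p[2], p[3]),
                 achieved_block5 = bp[length(bp)],
                 iterations = opt$counts[["function"]],
                 converged = opt$convergence == 0,
                 objective_value = opt$value, method = "nelder-mead",
                 seed = seed)
}

#' Fit every subject in a targets table
#'
#' Applies [fit_rejection()] or [fit_nelder_mead()] row by row to a targets
#' data frame (columns `subject_id`, `group`, `b1`..`b5`), deriving one
#' sub-seed per subject from `seed`.
#'
#' @param targets a data frame as produced by [cohort_to_fit_targets()] or
#'   [read_fit_targets()].
#' @param method `"rejection"` or `"nelder-mead"`.
#' @param task an [task_config()].
#' @param seed master seed.
#' @param ... passed on to the chosen fitting routine.
#' @return a data frame with one row per subject: `subject_id`, `group`,
#'   `M`, `Gs`, `Ls`, `method`, `converged`, `iterations`, `objective`,
#'   `achieved_block5`, `seed`.
#' @export
fit_subjects <- function(targets, method = c("rejection", "nelder-mead"),
                         task = task_config(), seed = 1, ...) {
  method <- match.arg(method)
  bcols <- grep("^b[0-9]+$", names(targets), value = TRUE)
  if (length(bcols) < 1)
    stop("`targets` must have block columns b1..bK", call. = FALSE)
  out <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tgt <- fit_target(targets$subject_id[i],
                      as.numeric(targets[i, bcols]),
                      if ("group" %in% names(targets)) targets$group[i]
                      else NA_character_)
    sub_seed <- agent_seed(seed, 1000000 + i)
    fit <- if (method == "rejection")
      fit_rejection(tgt, task = task, seed = sub_seed, ...)
    else
      fit_nelder_mead(tgt, task = task, seed = sub_seed, ...)
    out[[i]] <- data.frame(subject_id = tgt$subject_id, group = tgt$group,
                           M = fit$params$memory,
                           Gs = fit$params$gain_sensitivity,
                           Ls = fit$params$loss_sensitivity,
                           method = fit$method, converged = fit$converged,
                           iterations = fit$iterations,
                           objective = fit$objective_value,
                           achieved_block5 = fit$achieved_block5,
                           seed = fit$seed, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Re-simulate fitted parameters in replica groups
#'
#' Runs every subject's recovered parameters through the task `n_replicas`
#' times with fresh (counter-derived) seeds, mirroring the replication step
#' that validates whether recovered traits reproduce the cohort's
#' trajectory. The default of 5 replicas of a 40-subject cohort yields 200
#' simulated trajectories.
#'
#' @param params_per_subject a data frame with columns `subject_id`, `M`,
#'   `Gs`, `Ls` (e.g. the output of [fit_subjects()]), or a list of
#'   [agent_params()].
#' @param n_replicas number of replica groups (default 5).
#' @param task an [task_config()].
#' @param seed master seed.
#' @return a data frame in long form: `replica`, `subject_id`, `block`,
#'   `preference`.
#' @export
replicate_with_params <- function(params_per_subject, n_replicas = 5,
                                  task = task_config(), seed = 1) {
  if (is.list(params_per_subject) && !is.data.frame(params_per_subject)) {
    params_per_subject <- do.call(rbind, lapply(
      seq_along(params_per_subject), function(i) {
        p <- params_per_subject[[i]]
        data.frame(subject_id = paste0("s", i), M = p$memory,
                   Gs = p$gain_sensitivity, Ls = p$loss_sensitivity,
                   stringsAsFactors = FALSE)
      }))
  }
  stopifnot(nrow(params_per_subject) >= 1)
  tn <- task_norm_spec(task)
  n_sub <- nrow(params_per_subject)
  n_blocks <- task$n_trials %/% task$block_size
  out <- vector("list", n_replicas * n_sub)
  idx <- 0L
  for (r in seq_len(n_replicas)) {
    for (i in seq_len(n_sub)) {
      s <- agent_seed(seed, (r - 1) * n_sub + i)
      bp <- agent_block_prefs(tn, params_per_subject$M[i],
                              params_per_subject$Gs[i],
                              params_per_subject$Ls[i], s)
      idx <- idx + 1L
      out[[idx]] <- data.frame(replica = r,
                               subject_id = params_per_subject$subject_id[i],
                               block = seq_len(n_blocks), preference = bp,
                               stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read / write fitting targets as CSV
#'
#' Columns: `subject_id`, `group`, `b1`..`bK` (block preferences).
#'
#' @param path file path.
#' @return `read_fit_targets()` returns a data frame;
#'   `write_fit_targets()` returns `path` invisibly.
#' @export
read_fit_targets <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_fit_targets
#' @param targets a targets data frame.
#' @export
write_fit_targets <- function(targets, path) {
  write.csv(targets, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
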