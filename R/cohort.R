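#' Specify a synthetic cohort
#'
#' Describes groups of surrogate "participants" with known ground-truth
#' parameters drawn uniformly from per-group intervals, plus a lapse
#' probability `epsilon` with which any single choice is replaced by a
#' uniformly random deck — a simple way to keep surrogates from being
#' perfectly model-consistent, as human data never is. The default two
#' groups of 20 mirror a control / substance-abuse study design, with
#' parameter intervals anchored to the fitted subgroup values of the
#' modeled study (control-like: high memory, moderate-to-high loss
#' sensitivity, lower gain sensitivity; abuse-like: low memory, high gain
#' sensitivity, widely spread loss sensitivity).
#'
#' @param groups named list; each element is a list with `n` (subjects) and
#'   two-element ranges `memory`, `gain_sensitivity`, `loss_sensitivity`.
#' @param epsilon lapse probability in \[0, 0.5\] (default 0.05).
#' @param seed master seed; cohort generation is a pure function of the
#'   spec including this seed.
#' @return a list with class `igt_cohort_spec`.
#' @export
#' @examples
#' cohort_spec(epsilon = 0, seed = 7)
cohort_spec <- function(groups = list(
                          control = list(n = 20, memory = c(0.6, 0.95),
                                         gain_sensitivity = c(0.1, 0.6),
                                         loss_sensitivity = c(0.4, 0.9)),
                          abuse = list(n = 20, memory = c(0.05, 0.5),
                                       gain_sensitivity = c(0.5, 0.95),
                                       loss_sensitivity = c(0.1, 0.9))),
                        epsilon = 0.05, seed = 1) {
  if (epsilon < 0 || epsilon > 0.5)
    stop("`epsilon` must lie in [0, 0.5]", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list", call. = FALSE)
  for (g in names(groups)) {
    gr <- groups[[g]]
    stopifnot(gr$n >= 1)
    for (fld in c("memory", "gain_sensitivity", "loss_sensitivity")) {
      r <- gr[[fld]]
      if (length(r) != 2 || r[1] > r[2])
        stop(sprintf("group '%s': `%s` must be a (lo, hi) range", g, fld),
             call. = FALSE)
      lo_ok <- if (fld == "memory") r[1] >= 0 else r[1] > 0
      if (!lo_ok || r[2] > 1)
        stop(sprintf("group '%s': `%s` range outside the valid parameter range",
                     g, fld), call. = FALSE)
    }
  }
  structure(list(groups = groups, epsilon = epsilon, seed = seed),
            class = "igt_cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' For every subject, draws (M, Gs, Ls) from its group's intervals, runs a
#' full simulation with lapse probability `spec$epsilon`, and stores the
#' ground-truth parameters alongside the trial log and block preferences.
#' Parameter draws and agent runs use separate counter-derived seeds, so
#' the cohort is a pure function of the spec and any single subject can be
#' regenerated in isolation.
#'
#' @param spec an [cohort_spec()].
#' @param task an [task_config()].
#' @return an `igt_cohort`: list of subjects (each with `subject_id`,
#'   `group`, `true_params`, `sim`, `block_preferences`) plus the spec.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(groups = list(
#'   g = list(n = 4, memory = c(0.5, 0.9), gain_sensitivity = c(0.1, 0.5),
#'            loss_sensitivity = c(0.3, 0.9))), seed = 2))
#' cohort_to_fit_targets(co)
generate_cohort <- function(spec, task = task_config()) {
  stopifnot(inherits(spec, "igt_cohort_spec"))
  subjects <- list()
  counter <- 0L
  for (g in names(spec$groups)) {
    gr <- spec$groups[[g]]
    for (i in seq_len(gr$n)) {
      counter <- counter + 1L
      set.seed(agent_seed(spec$seed, 2 * counter - 1))
      params <- agent_params(
        memory = runif(1, gr$memory[1], gr$memory[2]),
        gain_sensitivity = runif(1, gr$gain_sensitivity[1],
                                 gr$gain_sensitivity[2]),
        loss_sensitivity = runif(1, gr$loss_sensitivity[1],
                                 gr$loss_sensitivity[2]))
      run_seed <- agent_seed(spec$seed, 2 * counter)
      sim <- run_agent(params, task, seed = run_seed,
                       epsilon = spec$epsilon)
      subjects[[counter]] <- list(subject_id = sprintf("%s_%02d", g, i),
                                  group = g, true_params = params,
                                  sim = sim,
                                  block_preferences = sim$block_preferences)
    }
  }
  structure(list(subjects = subjects, spec = spec, task = task),
            class = "igt_cohort")
}

#' @export
print.igt_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("IGT synthetic cohort: %d subjects (%s), epsilon = %g\n",
              length(x$subjects),
              paste(sprintf("%s: %d", names(table(groups)), table(groups)),
                    collapse = ", "),
              x$spec$epsilon))
  invisible(x)
}

#' Extract fitting targets from a cohort
#'
#' @param cohort an `igt_cohort`.
#' @return a data frame with columns `subject_id`, `group`, `b1`..`bK` —
#'   the shape [fit_subjects()] and the fitting CLI consume.
#' @export
cohort_to_fit_targets <- function(cohort) {
  stopifnot(inherits(cohort, "igt_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    bp <- as.list(s$block_preferences)
    names(bp) <- paste0("b", seq_along(bp))
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     stringsAsFactors = FALSE),
          as.data.frame(bp))
  }))
}

#' Ground-truth parameter table of a cohort
#'
#' @param cohort an `igt_cohort`.
#' @return a data frame with columns `subject_id`, `group`, `M`, `Gs`,
#'   `Ls` (the generating parameters), for parameter-recovery checks.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "igt_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               M = s$true_params$memory,
               Gs = s$true_params$gain_sensitivity,
               Ls = s$true_params$loss_sensitivity,
               stringsAsFactors = FALSE)
  }))
}
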