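#' Construct and validate agent parameters
#'
#' The agent has three traits: a memory factor M in \[0, 1\] weighting an
#' alternative's previous value in the linear-operator update, and gain /
#' loss sensitivities Gs, Ls in (0, 1\] weighting payoffs in the subjective
#' net gain. The decision rule is matching by default; Softmax is available
#' as a variant.
#'
#' @param memory memory factor M in \[0, 1\].
#' @param gain_sensitivity Gs in (0, 1\].
#' @param loss_sensitivity Ls in (0, 1\].
#' @param decision_rule `"matching"` (default) or `"softmax"`.
#' @param temperature Softmax temperature (> 0, default 1); ignored under
#'   matching.
#' @param decay_unchosen if `TRUE`, unchosen decks' values also decay
#'   toward 0 at rate M each trial (default `FALSE`: only the chosen
#'   alternative's value is updated).
#' @param value_floor rectification floor applied to values before the
#'   matching ratio (default 0.001). The matching rule is undefined for
#'   non-positive value sums, which the model reaches readily since net
#'   gains can be strongly negative; the floor keeps the choice
#'   distribution proper and exploration alive. Stored values are never
#'   floored, only the probabilities read from them.
#' @return a list with class `igt_agent_params`.
#' @export
#' @examples
#' agent_params(memory = 0.9, gain_sensitivity = 0.1, loss_sensitivity = 0.5)
agent_params <- function(memory, gain_sensitivity, loss_sensitivity,
                         decision_rule = c("matching", "softmax"),
                         temperature = 1, value_floor = 0.001,
                         decay_unchosen = FALSE) {
  decision_rule <- match.arg(decision_rule)
  chk <- function(x, nm, lo, hi, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (if (lo_open) x <= lo else x < lo) || x > hi)
      stop(sprintf("`%s` must lie in %s%g, %g]", nm,
                   if (lo_open) "(" else "[", lo, hi), call. = FALSE)
  }
  chk(memory, "memory", 0, 1)
  chk(gain_sensitivity, "gain_sensitivity", 0, 1, lo_open = TRUE)
  chk(loss_sensitivity, "loss_sensitivity", 0, 1, lo_open = TRUE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("`temperature` must be positive", call. = FALSE)
  if (!is.numeric(value_floor) || value_floor <= 0)
    stop("`value_floor` must be positive", call. = FALSE)
  structure(list(memory = memory, gain_sensitivity = gain_sensitivity,
                 loss_sensitivity = loss_sensitivity,
                 decision_rule = decision_rule, temperature = temperature,
                 value_floor = value_floor,
                 decay_unchosen = isTRUE(decay_unchosen)),
            class = "igt_agent_params")
}

#' @export
print.igt_agent_params <- function(x, ...) {
  cat(sprintf("IGT agent: M = %.3g, Gs = %.3g, Ls = %.3g (%s rule)\n",
              x$memory, x$gain_sensitivity, x$loss_sensitivity,
              x$decision_rule))
  invisible(x)
}

#' Sensitivity-weighted subjective net gain
#'
#' Gn = G * Gs - L * Ls, with the loss supplied as a positive magnitude.
#' With raw dollars, a $100 gain with a $250 loss is worth -215 to an agent
#' with Gs = 0.1, Ls = 0.9 but +65 to one with Gs = 0.9, Ls = 0.1.
#' Vectorized over `gain` / `loss`.
#'
#' @param gain gain (>= 0), any currency or normalized units.
#' @param loss loss magnitude (>= 0), same units as `gain`.
#' @param params an `igt_agent_params`.
#' @return the subjective net gain (may be negative).
#' @export
#' @examples
#' p <- agent_params(0.5, gain_sensitivity = 0.1, loss_sensitivity = 0.9)
#' net_gain(100, 250, p)  # -215
net_gain <- function(gain, loss, params) {
  if (any(gain < 0) || any(loss < 0))
    stop("`gain` and `loss` must be non-negative (losses are magnitudes)",
         call. = FALSE)
  gain * params$gain_sensitivity - loss * params$loss_sensitivity
}

#' Linear-operator value update
#'
#' V_t = M * V_{t-1} + (1 - M) * Gn: an exponentially weighted average of
#' past value and present net gain, so the update always lies between the
#' two and contracts toward Gn at rate M.
#'
#' @param v_prev previous value of the chosen alternative.
#' @param params an `igt_agent_params` (only `memory` is used).
#' @param gn the subjective net gain of the current outcome.
#' @return the updated value.
#' @export
#' @examples
#' update_value(0.25, agent_params(0.5, 0.5, 0.5), gn = 0.65)  # 0.45
update_value <- function(v_prev, params, gn) {
  params$memory * v_prev + (1 - params$memory) * gn
}

#' Matching-law choice probabilities
#'
#' Each value is rectified to `max(value, floor)` and divided by the sum of
#' rectified values, so the result is a proper probability vector even when
#' learned values are negative; when every rectified value is equal
#' (including the all-at-floor case) the distribution is uniform.
#'
#' @param values numeric value vector, one per alternative.
#' @param floor rectification floor (> 0, default 0.001).
#' @return a probability vector summing to 1.
#' @export
#' @examples
#' matching_probabilities(c(0.1, 0.3, 0.4, 0.2) * 5)
matching_probabilities <- function(values, floor = 0.001) {
  stopifnot(length(values) >= 1L, floor > 0)
  w <- pmax(values, floor)
  w / sum(w)
}

#' Softmax choice probabilities
#'
#' p_i = exp(v_i / tau) / sum_j exp(v_j / tau), computed with
#' max-subtraction so large values cannot overflow.
#'
#' @param values numeric value vector.
#' @param temperature tau > 0; larger is closer to uniform.
#' @return a probability vector summing to 1.
#' @export
#' @examples
#' softmax_probabilities(c(1, 0, 0, 0), temperature = 1)
softmax_probabilities <- function(values, temperature = 1) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("`temperature` must be positive", call. = FALSE)
  w <- exp((values - max(values)) / temperature)
  w / sum(w)
}

#' Sample one alternative from a probability vector
#'
#' The unit interval is partitioned into consecutive half-open intervals
#' \[c_{i-1}, c_i) of the cumulative probabilities and a single uniform draw
#' selects the interval containing it.
#'
#' @param probs probability vector; must sum to 1 within 1e-9.
#' @return the chosen index (1-based).
#' @export
#' @examples
#' set.seed(1)
#' choose_deck(c(0.25, 0.25, 0.25, 0.25))
choose_deck <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-9)
    stop("`probs` must sum to 1 (within 1e-9)", call. = FALSE)
  u <- runif(1)
  min(sum(u >= cumsum(probs)) + 1L, length(probs))
}
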