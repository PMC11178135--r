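#' Construct a single IGT deck
#'
#' A deck is described by the gain delivered on every card, the magnitude of
#' the punishment when one occurs, and the probability that a card carries a
#' punishment. Losses are stored as positive magnitudes; the net-gain rule
#' subtracts them.
#'
#' @param label deck label, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param gain currency units won on every card (> 0).
#' @param loss_magnitude currency units lost on a punished card (>= 0,
#'   positive magnitude).
#' @param loss_prob probability in \[0, 1\] that a card is punished.
#' @param advantageous logical flag marking the deck as long-term
#'   advantageous. The flag is carried verbatim into the relative-preference
#'   statistic; see `standard_decks()` for the default labeling.
#' @return a one-row `data.frame` with class `igt_decks`.
#' @seealso [standard_decks()], [normalize_deck()], [draw_outcome()]
#' @export
#' @examples
#' deck_spec("A", gain = 100, loss_magnitude = 1250, loss_prob = 0.1,
#'           advantageous = TRUE)
deck_spec <- function(label, gain, loss_magnitude, loss_prob, advantageous) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(gain) || gain <= 0)
    stop("`gain` must be a positive number", call. = FALSE)
  if (!is.numeric(loss_magnitude) || loss_magnitude < 0)
    stop("`loss_magnitude` must be >= 0 (stored as a positive magnitude)",
         call. = FALSE)
  if (!is.numeric(loss_prob) || loss_prob < 0 || loss_prob > 1)
    stop("`loss_prob` must lie in [0, 1]", call. = FALSE)
  d <- data.frame(label = label, gain = as.numeric(gain),
                  loss_magnitude = as.numeric(loss_magnitude),
                  loss_prob = as.numeric(loss_prob),
                  advantageous = as.logical(advantageous),
                  stringsAsFactors = FALSE)
  class(d) <- c("igt_decks", "data.frame")
  d
}

#' The standard four-deck IGT payoff structure
#'
#' Decks A and B pay 100 per card, C and D pay 50; punishments are
#' A: 1250 at p = 0.1, B: 250 at p = 0.5, C: 50 at p = 0.5, D: 250 at
#' p = 0.1. A and B carry the `advantageous` flag. Note that under these
#' payoffs the expected raw net per trial is -25 for A/B and +25 for C/D;
#' the flag follows the published labeling of the modeled study rather than
#' the raw expectation, and the relative-preference statistic is defined on
#' the flagged (A + B) decks. Relabel via the `advantageous` column if your
#' convention differs.
#'
#' @return an `igt_decks` data frame with four rows.
#' @export
#' @examples
#' standard_decks()
standard_decks <- function() {
  d <- rbind(
    deck_spec("A", 100, 1250, 0.1, TRUE),
    deck_spec("B", 100,  250, 0.5, TRUE),
    deck_spec("C",  50,   50, 0.5, FALSE),
    deck_spec("D",  50,  250, 0.1, FALSE)
  )
  class(d) <- c("igt_decks", "data.frame")
  d
}

#' Rescale deck payoffs by a normalizing constant
#'
#' Divides `gain` and `loss_magnitude` by `normalizer`; `loss_prob` is
#' untouched. The agent model operates on payoffs normalized by the maximum
#' deck gain (100 for the standard decks), e.g. deck C's gain becomes
#' 50/100 = 0.5 and deck A's loss magnitude 1250/100 = 12.5.
#'
#' @param deck an `igt_decks` data frame (one or more rows).
#' @param normalizer positive currency divisor.
#' @return the deck table in normalized units.
#' @export
#' @examples
#' normalize_deck(standard_decks(), 100)
normalize_deck <- function(deck, normalizer) {
  if (!is.numeric(normalizer) || length(normalizer) != 1L || normalizer <= 0)
    stop("`normalizer` must be a single positive number", call. = FALSE)
  deck$gain <- deck$gain / normalizer
  deck$loss_magnitude <- deck$loss_magnitude / normalizer
  deck
}

#' Sample card outcomes from a deck
#'
#' Each draw delivers the deck's gain; with probability `loss_prob` the same
#' card also carries a loss of `loss_magnitude`. Losses are i.i.d. Bernoulli
#' per draw (the payoff description of the model, not the fixed card
#' schedules of the original clinical task). Uses R's global RNG; seed with
#' `set.seed()`.
#'
#' @param deck a single-row `igt_decks` data frame.
#' @param n number of cards to draw.
#' @return a `data.frame` with columns `gain` and `loss` (positive
#'   magnitude, 0 when unpunished), one row per draw.
#' @export
#' @examples
#' set.seed(1)
#' draw_outcome(standard_decks()[1, ], n = 5)
draw_outcome <- function(deck, n = 1) {
  stopifnot(nrow(deck) == 1L, n >= 1)
  punished <- runif(n) < deck$loss_prob
  data.frame(gain = rep(deck$gain, n),
             loss = ifelse(punished, deck$loss_magnitude, 0))
}

#' Assemble a task configuration
#'
#' Bundles the deck table with the trial structure: `n_trials` must be an
#' exact multiple of `block_size` (default 100 trials in 5 blocks of 20).
#' `normalizer` defaults to the maximum deck gain, the divisor used to put
#' payoffs on the value scale the learning rule operates on.
#'
#' @param decks an `igt_decks` data frame (default [standard_decks()]).
#' @param n_trials trials per agent (default 100).
#' @param block_size trials per block (default 20).
#' @param normalizer positive currency divisor (default `max(decks$gain)`).
#' @return a list with class `igt_task`.
#' @export
#' @examples
#' task_config()
task_config <- function(decks = standard_decks(), n_trials = 100,
                        block_size = 20, normalizer = max(decks$gain)) {
  stopifnot(nrow(decks) >= 1L)
  if (n_trials < 1 || n_trials %% block_size != 0)
    stop("`n_trials` must be a positive multiple of `block_size`",
         call. = FALSE)
  if (!is.numeric(normalizer) || normalizer <= 0)
    stop("`normalizer` must be positive", call. = FALSE)
  if (anyDuplicated(decks$label))
    stop("deck labels must be unique", call. = FALSE)
  structure(list(decks = decks, n_trials = as.integer(n_trials),
                 block_size = as.integer(block_size),
                 normalizer = as.numeric(normalizer)),
            class = "igt_task")
}

#' @export
print.igt_task <- function(x, ...) {
  cat(sprintf("IGT task: %d decks, %d trials in blocks of %d, normalizer %g\n",
              nrow(x$decks), x$n_trials, x$block_size, x$normalizer))
  print(as.data.frame(x$decks))
  invisible(x)
}

#' Read / write a task configuration as JSON
#'
#' The JSON layout is `{decks: [{label, gain, loss_magnitude, loss_prob,
#' advantageous}], n_trials, block_size, normalizer}`. A bundled default,
#' `system.file("extdata", "standard_task.json", package = "igtsim")`,
#' reproduces the standard four decks.
#'
#' @param path file path.
#' @return `read_task_config()` returns an `igt_task`;
#'   `write_task_config()` returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  decks <- x$decks
  class(decks) <- c("igt_decks", "data.frame")
  task_config(decks = decks, n_trials = x$n_trials,
              block_size = x$block_size, normalizer = x$normalizer)
}

#' @rdname read_task_config
#' @param task an `igt_task`.
#' @export
write_task_config <- function(task, path) {
  jsonlite::write_json(
    list(decks = as.data.frame(task$decks), n_trials = task$n_trials,
         block_size = task$block_size, normalizer = task$normalizer),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
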