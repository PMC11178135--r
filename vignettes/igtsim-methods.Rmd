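---
title: "Methods: a linear-operator matching agent for the Iowa Gambling Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a linear-operator matching agent for the Iowa Gambling Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igtsim)
```

## The model

The Iowa Gambling Task presents four decks over 100 trials. In this
package's environment a deck is fully described by `(G, L, P)`: the gain on
every card, the loss magnitude, and the per-card loss probability. Losses
are sampled i.i.d. Bernoulli per draw. That is the payoff process the agent
model defines — not the fixed, escalating card schedules of the original
clinical task, which are a deliberate non-goal. A loss, when it occurs,
arrives on the same card as the gain.

The agent carries one value per deck, all initialized at 0.25, and three
traits:

* **Gain / loss sensitivity** `Gs, Ls ∈ (0, 1]` weight the outcome into a
  subjective net gain `Gn = G·Gs − L·Ls` (losses are stored as positive
  magnitudes and subtracted). Sensitivities scale perception: a
  loss-sensitive agent (`Gs = 0.1, Ls = 0.9`) values a $100/$250 card at
  −215, a gain-sensitive one (`Gs = 0.9, Ls = 0.1`) at +65.
* **Memory factor** `M ∈ [0, 1]`: the chosen deck's value updates by the
  linear operator `V_t = M·V_{t−1} + (1 − M)·Gn`, an exponentially weighted
  average that contracts toward `Gn` at rate `M`. Unchosen decks keep their
  values.
* **Choice rule**: matching, `P(X) = V_X / Σ_Y V_Y`. A Softmax variant
  (`temperature`, default 1) is selectable per agent.

Learning operates on payoffs normalized by the maximum deck gain
(`normalizer`, default 100), so `G ∈ {1, 0.5}` and `L ∈ {12.5, 2.5, 0.5}`;
trial logs keep raw currency alongside. Normalization matters beyond
cosmetics: the linear operator mixes `Gn` with values on the 0.25 scale, so
running the update on raw dollars would be a different model. The worked
net-gain example above is scale-free because `Gn` is linear in the payoffs.

### Negative values and the matching floor

The matching ratio is undefined once the value sum goes non-positive, which
happens readily (a normalized loss of 12.5 times any `Ls` dwarfs every
gain). How the original model handled this is unspecified; this package
rectifies each value at `value_floor = 0.001` *for the probability
computation only* — stored values stay un-rectified, and when every
rectified value is at the floor the choice is uniform. The floor keeps the
choice distribution proper, keeps exploration alive (a crashed deck retains
a small, nonzero probability), and reduces to the plain matching rule
whenever all values are positive. Sweep results depend on this choice, which
is why it is a visible parameter rather than a constant.

## The parametric sweep

`parameter_sweep()` crosses `M × Gs × Ls` on 0.1-step grids (729
combinations) with 50 agents each and records the mean overall preference
for the flagged advantageous decks, `(#A + #B) / 100`. Per-agent seeds
derive from the master seed by a counter (`agent_seed()`), so any cell or
single agent is reproducible in isolation. The full sweep takes a few
seconds (the trial loop is compiled; a bit-identical pure-R reference
engine backs it, and the test suite asserts their equality draw for draw).

Two quirks of the source material are worth stating plainly:

* The deck table flags A and B as advantageous, yet under the listed
  payoffs their raw expectation is −25 per trial versus +25 for C and D.
  The package follows the flags literally — the preference statistic is
  defined on them, and the `advantageous` column is exposed so users can
  relabel — but the contradiction is real and shapes the sweep.
* Because A and B carry the large losses, preference for them *falls* as
  loss sensitivity rises over most of the grid. The published direction
  ("advantageous preference rises with `M` and `Ls`") is recovered only in
  the low-`Gs` region that contains the published optimum (`Gs = 0.1`,
  `M = 0.9`): there, high `Ls` drives every value to the floor, choice
  drifts toward uniform (0.5), and preference for A + B rises relative to
  the C/D-dominated low-`Ls` regime. The directional tests are therefore
  conditioned on low `Gs`; the exact published argmax/argmin combinations
  are not targets (the published argmin even lists `Gs = 1`, off the stated
  grid). The overall-preference metric uses all 100 trials rather than the
  final block, for stability.

## Fitting

Targets are per-subject trajectories of five block preferences
(`(#A + #B)/20` per block of 20 trials).

**Rejection** (`fit_rejection()`): draw `(M, Gs, Ls)` uniformly on
`[0.01, 0.99]³`, run one agent, accept when its final-block preference is
within `tolerance = 0.01` of the target's. One agent per subject, matching
the design it reproduces; the sampling range is continuous because the
procedure it mirrors says only "randomly selected". The loop has no natural
termination for extreme targets, so `max_iterations = 10000` returns
best-so-far with `converged = FALSE`. Candidate draws and agent runs use
separate counter-derived seeds: the whole fit is a pure function of its
master seed, and the accepted run's seed is stored so the ≤ tolerance
contract can be audited by re-simulation.

**Nelder–Mead** (`fit_nelder_mead()`): minimizes the SSE between the
target's five block preferences and the mean trajectory of 20 agents
simulated at the candidate parameters with *common random numbers* — the
same 20 seeds for every candidate — making the objective deterministic.
Parameters are box-constrained to `[0.01, 0.99]` via a logistic transform.
The objective was not specified by the source; SSE over all five blocks is
the natural trajectory-level choice. A single mid-range start is the
default: multistart was evaluated and rejected, because on noisy
single-trajectory targets a lower objective systematically *worsens*
parameter recovery (it fits the realization, not the subject).

### Identifiability, honestly

Recovering three traits from five proportions is weakly determined, and for
the memory factor the weakness is structural: matching probabilities depend
only on value *ratios*, and each deck's value converges toward its expected
subjective gain regardless of `M` — the memory factor enters the mean
trajectory only through the initial transient and through variance effects
around the floor. The package's tests measure this rather than hide it: on
noiseless mean-trajectory targets the frozen median absolute recovery
errors are ≈ 0.26 (M), 0.27 (Gs), 0.23 (Ls), and on the default noisy
40-subject cohort even a brute-force grid-optimal fit yields a Spearman
correlation near zero for `M`. The acceptance test asserting positive
rank correlation per parameter is kept as stated and is expected to fail
for `M` (and, seed-dependently, `Ls`): a red light with a measured
explanation, not a relaxed threshold. Gain sensitivity, which controls the
trajectory's level most directly, recovers with reliably positive rank
correlation.

## Synthetic cohorts

`generate_cohort()` replaces human participants: two groups of 20 subjects
(the study design it stands in for), parameters drawn uniformly from
per-group intervals, 100 trials each. The default intervals are anchored to
the fitted subgroup values of the modeled study rather than invented —
control-like subjects get high `M` (0.6–0.95), lower `Gs` (0.1–0.6) and
substantial `Ls` (0.4–0.9); abuse-like subjects low `M` (0.05–0.5), high
`Gs` (0.5–0.95) and widely spread `Ls` (0.1–0.9). A lapse probability
`epsilon = 0.05` replaces a choice with a uniform deck, so surrogates are
not perfectly model-consistent; the generator caps it at 0.5 (beyond that
the "subject" is mostly noise). What the surrogates do *not* emulate:
demographics, fixed card schedules, within-session nonstationarity of human
attention, or any group difference beyond the parameter intervals — so a
green fitting test establishes that the pipeline recovers what this model
can express, not that the model is true of people.

## Summaries

* `fit_power()` fits `y = a·x^b` to block preferences over `x = 1..5` by
  least squares: exact log–log regression start, then direct SSE
  minimization (Nelder–Mead, BFGS polish). Zeros are clamped to 1e-6 so
  all-disadvantageous subjects keep a defined exponent; `b` is the rate of
  change, near-unbiased under block-scale noise (|bias| < 0.02 at σ = 0.02
  per the test suite's simulation).
* `quartile_subgroups()` partitions a cohort at its interpolated quartiles
  (type-7): Q1 strictly below q25, Q3 at or above q75, Q2 between. With all
  preferences equal the whole cohort lands in Q3 — the at-or-above rule
  holds with equality, a documented tie-break.
* `correlate_blocks()` pairs two block-mean vectors (or subgroup-by-block
  matrices, flattened) and returns Pearson `r`, a two-sided p-value, and
  RMSE, flagging the zero-variance case as undefined rather than guessing.
  The final block is conventionally excluded upstream
  (`subgroup_block_means(drop_last = TRUE)`) because it serves as the
  rejection-fitting objective.

## Numerical and design notes

* Grid inconsistency: the source text says "900 simulations" for a
  0.1-step three-parameter grid of 729 combinations × 50 agents; the
  package runs the full grid and treats 900 as a prose slip.
* The compiled engine consumes R's own RNG stream with a fixed draw order
  (lapse, choice, loss) and long-double accumulators, so `engine = "cpp"`
  and `engine = "r"` are bit-identical under a seed — a dual-route check
  the suite enforces, not an approximate equivalence.
* All multi-agent routines derive per-agent seeds as
  `agent_seed(master, counter)` (a Lehmer-style map into `[1, 2^31 − 1]`),
  so no result depends on how many agents ran before a given one.
* Degenerate inputs are defined, not accidental: `loss_prob ∈ {0, 1}`
  decks, `M ∈ {0, 1}` agents, all-equal matching values, flat power
  trajectories, and sub-4-subject cohorts all have stated behavior
  (uniform choice, no learning, uniform probabilities, `b = 0`, and a
  validation error respectively).

## Known limitations

* The model omits utility curvature, loss-aversion asymmetry beyond the
  linear sensitivities, decay of unchosen values (available behind a flag
  deliberately left off by default), and trial-dependent choice
  consistency.
* Fitting targets block-level preference only; trial-level likelihood
  methods would extract more information per subject but are out of scope.
* The advantageous labeling follows the source table verbatim despite its
  tension with the payoffs; users studying the classic task should relabel
  and re-derive directions before comparing.
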