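---
title: "Inferring strategies from long Iterated Prisoner's Dilemma experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring strategies from long Iterated Prisoner's Dilemma experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ipdinfer)
```

## Overview

`ipdinfer` infers behavioural strategies from round-by-round records of long
(≈100-round) Iterated Prisoner's Dilemma (IPD) sessions. Its pipeline has four
stages:

1. **Encoding.** Each player's play is rewritten as a sequence over an
   8-symbol *conditional-action* alphabet that couples the previous round's
   outcome (the *context*) to the player's current action.
2. **Contextual clustering.** Players are grouped by *which* situations they
   experienced (K-means on context counts).
3. **Behavioural sub-clustering.** Within each contextual cluster, players
   are grouped by *how* they responded (K-means on cooperative-response
   counts).
4. **Strategy models.** Each behavioural sub-cluster is summarised by a
   left-to-right multinomial hidden Markov model (HMM) fitted with a
   constrained Baum–Welch algorithm, plus memory-one conditional cooperation
   probabilities that are classified against canonical archetypes
   (AllC, AllD, TFT, GTFT, WSLS, Grim, Random).

A simulator of noisy memory-one cohorts provides ground-truthed synthetic
data, so every stage can be validated against planted strategies.

## The game and the simulator

Each round, two players simultaneously choose Cooperate (`C`) or Defect
(`D`). Payoffs come from the standard matrix with `R = 3` (mutual
cooperation), `S = 0` (sucker), `T = 4` (temptation), `P = 1` (mutual
defection); `payoff_matrix()` enforces `T > R > P > S` and `2R > T + S`, so
alternating exploitation cannot beat sustained cooperation.

Players are *memory-one* strategies: a cooperation probability for the first
round (`p_init`) and one per context (`p_cc`, `p_cd`, `p_dc`, `p_dd`), where
context `XY` means "I played `X`, my co-player played `Y` last round".
Execution noise `eps` flips the *executed* action with probability `eps`
independently each round; co-players observe (and condition on) executed
actions, so noise propagates through the interaction, as with human
implementation errors or mis-clicks.

Two matching modes mirror the two treatments the generator emulates:

* **FP (fixed partner):** one perfect matching held for the whole session.
  Partners are paired in cohort order (1–2, 3–4, ...), so a cohort built
  from archetype blocks pairs players within the same archetype block except
  at block boundaries. This keeps FP pairings deterministic and
  reproducible without an extra seed.
* **SP (shuffled partners):** a fresh uniformly random perfect matching each
  round, rejection-sampled so that no one meets the same partner in two
  consecutive rounds (requires at least 4 players).

Default cohort sizes follow the study conditions (92 players FP, 96 SP,
100 rounds, `eps = 0.05`); these defaults are fixed properties of the
emulated experiment, not tuning knobs.

```{r}
cohort <- archetype_cohort(c(TFT = 4, AllD = 4), noise = 0.05)
games <- simulate_cohort(cohort, n_rounds = 100, mode = "FP", seed = 1)
head(as.data.frame(games), 4)
```

The returned `game_table` carries the planted strategies as a
`ground_truth` attribute; `validate_game_table()` checks its structural
invariants (mirror symmetry, matching rules, payoff sums in
`{2R, T+S, 2P}`). `read_game_table()` accepts a `column_map` so real
experimental exports with foreign column names can enter the same pipeline.

## Conditional-action encoding

The alphabet has 8 symbols: `symbol = 2 * context_index + (action == "D")`
with contexts ordered `CC, CD, DC, DD`. So `(CC)C = 0`, `(CC)D = 1`, ...,
`(DD)D = 7`. Round 1 has no context and is excluded, so a `T`-round game
yields `T - 1` symbols per player.

```{r}
symbol_labels()
seqs <- player_sequences(games)
seqs[[1]][1:10]
```

Two marginal summaries drive clustering: the **context profile**
(`n_cc, ..., n_dd`: how often each situation arose) and the **behaviour
profile** (`c_cc, ..., c_dd`: how often the response was cooperative).
`action_profiles()` reports conditional cooperation `p = c / n` with `NA`
for never-experienced contexts rather than an arbitrary 0 — downstream code
excludes `NA` contexts pairwise instead of inventing data.

## Two-level clustering

Both levels use K-means (`stats::kmeans`) on raw counts (set
`normalize = TRUE` in `pipeline_config()` to use per-player frequencies
instead). Restarts are managed manually with seeded, distinct initial
centers drawn from the unique rows; this keeps results reproducible and
avoids duplicate-center failures on discrete count data.

The number of clusters is chosen by a kneedle-style elbow on the inertia
curve for `k = 1..K_max` (`K_max = 8` contextual, `6` behavioural by
default): the curve is min–max normalised, repaired to be non-increasing,
and the interior `k` with maximal vertical distance below the chord wins,
ties going to the smaller `k`. Flat curves fall back to `k = 2`, and
degenerate inputs (fewer distinct rows than needed for an interior elbow)
use the number of distinct rows, so a perfectly homogeneous noiseless
cohort yields a single cluster. Cluster quality is reported as the mean
silhouette width (`cluster::silhouette`). Note the elbow by construction
never selects the endpoints of the scanned range; `K_max` should therefore
exceed the number of groups you consider plausible by at least one.

Contextual clusters are labelled `A, B, ...` in decreasing size order;
behavioural sub-clusters get ids like `A.0`, `A.1`. Sub-clusters with fewer
than 4 members are not split further.

A known limitation: behavioural K-means on raw counts cannot separate
strategies whose count vectors differ only in coordinates with small
magnitude (e.g. TFT vs WSLS inside a mostly cooperative cluster, where the
discriminating contexts occur only a handful of times per game). The
archetype classification step, which uses conditional *probabilities*
rather than counts, is the more sensitive discriminator.

## Left-to-right HMMs

Each sub-cluster's symbol sequences are modelled by an `S`-state HMM with:

* start distribution fixed at `pi = (1, 0, ..., 0)`,
* upper-triangular transition matrix `A` (states can only advance —
  "phases" of play are irreversible within a session; `chain = TRUE`
  additionally restricts moves to the next state),
* an `S × 8` emission matrix `B` over the conditional-action alphabet.

`baum_welch()` is a hand-authored constrained EM: zeros in the transition
mask never resurrect, `pi` is never re-estimated, and the forward–backward
pass is scaled for numerical stability. Sequences of equal length are
batched into matrices so the per-iteration cost is a handful of `n × S`
matrix operations per time step — pure R, but fast enough that the full
test suite (hundreds of fits) runs in about two minutes. Emissions are
initialised from a Dirichlet(1) draw and transitions uniformly over the
allowed entries; `n_restarts = 5` seeded restarts guard against local
optima; convergence is a relative log-likelihood change below `1e-4`
(at most 500 iterations). The single-state model is fitted in closed form
(empirical symbol frequencies). Correctness is tested against brute-force
path enumeration of the likelihood and against parameter recovery from
sampled data.

```{r}
fit <- baum_welch(seqs, S = 2, seed = 1)
round(fit$A, 3)
round(fit$B, 3)
```

The number of states is chosen by `select_states()` scanning
`S = 1..S_max` (default 4). Two criteria are available, both pragmatic
stand-ins for a full model-selection study:

* `"gain"` (default): the smallest `S` whose relative log-likelihood gain
  over `S - 1` falls below `delta = 0.01`;
* `"bic"`: minimise BIC with
  `S(S+1)/2 - S` free transition parameters and `7S` emission parameters.

For display, `prune_for_display()` masks emission probabilities ≤ 0.05 and
transition probabilities ≤ 0.01 as `NA` *without renormalising the model* —
pruning is presentation, not inference. `hmm_to_dot()` renders the pruned
model as Graphviz DOT (initial state drawn with a heavy border), and
`write_hmm_json()`/`read_hmm_json()` round-trip models losslessly.

## Pipeline, archetypes and windows

`run_pipeline(games, pipeline_config(...))` runs all stages on one
treatment and returns player assignments, per-sub-cluster HMMs, pooled
conditional cooperation probabilities with binomial standard errors
`sqrt(p(1-p)/n)`, and archetype calls. `classify_archetype()` assigns the
archetype minimising the L1 distance on `(p_cc, p_cd, p_dc, p_dd)`,
excluding `NA` contexts pairwise; ties resolve in registry order.

```{r}
report <- run_pipeline(games, pipeline_config(seed = 1))
report$archetype_calls[, c("subcluster", "archetype", "distance")]
```

`window_analysis()` re-runs the analysis on consecutive windows of
(default) 25 rounds. Symbols are sliced from the *full* encoded sequence,
so windows after the first keep the context carried over from the previous
window's last round: a 100-round game gives windows of 24/25/25/25 symbols.
This makes mid-session strategy changes visible as shifts in the dominant
context and in the per-window models.

`first_round_cooperation()` and `questionnaire_percentage()` (a plain
`round(100 * yes / total, 2)`) cover the remaining descriptive statistics
of such experiments.

## Parameter defaults at a glance

| Parameter | Default | Rationale |
|---|---|---|
| payoffs `R,S,T,P` | 3, 0, 4, 1 | standard IPD matrix satisfying both dilemma conditions |
| `n_rounds` | 100 | long-game regime the method targets |
| `noise` | 0.05 | execution-error rate of the emulated conditions |
| `K_max_context` / `K_max_behavior` | 8 / 6 | elbow needs interior room above plausible group counts |
| `S_max` | 4 | phases of play stay interpretable; gains beyond 4 states are marginal on this alphabet |
| `delta` | 0.01 | relative log-likelihood gain considered negligible |
| `hmm_tol`, `hmm_max_iter` | 1e-4, 500 | EM converges far earlier on these data; caps are safety nets |
| `n_restarts_hmm` / `n_restarts_kmeans` | 5 / 10 | local-optimum insurance at modest cost |
| display thresholds | 0.05 emission, 0.01 transition | hide numerically negligible arcs without altering the model |

## Scope and caveats

* The simulator emulates *memory-one* players with i.i.d. execution noise.
  Real humans drift, learn and use longer memories; the HMM layer captures
  some of that (phase changes), the memory-one classification does not.
* `select_states()` criteria are heuristics; for publication-grade state
  counts, inspect the full selection table (`attr(sel, "selection")`) and
  the fitted models.
* All randomised components take explicit seeds and are deterministic given
  them; seeds must be below 2^31.
* Problem sizes validated in the test suite: cohorts up to 96 players ×
  100 rounds, HMM fits on 50 sequences × 100 symbols, scanned up to
  `S_max = 4`, all on a single CPU.
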