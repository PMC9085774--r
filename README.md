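# ipdinfer

Strategy inference for long Iterated Prisoner's Dilemma (IPD) experiments.

`ipdinfer` takes round-by-round records of ~100-round IPD sessions — either
simulated with its own ground-truthed generator or imported from real
experimental exports — and infers what strategies the players were using. It
is aimed at behavioural game theorists and experimental economists who run
long repeated-game sessions and want more than aggregate cooperation rates.

## Method

Each player's play is encoded over an 8-symbol **conditional-action
alphabet**: symbol `2*ctx + [action == D]`, where `ctx` indexes the previous
round's outcome (`CC, CD, DC, DD`, own action first). Round 1 has no context,
so a `T`-round game yields `T − 1` symbols.

Inference then proceeds in three stages:

1. **Contextual clustering** — K-means on each player's context counts
   (*which* situations they faced), with the number of clusters chosen by a
   kneedle-style elbow on the inertia curve and quality reported as mean
   silhouette width.
2. **Behavioural sub-clustering** — within each contextual cluster, K-means
   on cooperative-response counts (*how* they responded).
3. **Strategy models** — each sub-cluster is summarised by a left-to-right
   multinomial HMM (fixed start state, upper-triangular transitions) fitted
   with a constrained Baum–Welch algorithm, plus pooled conditional
   cooperation probabilities `(p_cc, p_cd, p_dc, p_dd)` with binomial
   standard errors, classified against canonical memory-one archetypes
   (AllC, AllD, TFT, GTFT, WSLS, Grim, Random) by L1 distance.

The bundled simulator plays cohorts of noisy memory-one strategies under the
standard payoff matrix (R=3, S=0, T=4, P=1) in two matching modes — fixed
partner (FP) and round-wise shuffled partners (SP, never the same partner
twice in a row) — with execution noise that flips played actions and is
observed by the co-player. Every simulated table carries its planted ground
truth, so the whole pipeline is testable against known answers.

`window_analysis()` repeats the analysis on consecutive 25-round windows
(24/25/25/25 symbols for a 100-round game) to expose mid-session strategy
changes. See the vignette (`vignettes/strategy-inference.Rmd`) for the full
model description, parameter rationale and caveats.

## Worked example

Simulate a 90-player fixed-partner cohort of three planted strategy groups
and run the full pipeline:

```r
library(ipdinfer)

cohort <- archetype_cohort(c(AllC = 30, AllD = 30, Random = 30), noise = 0.05)
games  <- simulate_cohort(cohort, n_rounds = 100, mode = "FP", seed = 11)
report <- run_pipeline(games, pipeline_config(seed = 11))

report$summary
#>   treatment cluster  n n_subclusters silhouette
#> 1        FP       A 30             3  0.4130288
#> 2        FP       B 30             2  0.2922369
#> 3        FP       C 30             2  0.4816035

report$archetype_calls[, c("subcluster", "archetype", "distance")]
#>   subcluster archetype   distance
#> 1        A.0      AllC 0.01677149
#> 2        A.1      AllC 0.34265692
#> 3        A.2      AllC 0.21798341
#> 4        B.0    Random 0.12915683
#> 5        B.1    Random 0.18227699
#> 6        C.0      AllD 0.20015692
#> 7        C.1      AllD 0.15129393

first_round_cooperation(games)
#> [1] 0.5333333
```

The contextual level recovers the three planted groups exactly (clusters A,
B, C of 30 players each), and every sub-cluster is classified as its planted
archetype. `report$hmms` holds the fitted HMM per sub-cluster;
`prune_for_display()`, `hmm_to_dot()` and `write_report()` turn a report
into CSVs, JSON models and Graphviz diagrams. Real data enters through
`read_game_table(path, column_map = ...)`.

## Reproducing results

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch against the installed package and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It simulates mixed FP (92-player) and SP (96-player) cohorts and reports
cluster counts, silhouettes, cooperation rates and mean HMM sizes; measures
contextual-clustering recovery (adjusted Rand index and elbow accuracy) on
planted three-group cohorts; measures end-to-end archetype recovery on pure
92-player cohorts; checks Baum–Welch parameter recovery and state selection
on data sampled from a known two-state model; and reports the questionnaire
percentages. All randomness derives from `--seed`; the run takes about two
minutes on one CPU.
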