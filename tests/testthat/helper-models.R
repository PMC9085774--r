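# Shared fixtures and independent oracles, built in code.

# Brute-force HMM likelihood: enumerate every hidden state path. Independent
# of the scaled forward recursion it checks; only usable at tiny S and T.
brute_force_loglik <- function(A, B, pi, symbols) {
  S <- nrow(A)
  T <- length(symbols)
  obs <- symbols + 1L
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    p <- pi[path[1]] * B[path[1], obs[1]]
    for (t in seq_len(T - 1)) {
      p <- p * A[path[t], path[t + 1]] * B[path[t + 1], obs[t + 1]]
    }
    total <- total + p
  }
  log(total)
}

# Random left-to-right model with pi = e1.
random_lr_model <- function(S) {
  A <- matrix(0, S, S)
  for (i in seq_len(S)) {
    w <- stats::rexp(S - i + 1)
    A[i, i:S] <- w / sum(w)
  }
  B <- matrix(stats::rexp(S * 8), S, 8)
  B <- B / rowSums(B)
  lr_hmm(A, B)
}

# Adjusted Rand index between two labelings (closed-form from the pair
# contingency table); independent of any clustering code under test.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Planted-cohort simulation used by several recovery tests.
planted_three_group <- function(seed, n_per_group = 30, noise = 0.05,
                                n_rounds = 100) {
  cohort <- archetype_cohort(
    c(AllC = n_per_group, AllD = n_per_group, Random = n_per_group),
    noise = noise)
  simulate_cohort(cohort, n_rounds, "FP", seed = seed)
}

# A hand-built game table: players switch from mutual defection to mutual
# cooperation at a given round (not expressible as a memory-one strategy).
switch_game_table <- function(n_players = 10, n_rounds = 100,
                              switch_round = 51) {
  rows <- list()
  for (p in seq(1, n_players, by = 2)) {
    a <- sprintf("P%02d", p)
    b <- sprintf("P%02d", p + 1)
    act <- ifelse(seq_len(n_rounds) < switch_round, "D", "C")
    pay <- payoffs(act, act)[, "focal"]
    rows[[a]] <- data.frame(treatment = "FP", session = "S1",
                            round = seq_len(n_rounds), player = a,
                            opponent = b, action = act, opp_action = act,
                            payoff = pay, stringsAsFactors = FALSE)
    rows[[b]] <- data.frame(treatment = "FP", session = "S1",
                            round = seq_len(n_rounds), player = b,
                            opponent = a, action = act, opp_action = act,
                            payoff = pay, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("game_table", "data.frame")
  out
}
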