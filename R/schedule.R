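#' Build a round-by-round pairing schedule
#'
#' Fixed partners (`"FP"`) pairs consecutive players (1-2, 3-4, ...) and
#' repeats that perfect matching every round, so an archetype-ordered cohort
#' is paired within archetype blocks. Shuffled partners (`"SP"`) draws an
#' independent uniform random perfect matching each round, resampled until no
#' player keeps the opponent of the immediately preceding round (the weakest
#' reading of "the opponent changes each round"); no constraint is placed on
#' re-meeting an opponent from earlier rounds.
#'
#' @param n_players Even number of players, >= 2 (>= 4 for SP, where the
#'   no-repeat constraint is otherwise unsatisfiable).
#' @param n_rounds Number of rounds, >= 1.
#' @param mode `"FP"` or `"SP"`.
#' @param seed RNG seed used for the SP matchings.
#' @return Integer matrix of dimension `n_rounds x n_players`;
#'   entry `[r, i]` is the opponent of player `i` in round `r`. The matching
#'   is symmetric: `schedule[r, schedule[r, i]] == i`.
#' @examples
#' make_schedule(4, 3, "FP")
#' @export
make_schedule <- function(n_players, n_rounds, mode = c("FP", "SP"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (n_players < 2 || n_players %% 2 != 0) {
    stop("`n_players` must be an even integer >= 2", call. = FALSE)
  }
  stopifnot(n_rounds >= 1)
  if (mode == "FP") {
    opp <- integer(n_players)
    opp[seq(1, n_players, by = 2)] <- seq(2, n_players, by = 2)
    opp[seq(2, n_players, by = 2)] <- seq(1, n_players, by = 2)
    return(matrix(rep(opp, each = n_rounds), nrow = n_rounds))
  }
  if (n_players < 4) {
    stop("SP requires >= 4 players: with 2 players the opponent cannot change",
         call. = FALSE)
  }
  with_seed(seed, {
    sched <- matrix(0L, nrow = n_rounds, ncol = n_players)
    prev <- rep(0L, n_players)
    for (r in seq_len(n_rounds)) {
      repeat {
        perm <- sample.int(n_players)
        opp <- integer(n_players)
        opp[perm[c(TRUE, FALSE)]] <- perm[c(FALSE, TRUE)]
        opp[perm[c(FALSE, TRUE)]] <- perm[c(TRUE, FALSE)]
        if (!any(opp == prev)) break
      }
      sched[r, ] <- opp
      prev <- opp
    }
    sched
  })
}
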