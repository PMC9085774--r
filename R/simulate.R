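#' Simulate an IPD cohort with known ground-truth strategies
#'
#' Plays `n_rounds` of the Iterated Prisoner's Dilemma among the given
#' memory-one players under fixed- or shuffled-partner matching. Each round,
#' every player draws an intended action from their strategy's cooperation
#' probability for the context they experienced in the previous round (the
#' opening round uses `p_init`); execution noise then flips the intended
#' action with the strategy's noise probability, and the co-player observes
#' the executed action. Contexts are always taken from the immediately
#' preceding round, even under shuffled partners where that round was played
#' against someone else — mirroring what a participant actually saw.
#'
#' @param cohort List of [strategy_spec()] objects; even length.
#' @param n_rounds Number of rounds (default 100).
#' @param mode `"FP"` (fixed partners) or `"SP"` (shuffled partners).
#' @param m A [payoff_matrix()].
#' @param seed RNG seed; the full game table is reproducible given the seed.
#' @param session Session label stored in the table.
#' @return A `game_table`: a data frame with one row per player per round and
#'   columns `treatment, session, round, player, opponent, action,
#'   opp_action, payoff`. The planted strategies are attached as attribute
#'   `"ground_truth"` (a data frame `player, strategy_name, p_init, p_cc,
#'   p_cd, p_dc, p_dd, noise`), retrievable with [ground_truth()].
#' @examples
#' g <- simulate_cohort(archetype_cohort(c(TFT = 2)), n_rounds = 5,
#'                      mode = "FP", seed = 1)
#' head(g)
#' @export
simulate_cohort <- function(cohort, n_rounds = 100, mode = c("FP", "SP"),
                            m = payoff_matrix(), seed = NULL,
                            session = "S1") {
  mode <- match.arg(mode)
  stopifnot(length(cohort) >= 2, n_rounds >= 1)
  if (length(cohort) %% 2 != 0) {
    stop("cohort size must be even", call. = FALSE)
  }
  if (!all(vapply(cohort, inherits, logical(1), "strategy_spec"))) {
    stop("`cohort` must be a list of strategy_spec objects", call. = FALSE)
  }
  n <- length(cohort)
  ids <- sprintf("P%0*d", max(2L, nchar(n)), seq_len(n))
  # conditional cooperation probabilities, one row per player
  probs <- t(vapply(cohort, function(s) {
    c(s$p_init, s$p_cc, s$p_cd, s$p_dc, s$p_dd, s$noise)
  }, numeric(6)))
  colnames(probs) <- c("p_init", "p_cc", "p_cd", "p_dc", "p_dd", "noise")

  with_seed(seed, {
    sched <- make_schedule(n, n_rounds, mode,
                           seed = sample.int(.Machine$integer.max, 1))
    act <- matrix("", nrow = n_rounds, ncol = n)
    for (r in seq_len(n_rounds)) {
      if (r == 1) {
        p_coop <- probs[, "p_init"]
      } else {
        own_prev <- act[r - 1, ]
        opp_prev <- act[r - 1, sched[r - 1, ]]
        ctx <- 2L * (own_prev == "D") + (opp_prev == "D") + 1L  # CC,CD,DC,DD
        p_coop <- probs[cbind(seq_len(n), 1L + ctx)]
      }
      intended <- ifelse(stats::runif(n) < p_coop, "C", "D")
      flip <- stats::runif(n) < probs[, "noise"]
      act[r, ] <- ifelse(flip, ifelse(intended == "C", "D", "C"), intended)
    }

    round_col <- rep(seq_len(n_rounds), each = n)
    player_col <- rep(seq_len(n), times = n_rounds)
    opp_col <- as.integer(t(sched))
    own_a <- as.character(t(act))
    opp_a <- act[cbind(round_col, opp_col)]
    pay <- payoffs(own_a, opp_a, m)[, "focal"]

    games <- data.frame(
      treatment = mode,
      session = session,
      round = round_col,
      player = ids[player_col],
      opponent = ids[opp_col],
      action = own_a,
      opp_action = opp_a,
      payoff = pay,
      stringsAsFactors = FALSE
    )
    gt <- data.frame(
      player = ids,
      strategy_name = vapply(cohort, `[[`, character(1), "name"),
      probs,
      stringsAsFactors = FALSE
    )
    attr(games, "ground_truth") <- gt
    class(games) <- c("game_table", "data.frame")
    games
  })
}

#' Planted strategies of a simulated game table
#'
#' @param games A `game_table` produced by [simulate_cohort()] or read with a
#'   ground-truth sidecar.
#' @return Data frame `player, strategy_name, p_init, p_cc, p_cd, p_dc,
#'   p_dd, noise`, or `NULL` for imported tables without ground truth.
#' @export
ground_truth <- function(games) {
  attr(games, "ground_truth")
}

#' @export
print.game_table <- function(x, ...) {
  cat(sprintf("<game_table> %s: %d players, %d rounds, %d rows\n",
              paste(unique(x$treatment), collapse = "+"),
              length(unique(x$player)), max(x$round), nrow(x)))
  NextMethod()
}

#' Validate game-table invariants
#'
#' Checks that every player appears exactly once per round, that pairings are
#' symmetric (`action`/`opp_action` mirror across a pair), that FP opponents
#' never change while SP opponents always differ from the previous round's,
#' and that each pair-round payoff sum is one of `2R`, `T+S`, `2P`.
#'
#' @param games A `game_table` data frame.
#' @param m The [payoff_matrix()] the table was generated under.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_game_table <- function(games, m = payoff_matrix()) {
  need <- c("treatment", "round", "player", "opponent", "action",
            "opp_action", "payoff")
  missing_cols <- setdiff(need, names(games))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(games[c("round", "player")])) {
    stop("a player appears more than once in a round", call. = FALSE)
  }
  key <- function(p, o, r) paste(p, o, r, sep = "\r")
  mirror <- match(key(games$opponent, games$player, games$round),
                  key(games$player, games$opponent, games$round))
  if (anyNA(mirror)) stop("pairing is not symmetric", call. = FALSE)
  if (!all(games$opp_action == games$action[mirror])) {
    stop("action/opp_action do not mirror across pairs", call. = FALSE)
  }
  pair_sum <- games$payoff + games$payoff[mirror]
  if (!all(pair_sum %in% c(2 * m$R, m$T + m$S, 2 * m$P))) {
    stop("pair-round payoff sums violate the payoff matrix", call. = FALSE)
  }
  expected <- payoffs(games$action, games$opp_action, m)[, "focal"]
  if (!all(games$payoff == expected)) {
    stop("payoff column inconsistent with actions", call. = FALSE)
  }
  for (tr in unique(games$treatment)) {
    gt <- games[games$treatment == tr, ]
    opp_by_round <- split(gt[order(gt$round, gt$player), "opponent"],
                          gt[order(gt$round, gt$player), "player"])
    if (tr == "FP") {
      if (any(vapply(opp_by_round,
                     function(o) length(unique(o)) != 1L, logical(1)))) {
        stop("FP opponent changed between rounds", call. = FALSE)
      }
    } else if (tr == "SP") {
      if (any(vapply(opp_by_round,
                     function(o) any(o[-1] == o[-length(o)]), logical(1)))) {
        stop("SP player met the same opponent in consecutive rounds",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
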