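#' The conditional-action alphabet
#'
#' Each round's decision is summarized by a *conditional action*: the pair of
#' the previous round's context (own action, opponent action, written
#' player-then-opponent) and the action played after observing it. The eight
#' pairs map bijectively onto the integers 0..7:
#'
#' | symbol | 0 | 1 | 2 | 3 | 4 | 5 | 6 | 7 |
#' |---|---|---|---|---|---|---|---|---|
#' | pair | (CC)C | (CC)D | (CD)C | (CD)D | (DC)C | (DC)D | (DD)C | (DD)D |
#'
#' @return Character vector of the 8 human-readable labels, in symbol order.
#' @examples
#' symbol_labels()
#' @export
symbol_labels <- function() {
  paste0("(", rep(CONTEXTS, each = 2), ")", rep(ACTIONS, times = 4))
}

#' Encode a (context, action) pair as a symbol
#'
#' @param context Context label(s) in `CC, CD, DC, DD`.
#' @param action Action(s) `"C"` or `"D"`.
#' @return Integer symbol(s) in 0..7. Vectorized.
#' @examples
#' encode_pair("CC", "C")  # 0
#' encode_pair("DD", "D")  # 7
#' @export
encode_pair <- function(context, action) {
  check_contexts(context)
  check_actions(action)
  2L * (match(context, CONTEXTS) - 1L) + (action == "D")
}

#' Decode symbols back to (context, action) pairs
#'
#' Exact inverse of [encode_pair()].
#'
#' @param symbol Integer symbol(s) in 0..7.
#' @return Data frame with columns `context` and `action`.
#' @export
decode_symbol <- function(symbol) {
  if (!all(symbol %in% 0:7)) {
    stop("symbols must be integers in 0..7", call. = FALSE)
  }
  data.frame(context = CONTEXTS[symbol %/% 2L + 1L],
             action = ACTIONS[symbol %% 2L + 1L],
             stringsAsFactors = FALSE)
}

#' Encode an action sequence as conditional-action symbols
#'
#' The symbol for round t combines the context given by round t-1's (own,
#' opponent) actions with the own action at round t; round 1 has no context
#' and contributes no symbol, so T rounds yield T-1 symbols.
#'
#' @param own_actions,opp_actions Equal-length character vectors of
#'   `"C"`/`"D"`, ordered by round; length >= 2.
#' @return Integer vector of symbols in 0..7, length `T - 1`.
#' @examples
#' sequence_encode(c("C", "D", "D"), c("D", "D", "D"))  # (CD)D, (DD)D = 3 7
#' @export
sequence_encode <- function(own_actions, opp_actions) {
  T <- length(own_actions)
  if (length(opp_actions) != T) {
    stop("own and opponent action sequences must have equal length",
         call. = FALSE)
  }
  if (T < 2) stop("need at least 2 rounds to encode", call. = FALSE)
  ctx <- paste0(own_actions[-T], opp_actions[-T])
  encode_pair(ctx, own_actions[-1])
}

#' Per-player conditional-action sequences of a game table
#'
#' @param games A `game_table` (one treatment).
#' @return Named list of integer symbol vectors, one per player, ordered by
#'   round. Players with fewer than 2 rounds are dropped.
#' @export
player_sequences <- function(games) {
  if (nrow(games) == 0) stop("empty game table", call. = FALSE)
  games <- games[order(games$player, games$round), ]
  seqs <- lapply(split(games[c("action", "opp_action")], games$player),
                 function(d) {
                   if (nrow(d) < 2) return(NULL)
                   sequence_encode(d$action, d$opp_action)
                 })
  Filter(Negate(is.null), seqs)
}

#' Context and behavior profiles of a symbol sequence
#'
#' Tallies, per context, how often it was experienced (`n_cc` ... `n_dd`) and
#' how often the response was cooperative (`c_cc` ... `c_dd`). Conditional
#' cooperation probabilities `c_X / n_X` are reported only for contexts that
#' were experienced; never-experienced contexts carry `NA`, an explicit
#' missing flag, never an imputed value.
#'
#' @param symbols Non-empty integer vector of symbols in 0..7.
#' @return List of class `action_profile` with components `n` (context
#'   counts, named `cc, cd, dc, dd`), `c` (cooperative-response counts) and
#'   `p` (conditional cooperation, `NA` where `n` is 0).
#' @examples
#' action_profiles(c(0, 0, 1))$p  # p(C|CC) = 2/3
#' @export
action_profiles <- function(symbols) {
  if (length(symbols) == 0) stop("empty symbol sequence", call. = FALSE)
  if (!all(symbols %in% 0:7)) {
    stop("symbols must be integers in 0..7", call. = FALSE)
  }
  ctx_names <- tolower(CONTEXTS)
  counts <- tabulate(symbols + 1L, nbins = 8L)
  n <- counts[c(1, 3, 5, 7)] + counts[c(2, 4, 6, 8)]
  cc <- counts[c(1, 3, 5, 7)]
  names(n) <- names(cc) <- ctx_names
  p <- ifelse(n > 0, cc / n, NA_real_)
  names(p) <- ctx_names
  structure(list(n = n, c = cc, p = p), class = "action_profile")
}

#' Per-player profile table for a set of sequences
#'
#' @param seqs Named list of symbol sequences (see [player_sequences()]).
#' @return Data frame `player, n_cc, n_cd, n_dc, n_dd, c_cc, c_cd, c_dc,
#'   c_dd`, one row per player — the feature tables of the two clustering
#'   levels.
#' @export
profile_table <- function(seqs) {
  if (length(seqs) == 0) stop("no sequences", call. = FALSE)
  rows <- lapply(seqs, function(s) {
    pr <- action_profiles(s)
    c(pr$n, pr$c)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("n_", tolower(CONTEXTS)),
                   paste0("c_", tolower(CONTEXTS)))
  data.frame(player = names(seqs), m, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pooled context frequencies and cooperation per treatment
#'
#' Pools all players' conditional actions of one treatment and reports, per
#' context, its relative frequency and the fraction of cooperative responses
#' that followed it.
#'
#' @param games A `game_table`.
#' @param treatment Optional treatment label to subset on (`"FP"`/`"SP"`).
#' @return Data frame `context, frequency, coop_fraction`; frequencies sum
#'   to 1, `coop_fraction` is `NA` for contexts never experienced.
#' @export
treatment_summary <- function(games, treatment = NULL) {
  if (!is.null(treatment)) games <- games[games$treatment == treatment, ]
  if (nrow(games) == 0) stop("empty game table", call. = FALSE)
  seqs <- player_sequences(games)
  if (length(seqs) == 0) stop("no player has >= 2 rounds", call. = FALSE)
  all_symbols <- unlist(seqs, use.names = FALSE)
  pr <- action_profiles(all_symbols)
  data.frame(context = CONTEXTS,
             frequency = as.vector(pr$n) / sum(pr$n),
             coop_fraction = as.vector(pr$p),
             stringsAsFactors = FALSE)
}

#' Write per-player profiles to CSV
#'
#' @param profiles Output of [profile_table()].
#' @param path CSV path with header
#'   `player,n_cc,n_cd,n_dc,n_dd,c_cc,c_cd,c_dc,c_dd`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
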