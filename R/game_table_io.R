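#' Write a game table (and optional ground-truth sidecar) to CSV
#'
#' @param games A `game_table`.
#' @param path Output CSV path; header
#'   `treatment,session,round,player,opponent,action,opp_action,payoff`.
#' @param ground_truth_path Optional path for the planted-strategy sidecar
#'   (`player,strategy_name,p_init,p_cc,p_cd,p_dc,p_dd,noise`); written only
#'   when the table carries ground truth.
#' @return `path`, invisibly.
#' @export
write_game_table <- function(games, path, ground_truth_path = NULL) {
  cols <- c("treatment", "session", "round", "player", "opponent",
            "action", "opp_action", "payoff")
  utils::write.csv(as.data.frame(games)[cols], path, row.names = FALSE,
                   quote = FALSE)
  gt <- ground_truth(games)
  if (!is.null(ground_truth_path) && !is.null(gt)) {
    utils::write.csv(gt, ground_truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a game table from CSV
#'
#' Reads a long-format game table: one row per player per round. Deposited
#' data with different column names (e.g. a public archive of the
#' experiments) can be adapted at run time through `column_map`, a named
#' character vector mapping the canonical names to the file's names; no
#' assumption is made about session structure or pairing beyond the table
#' itself.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector, e.g.
#'   `c(player = "subject_id", action = "choice")`; unmapped canonical
#'   columns must be present under their own names. A `session` column is
#'   optional and defaults to `"S1"`; `payoff` is recomputed from actions
#'   when absent.
#' @param m [payoff_matrix()] used to fill a missing `payoff` column.
#' @param ground_truth_path Optional sidecar CSV of planted strategies.
#' @return A `game_table` data frame.
#' @export
read_game_table <- function(path, column_map = NULL, m = payoff_matrix(),
                            ground_truth_path = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(raw)) {
        stop(sprintf("mapped column `%s` not found in %s", src, path),
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  if (!"session" %in% names(raw)) raw$session <- "S1"
  need <- c("treatment", "round", "player", "opponent", "action", "opp_action")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  check_actions(raw$action)
  check_actions(raw$opp_action, "opp_action")
  if (!"payoff" %in% names(raw)) {
    raw$payoff <- payoffs(raw$action, raw$opp_action, m)[, "focal"]
  }
  raw$player <- as.character(raw$player)
  raw$opponent <- as.character(raw$opponent)
  games <- raw[c("treatment", "session", "round", "player", "opponent",
                 "action", "opp_action", "payoff")]
  if (!is.null(ground_truth_path)) {
    attr(games, "ground_truth") <-
      utils::read.csv(ground_truth_path, stringsAsFactors = FALSE)
  }
  class(games) <- c("game_table", "data.frame")
  games
}
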