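#' Per-round payoff matrix of the Prisoner's Dilemma
#'
#' Defaults are the rewards used in both treatments: mutual cooperation pays
#' R = 3 each, a unilateral defector earns the temptation T = 4 against the
#' sucker's payoff S = 0, and mutual defection pays P = 1 each. The dilemma
#' requires T > R > P > S and 2R > T + S (so alternating exploitation cannot
#' beat sustained mutual cooperation).
#'
#' @param R,S,T,P Integer per-round rewards.
#' @return An object of class `payoff_matrix`.
#' @examples
#' payoff_matrix()
#' @export
payoff_matrix <- function(R = 3, S = 0, T = 4, P = 1) {
  stopifnot(is.numeric(c(R, S, T, P)))
  if (!(T > R && R > P && P > S)) {
    stop("payoff ordering T > R > P > S violated", call. = FALSE)
  }
  if (!(2 * R > T + S)) {
    stop("2R > T + S violated: mutual cooperation must beat alternation",
         call. = FALSE)
  }
  structure(list(R = R, S = S, T = T, P = P), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("<payoff_matrix> R=%g S=%g T=%g P=%g\n", x$R, x$S, x$T, x$P))
  invisible(x)
}

#' Per-round payoffs for a pair of actions
#'
#' @param action_a,action_b Actions (`"C"`/`"D"`) of the focal player and the
#'   co-player. Vectorized; vectors are recycled to a common length.
#' @param m A [payoff_matrix()].
#' @return Numeric matrix with columns `focal` and `other`.
#' @examples
#' payoffs("D", "C")  # temptation vs sucker: 4, 0
#' @export
payoffs <- function(action_a, action_b, m = payoff_matrix()) {
  stopifnot(inherits(m, "payoff_matrix"))
  check_actions(action_a)
  check_actions(action_b)
  n <- max(length(action_a), length(action_b))
  a <- rep_len(action_a, n)
  b <- rep_len(action_b, n)
  # rows of the 2x2 table indexed by (own, other)
  tab <- matrix(c(m$R, m$S, m$T, m$P), nrow = 2, byrow = TRUE,
                dimnames = list(ACTIONS, ACTIONS))
  cbind(focal = tab[cbind(a, b)], other = tab[cbind(b, a)])
}
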