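#' Define a stochastic memory-one strategy
#'
#' A memory-one strategy is fully described by the probability of cooperating
#' in the opening round plus four conditional cooperation probabilities, one
#' per previous-round context. Contexts are written player-then-opponent:
#' `CD` means the focal player cooperated and the opponent defected in the
#' previous round. Execution noise flips the intended action with the given
#' probability; the co-player observes the executed (noisy) action.
#'
#' @param name Strategy label.
#' @param p_init Probability of playing C in round 1.
#' @param p_cc,p_cd,p_dc,p_dd Probability of playing C after contexts
#'   CC, CD, DC, DD respectively.
#' @param noise Per-action execution-error probability in \[0, 1\].
#' @return An object of class `strategy_spec`.
#' @examples
#' strategy_spec("TFT", 1, 1, 0, 1, 0, noise = 0.05)
#' @export
strategy_spec <- function(name, p_init, p_cc, p_cd, p_dc, p_dd, noise = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  for (arg in c("p_init", "p_cc", "p_cd", "p_dc", "p_dd", "noise")) {
    check_probability(get(arg), arg)
  }
  structure(
    list(name = name, p_init = p_init,
         p_cc = p_cc, p_cd = p_cd, p_dc = p_dc, p_dd = p_dd,
         noise = noise),
    class = "strategy_spec"
  )
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf(
    "<strategy_spec> %s: p_init=%.3g, (CC,CD,DC,DD) -> C with (%.3g, %.3g, %.3g, %.3g), noise=%.3g\n",
    x$name, x$p_init, x$p_cc, x$p_cd, x$p_dc, x$p_dd, x$noise))
  invisible(x)
}

#' Registry of classic memory-one archetypes
#'
#' The canonical strategies of the repeated-games literature, parameterized
#' as `(p_init, p_cc, p_cd, p_dc, p_dd)`:
#' AllC (1,1,1,1,1), AllD (0,0,0,0,0), TFT (1,1,0,1,0),
#' GTFT (1,1,1/3,1,1/3), WSLS (1,1,0,0,1), Grim (1,1,0,0,0) and
#' Random (.5,.5,.5,.5,.5). Grim is the memory-one approximation of the
#' trigger strategy (true Grim conditions on the whole history).
#'
#' @param noise Execution noise applied to every archetype.
#' @return Named list of [strategy_spec()] objects, in canonical order.
#'   The order is the tie-break order used by [classify_archetype()].
#' @examples
#' names(archetype_registry())
#' @export
archetype_registry <- function(noise = 0) {
  specs <- list(
    AllC   = c(1, 1, 1, 1, 1),
    AllD   = c(0, 0, 0, 0, 0),
    TFT    = c(1, 1, 0, 1, 0),
    GTFT   = c(1, 1, 1 / 3, 1, 1 / 3),
    WSLS   = c(1, 1, 0, 0, 1),
    Grim   = c(1, 1, 0, 0, 0),
    Random = c(0.5, 0.5, 0.5, 0.5, 0.5)
  )
  out <- lapply(names(specs), function(nm) {
    p <- specs[[nm]]
    strategy_spec(nm, p[1], p[2], p[3], p[4], p[5], noise = noise)
  })
  names(out) <- names(specs)
  out
}

#' Build a cohort of archetype players
#'
#' Convenience constructor: a named count vector such as
#' `c(AllC = 10, TFT = 10)` becomes a list of [strategy_spec()] objects with
#' the requested execution noise, in the given order (useful together with
#' the consecutive fixed-partner pairing of [make_schedule()], which then
#' pairs players within an archetype block when counts are even).
#'
#' @param counts Named integer vector; names must be registry archetypes.
#' @param noise Execution noise for every player.
#' @return List of `strategy_spec` objects of length `sum(counts)`.
#' @examples
#' cohort <- archetype_cohort(c(AllC = 4, AllD = 4), noise = 0.05)
#' @export
archetype_cohort <- function(counts, noise = 0) {
  registry <- archetype_registry(noise = noise)
  bad <- setdiff(names(counts), names(registry))
  if (length(bad) > 0) {
    stop("unknown archetype(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unlist(lapply(names(counts), function(nm) {
    rep(registry[nm], counts[[nm]])
  }), recursive = FALSE, use.names = FALSE)
}

#' Sample one action from a memory-one strategy
#'
#' Draws the intended action (C with the strategy's initial or conditional
#' cooperation probability for the given context), then flips it with the
#' strategy's execution-noise probability.
#'
#' @param strategy A [strategy_spec()].
#' @param context One of `"none"` (round 1 only), `"CC"`, `"CD"`, `"DC"`,
#'   `"DD"`.
#' @return `"C"` or `"D"`.
#' @examples
#' play_action(archetype_registry()$TFT, "DC")  # copies opponent's C
#' @export
play_action <- function(strategy, context) {
  stopifnot(inherits(strategy, "strategy_spec"))
  check_contexts(context, allow_none = TRUE)
  p <- switch(context,
    none = strategy$p_init,
    CC = strategy$p_cc, CD = strategy$p_cd,
    DC = strategy$p_dc, DD = strategy$p_dd)
  intended <- if (stats::runif(1) < p) "C" else "D"
  if (stats::runif(1) < strategy$noise) {
    intended <- if (intended == "C") "D" else "C"
  }
  intended
}
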