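# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

ACTIONS  <- c("C", "D")
CONTEXTS <- c("CC", "CD", "DC", "DD")

check_actions <- function(x, arg = "action") {
  if (!all(x %in% ACTIONS)) {
    stop(sprintf("invalid %s label(s): %s", arg,
                 paste(unique(setdiff(x, ACTIONS)), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_contexts <- function(x, allow_none = FALSE) {
  valid <- if (allow_none) c("none", CONTEXTS) else CONTEXTS
  if (!all(x %in% valid)) {
    stop(sprintf("invalid context label(s): %s",
                 paste(unique(setdiff(x, valid)), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, arg) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", arg), call. = FALSE)
  }
  invisible(x)
}
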