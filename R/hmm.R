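#' Left-to-right multinomial hidden Markov model
#'
#' Constructs an HMM over the 8-symbol conditional-action alphabet with a
#' sequential (left-to-right) state topology: states are ordered, the chain
#' always starts in state 1 (the initial distribution is fixed to
#' `(1, 0, ..., 0)`), and transitions never return to an earlier state, i.e.
#' the transition matrix is upper triangular. Skipping ahead over states is
#' allowed unless the model was fit with `chain = TRUE`.
#'
#' @param A S x S row-stochastic transition matrix, zero below the diagonal.
#' @param B S x 8 row-stochastic emission matrix over symbols 0..7.
#' @param log_likelihood Optional training log-likelihood.
#' @param n_sequences,total_symbols Optional training metadata.
#' @return An object of class `lr_hmm`.
#' @export
lr_hmm <- function(A, B, log_likelihood = NA_real_,
                   n_sequences = NA_integer_, total_symbols = NA_integer_) {
  A <- as.matrix(A); B <- as.matrix(B)
  S <- nrow(A)
  stopifnot(ncol(A) == S, nrow(B) == S, ncol(B) == 8)
  if (any(abs(rowSums(A) - 1) > 1e-9) || any(abs(rowSums(B) - 1) > 1e-9)) {
    stop("rows of A and B must sum to 1", call. = FALSE)
  }
  if (S > 1 && any(A[lower.tri(A)] != 0)) {
    stop("A must be upper triangular (left-to-right topology)", call. = FALSE)
  }
  if (any(A < 0) || any(B < 0)) stop("negative probabilities", call. = FALSE)
  structure(list(S = S, pi = c(1, rep(0, S - 1)), A = A, B = B,
                 log_likelihood = log_likelihood,
                 n_sequences = n_sequences, total_symbols = total_symbols),
            class = "lr_hmm")
}

#' @export
print.lr_hmm <- function(x, ...) {
  cat(sprintf("<lr_hmm> %d state(s), 8 symbols, loglik=%s\n", x$S,
              ifelse(is.na(x$log_likelihood), "NA",
                     sprintf("%.4f", x$log_likelihood))))
  for (i in seq_len(x$S)) {
    keep <- which(x$B[i, ] > 0.005)
    cat(sprintf("  s%d: %s\n", i,
                paste(sprintf("%s %.2f", symbol_labels()[keep],
                              x$B[i, keep]), collapse = "  ")))
  }
  invisible(x)
}

# ---- internal machinery -----------------------------------------------------

check_symbols <- function(symbols) {
  if (!all(unlist(symbols, use.names = FALSE) %in% 0:7)) {
    stop("symbols must be integers in 0..7", call. = FALSE)
  }
}

# Scaled forward pass for a batch of equal-length sequences.
# O: n x T matrix of 1-based symbols. Returns per-sequence log-likelihood
# and, if keep = TRUE, the normalized alphas and emission lookups per t.
forward_batch <- function(A, B, O, keep = FALSE) {
  n <- nrow(O); T <- ncol(O); S <- nrow(A)
  tB <- t(B)                               # 8 x S, rows indexed by symbol
  loglik <- numeric(n)
  alphas <- if (keep) vector("list", T)
  emis <- if (keep) vector("list", T)
  E1 <- tB[O[, 1], , drop = FALSE]
  alpha <- matrix(0, n, S)
  alpha[, 1] <- E1[, 1]                    # pi = e1
  for (t in seq_len(T)) {
    if (t > 1) {
      Et <- tB[O[, t], , drop = FALSE]
      alpha <- (alpha %*% A) * Et
      if (keep) emis[[t]] <- Et
    } else if (keep) {
      emis[[1]] <- E1
    }
    sc <- rowSums(alpha)
    dead <- sc <= 0
    loglik <- loglik + ifelse(dead, -Inf, log(sc))
    sc[dead] <- 1
    alpha <- alpha / sc
    if (keep) alphas[[t]] <- alpha
  }
  list(loglik = loglik, alphas = alphas, emis = emis)
}

# Backward pass, rows renormalized per (sequence, t); valid because the
# E-step only uses per-t normalized gamma and xi.
backward_batch <- function(A, emis, n, T, S) {
  betas <- vector("list", T)
  beta <- matrix(1, n, S)
  betas[[T]] <- beta
  tA <- t(A)
  for (t in rev(seq_len(T - 1))) {
    beta <- (beta * emis[[t + 1]]) %*% tA
    mx <- pmax(apply(beta, 1, max), .Machine$double.xmin)
    beta <- beta / mx
    betas[[t]] <- beta
  }
  betas
}

# One E-step over a batch: expected transition counts (S x S), expected
# emission counts (S x 8), and gamma at t = 1 (unused, pi is fixed).
estep_batch <- function(A, B, O) {
  n <- nrow(O); T <- ncol(O); S <- nrow(A)
  fw <- forward_batch(A, B, O, keep = TRUE)
  betas <- backward_batch(A, fw$emis, n, T, S)
  A_num <- matrix(0, S, S)
  B_num <- matrix(0, S, 8)
  for (t in seq_len(T)) {
    g <- fw$alphas[[t]] * betas[[t]]
    g <- g / rowSums(g)
    for (sym in unique(O[, t])) {
      idx <- O[, t] == sym
      B_num[, sym] <- B_num[, sym] + colSums(g[idx, , drop = FALSE])
    }
    if (t < T) {
      P <- fw$alphas[[t]]
      Q <- betas[[t + 1]] * fw$emis[[t + 1]]
      z <- rowSums((P %*% A) * Q)
      A_num <- A_num + A * (t(P / z) %*% Q)
    }
  }
  list(A_num = A_num, B_num = B_num, loglik = sum(fw$loglik))
}

# Group 0-based symbol sequences into 1-based observation matrices by length.
batch_sequences <- function(seqs) {
  lens <- lengths(seqs)
  lapply(split(seqs, lens), function(grp) {
    do.call(rbind, lapply(grp, function(s) as.integer(s) + 1L))
  })
}

allowed_mask <- function(S, chain = FALSE) {
  M <- upper.tri(diag(S), diag = TRUE)
  if (chain && S > 1) {
    M[] <- FALSE
    M[cbind(seq_len(S), seq_len(S))] <- TRUE
    M[cbind(seq_len(S - 1), seq_len(S - 1) + 1L)] <- TRUE
  }
  M
}

# ---- public operations ------------------------------------------------------

#' Log-likelihood of a symbol sequence under an HMM
#'
#' Scaled forward recursion; equals the log of the sum over all hidden state
#' paths of the joint path probability. Returns `-Inf` for sequences the
#' model cannot produce.
#'
#' @param model An [lr_hmm()].
#' @param symbols Integer vector of symbols in 0..7.
#' @return Log-probability (scalar).
#' @export
forward_loglik <- function(model, symbols) {
  stopifnot(inherits(model, "lr_hmm"))
  check_symbols(list(symbols))
  if (length(symbols) == 0) stop("empty sequence", call. = FALSE)
  O <- matrix(as.integer(symbols) + 1L, nrow = 1)
  forward_batch(model$A, model$B, O)$loglik
}

#' Fit a left-to-right multinomial HMM by constrained Baum-Welch
#'
#' Multi-sequence expectation-maximization with the left-to-right structure
#' enforced throughout: the initial distribution stays fixed at state 1 and
#' the below-diagonal zeros of the transition matrix are preserved at every
#' iteration (EM never resurrects a structural zero). Emissions are
#' initialized from seeded Dirichlet(1) draws per state, transitions uniform
#' over the allowed entries; the best of `n_restarts` runs by final
#' log-likelihood is returned. A single state has a closed-form maximum
#' likelihood solution (the pooled empirical symbol frequencies), used
#' directly.
#'
#' @param seqs List of integer symbol sequences (values 0..7), or a single
#'   vector. Sequences are treated as independent.
#' @param S Number of hidden states, >= 1.
#' @param seed RNG seed; fits are deterministic given the seed.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Random restarts.
#' @param chain Restrict transitions to self-loops and the next state
#'   (`j in {i, i+1}`) instead of the default any-forward topology.
#' @return An [lr_hmm()] with `log_likelihood`, training metadata, and the
#'   per-iteration log-likelihood history of the winning restart in
#'   `attr(, "loglik_history")`.
#' @export
baum_welch <- function(seqs, S, seed = 1, tol = 1e-4, max_iter = 500,
                       n_restarts = 5, chain = FALSE) {
  if (is.numeric(seqs)) seqs <- list(seqs)
  seqs <- Filter(length, seqs)
  if (length(seqs) == 0) stop("no non-empty sequences", call. = FALSE)
  check_symbols(seqs)
  stopifnot(S >= 1)
  n_seq <- length(seqs)
  total <- sum(lengths(seqs))

  if (S == 1) {
    counts <- tabulate(unlist(seqs, use.names = FALSE) + 1L, nbins = 8L)
    B <- matrix(counts / total, nrow = 1)
    ll <- sum(counts[counts > 0] * log(B[counts > 0]))
    model <- lr_hmm(matrix(1), B, log_likelihood = ll,
                    n_sequences = n_seq, total_symbols = total)
    attr(model, "loglik_history") <- ll
    return(model)
  }

  batches <- batch_sequences(seqs)
  mask <- allowed_mask(S, chain)
  A0 <- mask / rowSums(mask)

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      B <- matrix(stats::rexp(S * 8), S, 8)
      B <- B / rowSums(B)
      A <- A0
      history <- numeric(0)
      ll_prev <- -Inf
      for (iter in seq_len(max_iter)) {
        es <- Reduce(function(acc, O) {
          e <- estep_batch(A, B, O)
          list(A_num = acc$A_num + e$A_num, B_num = acc$B_num + e$B_num,
               loglik = acc$loglik + e$loglik)
        }, batches,
        init = list(A_num = matrix(0, S, S), B_num = matrix(0, S, 8),
                    loglik = 0))
        history <- c(history, es$loglik)
        # M-step: rows with no expected mass keep their previous values
        rsA <- rowSums(es$A_num)
        A_new <- A
        upd <- rsA > 0
        A_new[upd, ] <- es$A_num[upd, , drop = FALSE] / rsA[upd]
        A_new[!mask] <- 0
        A_new <- A_new / rowSums(A_new)
        rsB <- rowSums(es$B_num)
        B_new <- B
        updB <- rsB > 0
        B_new[updB, ] <- es$B_num[updB, , drop = FALSE] / rsB[updB]
        converged <- is.finite(ll_prev) &&
          abs(es$loglik - ll_prev) < tol * (abs(ll_prev) + 1e-12)
        A <- A_new; B <- B_new
        ll_prev <- es$loglik
        if (converged) break
      }
      if (is.null(best) || ll_prev > best$loglik) {
        best <- list(A = A, B = B, loglik = ll_prev, history = history)
      }
    }
  })
  model <- lr_hmm(best$A, best$B, log_likelihood = best$loglik,
                  n_sequences = n_seq, total_symbols = total)
  attr(model, "loglik_history") <- best$history
  model
}

#' Choose the number of hidden states
#'
#' Fits models for S = 1..`S_max` and selects S. The state-count procedure
#' of the original analysis is not published, so two stand-in criteria are
#' provided: `"gain"` (default) returns the smallest S whose relative
#' log-likelihood gain over S-1 falls below `delta` — i.e. growth stops when
#' an extra state no longer pays; `"bic"` minimizes the Bayesian information
#' criterion with `S(S+1)/2 - S` free transition parameters (the initial
#' distribution is fixed) plus `7S` free emission parameters.
#'
#' @param seqs List of symbol sequences (0..7).
#' @param S_max Largest state count considered (default 4).
#' @param criterion `"gain"` or `"bic"`.
#' @param seed RNG seed (each S is fit with a seed derived from it).
#' @param delta Relative-gain threshold for `"gain"` (default 0.01).
#' @param ... Passed to [baum_welch()].
#' @return The selected [lr_hmm()]; the full score table (S, loglik,
#'   n_params, bic, rel_gain) is attached as `attr(, "selection")`.
#' @export
select_states <- function(seqs, S_max = 4, criterion = c("gain", "bic"),
                          seed = 1, delta = 0.01, ...) {
  criterion <- match.arg(criterion)
  stopifnot(S_max >= 1)
  fits <- lapply(seq_len(S_max), function(S) {
    baum_welch(seqs, S, seed = seed + S, ...)
  })
  ll <- vapply(fits, `[[`, numeric(1), "log_likelihood")
  total <- fits[[1]]$total_symbols
  n_params <- vapply(seq_len(S_max), function(S) {
    (S * (S + 1) / 2 - S) + 7 * S
  }, numeric(1))
  bic <- -2 * ll + n_params * log(total)
  rel_gain <- c(NA, diff(ll) / pmax(abs(ll[-S_max]), 1e-12))
  S_sel <- if (criterion == "bic") {
    which.min(bic)
  } else {
    sel <- S_max
    for (S in seq_len(S_max)[-1]) {
      g <- rel_gain[S]
      if (!is.finite(g)) g <- 0          # deterministic data: loglik 0 at every S
      if (g < delta) { sel <- S - 1L; break }
    }
    sel
  }
  model <- fits[[S_sel]]
  attr(model, "selection") <- data.frame(
    S = seq_len(S_max), loglik = ll, n_params = n_params, bic = bic,
    rel_gain = rel_gain)
  model
}

#' Mask small probabilities for display
#'
#' Returns a rendering copy of the model in which emission probabilities
#' `<= emission_threshold` (default 0.05) and transition probabilities
#' `<= transition_threshold` (default 0.01) are masked (set to `NA`). The
#' probabilistic model itself is untouched — nothing is renormalized; the
#' masked copy is a readability device for [hmm_to_dot()] only.
#'
#' @param model An [lr_hmm()].
#' @param emission_threshold,transition_threshold Masking thresholds,
#'   inclusive.
#' @return Object of class `lr_hmm_display`.
#' @export
prune_for_display <- function(model, emission_threshold = 0.05,
                              transition_threshold = 0.01) {
  stopifnot(inherits(model, "lr_hmm"))
  disp <- unclass(model)
  disp$B[disp$B <= emission_threshold] <- NA
  disp$A[disp$A <= transition_threshold] <- NA
  disp$emission_threshold <- emission_threshold
  disp$transition_threshold <- transition_threshold
  structure(disp, class = "lr_hmm_display")
}

#' Sample a symbol sequence from an HMM
#'
#' Generative use of a fitted model: the hidden path starts in state 1 and
#' walks the transition matrix, emitting one symbol per step.
#'
#' @param model An [lr_hmm()].
#' @param length Sequence length, >= 1.
#' @param seed RNG seed.
#' @return Integer vector of symbols in 0..7, with the hidden path in
#'   `attr(, "states")`.
#' @export
hmm_sample <- function(model, length, seed = NULL) {
  stopifnot(inherits(model, "lr_hmm"), length >= 1)
  with_seed(seed, {
    states <- integer(length)
    symbols <- integer(length)
    s <- 1L
    for (t in seq_len(length)) {
      states[t] <- s
      symbols[t] <- sample.int(8L, 1L, prob = model$B[s, ]) - 1L
      s <- sample.int(model$S, 1L, prob = model$A[s, ])
    }
    structure(symbols, states = states)
  })
}

#' Render a model as a GraphViz DOT graph
#'
#' One box per hidden state listing the surviving (conditional action,
#' probability) pairs in human-readable form (e.g. `(CD)D 0.62`); edges for
#' surviving transitions, self-loops included; the initial state is drawn
#' bold.
#'
#' @param model An `lr_hmm_display` from [prune_for_display()] (a full
#'   [lr_hmm()] is accepted and rendered unmasked).
#' @param labels Symbol labels, default [symbol_labels()].
#' @return DOT source text (single character string).
#' @export
hmm_to_dot <- function(model, labels = symbol_labels()) {
  stopifnot(inherits(model, c("lr_hmm", "lr_hmm_display")))
  S <- model$S
  lines <- c("digraph hmm {", "  rankdir=LR;", "  node [shape=box];")
  for (i in seq_len(S)) {
    keep <- which(!is.na(model$B[i, ]))
    body <- paste(sprintf("%s %.2f", labels[keep], model$B[i, keep]),
                  collapse = "\\n")
    pen <- if (i == 1) ", penwidth=3" else ""
    lines <- c(lines, sprintf('  s%d [label="s%d\\n%s"%s];', i, i, body, pen))
  }
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (!is.na(model$A[i, j]) && model$A[i, j] > 0) {
        lines <- c(lines, sprintf('  s%d -> s%d [label="%.2f"];',
                                  i, j, model$A[i, j]))
      }
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Serialize / restore an HMM as JSON
#'
#' @param model An [lr_hmm()].
#' @param path Output (input) JSON path.
#' @return `path` invisibly; `read_hmm_json()` returns the [lr_hmm()].
#' @export
write_hmm_json <- function(model, path) {
  stopifnot(inherits(model, "lr_hmm"))
  obj <- list(S = model$S, pi = model$pi,
              A = apply(model$A, 1, identity, simplify = FALSE),
              B = apply(model$B, 1, identity, simplify = FALSE),
              loglik = model$log_likelihood,
              n_sequences = model$n_sequences,
              total_symbols = model$total_symbols,
              alphabet = symbol_labels())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite simplifies a list of equal-length rows to a matrix already
  as_mat <- function(x, nrow) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = nrow, byrow = TRUE)
  }
  A <- as_mat(obj$A, obj$S)
  B <- as_mat(obj$B, obj$S)
  lr_hmm(A, B, log_likelihood = obj$loglik,
         n_sequences = obj$n_sequences, total_symbols = obj$total_symbols)
}
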