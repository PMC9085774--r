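test_that("constructor enforces the left-to-right structure", {
  A <- matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE)
  B <- matrix(1 / 8, 2, 8)
  m <- lr_hmm(A, B)
  expect_equal(m$pi, c(1, 0))
  expect_error(lr_hmm(matrix(c(0.5, 0.5, 0.5, 0.5), 2), B), "upper triangular")
  expect_error(lr_hmm(matrix(c(0.6, 0.5, 0, 1), 2, byrow = TRUE), B),
               "sum to 1")
})

test_that("forward log-likelihood matches tiny closed forms", {
  uni <- lr_hmm(matrix(1), matrix(1 / 8, 1, 8))
  expect_equal(forward_loglik(uni, c(0, 3, 7, 5)), 4 * log(1 / 8))

  # two states with delta emissions: P([0,7]) enumerates to 0.5
  m <- lr_hmm(matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE),
              rbind(c(1, rep(0, 7)), c(rep(0, 7), 1)))
  expect_equal(forward_loglik(m, c(0, 7)), log(0.5))
  expect_equal(forward_loglik(m, c(7, 0)), -Inf)
  expect_error(forward_loglik(m, c(0, 9)), "0..7")
})

test_that("forward recursion agrees with brute-force path enumeration", {
  set.seed(11)
  for (i in 1:30) {
    S <- sample(1:3, 1)
    m <- random_lr_model(S)
    len <- sample(2:6, 1)
    symbols <- sample(0:7, len, replace = TRUE)
    expect_equal(forward_loglik(m, symbols),
                 brute_force_loglik(m$A, m$B, m$pi, symbols),
                 tolerance = 1e-10)
  }
})

test_that("one-state Baum-Welch is the empirical symbol distribution", {
  fit <- baum_welch(list(rep(0, 10), rep(7, 10)), S = 1)
  expect_equal(as.vector(fit$B), c(0.5, 0, 0, 0, 0, 0, 0, 0.5))
  expect_equal(fit$log_likelihood, 20 * log(0.5))
  expect_error(baum_welch(list(integer(0)), S = 1), "non-empty")
})

test_that("EM keeps the structure and never decreases the log-likelihood", {
  set.seed(5)
  seqs <- lapply(1:10, function(i) sample(0:7, 40, replace = TRUE))
  fit <- baum_welch(seqs, S = 3, seed = 2, n_restarts = 2)
  expect_true(all(fit$A[lower.tri(fit$A)] == 0))      # mask preserved exactly
  expect_equal(fit$pi, c(1, 0, 0))                    # fixed initial state
  h <- attr(fit, "loglik_history")
  expect_true(all(diff(h) >= -1e-8))

  # chain topology restricts skips
  fitc <- baum_welch(seqs, S = 3, seed = 2, n_restarts = 2, chain = TRUE)
  expect_equal(fitc$A[1, 3], 0)
})

test_that("a two-state left-to-right model is recovered from its samples", {
  A <- matrix(c(0.95, 0.05, 0, 1), 2, byrow = TRUE)
  B <- rbind(c(0.45, 0.45, 0.05, 0.05, 0, 0, 0, 0),
             c(0, 0, 0, 0, 0.05, 0.05, 0.45, 0.45))
  true <- lr_hmm(A, B)
  seqs <- lapply(1:30, function(i) hmm_sample(true, 60, seed = 500 + i))
  fit <- baum_welch(seqs, 2, seed = 7)
  expect_lt(max(abs(fit$A - A)), 0.05)
  expect_lt(max(abs(fit$B - B)), 0.05)
})

test_that("state-count selection stops when extra states stop paying", {
  set.seed(21)
  iid <- lapply(1:20, function(i)
    sample(0:7, 50, replace = TRUE, prob = c(4, 2, 1, 1, 1, 1, 2, 4)))
  sel <- select_states(iid, S_max = 3, seed = 3)
  expect_equal(sel$S, 1L)
  tab <- attr(sel, "selection")
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$loglik) < 0.01 * abs(tab$loglik[-3])))

  single <- select_states(iid, S_max = 1, seed = 3)
  expect_equal(single$S, 1L)
})

test_that("display pruning masks at the documented inclusive thresholds", {
  B <- matrix(c(0.05, 0.051, 0.5, 0.399, rep(0, 4)), 1, 8)
  m <- lr_hmm(matrix(1), B)
  d <- prune_for_display(m)
  expect_true(is.na(d$B[1, 1]))      # 0.05 exactly: masked
  expect_equal(d$B[1, 2], 0.051)     # just above: retained
  expect_equal(m$B[1, 1], 0.05)      # original model untouched

  uniform <- lr_hmm(matrix(1), matrix(1 / 8, 1, 8))
  expect_false(anyNA(prune_for_display(uniform)$B))

  A2 <- matrix(c(0.99, 0.01, 0, 1), 2, byrow = TRUE)
  d2 <- prune_for_display(lr_hmm(A2, matrix(1 / 8, 2, 8)))
  expect_true(is.na(d2$A[1, 2]))     # transition 0.01: masked
})

test_that("sampling is generative and matches the emission law", {
  delta3 <- lr_hmm(matrix(1), matrix(c(0, 0, 0, 1, 0, 0, 0, 0), 1, 8))
  expect_equal(unique(as.integer(hmm_sample(delta3, 20, seed = 1))), 3L)

  # absorbing second state with delta emission: constant suffix
  m <- lr_hmm(matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE),
              rbind(rep(1 / 8, 8), c(rep(0, 7), 1)))
  s <- hmm_sample(m, 50, seed = 4)
  states <- attr(s, "states")
  expect_true(all(s[states == 2] == 7))
  expect_true(all(diff(states) >= 0))  # never returns to an earlier state

  B <- matrix(c(0.4, 0.1, 0.1, 0.1, 0.1, 0.1, 0.05, 0.05), 1, 8)
  big <- hmm_sample(lr_hmm(matrix(1), B), 1e4, seed = 9)
  freqs <- tabulate(big + 1L, 8) / 1e4
  expect_lt(max(abs(freqs - as.vector(B))), 0.02)
})

test_that("DOT rendering shows surviving structure only", {
  d1 <- prune_for_display(lr_hmm(matrix(1),
                                 matrix(c(1, rep(0, 7)), 1, 8)))
  dot1 <- hmm_to_dot(d1)
  expect_match(dot1, "\\(CC\\)C 1\\.00")
  expect_match(dot1, "penwidth=3")               # bold initial state

  A <- matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE)
  B <- rbind(c(0.9, 0.1, rep(0, 6)), c(rep(0, 6), 0.1, 0.9))
  d2 <- prune_for_display(lr_hmm(A, B))
  dot2 <- hmm_to_dot(d2)
  expect_match(dot2, "s1 -> s1")
  expect_match(dot2, "s1 -> s2")
  expect_match(dot2, "s2 -> s2")

  # masked transition absent
  A3 <- matrix(c(0.995, 0.005, 0, 1), 2, byrow = TRUE)
  d3 <- prune_for_display(lr_hmm(A3, B))
  expect_no_match(hmm_to_dot(d3), "s1 -> s2")
})

test_that("models round-trip through JSON", {
  set.seed(3)
  m <- random_lr_model(3)
  path <- tempfile(fileext = ".json")
  write_hmm_json(m, path)
  m2 <- read_hmm_json(path)
  expect_equal(m2$A, m$A, tolerance = 1e-12)
  expect_equal(m2$B, m$B, tolerance = 1e-12)
  expect_equal(m2$S, m$S)
  unlink(path)
})
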