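#' Pipeline configuration
#'
#' Collects the tunable parameters of the full analysis. Defaults mirror the
#' study conditions: a maximum of 8 contextual and 6 behavioral clusters
#' scanned by the elbow rule, HMMs of up to 4 states selected by the
#' relative log-likelihood gain rule, and seeded restarts everywhere for
#' reproducibility.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param K_max_context,K_max_behavior Largest k scanned per clustering
#'   level.
#' @param normalize Cluster on context frequencies instead of raw counts
#'   (for variable-length imports).
#' @param S_max Largest HMM state count considered.
#' @param criterion HMM state selection: `"gain"` or `"bic"`.
#' @param delta Relative-gain threshold of the `"gain"` criterion.
#' @param n_restarts_kmeans,n_restarts_hmm Restart counts.
#' @param hmm_tol,hmm_max_iter Baum-Welch convergence controls.
#' @param chain Restrict HMM transitions to adjacent states.
#' @param emission_threshold,transition_threshold Display-pruning thresholds.
#' @param verbose Print one structured log line per stage.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, K_max_context = 8, K_max_behavior = 6,
                            normalize = FALSE, S_max = 4,
                            criterion = "gain", delta = 0.01,
                            n_restarts_kmeans = 10, n_restarts_hmm = 5,
                            hmm_tol = 1e-4, hmm_max_iter = 500,
                            chain = FALSE,
                            emission_threshold = 0.05,
                            transition_threshold = 0.01,
                            verbose = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

log_stage <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(paste0("[ipdinfer] ", fmt), ...))
}

#' Classify a conditional cooperation vector as an archetype
#'
#' Finds the nearest memory-one archetype by L1 distance between the
#' observed conditional cooperation vector `(p_cc, p_cd, p_dc, p_dd)` and
#' each registry strategy's conditional probabilities. `NA` entries
#' (contexts never experienced) are excluded together with the matching
#' registry entries; ties break by registry order.
#'
#' @param cond_coop Numeric 4-vector of conditional cooperation
#'   probabilities in context order CC, CD, DC, DD; `NA` allowed.
#' @param registry Archetype list, default [archetype_registry()].
#' @return List of class `archetype_call` with `archetype`, `distance` and
#'   the input vector `cond_coop`.
#' @examples
#' classify_archetype(c(1, 0, 1, 0))$archetype  # "TFT"
#' @export
classify_archetype <- function(cond_coop, registry = archetype_registry()) {
  stopifnot(length(cond_coop) == 4)
  defined <- !is.na(cond_coop)
  if (!any(defined)) {
    stop("all conditional probabilities undefined; cannot classify",
         call. = FALSE)
  }
  if (any(cond_coop[defined] < 0 | cond_coop[defined] > 1)) {
    stop("conditional probabilities must lie in [0, 1]", call. = FALSE)
  }
  dists <- vapply(registry, function(s) {
    ref <- c(s$p_cc, s$p_cd, s$p_dc, s$p_dd)
    sum(abs(cond_coop[defined] - ref[defined]))
  }, numeric(1))
  best <- which.min(dists)  # which.min takes the first minimum: registry order
  structure(list(archetype = names(registry)[best],
                 distance = unname(dists[best]),
                 cond_coop = cond_coop),
            class = "archetype_call")
}

#' @export
print.archetype_call <- function(x, ...) {
  cat(sprintf("<archetype_call> %s (L1 distance %.3f)\n",
              x$archetype, x$distance))
  invisible(x)
}

#' Fraction of players cooperating in round 1
#'
#' @param games A `game_table`.
#' @param players Optional subset of player ids.
#' @return Fraction in \[0, 1\].
#' @export
first_round_cooperation <- function(games, players = NULL) {
  r1 <- games[games$round == 1, ]
  if (!is.null(players)) r1 <- r1[r1$player %in% players, ]
  if (nrow(r1) == 0) stop("no round-1 rows for the requested group",
                          call. = FALSE)
  mean(r1$action == "C")
}

#' Percentage of yes-answers, to two decimals
#'
#' Report-parity helper for the post-experiment questionnaire counts.
#'
#' @param n_yes,n_total Non-negative integers, `n_yes <= n_total`,
#'   `n_total > 0`.
#' @return `100 * n_yes / n_total` rounded to 2 decimals.
#' @examples
#' questionnaire_percentage(74, 92)  # 80.43
#' @export
questionnaire_percentage <- function(n_yes, n_total) {
  if (n_total <= 0) stop("`n_total` must be positive", call. = FALSE)
  if (n_yes < 0 || n_yes > n_total) {
    stop("`n_yes` must lie in [0, n_total]", call. = FALSE)
  }
  round(100 * n_yes / n_total, 2)
}

# Core analysis on encoded sequences; run_pipeline and window_analysis both
# funnel into this.
run_pipeline_seqs <- function(seqs, treatment, config,
                              ground_truth = NULL, window = "full") {
  profiles <- profile_table(seqs)
  ctx <- contextual_cluster(profiles, K_max = config$K_max_context,
                            seed = config$seed,
                            n_restarts = config$n_restarts_kmeans,
                            normalize = config$normalize)
  log_stage(config, "window=%s contextual: k=%d silhouette=%s",
            window, ctx$k,
            ifelse(is.na(ctx$silhouette), "NA",
                   sprintf("%.4f", ctx$silhouette)))

  # label contextual clusters A, B, C, ... by decreasing size for stability
  sizes <- table(ctx$labels)
  order_ids <- as.integer(names(sort(sizes, decreasing = TRUE)))
  letter_of <- stats::setNames(LETTERS[seq_along(order_ids)], order_ids)
  ctx_letter <- letter_of[as.character(ctx$labels)]
  names(ctx_letter) <- names(ctx$labels)

  assignments <- data.frame(player = profiles$player,
                            context_cluster = unname(ctx_letter),
                            behavior_subcluster = NA_character_,
                            stringsAsFactors = FALSE)
  sub_models <- list()
  hmms <- list()
  cond_rows <- list()
  call_rows <- list()
  summary_rows <- list()

  for (letter in sort(unique(ctx_letter))) {
    members <- profiles$player[ctx_letter == letter]
    mem_prof <- profiles[profiles$player %in% members, , drop = FALSE]
    beh <- behavioral_subcluster(mem_prof, K_max = config$K_max_behavior,
                                 seed = config$seed,
                                 n_restarts = config$n_restarts_kmeans)
    sub_models[[letter]] <- beh
    log_stage(config, "window=%s cluster %s (n=%d): %d sub-cluster(s)",
              window, letter, length(members), beh$k)
    summary_rows[[letter]] <- data.frame(
      treatment = treatment, cluster = letter, n = length(members),
      n_subclusters = beh$k,
      silhouette = beh$silhouette, stringsAsFactors = FALSE)

    for (sub in seq_len(beh$k)) {
      sub_id <- sprintf("%s.%d", letter, sub - 1L)   # hierarchical ids A.0, ...
      sub_members <- names(beh$labels)[beh$labels == sub]
      assignments$behavior_subcluster[
        assignments$player %in% sub_members] <- sub_id

      pooled <- seqs[sub_members]
      hmm <- select_states(pooled, S_max = config$S_max,
                           criterion = config$criterion,
                           seed = config$seed, delta = config$delta,
                           tol = config$hmm_tol,
                           max_iter = config$hmm_max_iter,
                           n_restarts = config$n_restarts_hmm,
                           chain = config$chain)
      log_stage(config, "window=%s sub-cluster %s (n=%d): S=%d loglik=%.2f",
                window, sub_id, length(sub_members), hmm$S,
                hmm$log_likelihood)
      hmms[[sub_id]] <- hmm

      pooled_prof <- action_profiles(unlist(pooled, use.names = FALSE))
      p <- as.vector(pooled_prof$p)
      n <- as.vector(pooled_prof$n)
      se <- ifelse(n > 0, sqrt(p * (1 - p) / n), NA_real_)
      cond_rows[[sub_id]] <- data.frame(
        subcluster = sub_id, context = CONTEXTS, n = n,
        coop = as.vector(pooled_prof$c), p = p, se = se,
        stringsAsFactors = FALSE)

      call <- classify_archetype(p)
      call_rows[[sub_id]] <- data.frame(
        subcluster = sub_id, n_players = length(sub_members),
        p_cc = p[1], p_cd = p[2], p_dc = p[3], p_dd = p[4],
        archetype = call$archetype, distance = call$distance,
        stringsAsFactors = FALSE)
    }
  }

  report <- structure(list(
    treatment = treatment,
    window = window,
    assignments = assignments,
    contextual = ctx,
    subclusters = sub_models,
    hmms = hmms,
    display_hmms = lapply(hmms, prune_for_display,
                          emission_threshold = config$emission_threshold,
                          transition_threshold = config$transition_threshold),
    conditional_cooperation = do.call(rbind, c(cond_rows,
                                               make.row.names = FALSE)),
    archetype_calls = do.call(rbind, c(call_rows, make.row.names = FALSE)),
    summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
    config = config,
    ground_truth = ground_truth
  ), class = "pipeline_report")
  report
}

#' Run the full strategy-inference pipeline
#'
#' Encodes every player's actions as conditional-action symbols, clusters
#' players on context counts (contextual clustering), sub-clusters each
#' contextual cluster on conditional cooperation counts (behavioral
#' clustering), fits a left-to-right multinomial HMM to each sub-cluster's
#' pooled sequences, and classifies each sub-cluster's pooled conditional
#' cooperation vector against the memory-one archetype registry.
#'
#' @param games A `game_table` for a single treatment.
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list with `assignments` (player, contextual
#'   cluster A/B/..., behavioral sub-cluster A.0/A.1/...), the fitted
#'   `cluster_model`s, per-sub-cluster `hmms` and display-pruned
#'   counterparts, `conditional_cooperation` (per context: n, cooperative
#'   count, probability, binomial standard error `sqrt(p(1-p)/n)`),
#'   `archetype_calls`, and a per-cluster `summary` (treatment, cluster, n,
#'   n_subclusters, silhouette).
#' @export
run_pipeline <- function(games, config = pipeline_config()) {
  if (nrow(games) == 0) stop("empty game table", call. = FALSE)
  treatment <- unique(games$treatment)
  if (length(treatment) != 1) {
    stop("run_pipeline expects a single treatment; subset first",
         call. = FALSE)
  }
  seqs <- player_sequences(games)
  run_pipeline_seqs(seqs, treatment, config,
                    ground_truth = ground_truth(games))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s (%s): %d players, %d contextual cluster(s), %d sub-cluster(s)\n",
              x$treatment, x$window, nrow(x$assignments),
              x$contextual$k, length(x$hmms)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Windowed re-analysis of a game table
#'
#' Re-runs the pipeline on consecutive round windows (default 25 rounds:
#' W1 = rounds 1-25, W2 = 26-50, ...) to expose learning effects. Window
#' boundaries do not discard context: round 26's symbol uses round 25's
#' actions, since participants saw the previous round regardless of analyst
#' windowing. The first window therefore has `window_size - 1` symbols per
#' player and later windows `window_size`.
#'
#' @param games A `game_table` for a single treatment, with at least
#'   `2 * window_size` rounds.
#' @param window_size Rounds per window (default 25).
#' @param config A [pipeline_config()].
#' @return Named list (`W1`, `W2`, ...) of `pipeline_report`s.
#' @export
window_analysis <- function(games, window_size = 25,
                            config = pipeline_config()) {
  n_rounds <- max(games$round)
  if (n_rounds < 2 * window_size) {
    stop("need at least 2 windows of rounds", call. = FALSE)
  }
  treatment <- unique(games$treatment)
  if (length(treatment) != 1) {
    stop("window_analysis expects a single treatment", call. = FALSE)
  }
  full <- player_sequences(games)  # symbol i corresponds to round i + 1
  n_windows <- n_rounds %/% window_size
  reports <- lapply(seq_len(n_windows), function(w) {
    rounds <- ((w - 1) * window_size + 1):(w * window_size)
    idx <- rounds[rounds >= 2] - 1L
    seqs <- lapply(full, function(s) s[idx])
    run_pipeline_seqs(seqs, treatment, config,
                      ground_truth = ground_truth(games),
                      window = sprintf("W%d", w))
  })
  names(reports) <- sprintf("W%d", seq_len(n_windows))
  reports
}
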