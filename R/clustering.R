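#' Seeded best-of-restarts K-means
#'
#' Thin, reproducible wrapper around [stats::kmeans()]: the RNG is seeded,
#' `n_restarts` random initializations are run and the solution with the
#' lowest inertia (total within-cluster sum of squares) is kept.
#'
#' @param X Numeric matrix or data frame, one row per observation.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param seed RNG seed.
#' @param n_restarts Number of random restarts (default 10).
#' @param level Optional label (`"contextual"`/`"behavioral"`) carried in the
#'   result.
#' @return An object of class `cluster_model`: list with `level`, `k`,
#'   `labels` (integer 1..k per row, named by rownames), `centers`,
#'   `inertia` and `silhouette` (mean silhouette coefficient, `NA` unless
#'   `2 <= k < n`).
#' @examples
#' m <- kmeans_fit(matrix(c(0, 0, 10, 10)), k = 2, seed = 1)
#' m$inertia
#' @export
kmeans_fit <- function(X, k, seed = 1, n_restarts = 10, level = NA_character_) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of observations",
                  call. = FALSE)
  stopifnot(k >= 1, ncol(X) >= 1)
  n_distinct <- nrow(unique(X))
  fit <- with_seed(seed, {
    if (k == 1 || n_distinct == 1) {
      center <- matrix(colMeans(X), nrow = 1)
      list(cluster = rep(1L, n), centers = center,
           tot.withinss = sum(sweep(X, 2, center)^2))
    } else if (k >= n_distinct) {
      # one center per distinct row: inertia 0, no Lloyd iterations needed
      centers <- unique(X)[seq_len(k), , drop = FALSE]
      key <- apply(X, 1, paste, collapse = "\r")
      list(cluster = as.integer(factor(key, levels = unique(key))),
           centers = centers, tot.withinss = 0)
    } else {
      # manual restarts with distinct initial centers: sampling rows directly
      # can duplicate centers on integer count data, which kmeans() rejects
      ux <- unique(X)
      best <- NULL
      for (r in seq_len(n_restarts)) {
        centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
        # suppress the Quick-TRANSfer warning triggered by heavily duplicated
        # integer rows; the best-of-restarts inertia comparison still applies
        cand <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100)),
          error = function(e) NULL)
        if (!is.null(cand) &&
            (is.null(best) || cand$tot.withinss < best$tot.withinss)) {
          best <- cand
        }
      }
      if (is.null(best)) stop("k-means failed to converge", call. = FALSE)
      best
    }
  })
  labels <- as.integer(fit$cluster)
  names(labels) <- rownames(X)
  sil <- if (k >= 2 && k < n && length(unique(labels)) >= 2) {
    silhouette_score(X, labels)
  } else {
    NA_real_
  }
  structure(list(level = level, k = k, labels = labels,
                 centers = fit$centers, inertia = fit$tot.withinss,
                 silhouette = sil),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> level=%s k=%d n=%d inertia=%.4g silhouette=%s\n",
              x$level, x$k, length(x$labels), x$inertia,
              ifelse(is.na(x$silhouette), "NA",
                     sprintf("%.4f", x$silhouette))))
  invisible(x)
}

#' Elbow (knee) selection of the number of clusters
#'
#' Given inertias for k = 1..K_max, selects the knee of the inertia curve:
#' after min-max normalizing both axes, the interior k with the greatest
#' vertical distance below the chord joining the curve's endpoints. Ties
#' break toward smaller k. The curve is first made non-increasing by a
#' running-minimum repair (restarted K-means can occasionally produce a
#' locally worse fit at larger k).
#'
#' @param inertias Numeric vector of inertias for k = 1, 2, ..., K_max;
#'   length >= 3.
#' @return The selected k (an interior value, 2..K_max-1).
#' @examples
#' elbow_select(c(100, 20, 15, 12, 11))  # 2
#' @export
elbow_select <- function(inertias) {
  K <- length(inertias)
  if (K < 3) stop("need inertias for at least 3 values of k", call. = FALSE)
  y <- cummin(as.numeric(inertias))       # monotone repair
  if (y[1] == y[K]) return(2L)            # flat curve: smallest interior k
  ynorm <- (y - y[K]) / (y[1] - y[K])
  xnorm <- (seq_len(K) - 1) / (K - 1)
  chord <- 1 - xnorm                      # line through (0,1) and (1,0)
  dist_below <- chord - ynorm
  interior <- 2:(K - 1)
  interior[which.max(dist_below[interior])]
}

#' Mean silhouette coefficient
#'
#' For each observation, with `a` the mean distance to its own cluster's
#' other members and `b` the mean distance to the nearest other cluster, the
#' silhouette is `(b - a) / max(a, b)`; singletons contribute 0. Returns the
#' mean over observations (Euclidean distances). Values near 1 indicate
#' well-separated clusters; near 0, overlapping ones; negative, likely
#' misassignment.
#'
#' @param X Numeric matrix/data frame of observations.
#' @param labels Cluster labels, one per row; at least 2 distinct values.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_score <- function(X, labels) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels)) {
    stop("`labels` must have one entry per row of `X`", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("silhouette undefined for a single cluster", call. = FALSE)
  }
  if (nrow(X) < 3) stop("need at least 3 observations", call. = FALSE)
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(X))
  mean(sil[, "sil_width"])
}

# Scan k = 1..K_max (capped by the number of distinct rows), pick k by the
# elbow rule, and return the chosen model plus the inertia scan.
select_k_and_fit <- function(X, K_max, seed, n_restarts, level) {
  X <- as.matrix(X)
  n_distinct <- nrow(unique(X))
  K_eff <- min(K_max, n_distinct, nrow(X))
  inertias <- vapply(seq_len(K_eff), function(k) {
    kmeans_fit(X, k, seed = seed + k, n_restarts = n_restarts)$inertia
  }, numeric(1))
  k_star <- if (K_eff >= 3) {
    elbow_select(inertias)
  } else {
    # too few distinct points to draw an elbow: every distinct row its own
    # cluster (k = 1 for fully degenerate input)
    K_eff
  }
  model <- kmeans_fit(X, k_star, seed = seed + k_star,
                      n_restarts = n_restarts, level = level)
  model$k_scan <- data.frame(k = seq_len(K_eff), inertia = inertias)
  model
}

#' Contextual clustering of players
#'
#' First level of the two-level clustering: players are grouped by the
#' contexts they experienced, i.e. on the 4-vector of context counts
#' `(n_cc, n_cd, n_dc, n_dd)`. The number of clusters is chosen by
#' [elbow_select()]; quality is reported as the mean silhouette.
#'
#' @param profiles Profile table from [profile_table()].
#' @param K_max Largest k scanned (default 8).
#' @param seed RNG seed.
#' @param n_restarts K-means restarts per k.
#' @param normalize Divide counts by each player's sequence length (use for
#'   variable-length imports; with a fixed round count, counts and
#'   frequencies are proportional and raw counts are the default).
#' @return A `cluster_model` (level `"contextual"`) with labels named by
#'   player and the inertia scan in `$k_scan`.
#' @export
contextual_cluster <- function(profiles, K_max = 8, seed = 1,
                               n_restarts = 10, normalize = FALSE) {
  X <- as.matrix(profiles[paste0("n_", tolower(CONTEXTS))])
  rownames(X) <- profiles$player
  if (normalize) X <- X / rowSums(X)
  if (nrow(X) < K_max + 1) {
    stop("need at least K_max + 1 players", call. = FALSE)
  }
  select_k_and_fit(X, K_max, seed, n_restarts, "contextual")
}

#' Behavioral sub-clustering within a contextual cluster
#'
#' Second level: members of one contextual cluster are grouped by their
#' conditional cooperation counts `(c_cc, c_cd, c_dc, c_dd)` — how often they
#' responded cooperatively to each context. Counts are always defined (a
#' never-experienced context simply counts 0), so no imputation is involved.
#' Clusters with fewer than 4 members are passed through as a single
#' sub-cluster: no meaningful elbow exists at that size.
#'
#' @param profiles Profile-table rows of the cluster's members (>= 2 rows).
#' @param K_max Largest k scanned (default 6).
#' @param seed RNG seed.
#' @param n_restarts K-means restarts per k.
#' @return A `cluster_model` (level `"behavioral"`).
#' @export
behavioral_subcluster <- function(profiles, K_max = 6, seed = 1,
                                  n_restarts = 10) {
  X <- as.matrix(profiles[paste0("c_", tolower(CONTEXTS))])
  rownames(X) <- profiles$player
  if (nrow(X) < 2) stop("cluster must have at least 2 members", call. = FALSE)
  if (nrow(X) < 4) {
    labels <- rep(1L, nrow(X))
    names(labels) <- rownames(X)
    return(structure(list(level = "behavioral", k = 1L, labels = labels,
                          centers = matrix(colMeans(X), nrow = 1),
                          inertia = sum(sweep(X, 2, colMeans(X))^2),
                          silhouette = NA_real_,
                          k_scan = NULL),
                     class = "cluster_model"))
  }
  select_k_and_fit(X, min(K_max, nrow(X) - 1L), seed, n_restarts, "behavioral")
}
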