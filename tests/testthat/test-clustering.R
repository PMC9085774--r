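test_that("kmeans_fit handles separable, saturated and single-cluster cases", {
  X <- matrix(c(0, 0, 10, 10))
  m <- kmeans_fit(X, 2, seed = 1)
  expect_equal(m$inertia, 0)
  expect_equal(length(unique(m$labels)), 2L)
  expect_equal(m$labels[1], m$labels[2], ignore_attr = TRUE)

  X2 <- matrix(c(0, 3, 10, 20))
  expect_equal(kmeans_fit(X2, 4, seed = 1)$inertia, 0)  # k = n

  m1 <- kmeans_fit(X2, 1, seed = 1)
  expect_equal(m1$inertia, sum((X2 - mean(X2))^2))      # total SS

  expect_error(kmeans_fit(X2, 5, seed = 1), "exceed")
})

test_that("restarts never worsen the returned inertia", {
  set.seed(99)
  X <- matrix(rnorm(60), ncol = 2)
  i1 <- kmeans_fit(X, 4, seed = 3, n_restarts = 1)$inertia
  i10 <- kmeans_fit(X, 4, seed = 3, n_restarts = 10)$inertia
  expect_lte(i10, i1 + 1e-12)
})

test_that("elbow selection finds the knee of the inertia curve", {
  expect_equal(elbow_select(c(100, 20, 15, 12, 11)), 2L)
  expect_equal(elbow_select(c(50, 10, 9.5, 9.4)), 2L)
  expect_equal(elbow_select(c(100, 99, 98, 97, 96)), 2L)  # linear: tie -> smallest
  expect_equal(elbow_select(c(100, 60, 5, 4, 3.5, 3.4)), 3L)
  expect_error(elbow_select(c(10, 5)), "at least 3")
})

test_that("silhouette matches the hand-computed value and edge cases", {
  X <- matrix(c(0, 0.1, 10, 10.1))
  s <- silhouette_score(X, c("A", "A", "B", "B"))
  expect_equal(s, 0.99, tolerance = 1e-3)  # a = 0.1, b ~ 10

  # coincident clusters: no separation
  Xc <- matrix(c(0, 1, 0, 1))
  expect_lte(silhouette_score(Xc, c("A", "A", "B", "B")), 0)

  # far-separated tight clusters approach 1
  Xf <- matrix(c(0, 0.001, 1000, 1000.001))
  expect_gt(silhouette_score(Xf, c("A", "A", "B", "B")), 0.999)

  expect_error(silhouette_score(X, rep("A", 4)), "single cluster")
})

test_that("contextual clustering recovers planted archetype groups", {
  g <- planted_three_group(seed = 1, n_per_group = 10)
  seqs <- player_sequences(g)
  prof <- profile_table(seqs)
  ctx <- contextual_cluster(prof, K_max = 8, seed = 1)
  gt <- ground_truth(g)
  planted <- gt$strategy_name[match(prof$player, gt$player)]
  expect_equal(ctx$k, 3L)
  expect_gt(adjusted_rand(ctx$labels, planted), 0.9)
  expect_gt(ctx$silhouette, 0.5)
})

test_that("degenerate cohorts collapse to the right cluster counts", {
  # all players identical: k = 1, no silhouette
  g <- simulate_cohort(archetype_cohort(c(AllC = 10)), 30, "FP", seed = 1)
  prof <- profile_table(player_sequences(g))
  ctx <- contextual_cluster(prof, K_max = 8, seed = 1)
  expect_equal(ctx$k, 1L)
  expect_true(is.na(ctx$silhouette))

  # two coincident feature points per group: k = 2, silhouette 1
  g2 <- simulate_cohort(archetype_cohort(c(AllC = 6, AllD = 6)), 30, "FP",
                        seed = 1)
  prof2 <- profile_table(player_sequences(g2))
  ctx2 <- contextual_cluster(prof2, K_max = 8, seed = 1)
  expect_equal(ctx2$k, 2L)
  expect_equal(ctx2$silhouette, 1)
})

test_that("behavioral sub-clustering separates distinct response styles", {
  # identical members: a single sub-cluster
  g <- simulate_cohort(archetype_cohort(c(TFT = 8)), 40, "FP", seed = 1)
  prof <- profile_table(player_sequences(g))
  beh <- behavioral_subcluster(prof, K_max = 6, seed = 1)
  expect_equal(beh$k, 1L)

  # constructed TFT-like vs WSLS-like cooperative-response counts
  prof2 <- data.frame(
    player = sprintf("P%d", 1:8),
    n_cc = 50, n_cd = 20, n_dc = 20, n_dd = 9,
    c_cc = c(rep(48, 4), rep(49, 4)),
    c_cd = c(rep(0, 4), rep(1, 4)),
    c_dc = c(rep(19, 4), rep(0, 4)),   # TFT cooperates after DC
    c_dd = c(rep(0, 4), rep(8, 4)))    # WSLS shifts to C after DD
  beh2 <- behavioral_subcluster(prof2, K_max = 6, seed = 1)
  expect_equal(beh2$k, 2L)
  expect_equal(length(unique(beh2$labels[1:4])), 1L)
  expect_equal(length(unique(beh2$labels[5:8])), 1L)
  expect_false(beh2$labels[1] == beh2$labels[5])

  # size-3 cluster passes through untouched
  beh3 <- behavioral_subcluster(prof2[1:3, ], K_max = 6, seed = 1)
  expect_equal(beh3$k, 1L)
  expect_equal(unname(beh3$labels), rep(1L, 3))
})

test_that("cluster labels are invariant to row permutation up to relabeling", {
  g <- planted_three_group(seed = 4, n_per_group = 8)
  prof <- profile_table(player_sequences(g))
  ctx <- contextual_cluster(prof, K_max = 5, seed = 2)
  perm <- sample(nrow(prof))
  ctx_p <- contextual_cluster(prof[perm, ], K_max = 5, seed = 2)
  expect_equal(adjusted_rand(ctx$labels[prof$player[perm]], ctx_p$labels), 1)
})
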