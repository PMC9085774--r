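test_that("noiseless archetypes respond to contexts as defined", {
  reg <- archetype_registry()
  expect_equal(play_action(reg$AllD, "CC"), "D")
  expect_equal(play_action(reg$TFT, "DC"), "C")   # copies opponent's C
  expect_equal(play_action(reg$TFT, "CD"), "D")
  expect_equal(play_action(reg$WSLS, "DD"), "C")  # lose-shift
  expect_equal(play_action(reg$WSLS, "DC"), "D")  # win-stay on T
  expect_equal(play_action(reg$Grim, "DD"), "D")
  expect_equal(play_action(reg$AllC, "none"), "C")
  expect_error(play_action(reg$TFT, "XX"), "context")
})

test_that("strategy_spec validates probabilities", {
  expect_error(strategy_spec("bad", 1.2, 1, 1, 1, 1), "p_init")
  expect_error(strategy_spec("bad", 1, 1, 1, 1, 1, noise = -0.1), "noise")
  expect_error(archetype_cohort(c(NotAStrategy = 2)), "unknown archetype")
})

test_that("payoffs reproduce the payoff table and reject bad input", {
  expect_equal(payoffs("C", "C")[1, ], c(focal = 3, other = 3))
  expect_equal(payoffs("D", "C")[1, ], c(focal = 4, other = 0))
  expect_equal(payoffs("C", "D")[1, ], c(focal = 0, other = 4))
  expect_equal(payoffs("D", "D")[1, ], c(focal = 1, other = 1))
  expect_error(payoffs("C", "X"), "invalid action")
  # dilemma conditions enforced on construction
  expect_error(payoff_matrix(R = 3, S = 0, T = 2, P = 1), "T > R > P > S")
  expect_error(payoff_matrix(R = 3, S = 0, T = 7, P = 1), "2R")
})

test_that("FP schedules repeat one perfect matching; SP never repeats", {
  fp <- make_schedule(4, 3, "FP")
  expect_equal(nrow(unique(fp)), 1L)
  expect_true(all(fp[1, fp[1, ]] == 1:4))  # symmetric matching

  fp2 <- make_schedule(2, 5, "FP")
  expect_equal(fp2, matrix(c(2L, 1L), 5, 2, byrow = TRUE))

  sp <- make_schedule(4, 100, "SP", seed = 7)
  expect_true(all(vapply(seq_len(nrow(sp)),
                         function(r) all(sp[r, sp[r, ]] == 1:4), logical(1))))
  expect_false(any(sp[-1, ] == sp[-nrow(sp), ]))  # opponent changes each round

  expect_error(make_schedule(5, 10, "FP"), "even")
  expect_error(make_schedule(2, 10, "SP"), "cannot change")
})

test_that("simulation is reproducible and matches hand-traced games", {
  reg <- archetype_registry()
  # TFT vs AllD: round 1 (C,D) = (0,4); rounds 2-3 (D,D) = (1,1) each
  g <- simulate_cohort(list(reg$TFT, reg$AllD), 3, "FP", seed = 1)
  totals <- tapply(g$payoff, g$player, sum)
  expect_equal(as.vector(totals), c(2, 6))

  # AllD pair: all D, P = 1 per round
  g2 <- simulate_cohort(list(reg$AllD, reg$AllD), 3, "FP", seed = 1)
  expect_true(all(g2$action == "D"))
  expect_equal(as.vector(tapply(g2$payoff, g2$player, sum)), c(3, 3))

  # TFT vs AllC cooperates throughout
  g3 <- simulate_cohort(list(reg$TFT, reg$AllC), 10, "FP", seed = 1)
  expect_true(all(g3$action == "C"))
  expect_equal(as.vector(tapply(g3$payoff, g3$player, sum)), c(30, 30))

  # identical seed + config => byte-identical table
  coh <- archetype_cohort(c(TFT = 4, WSLS = 4), noise = 0.1)
  expect_identical(simulate_cohort(coh, 20, "SP", seed = 42),
                   simulate_cohort(coh, 20, "SP", seed = 42))
  expect_false(identical(simulate_cohort(coh, 20, "SP", seed = 42),
                         simulate_cohort(coh, 20, "SP", seed = 43)))
})

test_that("game tables satisfy their structural invariants", {
  coh <- archetype_cohort(c(AllC = 4, TFT = 4, Random = 4), noise = 0.05)
  for (mode in c("FP", "SP")) {
    g <- simulate_cohort(coh, 30, mode, seed = 9)
    expect_true(validate_game_table(g))
    # per-pair per-round payoff sums
    key <- paste(g$opponent, g$round)
    mirror <- match(paste(g$player, g$round), key)
    expect_true(all((g$payoff + g$payoff[mirror]) %in% c(6, 4, 2)))
  }
  bad <- simulate_cohort(coh, 5, "FP", seed = 1)
  bad$opp_action[1] <- ifelse(bad$opp_action[1] == "C", "D", "C")
  expect_error(validate_game_table(bad), "mirror")
})

test_that("execution noise surfaces at its nominal rate", {
  # AllC vs AllC with noise eps: each executed action is D with prob eps
  eps <- 0.1
  coh <- archetype_cohort(c(AllC = 2), noise = eps)
  g <- simulate_cohort(coh, 2000, "FP", seed = 5)
  frac_d <- mean(g$action == "D")
  tol <- 4 * sqrt(eps * (1 - eps) / nrow(g))
  expect_lt(abs(frac_d - eps), tol)
})

test_that("game tables round-trip through CSV with ground truth", {
  coh <- archetype_cohort(c(TFT = 2, AllD = 2), noise = 0.05)
  g <- simulate_cohort(coh, 10, "FP", seed = 3)
  csv <- tempfile(fileext = ".csv")
  gt_csv <- tempfile(fileext = ".csv")
  write_game_table(g, csv, ground_truth_path = gt_csv)
  g2 <- read_game_table(csv, ground_truth_path = gt_csv)
  expect_equal(as.data.frame(g)[order(g$round, g$player), ],
               as.data.frame(g2)[order(g2$round, g2$player), ],
               ignore_attr = TRUE)
  expect_equal(ground_truth(g2)$strategy_name, ground_truth(g)$strategy_name)

  # column-mapping importer for foreign schemas
  foreign <- as.data.frame(g)
  names(foreign)[names(foreign) == "player"] <- "subject_id"
  foreign$payoff <- NULL
  f_csv <- tempfile(fileext = ".csv")
  utils::write.csv(foreign, f_csv, row.names = FALSE)
  g3 <- read_game_table(f_csv, column_map = c(player = "subject_id"))
  expect_equal(g3$payoff, g$payoff)  # recomputed from actions
  unlink(c(csv, gt_csv, f_csv))
})
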