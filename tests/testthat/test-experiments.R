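test_that("summary statistics use population normalisation", {
  expect_equal(mean_sd_sem(5), c(mean = 5, sd = 0, sem = 0))
  st <- mean_sd_sem(c(1, 2, 3))
  expect_equal(st[["mean"]], 2)
  expect_equal(st[["sd"]], sqrt(2 / 3))
  expect_equal(st[["sem"]], sqrt(2 / 3) / sqrt(3))
  expect_equal(mean_sd_sem(rep(4.2, 10))[["sd"]], 0)
  expect_error(mean_sd_sem(numeric(0)), "length")
})

test_that("child seeds are reproducible functions of the master seed", {
  expect_identical(child_seeds(42, 10), child_seeds(42, 10))
  expect_false(any(duplicated(child_seeds(42, 1000))))
  expect_false(identical(child_seeds(42, 10), child_seeds(43, 10)))
})

test_that("a one-cell one-simulation sweep equals the bare run", {
  sw <- sweep_ratio_grid("SR", "IR",
    ratios = 1, n_sims = 1, master_seed = 77
  )
  expect_identical(nrow(sw), 1L)
  seed <- child_seeds(77, 1)
  run <- run_navigation(
    agent_spec("SR", "IR", 0.5, 0.5, 0.5, 0.5),
    "original",
    seed = seed
  )
  expect_equal(sw$mean, run$total_rewards)
})

test_that("same-representation sweeps merge symmetric conditions", {
  sw <- sweep_free_rates("IR", "IR",
    rates = c(0.2, 0.8), n_sims = 2,
    master_seed = 78
  )
  # 4 (pos, neg) combinations per system -> 4*5/2 = 10 unordered pairs
  expect_identical(nrow(sw), 10L)
  expect_true(all(sw$n == 2))
  key <- function(p, m) paste(p, m)
  k1 <- key(sw$alpha1_pos, sw$alpha1_neg)
  k2 <- key(sw$alpha2_pos, sw$alpha2_neg)
  expect_false(any(duplicated(paste(pmin(k1, k2), pmax(k1, k2)))))

  # ratio grid: same-representation half-grid vs full mixed grid
  swr <- sweep_ratio_grid("IR", "IR",
    ratios = c(0.5, 1, 2), n_sims = 1,
    master_seed = 79
  )
  expect_identical(nrow(swr), 6L) # 3*4/2
  swm <- sweep_ratio_grid("SR", "IR",
    ratios = c(0.5, 1, 2), n_sims = 1,
    master_seed = 79
  )
  expect_identical(nrow(swm), 9L)
})

test_that("ratio cells implying a rate above 1 are dropped", {
  sw <- sweep_ratio_grid("SR", "IR",
    sum_alpha = 1.25, ratios = ratio_grid(),
    n_sims = 1, master_seed = 80
  )
  kept <- sort(unique(sw$ratio1))
  expect_identical(kept, sort(setdiff(ratio_grid(), c(0.2, 5))))
  expect_true(all(sw[, c(
    "alpha1_pos", "alpha1_neg",
    "alpha2_pos", "alpha2_neg"
  )] <= 1))
})

test_that("sweep means stay within the attainable range", {
  sw <- sweep_ratio_grid("SR", "IR",
    ratios = c(0.25, 4), n_sims = 3,
    master_seed = 81
  )
  expect_true(all(sw$mean >= 0 & sw$mean <= 900))
  expect_equal(sw$sem, sw$sd / sqrt(sw$n))
})

test_that("best-condition frequencies count one argmax per repeat", {
  # toy two-condition sweep with a known mean gap
  toy_sweep <- function(ms) {
    set.seed(ms)
    data.frame(
      cond = c("worse", "better"),
      mean = c(rnorm(1, 10, 1), rnorm(1, 13, 1)),
      sd = 1, sem = 1, n = 1
    )
  }
  freq <- best_condition_frequency(toy_sweep, n_repeats = 30, master_seed = 5)
  expect_identical(sum(freq$best_count), 30L)
  # mass concentrates on the truly better condition (gap = 3 SD)
  expect_identical(freq$cond[1], "better")
  expect_gte(freq$best_count[freq$cond == "better"], 25)
})

test_that("learning curves demand logs from the original task", {
  fake <- list(list(
    task_variant = "single_epoch", goal_times = 600L,
    placement_epochs = 1L
  ))
  expect_error(learning_curves(fake), "original task")
})

test_that("learning curves from real runs are structurally sound", {
  spec <- agent_spec("SR", "IR", 0.8, 0.2, 0.2, 0.8)
  seeds <- child_seeds(91, 30)
  logs <- lapply(seeds, function(sd) {
    run_navigation(spec, "original", seed = sd, want_snapshot = FALSE)
  })
  cv <- learning_curves(logs)
  expect_gt(nrow(cv), 0)
  expect_identical(cv$reward_index, seq_len(nrow(cv)))
  # each reward needs at least 5 steps (4 moves + the teleport step)
  expect_true(all(cv$mean_time >= 5))
  expect_true(all(cv$min_n_sims >= 0.25 * 30))
})
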