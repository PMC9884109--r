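test_that("task variants have the published epoch structure", {
  orig <- nav_task("original")
  expect_identical(orig$n_noreward_steps, 500L)
  expect_identical(orig$epoch_length, 500L)
  expect_identical(orig$n_reward_epochs, 9L)
  expect_equal(orig$p_special, 0.6)

  set.seed(1)
  orig <- draw_task_order(orig)
  expect_identical(sort(orig$special_state_order), sort(orig$candidate_states))

  dse <- nav_task("deterministic_short_epochs")
  expect_identical(dse$epoch_length, 100L)
  expect_identical(dse$n_reward_epochs, 45L)
  expect_equal(dse$p_special, 1)
  set.seed(1)
  dse <- draw_task_order(dse)
  expect_length(dse$special_state_order, 45)
  # five consecutive permutations, each covering all nine candidates
  for (b in 0:4) {
    block <- dse$special_state_order[b * 9 + 1:9]
    expect_identical(sort(block), sort(dse$candidate_states))
  }

  single <- nav_task("single_epoch")
  expect_identical(single$epoch_length, 4500L)
  expect_identical(single$n_reward_epochs, 1L)
  set.seed(1)
  expect_length(draw_task_order(single)$special_state_order, 1)

  expect_equal(nav_task("uniform_candidates")$p_special, 1 / 9)
  expect_identical(nav_task("periodic_reset_250")$reset_period, 250L)
  fixed <- nav_task("fixed_order_control")
  expect_identical(
    fixed$fixed_reward_order,
    c(state_index(5, 1), state_index(5, 5), state_index(1, 5))
  )
  expect_error(nav_task("not_a_variant"))

  # every variant preserves the 500 + 4500 step budget
  for (v in c(
    "original", "p_special_100", "periodic_reset_50", "single_epoch",
    "deterministic_short_epochs", "uniform_candidates", "fixed_order_control"
  )) {
    tk <- nav_task(v)
    expect_identical(
      tk$n_noreward_steps + tk$epoch_length * tk$n_reward_epochs, 5000L
    )
  }
})

test_that("reward placement has the stated distribution", {
  task <- nav_task("original")
  special <- task$candidate_states[1]
  set.seed(7)
  draws <- replicate(10000, draw_reward_location(task, special))
  p_hat <- mean(draws == special)
  # within 3 binomial SDs of 0.6
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))
  others <- table(draws[draws != special])
  expect_length(others, 8)
  expect_true(all(abs(others / 10000 - 0.05) < 3 * sqrt(0.05 * 0.95 / 10000)))

  # degenerate distribution at p_special = 1
  task100 <- nav_task("p_special_100")
  set.seed(7)
  expect_true(all(replicate(50, draw_reward_location(task100, special))
  == special))

  # uniform variant: each candidate ~ 1/9
  uni <- nav_task("uniform_candidates")
  set.seed(7)
  draws <- replicate(18000, draw_reward_location(uni, special))
  freqs <- table(factor(draws, levels = uni$candidate_states)) / 18000
  expect_true(all(abs(freqs - 1 / 9) < 3 * sqrt((1 / 9) * (8 / 9) / 18000)))

  expect_error(
    draw_reward_location(nav_task("fixed_order_control"), special),
    "deterministic"
  )
  expect_error(draw_reward_location(task, 3), "candidate")
})

test_that("nav_step moves, consumes, teleports, and persists rewards", {
  task <- nav_task("original")
  set.seed(11)
  task <- draw_task_order(task)
  env <- nav_env_init(task)
  # ordinary move in the no-reward epoch
  out <- nav_step(env, action = 2L, task)
  expect_equal(out$reward, 0)
  expect_false(out$terminal)
  expect_identical(out$env$current, 2L)
  expect_identical(out$env$t, 2L)
  expect_error(nav_step(out$env, action = 25L, task), "neighbour")

  # walk to the end of the no-reward epoch: reward appears at t = 501
  env <- out$env
  while (env$t <= 500L) {
    nb <- grid_neighbors(env$current)
    env <- nav_step(env, nb[1], task)$env
  }
  expect_identical(env$epoch_index, 1L)
  expect_identical(env$special_state, task$special_state_order[1])
  expect_true(env$reward_state %in% task$candidate_states)

  # place the agent on the reward: consumption, teleport, fresh reward
  env$current <- env$reward_state
  out <- nav_step(env, NA, task)
  expect_equal(out$reward, 1)
  expect_true(out$terminal)
  expect_identical(out$env$current, 1L) # carried back to start
  expect_true(out$env$reward_state %in% task$candidate_states)

  # an unconsumed reward persists across an epoch boundary
  env2 <- out$env
  env2$t <- 1000L # last step of epoch 1
  env2$current <- 13L
  pending <- env2$reward_state
  out2 <- nav_step(env2, grid_neighbors(13L)[1], task)
  expect_identical(out2$env$reward_state, pending)
  expect_identical(out2$env$epoch_index, 2L)
  expect_identical(out2$env$special_state, task$special_state_order[2])
})

test_that("fixed-order control cycles its three states deterministically", {
  task <- nav_task("fixed_order_control")
  task$special_state_order <- integer(0)
  env <- nav_env_init(task)
  env$t <- 500L
  env$current <- 13L
  env <- nav_step(env, grid_neighbors(13L)[1], task)$env
  expect_identical(env$reward_state, state_index(5, 1))
  seen <- integer(0)
  for (i in 1:4) {
    env$current <- env$reward_state
    seen <- c(seen, env$reward_state)
    env <- nav_step(env, NA, task)$env
  }
  expect_identical(
    seen,
    c(
      state_index(5, 1), state_index(5, 5), state_index(1, 5),
      state_index(5, 1)
    )
  )
})

test_that("periodic resets re-draw the reward at reset boundaries", {
  task <- nav_task("periodic_reset_50")
  set.seed(3)
  task <- draw_task_order(task)
  env <- nav_env_init(task)
  env$t <- 550L # next step starts at t = 551 = 501 + 50
  env$current <- 13L
  env$epoch_index <- 1L
  env$special_state <- task$special_state_order[1]
  env$reward_state <- task$candidate_states[1]
  # across many re-draws the reset boundary must eventually move the reward
  set.seed(4)
  moved <- FALSE
  for (rep in 1:50) {
    e <- env
    out <- nav_step(e, grid_neighbors(13L)[1], task)
    if (out$env$reward_state != env$reward_state) moved <- TRUE
  }
  expect_true(moved)
  # no reset one step earlier
  env2 <- env
  env2$t <- 549L
  out <- nav_step(env2, grid_neighbors(13L)[1], task)
  expect_identical(out$env$reward_state, env$reward_state)
})
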