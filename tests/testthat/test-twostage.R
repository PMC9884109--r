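test_that("random-walk schedules respect bounds and step size", {
  set.seed(41)
  sched <- make_random_walk_schedule(5000, n_options = 4)
  expect_true(all(sched >= 0.25 & sched <= 0.75))
  # interior steps (away from the reflecting boundaries) have SD ~ 0.025
  steps <- diff(sched[, 1])
  interior <- sched[-nrow(sched), 1] > 0.30 & sched[-nrow(sched), 1] < 0.70
  expect_equal(sd(steps[interior]), 0.025, tolerance = 0.15)
  # degenerate walk is constant
  set.seed(41)
  flat <- make_random_walk_schedule(50, 4, step_sd = 0)
  expect_true(all(apply(flat, 2, function(x) all(x == x[1]))))
})

test_that("contingency schedules switch at the listed trials", {
  s2 <- make_contingency_schedule("contingency_change", 201)
  expect_identical(dim(s2), c(201L, 4L))
  expect_equal(s2[1, ], c(0.1, 0.5, 0.5, 0.9))
  expect_equal(s2[50, ], c(0.1, 0.5, 0.5, 0.9))
  expect_equal(s2[51, ], c(0.9, 0.5, 0.5, 0.1))
  expect_equal(s2[101, ], c(0.5, 0.1, 0.9, 0.5))
  expect_equal(s2[151, ], c(0.5, 0.9, 0.1, 0.5))
  expect_equal(s2[201, ], c(0.5, 0.9, 0.1, 0.5))

  s3 <- make_contingency_schedule("three_option", 150)
  expect_identical(dim(s3), c(150L, 6L))
  expect_equal(s3[1, ], c(0.5, 0.9, 0.1, 0.5, 0.1, 0.5))
  expect_equal(s3[51, ], c(0.5, 0.1, 0.9, 0.5, 0.5, 0.1))
  expect_equal(s3[101, ], c(0.1, 0.5, 0.1, 0.5, 0.5, 0.9))
  expect_equal(s3[150, ], c(0.1, 0.5, 0.1, 0.5, 0.5, 0.9))
})

test_that("stage transitions follow the transition matrix", {
  task2 <- twostage_task("random_walk")
  set.seed(51)
  draws <- replicate(4000, run_trial_transition(1, task2))
  expect_equal(mean(draws == 1), 0.7, tolerance = 3 * sqrt(0.21 / 4000) / 0.7)
  task3 <- twostage_task("three_option")
  set.seed(51)
  draws3 <- replicate(6000, run_trial_transition(2, task3))
  freqs <- table(factor(draws3, levels = 1:3)) / 6000
  expect_equal(as.numeric(freqs), c(0.2, 0.6, 0.2), tolerance = 0.1)
  # degenerate row
  taskd <- task2
  taskd$transition_matrix[1, ] <- c(1, 0)
  set.seed(51)
  expect_true(all(replicate(20, run_trial_transition(1, taskd)) == 1))
})

test_that("initial SR encodes the presumed transitions and random policy", {
  task2 <- twostage_task("random_walk")
  sig <- initial_sr_twostage(task2, gamma = 1)
  expect_equal(sig[1, ], c(1, 0, 0.35, 0.35, 0.15, 0.15))
  expect_equal(sig[2, ], c(0, 1, 0.15, 0.15, 0.35, 0.35))
  # second-stage rows are identity rows (terminal options)
  for (s in 3:6) expect_equal(sig[s, ], as.numeric(1:6 == s))
  # first-stage rows sum to 1 + gamma
  expect_equal(unname(rowSums(sig)[1:2]), rep(2, 2))
  g <- 0.9
  expect_equal(unname(rowSums(initial_sr_twostage(task2, g))[1:2]),
    rep(1 + g, 2))

  task3 <- twostage_task("three_option")
  sig3 <- initial_sr_twostage(task3, gamma = 1)
  expect_equal(sig3[1, ], c(1, 0, 0, 0.3, 0.3, 0.1, 0.1, 0.1, 0.1))
  expect_equal(unname(rowSums(sig3)[1:3]), rep(2, 3))
})

test_that("two-stage engines agree bit for bit and are reproducible", {
  spec <- agent_spec("SR", "IR", 0.8, 0.2, 0.2, 0.8, gamma = 1, beta = 5)
  for (v in c("random_walk", "contingency_change", "three_option")) {
    rc <- run_twostage(spec, v, seed = 61)
    rr <- run_twostage(spec, v, seed = 61, engine = "r")
    expect_identical(rc$rewards, rr$rewards)
    expect_identical(rc$first_choice, rr$first_choice)
    expect_identical(rc$second_choice, rr$second_choice)
    expect_identical(unname(rc$v_system1), unname(rr$v_system1))
    expect_identical(unname(rc$v_system2), unname(rr$v_system2))
    expect_identical(
      run_twostage(spec, v, seed = 61)$rewards,
      rc$rewards
    )
  }
})

test_that("zero-initialised agents have a zero first-stage RPE on trial 1", {
  task <- twostage_task("random_walk")
  spec <- agent_spec("SR", "IR", 0.8, 0.2, 0.2, 0.8, gamma = 1, beta = 5)
  ag <- agent_init(spec, 6, sigma_init = initial_sr_twostage(task, 1))
  out <- agent_step(ag, 1, 3, reward = 0, terminal = FALSE)
  expect_identical(out$delta, 0)
})

test_that("flat reward schedules yield chance-level totals for any agent", {
  task <- twostage_task("random_walk")
  task$reward_prob_schedule <- matrix(0.25, task$n_trials, 4)
  for (spec in list(
    agent_spec("SR", "IR", 0.8, 0.2, 0.2, 0.8, gamma = 1, beta = 5),
    agent_spec("IR", "IR", 0.5, 0.5, 0.5, 0.5, gamma = 1, beta = 5)
  )) {
    totals <- vapply(
      1:150,
      function(sd) run_twostage(spec, task, seed = sd)$total_rewards,
      numeric(1)
    )
    # mean ~ 0.25 * 201 = 50.25, SE ~ 0.5
    expect_equal(mean(totals), 0.25 * task$n_trials, tolerance = 0.04)
  }
})
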