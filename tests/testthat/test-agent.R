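test_that("softmax selection has the stated probabilities", {
  set.seed(1)
  # symmetry
  expect_equal(softmax_select(c(0.3, 0.3), beta = 5)$probs, c(0.5, 0.5))
  # uniform limit at beta = 0
  expect_equal(softmax_select(rep(0.7, 4) + rnorm(4), beta = 0)$probs,
    rep(0.25, 4),
    tolerance = 1e-12
  )
  # direct evaluation: values (0, 0.2), beta 5 -> (1/(1+e), e/(1+e))
  expect_equal(
    softmax_select(c(0, 0.2), beta = 5)$probs,
    c(1 / (1 + exp(1)), exp(1) / (1 + exp(1)))
  )
  expect_error(softmax_select(numeric(0), 5), "no options")
  expect_error(softmax_select(c(1, Inf), 5), "finite")
})

test_that("TD-RPE follows the terminal/non-terminal equations", {
  expect_equal(value_td_rpe(0, NA, 1, 0.7, terminal = TRUE), 1)
  expect_equal(value_td_rpe(0.5, 0.5, 0, 0.7, terminal = FALSE), -0.15)
  expect_equal(value_td_rpe(0, 0, 0, 0.7, terminal = FALSE), 0)
  # terminal drops the successor term entirely
  expect_equal(value_td_rpe(0.25, 99, 1, 0.7, terminal = TRUE), 0.75)
})

test_that("valence gating treats zero TD-RPE as positive", {
  expect_equal(valence_rate(0, 0.8, 0.2), 0.8)
  expect_equal(valence_rate(0.3, 0.8, 0.2), 0.8)
  expect_equal(valence_rate(-0.3, 0.8, 0.2), 0.2)
})

test_that("IR and SR elementary updates act on the right entries", {
  ir <- list(rep = "IR", V = numeric(5))
  ir <- ir_update(ir, 2, delta = 0.6, alpha_eff = 0.8)
  expect_equal(ir$V, c(0, 0.48, 0, 0, 0))
  ir <- ir_update(ir, 2, delta = -0.5, alpha_eff = 0.2)
  expect_equal(ir$V[2], 0.38)
  expect_identical(ir_update(ir, 4, delta = 0, alpha_eff = 0.9)$V, ir$V)

  sr <- list(rep = "SR", sigma = matrix(0, 4, 4), w = numeric(4))
  # non-terminal step from zero-initialised features
  sr1 <- sr_feature_update(sr, 2, 3, gamma = 0.7, alpha_sr = 0.05,
    terminal = FALSE
  )
  expect_equal(sr1$sigma[2, ], c(0, 0.05, 0, 0))
  expect_equal(sr1$sigma[-2, ], sr$sigma[-2, ]) # only row s changes
  # terminal step: successor term dropped, same result from zero
  sr2 <- sr_feature_update(sr, 2, NA, gamma = 0.7, alpha_sr = 0.05,
    terminal = TRUE
  )
  expect_equal(sr2$sigma[2, ], c(0, 0.05, 0, 0))
  # non-terminal step picks up the successor's features
  srn <- sr
  srn$sigma[3, ] <- c(0, 0, 1, 0.5)
  sr3 <- sr_feature_update(srn, 2, 3, gamma = 0.7, alpha_sr = 0.05,
    terminal = FALSE
  )
  expect_equal(sr3$sigma[2, ], 0.05 * (c(0, 1, 0, 0) + 0.7 * c(0, 0, 1, 0.5)))

  # sr_value: identity features make the SR an IR
  sid <- list(rep = "SR", sigma = diag(4), w = c(1, -2, 0.5, 0))
  expect_equal(vapply(1:4, function(s) sr_value(sid, s), numeric(1)),
    sid$w)
  expect_equal(sr_value(list(rep = "SR", sigma = rbind(c(0.5, 0.5, 0)),
    w = c(1, -1, 7)), 1), 0)

  # weight update spreads credit over the feature row
  sw <- list(rep = "SR", sigma = rbind(c(0.5, 0.2, 0), c(0, 1, 0),
    c(0, 0, 1)), w = numeric(3))
  sw1 <- sr_weight_update(sw, 1, delta = -0.2, alpha_eff = 0.25)
  expect_equal(sw1$w, 0.25 * c(0.5, 0.2, 0) * -0.2)
  expect_identical(
    sr_weight_update(list(rep = "SR", sigma = matrix(0, 2, 2),
      w = c(1, 2)), 1, 5, 0.9)$w,
    c(1, 2)
  )
})

test_that("integrated value is the mean of the two systems", {
  spec <- agent_spec("IR", "IR", 0.5, 0.5, 0.5, 0.5)
  ag <- agent_init(spec, 4)
  expect_equal(integrated_value(ag, 1:4), rep(0, 4))
  ag$sys1$V[2] <- 0.6
  ag$sys2$V[2] <- -0.4
  expect_equal(integrated_value(ag, 2), 0.1)
})

test_that("agent_step shares one TD-RPE and orchestrates both systems", {
  spec <- agent_spec("SR", "IR", 0.8, 0.2, 0.4, 0.6,
    alpha_sr = 0.05, gamma = 0.7
  )
  ag <- agent_init(spec, 4)
  ag$sys1$sigma <- diag(4)
  ag$sys1$w <- c(0.2, 0, 0, 0)
  ag$sys2$V <- c(0.4, 0.1, 0, 0)
  # non-terminal step 1 -> 2: delta from integrated pre-update values
  v1 <- (0.2 + 0.4) / 2
  v2 <- (0 + 0.1) / 2
  delta <- 0.7 * v2 - v1
  out <- agent_step(ag, 1, 2, reward = 0, terminal = FALSE)
  expect_equal(out$delta, delta)
  # IR got alpha- (delta < 0) on state 1 only
  expect_equal(out$agent$sys2$V, c(0.4 + 0.6 * delta, 0.1, 0, 0))
  # SR feature row of state 1 updated first, then weights use that row
  sig_row <- c(1, 0, 0, 0) + 0.05 * (c(1, 0, 0, 0) + 0.7 * c(0, 1, 0, 0) -
    c(1, 0, 0, 0))
  expect_equal(out$agent$sys1$sigma[1, ], sig_row)
  expect_equal(out$agent$sys1$w, c(0.2, 0, 0, 0) + 0.2 * sig_row * delta)

  # terminal step at state 1 with reward 1
  out_t <- agent_step(ag, 1, NA, reward = 1, terminal = TRUE)
  expect_equal(out_t$delta, 1 - v1)
  # terminal SR feature update drops the successor term
  expect_equal(
    out_t$agent$sys1$sigma[1, ],
    c(1, 0, 0, 0) + 0.05 * (c(1, 0, 0, 0) - c(1, 0, 0, 0))
  )
  # update_features = FALSE leaves the SR matrix untouched
  out_nf <- agent_step(ag, 1, NA, reward = 1, terminal = TRUE,
    update_features = FALSE
  )
  expect_identical(out_nf$agent$sys1$sigma, ag$sys1$sigma)
})

test_that("agent_spec validates rates and parameters", {
  expect_error(agent_spec("SR", "IR", alpha1_pos = 1.2), "\\[0, 1\\]")
  expect_error(agent_spec("SR", "IR", alpha2_neg = -0.1), "\\[0, 1\\]")
  expect_error(agent_spec("SR", "IR", beta = -1), "beta")
  expect_error(agent_spec("SR", "IR", gamma = 1.1), "gamma")
  expect_equal(rates_from_ratio(1, 4), c(pos = 0.8, neg = 0.2))
  expect_equal(rates_from_ratio(1, 0.25), c(pos = 0.2, neg = 0.8))
  expect_equal(sum(rates_from_ratio(0.75, 3)), 0.75)
})
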