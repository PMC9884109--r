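#' Build a two-stage task specification
#'
#' Three variants of the sequential two-stage decision task:
#' \describe{
#'   \item{`random_walk`}{the classic task: two first-stage options, each
#'     leading to one of two second-stage option pairs with fixed 70%/30%
#'     probabilities; the reward probability of each of the four
#'     second-stage options drifts as an independent Gaussian random walk
#'     (step SD 0.025) with reflecting boundaries at 0.25 and 0.75, over
#'     201 trials.}
#'   \item{`contingency_change`}{same structure, but the four reward
#'     probabilities are fixed values that switch three times: initially
#'     (0.1, 0.5) for the first pair and (0.5, 0.9) for the second,
#'     changing at trials 51, 101, and 151.}
#'   \item{`three_option`}{three first-stage options and three pairs,
#'     transition probabilities (0.6, 0.2, 0.2) rows; six fixed reward
#'     probabilities switching at trials 51 and 101, over 150 trials.}
#' }
#'
#' @param variant One of `"random_walk"`, `"contingency_change"`,
#'   `"three_option"`.
#' @return An object of class `twostage_task` with `n_trials`, `n_first`,
#'   `n_pairs`, the `transition_matrix` (first-stage option x pair), and
#'   for the fixed-schedule variants the full `reward_prob_schedule`
#'   (trial x second-stage option). For `random_walk` the schedule is
#'   drawn per run by [make_random_walk_schedule()].
#' @export
twostage_task <- function(variant = c(
                            "random_walk", "contingency_change",
                            "three_option"
                          )) {
  variant <- match.arg(variant)
  if (variant == "three_option") {
    trans <- matrix(0.2, 3, 3)
    diag(trans) <- 0.6
    spec <- list(
      variant = variant, n_trials = 150L, n_first = 3L, n_pairs = 3L,
      transition_matrix = trans,
      reward_prob_schedule = make_contingency_schedule(variant, 150L)
    )
  } else {
    trans <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2, byrow = TRUE)
    spec <- list(
      variant = variant, n_trials = 201L, n_first = 2L, n_pairs = 2L,
      transition_matrix = trans,
      reward_prob_schedule = if (variant == "contingency_change") {
        make_contingency_schedule(variant, 201L)
      } else {
        NULL
      }
    )
  }
  structure(spec, class = "twostage_task")
}

#' Gaussian random-walk reward-probability schedule
#'
#' Each option's reward probability starts uniformly in \[0.25, 0.75\]
#' (the stationary support; the initial level is not otherwise
#' constrained) and changes at each trial by an independent Gaussian step
#' (mean 0, SD `step_sd`), reflected at the boundaries 0.25 and 0.75.
#'
#' @param n_trials Number of trials.
#' @param n_options Number of second-stage options (columns).
#' @param step_sd Step standard deviation (default 0.025).
#' @param lower,upper Reflecting boundaries.
#' @return A `n_trials` x `n_options` matrix of probabilities.
#' @export
make_random_walk_schedule <- function(n_trials, n_options = 4L,
                                      step_sd = 0.025,
                                      lower = 0.25, upper = 0.75) {
  stopifnot(n_trials >= 1)
  sched <- matrix(NA_real_, n_trials, n_options)
  p <- runif(n_options, lower, upper)
  sched[1, ] <- p
  if (n_trials > 1) {
    for (k in 2:n_trials) {
      p <- p + rnorm(n_options, 0, step_sd)
      # reflect at the boundaries
      for (i in seq_len(n_options)) {
        while (p[i] < lower || p[i] > upper) {
          if (p[i] < lower) p[i] <- 2 * lower - p[i]
          if (p[i] > upper) p[i] <- 2 * upper - p[i]
        }
      }
      sched[k, ] <- p
    }
  }
  sched
}

#' Piecewise-constant reward-probability schedules
#'
#' The fixed schedules of the contingency-change variants. Trials are
#' 1-based: "changed at the 51st trial" means trials 1-50 use the first
#' block and trial 51 the second.
#'
#' @param variant `"contingency_change"` (four options, blocks starting
#'   at trials 1, 51, 101, 151 over 201 trials) or `"three_option"` (six
#'   options, blocks starting at trials 1, 51, 101 over 150 trials).
#' @param n_trials Number of trials.
#' @return A `n_trials` x options matrix of probabilities.
#' @export
make_contingency_schedule <- function(variant, n_trials) {
  variant <- match.arg(variant, c("contingency_change", "three_option"))
  if (variant == "contingency_change") {
    blocks <- rbind(
      c(0.1, 0.5, 0.5, 0.9),
      c(0.9, 0.5, 0.5, 0.1),
      c(0.5, 0.1, 0.9, 0.5),
      c(0.5, 0.9, 0.1, 0.5)
    )
    starts <- c(1L, 51L, 101L, 151L)
  } else {
    blocks <- rbind(
      c(0.5, 0.9, 0.1, 0.5, 0.1, 0.5),
      c(0.5, 0.1, 0.9, 0.5, 0.5, 0.1),
      c(0.1, 0.5, 0.1, 0.5, 0.5, 0.9)
    )
    starts <- c(1L, 51L, 101L)
  }
  block_of <- findInterval(seq_len(n_trials), starts)
  blocks[block_of, , drop = FALSE]
}

#' Initial SR matrix for the two-stage tasks
#'
#' The SR over all first- and second-stage options under the random
#' policy at the second stage, incorporating the presumed stage-
#' transition probabilities. Second-stage options are terminal, so their
#' rows are identity rows. A first-stage option's row has 1 on itself and
#' `gamma * P(pair) * 0.5` on each option of each pair.
#'
#' @param task A `twostage_task`.
#' @param gamma Discount factor (1 in the two-stage tasks).
#' @return A square matrix over `n_first + 2 * n_pairs` options.
#' @export
initial_sr_twostage <- function(task, gamma = 1) {
  stopifnot(inherits(task, "twostage_task"))
  n1 <- task$n_first
  n <- n1 + 2L * task$n_pairs
  sigma <- diag(n)
  for (i in seq_len(n1)) {
    for (p in seq_len(task$n_pairs)) {
      cols <- n1 + 2L * (p - 1L) + 1:2
      sigma[i, cols] <- gamma * task$transition_matrix[i, p] * 0.5
    }
  }
  sigma
}

#' Draw the second-stage pair reached from a first-stage choice
#'
#' @param first_choice First-stage option index.
#' @param task A `twostage_task`.
#' @return Pair index, drawn from the transition-matrix row (one uniform
#'   variate against the cumulative probabilities).
#' @export
run_trial_transition <- function(first_choice, task) {
  trow <- task$transition_matrix[first_choice, ]
  u <- runif(1)
  pair <- which(u <= cumsum(trow))[1]
  if (is.na(pair)) pair <- length(trow)
  pair
}

#' Run one two-stage simulation
#'
#' Per trial: first-stage choice (softmax over integrated first-stage
#' option values), stage transition, second-stage choice (softmax over
#' the reached pair), then the SARSA-type first-stage TD-RPE
#' `delta(1) = gamma * V(O2) - V(O1)` with its updates (the chosen
#' first-stage option's SR feature row is updated here, after the
#' transition), the Bernoulli outcome, and the second-stage TD-RPE
#' `delta(2) = R - V(O2)` computed from values reflecting the first-stage
#' updates. Second-stage options are terminal: their SR rows are never
#' updated. Defaults in the agent spec should be `gamma = 1`, `beta = 5`,
#' `alpha_sr = 0.05`.
#'
#' @param spec An [agent_spec()].
#' @param task A `twostage_task` or variant name.
#' @param seed Integer seed.
#' @param engine `"cpp"` or `"r"` (bit-identical).
#' @return An object of class `twostage_run` with `total_rewards`, the
#'   per-trial log (`first_choice`, `pair`, `second_choice`, `rewards`),
#'   final system values, and the realised `schedule`.
#' @export
run_twostage <- function(spec, task = "random_walk", seed,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "agent_spec"))
  if (!inherits(task, "twostage_task")) task <- twostage_task(task)
  set.seed(seed)
  sched <- task$reward_prob_schedule
  if (is.null(sched)) {
    sched <- make_random_walk_schedule(task$n_trials, 2L * task$n_pairs)
  }
  sigma0 <- initial_sr_twostage(task, spec$gamma)

  res <- if (engine == "cpp") {
    sim_twostage_cpp(
      spec$rep1 == "SR", spec$rep2 == "SR",
      spec$alpha1_pos, spec$alpha1_neg, spec$alpha2_pos, spec$alpha2_neg,
      spec$alpha_sr, spec$beta, spec$gamma,
      task$n_first, task$n_pairs, task$transition_matrix, sched, sigma0
    )
  } else {
    sim_twostage_r(spec, task, sched, sigma0)
  }
  structure(
    c(res, list(
      task_variant = task$variant, schedule = sched, seed = seed,
      spec = spec
    )),
    class = "twostage_run"
  )
}

# Pure-R two-stage engine; mirrors sim_twostage_cpp step for step.
sim_twostage_r <- function(spec, task, sched, sigma0) {
  n1 <- task$n_first
  n <- n1 + 2L * task$n_pairs
  agent <- agent_init(spec, n, sigma_init = sigma0)
  n_trials <- task$n_trials
  o1v <- integer(n_trials)
  pairv <- integer(n_trials)
  o2v <- integer(n_trials)
  Rv <- integer(n_trials)
  for (k in seq_len(n_trials)) {
    o1 <- softmax_select(integrated_value(agent, seq_len(n1)), spec$beta)$choice
    pair <- run_trial_transition(o1, task)
    s1 <- n1 + 2L * (pair - 1L) + 1L
    o2 <- s1 - 1L +
      softmax_select(integrated_value(agent, c(s1, s1 + 1L)), spec$beta)$choice
    agent <- agent_step(agent,
      s = o1, s_next = o2, reward = 0,
      terminal = FALSE
    )$agent
    R <- as.integer(runif(1) < sched[k, o2 - n1])
    agent <- agent_step(agent,
      s = o2, s_next = NA, reward = R,
      terminal = TRUE, update_features = FALSE
    )$agent
    o1v[k] <- o1
    pairv[k] <- pair
    o2v[k] <- o2
    Rv[k] <- R
  }
  vv <- vapply(seq_len(n), function(s) {
    c(system_value(agent$sys1, s), system_value(agent$sys2, s))
  }, numeric(2))
  list(
    total_rewards = sum(Rv), first_choice = o1v, pair = pairv,
    second_choice = o2v, rewards = Rv,
    v_system1 = vv[1, ], v_system2 = vv[2, ]
  )
}

#' @export
print.twostage_run <- function(x, ...) {
  cat(
    "<twostage_run> variant:", x$task_variant, " seed:", x$seed,
    " total rewards:", x$total_rewards, "\n"
  )
  invisible(x)
}
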