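#' Run one navigation simulation
#'
#' Executes one full run of the reward-navigation task: 500 no-reward
#' steps followed by 4500 rewarded steps (5000 in total for every
#' variant). The per-epoch special-state order is drawn from the run's
#' own random stream (a fresh permutation per simulation), then the agent
#' walks the grid under softmax action selection over integrated state
#' values, learning from the shared TD-RPE at every step. Runs are
#' bit-reproducible given the seed: the compiled engine (`"cpp"`,
#' default) and the pure-R engine (`"r"`, composed of [nav_step()] and
#' [agent_step()]) consume the random stream identically and produce
#' identical logs.
#'
#' @param spec An [agent_spec()].
#' @param task A `nav_task` or variant name (default `"original"`).
#' @param seed Integer seed for the run.
#' @param engine `"cpp"` or `"r"`.
#' @param want_snapshot Record the system-specific values just after the
#'   last reward consumption (used for value snapshots).
#' @return An object of class `nav_run`: `total_rewards`, `goal_times`
#'   (time steps of reward consumptions, strictly increasing, all within
#'   the run), `placement_epochs` and `placement_states` (epoch and state
#'   in which each consumed reward had been placed), final system-value
#'   vectors `v_system1`/`v_system2`, the final per-system learning state
#'   (`system1`, `system2`), a `snapshot` taken at the last consumption,
#'   and the drawn `special_state_order`.
#' @export
run_navigation <- function(spec, task = "original", seed,
                           engine = c("cpp", "r"), want_snapshot = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "agent_spec"))
  task <- as_nav_task(task)
  set.seed(seed)
  if (is.null(task$special_state_order)) task <- draw_task_order(task)

  res <- if (engine == "cpp") {
    out <- sim_nav_cpp(
      spec$rep1 == "SR", spec$rep2 == "SR",
      spec$alpha1_pos, spec$alpha1_neg, spec$alpha2_pos, spec$alpha2_neg,
      spec$alpha_sr, spec$beta, spec$gamma,
      task$n_noreward_steps, task$epoch_length, task$n_reward_epochs,
      if (is.na(task$p_special)) 0 else task$p_special,
      task$candidate_states, task$special_state_order,
      if (is.na(task$reset_period)) 0L else task$reset_period,
      if (is.null(task$fixed_reward_order)) {
        integer(0)
      } else {
        task$fixed_reward_order
      },
      want_snapshot
    )
    # compiled sigma buffers come back transposed (row-major vs R's
    # column-major); restore the (state, feature) orientation
    for (nm in c("system1", "system2")) {
      if (identical(out[[nm]]$rep, "SR")) {
        out[[nm]]$sigma <- t(out[[nm]]$sigma)
      }
    }
    out
  } else {
    sim_nav_r(spec, task, want_snapshot)
  }

  structure(
    c(res, list(
      task_variant = task$variant,
      special_state_order = task$special_state_order,
      seed = seed, spec = spec
    )),
    class = "nav_run"
  )
}

# Pure-R navigation engine; mirrors sim_nav_cpp step for step.
sim_nav_r <- function(spec, task, want_snapshot = TRUE) {
  n_states <- N_STATES
  agent <- agent_init(spec, n_states)
  nbt <- neighbor_table()
  env <- nav_env_init(task)
  T_total <- task$n_noreward_steps +
    task$epoch_length * task$n_reward_epochs

  goal_times <- integer(0)
  place_epochs <- integer(0)
  place_states <- integer(0)
  snapshot <- list(
    v_system1 = rep(NA_real_, n_states), v_system2 = rep(NA_real_, n_states),
    place_epoch = NA_integer_, place_state = NA_integer_,
    special = NA_integer_, time = NA_integer_
  )

  all_values <- function() {
    vapply(seq_len(n_states), function(s) {
      c(
        system_value(agent$sys1, s),
        system_value(agent$sys2, s)
      )
    }, numeric(2))
  }

  for (t in seq_len(T_total)) {
    at_reward <- !is.na(env$reward_state) && env$current == env$reward_state
    if (at_reward) {
      consumed_epoch <- env$place_epoch
      consumed_state <- env$place_state
      consumed_special <- env$special_state
      agent <- agent_step(agent,
        s = env$current, s_next = NA, reward = 1,
        terminal = TRUE
      )$agent
      goal_times <- c(goal_times, t)
      place_epochs <- c(place_epochs, consumed_epoch)
      place_states <- c(place_states, consumed_state)
      if (want_snapshot) {
        vv <- all_values()
        snapshot <- list(
          v_system1 = vv[1, ], v_system2 = vv[2, ],
          place_epoch = consumed_epoch, place_state = consumed_state,
          special = consumed_special, time = t
        )
      }
      env <- nav_step(env, NA, task)$env
    } else {
      nb <- nbt[[env$current]]
      vals <- integrated_value(agent, nb)
      nxt <- nb[softmax_select(vals, spec$beta)$choice]
      agent <- agent_step(agent,
        s = env$current, s_next = nxt, reward = 0,
        terminal = FALSE
      )$agent
      env <- nav_step(env, nxt, task)$env
    }
  }

  vv <- all_values()
  list(
    total_rewards = length(goal_times), goal_times = goal_times,
    placement_epochs = place_epochs, placement_states = place_states,
    v_system1 = vv[1, ], v_system2 = vv[2, ],
    system1 = agent$sys1, system2 = agent$sys2, snapshot = snapshot
  )
}

#' @export
print.nav_run <- function(x, ...) {
  cat(
    "<nav_run> variant:", x$task_variant, " seed:", x$seed,
    " total rewards:", x$total_rewards, "\n"
  )
  invisible(x)
}
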