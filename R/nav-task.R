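#' Reward-candidate states of the navigation task
#'
#' The nine candidate states sit on the two far edges of the grid, away
#' from the start state (1,1): (1,5), (2,5), (3,5), (4,5), (5,1), (5,2),
#' (5,3), (5,4), (5,5).
#'
#' @return Integer vector of the nine candidate state indices.
#' @export
nav_candidate_states <- function() {
  c(
    state_index(1:4, 5L), # (1,5)..(4,5)
    state_index(5L, 1:5) # (5,1)..(5,5)
  )
}

NAV_VARIANTS <- c(
  "original",
  "p_special_70", "p_special_80", "p_special_90", "p_special_100",
  "periodic_reset_500", "periodic_reset_250", "periodic_reset_100",
  "periodic_reset_50",
  "single_epoch",
  "deterministic_short_epochs",
  "uniform_candidates",
  "fixed_order_control"
)

#' Build a navigation-task specification
#'
#' Constructs the dynamic reward-navigation task: a 500-step no-reward
#' epoch followed by rewarded epochs totalling 4500 steps in every
#' variant. In the original task there are nine 500-step rewarded epochs;
#' in each epoch one of the nine candidate states is the "special"
#' candidate, and each new reward is placed at the special candidate with
#' probability `p_special` (0.6) or at one of the eight normal candidates
#' with equal probability. Which candidate is special in which epoch is a
#' fresh pseudorandom permutation in every simulation, so by default the
#' per-epoch order is left undrawn (`special_state_order = NULL`) and
#' drawn from the run's own random stream by [run_navigation()]; call
#' [draw_task_order()] to fix it explicitly.
#'
#' Variants:
#' \describe{
#'   \item{`p_special_70/80/90/100`}{placement probability at the special
#'     candidate raised to 0.7, 0.8, 0.9, or 1.}
#'   \item{`periodic_reset_500/250/100/50`}{reward location additionally
#'     re-drawn every 500, 250, 100, or 50 steps of the rewarded phase,
#'     whether or not the pending reward was consumed.}
#'   \item{`single_epoch`}{one rewarded epoch of 4500 steps; the special
#'     candidate varies only across simulations.}
#'   \item{`deterministic_short_epochs`}{45 epochs of 100 steps,
#'     `p_special = 1`; the special-state order is five consecutive
#'     permutations of the nine candidates.}
#'   \item{`uniform_candidates`}{each candidate equally likely (1/9).}
#'   \item{`fixed_order_control`}{no special states; the rewarded state
#'     cycles deterministically through (5,1), (5,5), (1,5).}
#' }
#'
#' @param variant One of the variant names above.
#' @return An object of class `nav_task`.
#' @export
nav_task <- function(variant = "original") {
  variant <- match.arg(variant, NAV_VARIANTS)
  spec <- list(
    variant = variant,
    n_noreward_steps = 500L,
    epoch_length = 500L,
    n_reward_epochs = 9L,
    p_special = 0.6,
    candidate_states = nav_candidate_states(),
    special_state_order = NULL,
    reset_period = NA_integer_,
    fixed_reward_order = NULL
  )
  if (grepl("^p_special_", variant)) {
    spec$p_special <- as.numeric(sub("p_special_", "", variant)) / 100
  } else if (grepl("^periodic_reset_", variant)) {
    spec$reset_period <- as.integer(sub("periodic_reset_", "", variant))
  } else if (variant == "single_epoch") {
    spec$epoch_length <- 4500L
    spec$n_reward_epochs <- 1L
  } else if (variant == "deterministic_short_epochs") {
    spec$epoch_length <- 100L
    spec$n_reward_epochs <- 45L
    spec$p_special <- 1
  } else if (variant == "uniform_candidates") {
    spec$p_special <- 1 / 9
  } else if (variant == "fixed_order_control") {
    # (5,1), (5,5), (1,5), repeated
    spec$fixed_reward_order <- state_index(c(5L, 5L, 1L), c(1L, 5L, 5L))
    spec$p_special <- NA_real_
  }
  stopifnot(spec$n_noreward_steps + spec$epoch_length * spec$n_reward_epochs
    == 5000L)
  structure(spec, class = "nav_task")
}

as_nav_task <- function(task) {
  if (inherits(task, "nav_task")) task else nav_task(task)
}

#' Draw the per-simulation special-state order for a task
#'
#' Consumes the current random stream. For the original task and its
#' probability/reset variants this is one permutation of the nine
#' candidates; `deterministic_short_epochs` concatenates five consecutive
#' permutations; `single_epoch` draws a single special candidate;
#' `fixed_order_control` needs no order.
#'
#' @param task A `nav_task`.
#' @return The task with `special_state_order` filled in.
#' @export
draw_task_order <- function(task) {
  task <- as_nav_task(task)
  cand <- task$candidate_states
  task$special_state_order <- switch(task$variant,
    fixed_order_control = integer(0),
    single_epoch = cand[sample.int(9L, 1L)],
    deterministic_short_epochs =
      as.integer(unlist(lapply(1:5, function(i) cand[sample.int(9L)]))),
    cand[sample.int(9L)]
  )
  task
}

#' Draw a reward location
#'
#' Places a reward at the special candidate state with probability
#' `p_special`, otherwise uniformly at one of the eight remaining
#' candidates. The `uniform_candidates` variant (`p_special = 1/9`)
#' makes all nine candidates equally likely. Consumes one uniform variate
#' for the special/normal decision and, only when a normal candidate is
#' chosen, a second one to pick it; this stream discipline is mirrored by
#' the compiled engine.
#'
#' @param task A `nav_task` (must not be `fixed_order_control`, whose
#'   placements are deterministic).
#' @param special State index of the current epoch's special candidate.
#' @return A candidate state index.
#' @export
draw_reward_location <- function(task, special) {
  task <- as_nav_task(task)
  if (task$variant == "fixed_order_control") {
    stop("fixed_order_control places rewards deterministically", call. = FALSE)
  }
  stopifnot(special %in% task$candidate_states)
  if (runif(1) < task$p_special) {
    return(as.integer(special))
  }
  others <- task$candidate_states[task$candidate_states != special]
  others[min(floor(runif(1) * 8) + 1, 8)]
}

#' Initialise the navigation environment state
#'
#' @param task A `nav_task` with its order drawn (except
#'   `fixed_order_control`).
#' @return A `nav_env` state at `t = 1`: agent at the start state, no
#'   reward placed yet.
#' @export
nav_env_init <- function(task) {
  task <- as_nav_task(task)
  if (is.null(task$special_state_order) &&
    task$variant != "fixed_order_control") {
    stop("task order not drawn; call draw_task_order() first", call. = FALSE)
  }
  structure(
    list(
      t = 1L, current = START_STATE, reward_state = NA_integer_,
      epoch_index = 0L, special_state = NA_integer_,
      cycle_pos = 0L, place_epoch = NA_integer_, place_state = NA_integer_
    ),
    class = "nav_env"
  )
}

place_new_reward <- function(env, task) {
  if (task$variant == "fixed_order_control") {
    ord <- task$fixed_reward_order
    env$reward_state <- ord[env$cycle_pos %% length(ord) + 1L]
    env$cycle_pos <- env$cycle_pos + 1L
  } else {
    env$reward_state <- draw_reward_location(task, env$special_state)
  }
  env$place_epoch <- env$epoch_index
  env$place_state <- env$reward_state
  env
}

#' Advance the navigation environment by one time step
#'
#' Executes time step `env$t`. If the agent occupies the rewarded state,
#' the reward (always size 1) is consumed, the agent is carried back to
#' the start state — the teleport occupies the next time step, so no
#' action is selected at the rewarded state — and a new reward is placed
#' immediately using the special candidate of the epoch containing the
#' consumption step. Otherwise the agent moves to `action`, which must be
#' a neighbour of the current state. Epoch bookkeeping then advances:
#' the special state changes exactly at epoch boundaries (t = 500, 1000,
#' ...) even when a reward is pending, the first reward is introduced at
#' t = 501, and periodic-reset variants re-draw the reward location at
#' their reset boundaries. A reward placed in one epoch and not yet
#' consumed persists into the next.
#'
#' @param env A `nav_env` state.
#' @param action Next state index (ignored, may be `NA`, when the agent
#'   is on the rewarded state).
#' @param task The `nav_task`.
#' @return A list with elements `env` (advanced state), `reward` (0 or
#'   1), and `terminal` (`TRUE` when the reward was consumed this step).
#' @export
nav_step <- function(env, action, task) {
  task <- as_nav_task(task)
  at_reward <- !is.na(env$reward_state) && env$current == env$reward_state
  if (at_reward) {
    reward <- 1
    env <- place_new_reward(env, task)
    env$current <- START_STATE
  } else {
    reward <- 0
    if (!(action %in% grid_neighbors(env$current))) {
      stop("action must be a neighbour of the current state", call. = FALSE)
    }
    env$current <- as.integer(action)
  }
  # bookkeeping effective at t + 1
  tn <- env$t + 1L
  n0 <- task$n_noreward_steps
  T_total <- n0 + task$epoch_length * task$n_reward_epochs
  if (tn > n0 && tn <= T_total) {
    ep <- (tn - n0 - 1L) %/% task$epoch_length + 1L
    if (ep != env$epoch_index) {
      env$epoch_index <- ep
      if (task$variant != "fixed_order_control") {
        env$special_state <- task$special_state_order[ep]
      }
    }
    if (tn == n0 + 1L) {
      env <- place_new_reward(env, task)
    } else if (!is.na(task$reset_period) &&
      (tn - n0 - 1L) %% task$reset_period == 0L) {
      env <- place_new_reward(env, task)
    }
  }
  env$t <- tn
  list(env = env, reward = reward, terminal = at_reward)
}
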