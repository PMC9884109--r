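#' Mean learning curve over rewarded epochs
#'
#' Computes, for the original navigation task, the mean time (number of
#' time steps) used to obtain the first, second, third, ... reward placed
#' in each of the second to ninth rewarded epochs. The time for a reward
#' is the difference between the time steps of two consecutive goal
#' reaches (the first consumed reward of a run is timed from the end of
#' the no-reward epoch). Each consumed reward is attributed to the epoch
#' in which it was *placed*: a reward placed in epoch 2 but obtained in
#' epoch 3 counts as the last reward of epoch 2, not the first of epoch
#' 3. The first rewarded epoch is excluded (it has no preceding reward,
#' so the situation differs qualitatively). Per reward index, times are
#' averaged across the simulations that obtained that reward, then across
#' epochs 2-9; a reward index is reported only if it was obtained in at
#' least `min_frac` of the simulations in *all* eight epochs (a quarter
#' by default), so that rare deep rewards do not misrepresent the average
#' behaviour.
#'
#' @param run_logs List of `nav_run` objects from the original task.
#' @param min_frac Minimum fraction of simulations in which a reward
#'   index must be obtained in every epoch (default 0.25).
#' @return A data frame with one row per reported reward index:
#'   `reward_index`, `mean_time` (mean over epochs 2-9 of the per-epoch
#'   across-simulation means), `sd_across_epochs` (population SD over the
#'   eight epoch means), and `min_n_sims` (smallest per-epoch simulation
#'   count). The full per-epoch mean matrix is attached as attribute
#'   `"epoch_means"`.
#' @export
learning_curves <- function(run_logs, min_frac = 0.25) {
  stopifnot(length(run_logs) >= 1)
  variants <- vapply(run_logs, function(x) x$task_variant, character(1))
  if (!all(variants == "original")) {
    stop("learning curves are defined for the original task only",
      call. = FALSE
    )
  }
  n_sims <- length(run_logs)
  epochs <- 2:9
  max_r <- max(c(1L, vapply(run_logs, function(log) {
    if (length(log$placement_epochs) == 0) {
      return(0L)
    }
    max(table(factor(log$placement_epochs, levels = 1:9)))
  }, integer(1))))

  # sum and count of times per (epoch, reward index)
  t_sum <- matrix(0, nrow = 9, ncol = max_r)
  t_cnt <- matrix(0L, nrow = 9, ncol = max_r)
  for (log in run_logs) {
    if (length(log$goal_times) == 0) next
    times <- diff(c(500L, log$goal_times))
    idx_in_epoch <- stats::ave(
      seq_along(log$placement_epochs), log$placement_epochs,
      FUN = seq_along
    )
    for (i in seq_along(times)) {
      e <- log$placement_epochs[i]
      r <- idx_in_epoch[i]
      t_sum[e, r] <- t_sum[e, r] + times[i]
      t_cnt[e, r] <- t_cnt[e, r] + 1L
    }
  }

  epoch_means <- t_sum[epochs, , drop = FALSE] /
    ifelse(t_cnt[epochs, , drop = FALSE] > 0,
      t_cnt[epochs, , drop = FALSE], NA
    )
  include <- apply(
    t_cnt[epochs, , drop = FALSE] >= min_frac * n_sims, 2, all
  )
  idx <- which(include)
  out <- data.frame(
    reward_index = idx,
    mean_time = vapply(idx, function(r) mean(epoch_means[, r]), numeric(1)),
    sd_across_epochs = vapply(
      idx,
      function(r) mean_sd_sem(epoch_means[, r])[["sd"]], numeric(1)
    ),
    min_n_sims = vapply(
      idx,
      function(r) min(t_cnt[epochs, r]), numeric(1)
    )
  )
  attr(out, "epoch_means") <- epoch_means
  attr(out, "n_sims") <- n_sims
  out
}

#' Per-state value snapshot of a run
#'
#' Tabulates the system-specific and integrated state values recorded
#' just after the agent obtained the last reward of a run.
#'
#' @param run A `nav_run` with a recorded snapshot.
#' @return A 25-row data frame: `state`, `x`, `y`, `v_system1`,
#'   `v_system2`, `v_integrated` (the mean of the two system columns).
#' @export
value_snapshot <- function(run) {
  snap <- run$snapshot
  if (all(is.na(snap$v_system1))) {
    stop("run has no recorded snapshot (no reward was consumed)",
      call. = FALSE
    )
  }
  co <- coord_of(1:25)
  data.frame(
    state = 1:25, x = co$x, y = co$y,
    v_system1 = snap$v_system1, v_system2 = snap$v_system2,
    v_integrated = (snap$v_system1 + snap$v_system2) / 2
  )
}

#' Find a run whose final reward qualifies for the value snapshot
#'
#' Value snapshots are shown for single simulations in which the last
#' obtained reward was placed in the last (ninth) rewarded epoch at that
#' epoch's special candidate state. Runs are executed for successive
#' seeds and the first qualifying one is returned.
#'
#' @param spec An [agent_spec()].
#' @param task Navigation task or variant name.
#' @param master_seed Seed used to spawn the candidate run seeds.
#' @param max_tries Maximum number of runs to try.
#' @return The first qualifying `nav_run` (with its `seed`), or an error
#'   if none is found within `max_tries`.
#' @export
find_snapshot_run <- function(spec, task = "original", master_seed = 1,
                              max_tries = 200) {
  seeds <- child_seeds(master_seed, max_tries)
  for (sd in seeds) {
    run <- run_navigation(spec, task, seed = sd)
    snap <- run$snapshot
    if (!is.na(snap$place_epoch) && snap$place_epoch == 9L &&
      !is.na(snap$special) && snap$place_state == snap$special) {
      return(run)
    }
  }
  stop("no qualifying run found within `max_tries`", call. = FALSE)
}
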