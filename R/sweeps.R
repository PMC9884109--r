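#' The learning-rate ratio grid
#'
#' The nine positive/negative learning-rate ratios used in the ratio
#' sweeps: 0.2, 0.25, 1/3, 0.5, 1, 2, 3, 4, 5.
#'
#' @return Numeric vector of ratios.
#' @export
ratio_grid <- function() {
  c(0.2, 0.25, 1 / 3, 0.5, 1, 2, 3, 4, 5)
}

run_condition <- function(spec, task, seeds, task_kind = "navigation") {
  vapply(seeds, function(sd) {
    if (task_kind == "navigation") {
      run_navigation(spec, task, seed = sd, want_snapshot = FALSE)$total_rewards
    } else {
      run_twostage(spec, task, seed = sd)$total_rewards
    }
  }, numeric(1))
}

#' Sweep the positive/negative learning-rate ratios of both systems
#'
#' Runs the 9 x 9 grid of ratio conditions with the sum of each system's
#' learning rates held constant: `alpha+ = sum * r / (1 + r)`,
#' `alpha- = sum / (1 + r)` for each ratio r in [ratio_grid()]. Ratios
#' whose implied rate would exceed 1 (e.g. r = 5 with sum 1.25) are
#' dropped. When both systems use the same representation, conditions
#' (r1, r2) and (r2, r1) describe the same model, so only the half-grid
#' with r1 <= r2 is run.
#'
#' @param rep1,rep2 Representations (`"SR"`/`"IR"`).
#' @param sum_alpha Constant sum alpha+ + alpha- per system (default 1).
#' @param beta,gamma,alpha_sr Agent parameters.
#' @param ratios Ratio grid.
#' @param n_sims Simulations per condition (default 100).
#' @param task Navigation variant or `nav_task`, or a `twostage_task` /
#'   two-stage variant name with `task_kind = "twostage"`.
#' @param master_seed Master seed; child seeds are spawned per
#'   (condition, simulation).
#' @param task_kind `"navigation"` or `"twostage"`.
#' @return A `sweep_result` data frame: one row per condition with the
#'   four learning rates, the ratios, and mean/sd/sem/n of total rewards.
#' @export
sweep_ratio_grid <- function(rep1 = "SR", rep2 = "IR", sum_alpha = 1,
                             beta = 5, gamma = 0.7, alpha_sr = 0.05,
                             ratios = ratio_grid(), n_sims = 100,
                             task = "original", master_seed = 1,
                             task_kind = c("navigation", "twostage")) {
  task_kind <- match.arg(task_kind)
  ok <- vapply(ratios, function(r) {
    all(rates_from_ratio(sum_alpha, r) <= 1)
  }, logical(1))
  ratios <- ratios[ok]
  grid <- expand.grid(ratio1 = ratios, ratio2 = ratios)
  if (rep1 == rep2) {
    grid <- grid[match(grid$ratio1, ratios) <= match(grid$ratio2, ratios), ]
  }
  seeds <- matrix(
    child_seeds(master_seed, nrow(grid) * n_sims),
    nrow = nrow(grid)
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r1 <- grid$ratio1[i]
    r2 <- grid$ratio2[i]
    a1 <- rates_from_ratio(sum_alpha, r1)
    a2 <- rates_from_ratio(sum_alpha, r2)
    spec <- agent_spec(rep1, rep2, a1[["pos"]], a1[["neg"]],
      a2[["pos"]], a2[["neg"]],
      alpha_sr = alpha_sr, beta = beta, gamma = gamma
    )
    stat <- mean_sd_sem(run_condition(spec, task, seeds[i, ], task_kind))
    data.frame(
      rep1 = rep1, rep2 = rep2, ratio1 = r1, ratio2 = r2,
      alpha1_pos = a1[["pos"]], alpha1_neg = a1[["neg"]],
      alpha2_pos = a2[["pos"]], alpha2_neg = a2[["neg"]],
      alpha_sr = alpha_sr,
      mean = stat[["mean"]], sd = stat[["sd"]], sem = stat[["sem"]],
      n = n_sims
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(
    sum_alpha = sum_alpha, beta = beta, gamma = gamma,
    master_seed = master_seed, task_kind = task_kind,
    task = if (inherits(task, "nav_task") ||
      inherits(task, "twostage_task")) {
      task$variant
    } else {
      task
    }
  )
  class(out) <- c("sweep_result", class(out))
  out
}

#' Sweep all four learning rates freely
#'
#' Varies the learning rate for positive and negative TD-RPEs in each
#' system over a free grid (default {0.2, 0.35, 0.5, 0.65, 0.8}),
#' optionally crossed with a grid of SR-feature learning rates. When both
#' systems use the same representation, conditions
#' `(a1+, a1-, a2+, a2-) = (x, y, z, w)` and `(z, w, x, y)` describe the
#' same model, so each unordered pair is run once with the full `n_sims`
#' (the two orderings' halves merged).
#'
#' @param rep1,rep2 Representations.
#' @param rates Free grid for the four TD-RPE learning rates.
#' @param alpha_sr_set Grid for the SR-feature learning rate; only used
#'   when at least one system is SR-based.
#' @param beta,gamma Agent parameters.
#' @param n_sims Simulations per (merged) condition.
#' @param task Navigation variant or task.
#' @param master_seed Master seed.
#' @return A `sweep_result` data frame sorted by decreasing mean, one row
#'   per merged condition.
#' @export
sweep_free_rates <- function(rep1 = "IR", rep2 = "IR",
                             rates = c(0.2, 0.35, 0.5, 0.65, 0.8),
                             alpha_sr_set = 0.05, beta = 5, gamma = 0.7,
                             n_sims = 100, task = "original",
                             master_seed = 1) {
  any_sr <- rep1 == "SR" || rep2 == "SR"
  if (!any_sr) alpha_sr_set <- alpha_sr_set[1]
  grid <- expand.grid(
    a1p = rates, a1m = rates, a2p = rates, a2m = rates,
    alpha_sr = alpha_sr_set
  )
  if (rep1 == rep2) {
    # merge symmetric pairs: keep (sys1, sys2) with sys1 <= sys2 in the
    # rate-grid ordering
    k1 <- match(grid$a1p, rates) * 10L + match(grid$a1m, rates)
    k2 <- match(grid$a2p, rates) * 10L + match(grid$a2m, rates)
    grid <- grid[k1 <= k2, ]
  }
  seeds <- matrix(
    child_seeds(master_seed, nrow(grid) * n_sims),
    nrow = nrow(grid)
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- agent_spec(rep1, rep2, grid$a1p[i], grid$a1m[i],
      grid$a2p[i], grid$a2m[i],
      alpha_sr = grid$alpha_sr[i], beta = beta, gamma = gamma
    )
    stat <- mean_sd_sem(run_condition(spec, task, seeds[i, ]))
    data.frame(
      rep1 = rep1, rep2 = rep2,
      alpha1_pos = grid$a1p[i], alpha1_neg = grid$a1m[i],
      alpha2_pos = grid$a2p[i], alpha2_neg = grid$a2m[i],
      ratio1 = grid$a1p[i] / grid$a1m[i],
      ratio2 = grid$a2p[i] / grid$a2m[i],
      alpha_sr = grid$alpha_sr[i],
      mean = stat[["mean"]], sd = stat[["sd"]], sem = stat[["sem"]],
      n = n_sims
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean), ]
  rownames(out) <- NULL
  attr(out, "params") <- list(
    beta = beta, gamma = gamma, master_seed = master_seed,
    task = if (inherits(task, "nav_task")) task$variant else task
  )
  class(out) <- c("sweep_result", class(out))
  out
}

#' Frequency with which each condition gives the best sweep mean
#'
#' Repeats a whole sweep independently and counts, per condition, how
#' often it attains the best mean performance (one argmax per repeat, so
#' counts sum to `n_repeats`).
#'
#' @param sweep_fn Function taking a master seed and returning a
#'   `sweep_result`.
#' @param n_repeats Number of independent sweep repetitions (default 50).
#' @param master_seed Seed used to spawn one master seed per repeat.
#' @return A data frame of the conditions that were best at least once,
#'   with a `best_count` column (one argmax per repeat, so the counts sum
#'   to `n_repeats`), sorted by decreasing count.
#' @export
best_condition_frequency <- function(sweep_fn, n_repeats = 50,
                                     master_seed = 1) {
  repeat_seeds <- child_seeds(master_seed, n_repeats)
  best <- lapply(seq_len(n_repeats), function(i) {
    sw <- sweep_fn(repeat_seeds[i])
    cond <- sw[which.max(sw$mean), setdiff(names(sw), c("sd", "sem", "n")),
      drop = FALSE
    ]
    names(cond)[names(cond) == "mean"] <- "best_mean"
    cond
  })
  best <- do.call(rbind, best)
  key_cols <- setdiff(names(best), "best_mean")
  key <- do.call(paste, c(best[key_cols], sep = "\r"))
  counts <- table(key)
  out <- best[match(names(counts), key), key_cols, drop = FALSE]
  out$best_count <- as.integer(counts)
  out <- out[order(-out$best_count), ]
  rownames(out) <- NULL
  out
}
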