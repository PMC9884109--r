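#!/usr/bin/env Rscript

# Learning profiles of three representative ratio combinations of the
# SR+IR model: mean learning curves (time per successive reward within an
# epoch, rewards attributed to their placement epoch, epochs 2-9) and
# single-run state-value snapshots taken just after the last reward of
# the final epoch when that reward sat on the special candidate state.

suppressPackageStartupMessages(library(opponentSR))
dir.create("results", showWarnings = FALSE)

cases <- list(
  appetitiveSR = c(4, 0.25),
  balanced = c(1, 1),
  aversiveSR = c(0.25, 4)
)
curves <- list()
for (nm in names(cases)) {
  r <- cases[[nm]]
  a1 <- rates_from_ratio(1, r[1])
  a2 <- rates_from_ratio(1, r[2])
  spec <- agent_spec("SR", "IR", a1[["pos"]], a1[["neg"]],
    a2[["pos"]], a2[["neg"]],
    beta = 5, gamma = 0.7
  )
  seeds <- child_seeds(131, 100)
  logs <- lapply(seeds, function(sd) {
    run_navigation(spec, "original", seed = sd, want_snapshot = FALSE)
  })
  cv <- learning_curves(logs)
  cv$case <- nm
  curves[[nm]] <- cv
  message(sprintf(
    "%s (ratios %.4g, %.4g): %d reward indices kept; time to first reward %.1f steps",
    nm, r[1], r[2], nrow(cv), cv$mean_time[1]
  ))

  snap <- value_snapshot(find_snapshot_run(spec, master_seed = 141))
  utils::write.csv(snap, sprintf("results/value_snapshot_%s.csv", nm),
    row.names = FALSE
  )
  message(sprintf(
    "  snapshot: SR values in [%.2f, %.2f], IR values in [%.2f, %.2f]",
    min(snap$v_system1), max(snap$v_system1),
    min(snap$v_system2), max(snap$v_system2)
  ))
}
utils::write.csv(do.call(rbind, curves), "results/learning_curves.csv",
  row.names = FALSE
)
message("wrote results/learning_curves.csv and value_snapshot_*.csv")
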