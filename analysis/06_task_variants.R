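#!/usr/bin/env Rscript

# Does the advantage of the appetitive-SR/aversive-IR combination depend
# on the task's reward dynamics? Repeats the SR+IR ratio sweep on six
# task variants: fully deterministic placement, fast periodic resets, a
# single long epoch, short deterministic epochs, uniform candidates, and
# the fixed-order control where only rapid unlearning helps.

suppressPackageStartupMessages(library(opponentSR))
dir.create("results", showWarnings = FALSE)

variants <- c(
  "p_special_100", "periodic_reset_50", "single_epoch",
  "deterministic_short_epochs", "uniform_candidates", "fixed_order_control"
)
for (i in seq_along(variants)) {
  v <- variants[i]
  sw <- sweep_ratio_grid("SR", "IR",
    n_sims = 100, task = v,
    master_seed = 150 + i
  )
  export_sweep(sw, sprintf("results/ratio_sweep_%s.csv", v))
  b <- sw[which.max(sw$mean), ]
  message(sprintf(
    "%-27s best ratios (%.4g, %.4g), mean %.2f  [grid range %.1f..%.1f]",
    v, b$ratio1, b$ratio2, b$mean, min(sw$mean), max(sw$mean)
  ))
}
message("wrote results/ratio_sweep_<variant>.csv")
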