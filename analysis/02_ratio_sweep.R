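#!/usr/bin/env Rscript

# Performance of the dual-system agent as a function of the
# positive/negative learning-rate ratio in each system (sum of rates 1,
# beta = 5, gamma = 0.7, 100 simulations per condition): the SR+IR
# combination over the full 9x9 ratio grid, and the SR+SR and IR+IR
# models over their symmetric half-grids.

suppressPackageStartupMessages(library(opponentSR))
dir.create("results", showWarnings = FALSE)

sw <- sweep_ratio_grid("SR", "IR", n_sims = 100, master_seed = 101)
export_sweep(sw, "results/ratio_sweep_sr_ir.csv")
best <- sw[which.max(sw$mean), ]
message(sprintf(
  "SR+IR best cell: alphaSR+/alphaSR- = %.4g, alphaIR+/alphaIR- = %.4g, mean %.2f (SEM %.2f)",
  best$ratio1, best$ratio2, best$mean, best$sem
))
a <- sw[sw$ratio1 == 4 & sw$ratio2 == 0.25, ]
b <- sw[sw$ratio1 == 0.25 & sw$ratio2 == 4, ]
message(sprintf(
  "appetitive-SR/aversive-IR (4, 0.25): %.2f vs mirrored (0.25, 4): %.2f",
  a$mean, b$mean
))

for (rep in c("SR", "IR")) {
  sws <- sweep_ratio_grid(rep, rep, n_sims = 100,
    master_seed = if (rep == "SR") 102 else 103
  )
  export_sweep(sws, sprintf("results/ratio_sweep_%s_%s.csv",
    tolower(rep), tolower(rep)
  ))
  bs <- sws[which.max(sws$mean), ]
  message(sprintf(
    "%s+%s best cell: ratios (%.4g, %.4g), mean %.2f",
    rep, rep, bs$ratio1, bs$ratio2, bs$mean
  ))
}
message("wrote results/ratio_sweep_*.csv (+ _matrix companions)")
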