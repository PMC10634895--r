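#!/usr/bin/env Rscript
# Compare the competing failed-Stop hypotheses against a self-generated
# target whose only change from the successful model is a +19 ms delay of
# the late proximal drive. Reduced network scale keeps the fits fast.
# Usage: Rscript analysis/02_hypothesis_comparison.R [--seed N]

suppressPackageStartupMessages(library(stopcolumn))
args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) as.integer(args[match("--seed", args) + 1]) else 1L
dir.create("results", showWarnings = FALSE)

truth <- set_preset_parameters(load_preset("successful"), c(P2.mu = 325))
tgt <- generate_simulator_target(truth, sim_config(seed = 900 + seed,
                                                   n_trials = 5),
                                 n_pyramidal = 25)
message("fitting presets ...")
rep <- compare_models(tgt$time_ms, tgt$target,
                      c("failed_timing", "failed_strength", "failed_onespike"),
                      config = sim_config(seed = seed, n_trials = 5),
                      n_pyramidal = 25, budget = 20)
write.csv(as.data.frame(rep), "results/hypothesis_comparison.csv",
          row.names = FALSE)
print(as.data.frame(rep))
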