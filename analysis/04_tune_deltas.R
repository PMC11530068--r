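#!/usr/bin/env Rscript
# Random-search tuning of the per-ratio oversampling increments on the
# desk-scale benchmark, scored by mean five-fold validation RMSE on the
# mixture data. The desk grid spans 8..48 in steps of 8 (the full-scale
# design searches 64..384 in steps of 64; both give 6 values per ratio,
# a 6^4 = 1296-candidate joint space).
#
# Usage: Rscript analysis/04_tune_deltas.R [n_draws] [seed]

library(mixshape)

args <- commandArgs(trailingOnly = TRUE)
n_draws <- if (length(args) >= 1) as.integer(args[1]) else 5L
seed <- if (length(args) >= 2) as.integer(args[2]) else 10L

desk_dir <- file.path("results", "data_desk")
if (!file.exists(file.path(desk_dir, "manifest.csv")))
  stop("run analysis/01_generate_data.R first")

cfg <- run_config(desk_dir, file.path("results", "tuning"), "M4",
                  model = model_config_desk(7), K = 5, seed = 5L)
res <- tune_deltas(cfg, grid = seq(8, 48, by = 8), n_draws = n_draws,
                   seed = seed)
cat("best increments:\n"); print(res$best)
cat(sprintf("best mean validation RMSE: %.4f\n", res$best_rmse))
utils::write.csv(res$trace, file.path("results", "tuning_trace.csv"),
                 row.names = FALSE)
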