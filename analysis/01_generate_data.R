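#!/usr/bin/env Rscript
# Generate the desk-scale synthetic benchmark: 60 images per homogeneous
# class (PARENTAL / RESISTANT / CONTROL) and 40 per mixture ratio (1:2,
# 2:1, 1:3, 3:1 PARENTAL:RESISTANT), rendered at 32x32 with 8 cells per
# scene so every declared ratio realizes exactly. Also writes the tiny
# "mini" preset (5 per class, 4 per ratio) as a quick visual sanity set.
#
# Usage: Rscript analysis/01_generate_data.R [seed]

library(mixshape)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 101L

dir.create("results", showWarnings = FALSE)
desk_dir <- file.path("results", "data_desk")
mini_dir <- file.path("results", "data_mini")
unlink(c(desk_dir, mini_dir), recursive = TRUE)

mani <- generate_dataset(preset_desk(), desk_dir, seed = seed,
                         overlap_policy = "allow")
cat(sprintf("desk benchmark: %d images (%d homogeneous, %d mixture) -> %s\n",
            nrow(mani),
            sum(mani$tag %in% c("PARENTAL", "RESISTANT", "CONTROL")),
            sum(!(mani$tag %in% c("PARENTAL", "RESISTANT", "CONTROL"))),
            desk_dir))
print(table(mani$tag))

mini <- generate_dataset(preset_mini(), mini_dir, seed = seed)
cat(sprintf("mini preview set: %d images -> %s\n", nrow(mini), mini_dir))
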