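#!/usr/bin/env Rscript
# Assemble Mean(SE) validation tables, mixture proportion tables,
# dominant-class accuracies and a Grad-CAM gallery for each completed
# run under results/run_*/.
#
# Usage: Rscript analysis/03_report.R

library(mixshape)

runs <- list.dirs("results", recursive = FALSE)
runs <- runs[grepl("run_", runs)]
if (!length(runs)) stop("no completed runs under results/")

for (rd in runs) {
  cat("==", basename(rd), "==\n")
  rep <- report_run(rd, gallery_n = 1, seed = 1)
  print(rep$validation, row.names = FALSE)
  if (!is.null(rep$proportions)) {
    cat("approximated proportions (percent, PARENTAL:RESISTANT):\n")
    print(rep$proportions, row.names = FALSE)
    cat("dominant-class accuracy (percent):\n")
    print(rep$dominant, row.names = FALSE)
  }
  cat("report tables and Grad-CAM gallery ->", file.path(rd, "report"), "\n\n")
}
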