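#!/usr/bin/env Rscript
# NB Wald differential tests for each triad comparison at both stages:
# F1 vs each parent, parent vs parent, and F1 vs the mid-parent-value (MPV)
# pseudo-samples whose significant features are the nonadditive set.

suppressPackageStartupMessages(library(heterosisr))

out <- "results/run"
thr <- call_thresholds(min_fold = 1.5, max_p = 0.05, use_adjusted = FALSE)

for (stage in c("S", "H")) {
  tc <- read_count_matrix(file.path(out, sprintf("counts_%s.tsv", stage)),
                          file.path(out, sprintf("samples_%s.tsv", stage)))
  aug <- make_mpv_pseudosamples(tc, stage)
  for (cmp in list(c("P1", "F1"), c("P2", "F1"), c("P2", "P1"), c("MPV", "F1"))) {
    de <- triad_de(aug, stage, cmp[1], cmp[2])
    called <- call_differential(de, thr)
    write_results(de, file.path(out, sprintf("de_%s_%s.tsv", de$comparison[1], stage)))
    message(sprintf("%s %-10s: %3d/%d called (%d up, %d down)",
                    stage, de$comparison[1], nrow(called), nrow(de),
                    sum(called$direction == "up"), sum(called$direction == "down")))
  }
}
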