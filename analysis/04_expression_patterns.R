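#!/usr/bin/env Rscript
# Eight-way P1-H-P2 expression-pattern classification per stage, summary
# tallies (ELD direction, nonadditive up/down), the cross-stage overlap of
# nonadditive features, and recovery against the planted truth.

suppressPackageStartupMessages(library(heterosisr))

out <- "results/run"
thr <- call_thresholds()
all_calls <- list()

for (stage in c("S", "H")) {
  tc <- read_count_matrix(file.path(out, sprintf("counts_%s.tsv", stage)),
                          file.path(out, sprintf("samples_%s.tsv", stage)))
  calls <- classify_patterns(tc, stage, thr)
  all_calls[[stage]] <- calls
  write_results(as.data.frame(calls), file.path(out, sprintf("patterns_%s.tsv", stage)))
  s <- summarize_patterns(calls)
  message(sprintf("stage %s labels: %s", stage,
                  paste(names(s$label_counts), s$label_counts, sep = "=", collapse = " ")))
  message(sprintf("stage %s: nonadditive %d up / %d down; high-parental ELD %.0f%% of ELD",
                  stage, s$n_nonadditive_up, s$n_nonadditive_down, s$pct_high_eld))
  truth <- read_results(file.path(out, sprintf("truth_%s.tsv", stage)))
  acc <- per_class_accuracy(calls, truth)
  message(sprintf("stage %s planted-class recovery: %s", stage,
                  paste(names(acc), sprintf("%.2f", acc), sep = "=", collapse = " ")))
  write_results(data.frame(class = names(acc), recovery = unname(acc)),
                file.path(out, sprintf("pattern_recovery_%s.tsv", stage)))
}

shared <- stage_overlap(all_calls$S, all_calls$H, nonadditive_only = TRUE)
message(sprintf("%d nonadditive features shared between the S and H stages", length(shared)))
write_results(data.frame(feature_id = shared), file.path(out, "nonadditive_overlap.tsv"))
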