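#!/usr/bin/env Rscript
# Heterosis indices from the simulated phenotype table: per-trait MPH/BPH
# with an F1-vs-better-parent t-test, and the trait correlation matrix.

suppressPackageStartupMessages(library(heterosisr))

out <- "results/run"
pheno <- read_results(file.path(out, "phenotypes.tsv"))

rep <- heterosis_report(pheno)
write_results(rep, file.path(out, "heterosis_report.tsv"))
message("per-trait heterosis (planted MPH 92, BPH 55):")
for (i in seq_len(nrow(rep))) {
  message(sprintf("  %-4s MPH %6.1f%%  BPH %6.1f%%  p(F1 vs BP) %.2g",
                  rep$trait[i], rep$MPH[i], rep$BPH[i], rep$t_p_value_F1_vs_BP[i]))
}

r <- trait_correlations(pheno)
write_results(data.frame(trait = rownames(r), as.data.frame(r)),
              file.path(out, "trait_correlations.tsv"))
message(sprintf("trait correlations: %d x %d matrix, off-diagonal range [%.2f, %.2f]",
                nrow(r), ncol(r), min(r[upper.tri(r)]), max(r[upper.tri(r)])))
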