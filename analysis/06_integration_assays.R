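#!/usr/bin/env Rscript
# miRNA-target expression anticorrelation on planted pairs, plus the
# closed-form assay computations (chlorophyll content, 2^-ddCt folds,
# mean cell size).

suppressPackageStartupMessages(library(heterosisr))

out <- "results/run"

# planted anticorrelated miRNA/target pairs (r_true = -0.62 across 18 samples)
pc <- gen_correlated_pairs(n_pairs = 10, r_true = -0.62, n_samples = 18, seed = 32)
cors <- pair_correlations(pc$mirna, pc$gene, pc$pairs)
write_results(cors, file.path(out, "pair_correlations.tsv"))
message(sprintf("pair correlations: mean r = %.2f over %d planted pairs (planted -0.62)",
                mean(cors$r), nrow(cors)))

# pigment assay: worked absorbance pairs
ab <- data.frame(A663_6 = c(0.5, 1.0, 0.8), A646_6 = c(0.5, 0.2, 0.6))
pig <- cbind(ab, chlorophyll(ab$A663_6, ab$A646_6))
write_results(pig, file.path(out, "chlorophyll.tsv"))
message(sprintf("chlorophyll at A663.6 = 0.5, A646.6 = 0.5: a %.2f, b %.2f, total %.2f ug/mL",
                pig$chlorophyll_a[1], pig$chlorophyll_b[1], pig$total[1]))

# qPCR relative quantification
qpcr <- data.frame(ct_target_test = c(20, 19), ct_ref_test = 18,
                   ct_target_cal = c(22, 20), ct_ref_cal = 18)
qpcr$fold <- ddct_fold(qpcr$ct_target_test, qpcr$ct_ref_test,
                       qpcr$ct_target_cal, qpcr$ct_ref_cal)
write_results(qpcr, file.path(out, "qpcr_folds.tsv"))
message(sprintf("ddCt folds: %s", paste(qpcr$fold, collapse = ", ")))

# leaf cell size from counts per area
message(sprintf("mean cell size, 600 um^2 / 24 cells: %.0f um^2", mean_cell_size(600, 24)))
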