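#!/usr/bin/env Rscript
# Generate every input for the downstream analyses with known ground truth:
# NB count triads (P1/F1/P2) for the seedling (S) and early-heading (H)
# stages with planted expression-pattern classes, plant-level phenotypes with
# planted heterosis, and degradome inputs with planted cleavage sites.

suppressPackageStartupMessages(library(heterosisr))

seed <- 1
out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (stage in c("S", "H")) {
  cfg <- triad_sim_config(n_features = 1000, seed = seed + (stage == "H"))
  sim <- gen_triad_counts(cfg, stage = stage)
  write_count_matrix(sim$counts,
                     file.path(out, sprintf("counts_%s.tsv", stage)),
                     file.path(out, sprintf("samples_%s.tsv", stage)),
                     comment = sprintf("seed=%d stage=%s", cfg$seed, stage))
  write_results(sim$truth, file.path(out, sprintf("truth_%s.tsv", stage)),
                comment = sprintf("seed=%d", cfg$seed))
  message(sprintf("stage %s: %d features x %d samples, planted classes: %s",
                  stage, nrow(sim$counts$counts), ncol(sim$counts$counts),
                  paste(names(table(sim$truth$planted_class)),
                        table(sim$truth$planted_class), collapse = " ", sep = "=")))
}

# phenotypes: six traits, gross-weight-like heterosis (MPH 92%, BPH 55%)
pheno <- gen_phenotypes(c("GW", "PH", "SLW", "LN", "LL", "LW"), n_plants = 50,
                        planted_mph = 92, planted_bph = 55, noise_cv = 0.1,
                        seed = seed + 11)
write_results(pheno, file.path(out, "phenotypes.tsv"),
              comment = sprintf("seed=%d planted_mph=92 planted_bph=55 cv=0.1", seed + 11))
message(sprintf("phenotypes: %d plants x %d traits", 150, 6))

# degradome: 20 planted perfect-complement cleavage sites over Poisson background
planted <- data.frame(mirna_id = sprintf("mir_%03d", rep(1:10, 2)),
                      transcript_id = sprintf("tx_%03d", 1:20),
                      cleavage_position = seq(60, 250, 10),
                      tag_count = 10L)
dsim <- gen_degradome(degradome_sim_config(
  n_transcripts = 20, n_mirnas = 10, planted_sites = planted,
  background_tag_rate = 0.1, seed = seed + 23))
write_fasta(dsim$mirnas, file.path(out, "mirnas.fa"))
write_fasta(dsim$transcripts, file.path(out, "transcripts.fa"))
write_profiles(dsim$profiles, file.path(out, "degradome_profiles.tsv"))
write_results(dsim$planted_sites, file.path(out, "planted_sites.tsv"),
              comment = "cleavage_position pairs miRNA position 10; 1-based")
message(sprintf("degradome: %d miRNAs, %d transcripts, %d planted sites",
                length(dsim$mirnas), length(dsim$transcripts), nrow(planted)))
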