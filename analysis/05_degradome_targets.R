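#!/usr/bin/env Rscript
# miRNA target-site discovery by complementarity scoring, degradome category
# assignment for every candidate cleavage site, a T-plot table for one
# planted transcript, and recovery of the planted sites as category 0.

suppressPackageStartupMessages(library(heterosisr))

out <- "results/run"
mirnas <- read_fasta(file.path(out, "mirnas.fa"))
transcripts <- read_fasta(file.path(out, "transcripts.fa"))
profiles <- read_profiles(file.path(out, "degradome_profiles.tsv"))
planted <- read_results(file.path(out, "planted_sites.tsv"))

sites <- do.call(rbind, lapply(names(mirnas), function(mid) {
  do.call(rbind, lapply(names(transcripts), function(tid) {
    find_target_sites(mirnas[[mid]], transcripts[[tid]],
                      max_score = 7, mirna_id = mid, transcript_id = tid)
  }))
}))
message(sprintf("%d candidate sites at score <= 7 over %d miRNA x %d transcripts",
                nrow(sites), length(mirnas), length(transcripts)))

cat_sites <- categorize_sites(sites, profiles)
write_results(cat_sites, file.path(out, "sites_categorized.tsv"),
              comment = "coordinates 1-based inclusive; cleavage pairs miRNA position 10")
message(sprintf("category tallies: %s",
                paste(names(table(cat_sites$category)), table(cat_sites$category),
                      sep = ":", collapse = " ")))

hit <- merge(planted, cat_sites,
             by.x = c("mirna_id", "transcript_id", "cleavage_position"),
             by.y = c("mirna_id", "transcript_id", "predicted_cleavage"))
message(sprintf("%d/%d planted sites recovered as category 0",
                sum(hit$category == 0), nrow(planted)))

tx1 <- planted$transcript_id[1]
write_results(tplot_table(profiles[[tx1]],
                          cat_sites[cat_sites$transcript_id == tx1, , drop = FALSE]),
              file.path(out, "tplot_example.tsv"),
              comment = paste0("transcript=", tx1))
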