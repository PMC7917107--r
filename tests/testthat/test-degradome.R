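test_that("alignment scoring matches hand-computed penalties", {
  mirna <- "ACGUGCAUGCAUGCAUGCAUG"          # 21 nt
  perfect <- reverse_complement(mirna, out = "DNA")
  expect_equal(score_alignment(mirna, perfect)$score, 0)
  expect_equal(score_alignment(mirna, perfect)$pairing,
               paste(rep("|", 21), collapse = ""))
  L <- 21
  # G:U wobble opposite miRNA position 5 (a G): doubled half penalty = 1.0
  w5 <- perfect
  substr(w5, L - 5 + 1, L - 5 + 1) <- "T"
  expect_equal(score_alignment(mirna, w5)$score, 1.0)
  # mismatch opposite miRNA position 15 (an A; C pairs nothing): undoubled 1.0
  w15 <- perfect
  substr(w15, L - 15 + 1, L - 15 + 1) <- "C"
  expect_equal(score_alignment(mirna, w15)$score, 1.0)
  # mismatch in the doubled region: 2.0
  w2 <- perfect
  substr(w2, L - 2 + 1, L - 2 + 1) <- "A"   # miRNA pos 2 is C, pairs G
  expect_equal(score_alignment(mirna, w2)$score, 2.0)
  expect_error(score_alignment(mirna, "ACGU"), "length mismatch")
  expect_error(score_alignment("ACXU", "ACGU"), "non-ACGUTN")
})

test_that("U and T are interchangeable for pairing", {
  mirna <- "ACGUGCAUGCAUGCAUGCAUG"
  dna_win <- reverse_complement(mirna, out = "DNA")
  rna_win <- chartr("T", "U", dna_win)
  expect_equal(score_alignment(mirna, rna_win)$score, 0)
  expect_equal(score_alignment(chartr("U", "T", mirna), dna_win)$score, 0)
})

test_that("an embedded perfect site is found with the right cleavage coordinate", {
  set.seed(3)
  mirna <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  flank5 <- paste(rep("A", 49), collapse = "")
  flank3 <- paste(rep("C", 60), collapse = "")
  tx <- paste0(flank5, reverse_complement(mirna, out = "DNA"), flank3)
  hits <- find_target_sites(mirna, tx, max_score = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$target_start, 50)
  expect_equal(hits$target_end, 70)
  expect_equal(hits$predicted_cleavage, 50 + 21 - 10)
  expect_equal(hits$score, 0)
})

test_that("sliding-window scoring agrees with a brute-force oracle", {
  set.seed(41)
  for (i in 1:20) {
    mirna <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
    tx <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    hits <- find_target_sites(mirna, tx, max_score = 14)
    want <- oracle_sites(mirna, tx, max_score = 14)
    if (is.null(want)) {
      expect_equal(nrow(hits), 0)
    } else {
      expect_equal(hits$target_start, unname(want[, "start"]))
      expect_equal(hits$score, unname(want[, "score"]))
    }
    # every reported score re-derives under the single-window scorer
    for (k in seq_len(nrow(hits))) {
      expect_equal(hits$score[k],
                   oracle_score(mirna, substr(tx, hits$target_start[k], hits$target_end[k])))
    }
  }
})

test_that("a random miRNA almost never matches a random transcript perfectly", {
  set.seed(43)
  mirna <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  tx <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  expect_equal(nrow(find_target_sites(mirna, tx, max_score = 0)), 0)
})

test_that("tag profiles accumulate counts and validate coordinates", {
  tags <- data.frame(transcript = c("t1", "t1", "t1"), position = c(3L, 3L, 7L))
  prof <- build_profile(tags, c(t1 = 10L, t2 = 5L))
  expect_equal(prof$t1[3], 2L)
  expect_equal(prof$t1[7], 1L)
  expect_equal(sum(prof$t1), 3L)
  expect_equal(prof$t2, integer(5))
  # permutation invariance of input rows
  perm <- tags[c(3, 1, 2), ]
  expect_identical(build_profile(perm, c(t1 = 10L, t2 = 5L)), prof)
  expect_error(build_profile(data.frame(transcript = "t1", position = 11L),
                             c(t1 = 10L)), "out of range.*t1")
  expect_error(build_profile(data.frame(transcript = "tx", position = 1L),
                             c(t1 = 10L)), "unknown transcript")
})

test_that("site categories match the rule table on worked examples", {
  expect_equal(categorize_site(c(5L, 1L, 0L, 2L), 1)$category, 0L)  # unique max
  expect_equal(categorize_site(c(5L, 5L, 1L), 1)$category, 1L)     # tied max
  expect_equal(categorize_site(c(5L, 1L, 0L, 2L), 2)$category, 4L) # single read
  expect_equal(categorize_site(c(9L, 3L, 2L, 2L, 2L), 2)$category, 2L) # above median
  expect_equal(categorize_site(c(9L, 3L, 2L, 2L, 2L), 3)$category, 3L) # at/below median
  expect_true(is.na(categorize_site(c(5L, 0L), 2)$category))       # no signal
  expect_error(categorize_site(c(1L, 2L), 5), "outside")
})

test_that("categorization agrees with brute-force enumeration of small profiles", {
  for (len in 1:6) {
    grid <- as.matrix(expand.grid(rep(list(0:3), len)))
    got <- integer(0); want <- integer(0)
    for (row in seq_len(nrow(grid))) {
      prof <- as.integer(grid[row, ])
      if (all(prof == 0)) next
      for (pos in seq_len(len)) {
        got <- c(got, categorize_site(prof, pos)$category)
        want <- c(want, oracle_category(prof, pos))
      }
    }
    expect_identical(got, want, label = sprintf("profiles of length %d", len))
  }
})

test_that("categories partition sites with at least one read", {
  set.seed(47)
  for (i in 1:100) {
    prof <- as.integer(rpois(20, 1.2))
    pos <- sample(20, 1)
    got <- categorize_site(prof, pos)$category
    if (prof[pos] == 0) expect_true(is.na(got))
    else expect_true(got %in% 0:4)
  }
})

test_that("T-plot tables cover every position and flag planted sites", {
  prof <- c(0L, 8L, 1L, 0L, 2L)
  sites <- data.frame(mirna_id = c("m1", "m2"), predicted_cleavage = c(2L, 2L))
  tab <- tplot_table(prof, sites)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$count, prof)
  expect_equal(which(tab$is_predicted_cleavage), 2L)
  expect_equal(tab$mirna_id[2], "m1,m2")
  empty <- tplot_table(prof)
  expect_false(any(empty$is_predicted_cleavage))
})

test_that("planted perfect sites emerge as category 0 end to end", {
  planted <- data.frame(mirna_id = sprintf("mir_%03d", rep(1:3, 2)),
                        transcript_id = sprintf("tx_%03d", 1:6),
                        cleavage_position = seq(80, 180, 20),
                        tag_count = 10L)
  cfg <- degradome_sim_config(n_transcripts = 6, n_mirnas = 3,
                              planted_sites = planted,
                              background_tag_rate = 0.1, seed = 29)
  sim <- gen_degradome(cfg)
  sites <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
    find_target_sites(sim$mirnas[[planted$mirna_id[i]]],
                      sim$transcripts[[planted$transcript_id[i]]],
                      mirna_id = planted$mirna_id[i],
                      transcript_id = planted$transcript_id[i])
  }))
  cat_sites <- suppressMessages(categorize_sites(sites, sim$profiles))
  hit <- merge(planted, cat_sites,
               by.x = c("mirna_id", "transcript_id", "cleavage_position"),
               by.y = c("mirna_id", "transcript_id", "predicted_cleavage"))
  expect_equal(nrow(hit), 6)
  expect_gte(sum(hit$category == 0), 5)
})
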