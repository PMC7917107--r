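# Shared fixture builders; everything is generated in code, no stored data.

# tiny deterministic count triad (2 genotype-balanced stages optional)
toy_triad <- function(counts = NULL, stage = "S", n_reps = 3) {
  if (is.null(counts)) {
    counts <- matrix(c(10L, 20L, 30L, 100L, 110L, 90L,
                       40L, 50L, 60L, 200L, 210L, 190L,
                       70L, 80L, 90L, 300L, 310L, 290L),
                     nrow = 2, byrow = TRUE)[rep(1:2, length.out = 2), 1:(3 * n_reps), drop = FALSE]
    counts <- matrix(as.integer(abs(counts)), 2, 3 * n_reps)
  }
  rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  genotype <- rep(c("P1", "F1", "P2"), each = n_reps)
  ids <- paste(genotype, stage, rep(seq_len(n_reps), 3), sep = "_")
  colnames(counts) <- ids
  meta <- data.frame(sample = ids, genotype = genotype, stage = stage,
                     replicate = rep(seq_len(n_reps), 3), stringsAsFactors = FALSE)
  triad_counts(counts, meta)
}

# triad with per-genotype constant mean counts (deterministic)
flat_triad <- function(mu_p1, mu_f1, mu_p2, n_features = 1, n_reps = 3, stage = "S") {
  genotype <- rep(c("P1", "F1", "P2"), each = n_reps)
  mu <- c(P1 = mu_p1, F1 = mu_f1, P2 = mu_p2)
  counts <- matrix(rep(as.integer(mu[genotype]), each = n_features),
                   nrow = n_features)
  rownames(counts) <- paste0("f", seq_len(n_features))
  ids <- paste(genotype, stage, rep(seq_len(n_reps), 3), sep = "_")
  colnames(counts) <- ids
  meta <- data.frame(sample = ids, genotype = genotype, stage = stage,
                     replicate = rep(seq_len(n_reps), 3), stringsAsFactors = FALSE)
  triad_counts(counts, meta)
}

# minimal pattern_calls data.frame for summary/overlap tests
fake_calls <- function(labels, stage = "S", nonadd_dir = NULL,
                       ids = sprintf("feat_%04d", seq_along(labels))) {
  n <- length(labels)
  if (is.null(nonadd_dir)) nonadd_dir <- rep(NA_character_, n)
  data.frame(feature_id = ids, stage = stage, label = labels,
             ambiguous = FALSE,
             nonadditive = !is.na(nonadd_dir),
             nonadditive_direction = nonadd_dir,
             stringsAsFactors = FALSE)
}

# independent brute-force re-scorer for miRNA/target windows, written from the
# penalty rules (match 0 / G:U 0.5 / mismatch 1, doubled at miRNA pos 2-13)
# without reference to the package implementation
oracle_score <- function(mirna, window) {
  m <- strsplit(chartr("u", "t", tolower(mirna)), "")[[1]]
  w <- strsplit(chartr("u", "t", tolower(window)), "")[[1]]
  L <- length(m)
  stopifnot(length(w) == L)
  total <- 0
  for (i in seq_len(L)) {
    tb <- w[L - i + 1]
    pen <- if ((m[i] == "a" && tb == "t") || (m[i] == "t" && tb == "a") ||
               (m[i] == "c" && tb == "g") || (m[i] == "g" && tb == "c")) 0
           else if ((m[i] == "g" && tb == "t") || (m[i] == "t" && tb == "g")) 0.5
           else 1
    if (i >= 2 && i <= 13) pen <- pen * 2
    total <- total + pen
  }
  total
}

oracle_sites <- function(mirna, transcript, max_score) {
  L <- nchar(mirna)
  out <- list()
  for (s in seq_len(nchar(transcript) - L + 1)) {
    sc <- oracle_score(mirna, substr(transcript, s, s + L - 1))
    if (sc <= max_score) out[[length(out) + 1]] <- c(start = s, score = sc)
  }
  do.call(rbind, out)
}

# independent degradome category oracle, a direct transliteration of the rule
# text evaluated case by case
oracle_category <- function(profile, position) {
  r <- profile[position]
  if (r == 0) return(NA_integer_)
  if (r == 1) return(4L)
  M <- max(profile)
  med <- median(profile[profile >= 1])
  if (r == M) {
    if (sum(profile == M) == 1) return(0L) else return(1L)
  }
  if (r > med) return(2L)
  3L
}
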