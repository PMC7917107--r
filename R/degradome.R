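#' Reverse complement of a nucleotide string
#'
#' U and T are treated as equivalent; output alphabet is selectable so an RNA
#' miRNA can be written back into a DNA transcript.
#'
#' @param x single nucleotide string over A, C, G, U, T, N.
#' @param out output alphabet, `"DNA"` (complement of A is T) or `"RNA"`.
#' @return reverse-complemented uppercase string.
#' @export
reverse_complement <- function(x, out = c("DNA", "RNA")) {
  out <- match.arg(out)
  x <- toupper(x)
  comp <- if (out == "DNA") chartr("ACGUTN", "TGCAAN", x) else chartr("ACGUTN", "UGCAAN", x)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# integer encoding shared by the scorer: A=1 C=2 G=3 T/U=4 N=5
encode_nt <- function(x) {
  v <- strsplit(chartr("U", "T", toupper(x)), "")[[1]]
  code <- match(v, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) stop("non-ACGUTN symbol in sequence: ", paste(unique(v[is.na(code)]), collapse = ", "))
  code
}

# penalty lookup: rows = miRNA base, cols = target base.
# Watson-Crick match 0; G:U wobble (miRNA G vs target U, or miRNA U vs target G)
# 0.5; anything else (incl. N) 1.
penalty_table <- local({
  P <- matrix(1, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                       c("A", "C", "G", "T", "N")))
  P["A", "T"] <- 0; P["T", "A"] <- 0; P["C", "G"] <- 0; P["G", "C"] <- 0
  P["G", "T"] <- 0.5; P["T", "G"] <- 0.5
  P
})

pairing_symbol <- c("0" = "|", "0.5" = "o", "1" = ".")

#' Score miRNA/target-window complementarity
#'
#' Standard plant-miRNA penalty scheme: miRNA position i (5'->3') pairs target
#' window position `L - i + 1`; per-position penalties are 0 for a
#' Watson-Crick match, 0.5 for a G:U wobble and 1 for a mismatch, doubled over
#' miRNA positions 2-13 (the seed plus central region covering the cleavage
#' site). A perfect reverse complement scores 0.
#'
#' @param mirna miRNA sequence 5'->3' (RNA or DNA letters).
#' @param target_window transcript window 5'->3', same length as `mirna`.
#' @param mirna_id,transcript_id,target_start optional annotations carried
#'   into the result.
#' @return list with `score`, `pairing` (one character per miRNA position:
#'   `|` match, `o` G:U, `.` mismatch), `target_start`, `target_end` and
#'   `predicted_cleavage` (target position paired with miRNA position 10)
#'   when `target_start` is given.
#' @export
score_alignment <- function(mirna, target_window, mirna_id = NA_character_,
                            transcript_id = NA_character_, target_start = NA_integer_) {
  m <- encode_nt(mirna)
  t_ <- encode_nt(target_window)
  L <- length(m)
  if (length(t_) != L) stop(sprintf("length mismatch: miRNA %d nt vs window %d nt", L, length(t_)))
  pen <- penalty_table[cbind(m, t_[L - seq_len(L) + 1])]
  w <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  list(mirna_id = mirna_id, transcript_id = transcript_id,
       score = sum(w * pen),
       pairing = paste(pairing_symbol[as.character(pen)], collapse = ""),
       target_start = target_start,
       target_end = if (is.na(target_start)) NA_integer_ else target_start + L - 1L,
       predicted_cleavage = if (is.na(target_start)) NA_integer_ else target_start + L - 10L)
}

#' Find candidate miRNA target sites on a transcript
#'
#' Slides an ungapped window of miRNA length along the transcript, scores each
#' window with the [score_alignment()] penalty scheme, and keeps windows with
#' score at or below `max_score` (7.0 by default, the conventional plant
#' cutoff). The predicted cleavage coordinate is the transcript position
#' paired with miRNA position 10, i.e. `target_start + L - 10`.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param transcript transcript sequence 5'->3'.
#' @param max_score maximum allowed penalty score.
#' @param mirna_id,transcript_id annotations for the output.
#' @return data.frame with one row per retained site: `mirna_id`,
#'   `transcript_id`, `target_start`, `target_end`, `score`, `pairing`,
#'   `predicted_cleavage` (all coordinates 1-based inclusive).
#' @export
find_target_sites <- function(mirna, transcript, max_score = 7.0,
                              mirna_id = NA_character_, transcript_id = NA_character_) {
  m <- encode_nt(mirna)
  tr <- encode_nt(transcript)
  L <- length(m)
  n <- length(tr)
  empty <- data.frame(mirna_id = character(), transcript_id = character(),
                      target_start = integer(), target_end = integer(),
                      score = numeric(), pairing = character(),
                      predicted_cleavage = integer(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  n_win <- n - L + 1L
  w <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  # score(s) = sum_i w_i * P[m_i, tr[s + L - i]]; accumulate one vector add
  # per miRNA position instead of re-scoring every window
  scores <- numeric(n_win)
  for (i in seq_len(L)) {
    scores <- scores + w[i] * penalty_table[m[i], tr[seq_len(n_win) + L - i]]
  }
  keep <- which(scores <= max_score)
  if (!length(keep)) return(empty)
  tr_chars <- strsplit(chartr("U", "T", toupper(transcript)), "")[[1]]
  rows <- lapply(keep, function(s) {
    aln <- score_alignment(mirna, paste(tr_chars[s:(s + L - 1L)], collapse = ""),
                           mirna_id = mirna_id, transcript_id = transcript_id,
                           target_start = as.integer(s))
    as.data.frame(aln, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build per-transcript degradome tag profiles
#'
#' @param tags data.frame with columns `transcript`, `position` (1-based
#'   5'-end coordinate) and optionally `count` (default 1 per row).
#' @param transcript_lengths named integer vector of transcript lengths.
#' @return named list of integer vectors; element `t` has
#'   `transcript_lengths[t]` entries, `counts[p]` = tags with 5' end at `p`.
#' @export
build_profile <- function(tags, transcript_lengths) {
  if (is.null(names(transcript_lengths))) stop("transcript_lengths must be named")
  if (!"count" %in% names(tags)) tags$count <- 1L
  unknown <- setdiff(unique(tags$transcript), names(transcript_lengths))
  if (length(unknown)) stop("tags reference unknown transcript(s): ",
                            paste(unknown, collapse = ", "))
  profiles <- lapply(names(transcript_lengths), function(tid) {
    n <- transcript_lengths[[tid]]
    prof <- integer(n)
    here <- tags[tags$transcript == tid, , drop = FALSE]
    bad <- here$position < 1 | here$position > n
    if (any(bad)) {
      stop(sprintf("tag position out of range for transcript %s: %d (length %d)",
                   tid, here$position[which(bad)[1]], n))
    }
    for (i in seq_len(nrow(here))) {
      prof[here$position[i]] <- prof[here$position[i]] + here$count[i]
    }
    prof
  })
  names(profiles) <- names(transcript_lengths)
  profiles
}

#' Categorize a degradome cleavage site
#'
#' Degradome categories rank the tag abundance at the predicted cleavage
#' position against the rest of the transcript: with `r` reads at the site,
#' `M` the transcript maximum and `med` the median over positions carrying at
#' least one read — category 4 if `r == 1`; 0 if `r > 1` and `r` is the unique
#' maximum; 1 if `r > 1` equals a tied maximum; 2 if `1 < r < M` and
#' `r > med`; 3 if `1 < r <= med`. A site with zero reads is untestable and
#' returns `NA`.
#'
#' @param profile integer vector of per-position tag counts for one transcript.
#' @param position 1-based cleavage position.
#' @return list with `category` (integer or `NA`), `site_reads`,
#'   `transcript_max`, `transcript_median`.
#' @export
categorize_site <- function(profile, position) {
  if (position < 1 || position > length(profile)) {
    stop(sprintf("position %d outside profile of length %d", position, length(profile)))
  }
  r <- profile[position]
  M <- max(profile)
  covered <- profile[profile >= 1]
  med <- if (length(covered)) stats::median(covered) else NA_real_
  category <- if (r == 0) NA_integer_
    else if (r == 1) 4L
    else if (r == M && sum(profile == M) == 1L) 0L
    else if (r == M) 1L
    else if (r > med) 2L
    else 3L
  list(category = category, site_reads = as.integer(r),
       transcript_max = as.integer(M), transcript_median = med)
}

#' Categorize every predicted target site against degradome profiles
#'
#' @param sites data.frame as from [find_target_sites()] (must carry
#'   `transcript_id` and `predicted_cleavage`).
#' @param profiles named list of per-position tag count vectors.
#' @return `sites` with appended `category`, `site_reads`, `transcript_max`,
#'   `transcript_median` columns; sites with zero reads at the cleavage
#'   position are dropped with a message.
#' @export
categorize_sites <- function(sites, profiles) {
  if (!nrow(sites)) {
    return(cbind(sites, data.frame(category = integer(), site_reads = integer(),
                                   transcript_max = integer(),
                                   transcript_median = numeric())))
  }
  res <- lapply(seq_len(nrow(sites)), function(i) {
    prof <- profiles[[sites$transcript_id[i]]]
    if (is.null(prof)) stop("no profile for transcript ", sites$transcript_id[i])
    categorize_site(prof, sites$predicted_cleavage[i])
  })
  out <- cbind(sites, do.call(rbind, lapply(res, as.data.frame)))
  drop <- is.na(out$category)
  if (any(drop)) {
    message(sprintf("dropped %d site(s) with no degradome signal at the cleavage position", sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-position T-plot table for one transcript
#'
#' The tabular form of a T-plot: tag count at every transcript position with
#' predicted cleavage sites flagged (the "red dots").
#'
#' @param profile integer vector of per-position tag counts.
#' @param sites data.frame of sites on this transcript (columns
#'   `predicted_cleavage`, `mirna_id`); may be empty.
#' @return data.frame with `position` (1-based), `count`,
#'   `is_predicted_cleavage`, `mirna_id` (comma-joined when several miRNAs
#'   predict the same position, `NA` elsewhere); one row per position.
#' @export
tplot_table <- function(profile, sites = NULL) {
  n <- length(profile)
  out <- data.frame(position = seq_len(n), count = as.integer(profile),
                    is_predicted_cleavage = FALSE, mirna_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(sites) && nrow(sites)) {
    for (p in unique(sites$predicted_cleavage)) {
      out$is_predicted_cleavage[p] <- TRUE
      out$mirna_id[p] <- paste(sites$mirna_id[sites$predicted_cleavage == p], collapse = ",")
    }
  }
  out
}
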