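#' Classify one feature into the eight P1-H-P2 expression patterns
#'
#' Decision tree over the three pairwise calls (each "significant" means
#' called at the common fold and p thresholds):
#' 1. parents differ, F1 matches P1, F1 differs from P2 -> `ELD-P1-high` when
#'    P1 is the higher-expressing parent, else `ELD-P1-low`;
#' 2. the mirror rule for P2;
#' 3. F1 significantly above both parents -> `transgressive-up`; below both
#'    -> `transgressive-down`;
#' 4. parents differ, F1 differs from both and its mean lies strictly between
#'    the parental means -> `additive`;
#' 5. no significant comparison -> `conserved`;
#' 6. any remaining combination -> `conserved` with `ambiguous = TRUE`
#'    (e.g. F1 different from both parents but outside the parental range
#'    without transgressive significance in both directions, or a mean tie
#'    between significantly different parents).
#'
#' @param sig_p1p2,sig_f1p1,sig_f1p2 logical: is the comparison called at the
#'   thresholds?
#' @param lfc_f1p1,lfc_f1p2 log2 fold change of F1 over the parent.
#' @param mean_p1,mean_f1,mean_p2 normalized genotype means.
#' @return list with `label` (one of [pattern_labels]) and `ambiguous`.
#' @export
classify_triad <- function(sig_p1p2, sig_f1p1, sig_f1p2,
                           lfc_f1p1, lfc_f1p2,
                           mean_p1, mean_f1, mean_p2) {
  amb <- FALSE
  if (sig_p1p2 && !sig_f1p1 && sig_f1p2) {
    if (mean_p1 == mean_p2) { label <- "conserved"; amb <- TRUE }
    else label <- if (mean_p1 > mean_p2) "ELD-P1-high" else "ELD-P1-low"
  } else if (sig_p1p2 && sig_f1p1 && !sig_f1p2) {
    if (mean_p1 == mean_p2) { label <- "conserved"; amb <- TRUE }
    else label <- if (mean_p2 > mean_p1) "ELD-P2-high" else "ELD-P2-low"
  } else if (sig_f1p1 && sig_f1p2 && lfc_f1p1 > 0 && lfc_f1p2 > 0) {
    label <- "transgressive-up"
  } else if (sig_f1p1 && sig_f1p2 && lfc_f1p1 < 0 && lfc_f1p2 < 0) {
    label <- "transgressive-down"
  } else if (sig_p1p2 && sig_f1p1 && sig_f1p2 &&
             mean_f1 > min(mean_p1, mean_p2) && mean_f1 < max(mean_p1, mean_p2)) {
    label <- "additive"
  } else if (!sig_p1p2 && !sig_f1p1 && !sig_f1p2) {
    label <- "conserved"
  } else {
    label <- "conserved"; amb <- TRUE
  }
  list(label = label, ambiguous = amb)
}

#' Classify every feature at one stage
#'
#' Runs the four triad comparisons (F1 vs P1, F1 vs P2, P1 vs P2, F1 vs MPV)
#' on an MPV-augmented triad and applies [classify_triad()] per feature.
#' The F1-vs-MPV call does not enter the eight-way label; it defines
#' nonadditive (MPV-differential) features.
#'
#' @param tc a [triad_counts()] object containing the stage.
#' @param stage stage label.
#' @param thresholds a [call_thresholds()] applied to all four comparisons.
#' @return data.frame of class `pattern_calls`: `feature_id`, `stage`,
#'   `label`, `ambiguous`, `nonadditive`, `nonadditive_direction`, the four
#'   raw p-values and the three genotype means.
#' @export
classify_patterns <- function(tc, stage, thresholds = call_thresholds()) {
  aug <- make_mpv_pseudosamples(tc, stage)
  de_f1p1 <- triad_de(aug, stage, "P1", "F1")
  de_f1p2 <- triad_de(aug, stage, "P2", "F1")
  de_p1p2 <- triad_de(aug, stage, "P2", "P1")
  de_mpv  <- triad_de(aug, stage, "MPV", "F1")
  fl_f1p1 <- differential_flags(de_f1p1, thresholds)
  fl_f1p2 <- differential_flags(de_f1p2, thresholds)
  fl_p1p2 <- differential_flags(de_p1p2, thresholds)
  fl_mpv  <- differential_flags(de_mpv, thresholds)
  n <- nrow(de_f1p1)
  labels <- character(n); amb <- logical(n)
  for (i in seq_len(n)) {
    cl <- classify_triad(fl_p1p2$called[i], fl_f1p1$called[i], fl_f1p2$called[i],
                         de_f1p1$log2fc[i], de_f1p2$log2fc[i],
                         de_f1p1$mean_A[i], de_f1p1$mean_B[i], de_f1p2$mean_A[i])
    labels[i] <- cl$label; amb[i] <- cl$ambiguous
  }
  res <- data.frame(feature_id = de_f1p1$feature_id, stage = stage,
                    label = labels, ambiguous = amb,
                    nonadditive = fl_mpv$called,
                    nonadditive_direction = ifelse(fl_mpv$called, fl_mpv$direction, NA_character_),
                    p_F1_vs_P1 = de_f1p1$p_raw, p_F1_vs_P2 = de_f1p2$p_raw,
                    p_P1_vs_P2 = de_p1p2$p_raw, p_F1_vs_MPV = de_mpv$p_raw,
                    mean_P1 = de_f1p1$mean_A, mean_F1 = de_f1p1$mean_B,
                    mean_P2 = de_f1p2$mean_A,
                    stringsAsFactors = FALSE)
  class(res) <- c("pattern_calls", "data.frame")
  res
}

#' Tally pattern calls for one stage
#'
#' @param calls a `pattern_calls` data.frame from [classify_patterns()].
#' @return list with `stage`, `label_counts` (named over [pattern_labels]),
#'   `n_nonadditive_up` / `n_nonadditive_down` (F1 vs MPV calls),
#'   `n_high_eld` / `n_low_eld` and `pct_high_eld` (percent of ELD features
#'   matching the higher parent).
#' @export
summarize_patterns <- function(calls) {
  label_counts <- table(factor(calls$label, levels = pattern_labels))
  n_high <- sum(calls$label %in% c("ELD-P1-high", "ELD-P2-high"))
  n_low  <- sum(calls$label %in% c("ELD-P1-low", "ELD-P2-low"))
  list(stage = unique(calls$stage),
       label_counts = as.vector(label_counts) |> stats::setNames(pattern_labels),
       n_nonadditive_up = sum(calls$nonadditive & calls$nonadditive_direction == "up", na.rm = TRUE),
       n_nonadditive_down = sum(calls$nonadditive & calls$nonadditive_direction == "down", na.rm = TRUE),
       n_high_eld = n_high, n_low_eld = n_low,
       pct_high_eld = if (n_high + n_low > 0) 100 * n_high / (n_high + n_low) else NA_real_)
}

#' Features shared between two stages
#'
#' @param calls_a,calls_b `pattern_calls` data.frames for the two stages.
#' @param labels optional label filter applied to both stages.
#' @param nonadditive_only restrict to MPV-differential features (the
#'   MPV-DEM/DEG overlap of the study).
#' @return character vector of shared feature ids.
#' @export
stage_overlap <- function(calls_a, calls_b, labels = NULL, nonadditive_only = FALSE) {
  pick <- function(calls) {
    keep <- rep(TRUE, nrow(calls))
    if (!is.null(labels)) keep <- keep & calls$label %in% labels
    if (nonadditive_only) keep <- keep & calls$nonadditive
    calls$feature_id[keep]
  }
  intersect(pick(calls_a), pick(calls_b))
}
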