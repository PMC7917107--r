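#' miRNA-target expression correlations
#'
#' Pearson correlation between each miRNA and its degradome-predicted target
#' across the samples shared by the two normalized matrices, computed on
#' `log2(value + 1)`. A pair is flagged anticorrelated when `r < 0` and, if
#' differential-call sets are supplied, both members were called.
#'
#' @param mirna_matrix,gene_matrix normalized matrices (features x samples).
#' @param pairs data.frame with columns `mirna_id`, `target_id`.
#' @param mirna_called,gene_called optional character vectors of
#'   differentially called feature ids; when omitted the flag reduces to
#'   `r < 0`.
#' @return data.frame: `mirna_id`, `target_id`, `r`, `n_samples`,
#'   `negative_flag`. Zero-variance members give `r = NA`.
#' @export
pair_correlations <- function(mirna_matrix, gene_matrix, pairs,
                              mirna_called = NULL, gene_called = NULL) {
  if (!nrow(pairs)) stop("pairs must be nonempty")
  shared <- intersect(colnames(mirna_matrix), colnames(gene_matrix))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  lm_ <- log2(mirna_matrix[, shared, drop = FALSE] + 1)
  lg_ <- log2(gene_matrix[, shared, drop = FALSE] + 1)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- lm_[pairs$mirna_id[i], ]
    y <- lg_[pairs$target_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  flag <- !is.na(r) & r < 0
  if (!is.null(mirna_called)) flag <- flag & pairs$mirna_id %in% mirna_called
  if (!is.null(gene_called))  flag <- flag & pairs$target_id %in% gene_called
  data.frame(mirna_id = pairs$mirna_id, target_id = pairs$target_id,
             r = r, n_samples = length(shared), negative_flag = flag,
             stringsAsFactors = FALSE)
}

#' Chlorophyll content from absorbance
#'
#' Spectrophotometric pigment equations for 95% ethanol extracts:
#' `chl a (ug/mL) = 12.25 * A663.6 - 2.55 * A646.6` and
#' `chl b (ug/mL) = 20.31 * A646.6 - 4.91 * A663.6`; total is their sum.
#' Negative computed pigment values (possible on noisy or degraded extracts)
#' are flagged, never clamped.
#'
#' @param a663_6,a646_6 absorbances at 663.6 and 646.6 nm (>= 0, vectorized).
#' @return data.frame: `chlorophyll_a`, `chlorophyll_b`, `total` (ug/mL),
#'   `flagged` (TRUE when a or b is negative).
#' @export
chlorophyll <- function(a663_6, a646_6) {
  if (any(a663_6 < 0) || any(a646_6 < 0)) stop("absorbance must be >= 0")
  a <- 12.25 * a663_6 - 2.55 * a646_6
  b <- 20.31 * a646_6 - 4.91 * a663_6
  data.frame(chlorophyll_a = a, chlorophyll_b = b, total = a + b,
             flagged = a < 0 | b < 0)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` within each condition; `ddCt = dCt_test -
#' dCt_calibrator`; fold change `= 2^-ddCt`.
#'
#' @param ct_target_test,ct_ref_test cycle thresholds in the test condition.
#' @param ct_target_cal,ct_ref_cal cycle thresholds in the calibrator.
#' @return fold change (vectorized, always positive).
#' @export
ddct_fold <- function(ct_target_test, ct_ref_test, ct_target_cal, ct_ref_cal) {
  stopifnot(all(is.finite(c(ct_target_test, ct_ref_test, ct_target_cal, ct_ref_cal))))
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}

#' Mean cell size from a cell count per area
#'
#' @param area measured area in um^2 (> 0).
#' @param cell_count number of cells in the area (>= 1).
#' @return mean cell size, um^2 per cell.
#' @export
mean_cell_size <- function(area, cell_count) {
  if (any(area <= 0)) stop("area must be positive")
  if (any(cell_count < 1)) stop("cell_count must be >= 1")
  area / cell_count
}
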