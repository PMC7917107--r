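#' Median-of-ratios size factors
#'
#' Library-size factors for the NB test: each sample's factor is the median,
#' over features with strictly positive counts in every sample, of the ratio
#' of its count to the per-feature geometric-mean reference. Factors are
#' rescaled to geometric mean 1. When no feature is positive everywhere the
#' function falls back to total-count ratios with a warning.
#'
#' @param m a [triad_counts()] object or a count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "triad_counts")) m$counts else as.matrix(m)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    warning("no feature with positive counts in all samples; using total-count size factors")
    sf <- colSums(counts)
  } else {
    logref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    sf <- apply(counts[all_pos, , drop = FALSE], 2,
                function(col) stats::median(exp(log(col) - logref)))
  }
  sf <- sf / exp(mean(log(sf)))
  sf
}

norm_matrix <- function(values, method) {
  attr(values, "norm_method") <- method
  values
}

#' Normalization method tag of a normalized matrix
#' @param x matrix produced by [tpm()] or [fpkm()].
#' @return character method label.
#' @export
norm_method <- function(x) attr(x, "norm_method")

#' Transcripts-per-million normalization
#'
#' With feature lengths: per-kilobase rates are rescaled so each column sums
#' to one million. Without lengths (`lengths = NULL`, the miRNA case, where
#' mature miRNAs are all ~21 nt and the length term cancels) the values are
#' counts-per-million, tagged `"TPM (length-free)"`.
#'
#' @param m a [triad_counts()] object or count matrix.
#' @param lengths feature lengths in bp; defaults to `m$feature_lengths`,
#'   `NULL` for the length-free variant.
#' @return numeric matrix with columns summing to 1e6, method recorded in the
#'   `"norm_method"` attribute.
#' @export
tpm <- function(m, lengths = if (inherits(m, "triad_counts")) m$feature_lengths else NULL) {
  counts <- if (inherits(m, "triad_counts")) m$counts else as.matrix(m)
  if (is.null(lengths)) {
    rate <- counts
    method <- "TPM (length-free)"
  } else {
    lengths <- lengths[rownames(counts)]
    if (anyNA(lengths) || any(lengths <= 0)) stop("zero or missing feature length")
    rate <- counts / (lengths / 1000)
    method <- "TPM"
  }
  tot <- colSums(rate)
  if (any(tot == 0)) stop("column with zero total rate: ", colnames(counts)[which(tot == 0)[1]])
  norm_matrix(sweep(rate, 2, tot, "/") * 1e6, method)
}

#' Fragments-per-kilobase-per-million normalization
#'
#' `FPKM = 1e9 * count / (length_bp * column_total)`.
#'
#' @inheritParams tpm
#' @return numeric matrix of FPKM values.
#' @export
fpkm <- function(m, lengths = if (inherits(m, "triad_counts")) m$feature_lengths else NULL) {
  counts <- if (inherits(m, "triad_counts")) m$counts else as.matrix(m)
  if (is.null(lengths)) stop("feature lengths are required for FPKM")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) stop("zero or missing feature length")
  tot <- colSums(counts)
  if (any(tot == 0)) stop("column with zero total count: ", colnames(counts)[which(tot == 0)[1]])
  norm_matrix(1e9 * counts / outer(as.numeric(lengths), as.numeric(tot)), "FPKM")
}
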