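#' Construct a triad count matrix
#'
#' Container for raw integer counts of a P1/F1/P2 triad experiment, modelled
#' on the list-style objects of count-based differential-expression packages.
#' Rows are features (miRNAs or genes), columns are samples; every sample
#' carries genotype, stage and replicate metadata.
#'
#' @param counts integer matrix, features x samples, non-negative. Row names
#'   are feature ids, column names sample ids.
#' @param sample_meta data.frame with one row per sample and columns
#'   `sample` (matching `colnames(counts)`), `genotype` (one of `"P1"`,
#'   `"F1"`, `"P2"`, or `"MPV"` for mid-parent pseudo-samples), `stage`
#'   (`"S"` seedling or `"H"` early heading) and `replicate` (integer).
#'   An optional `size_factor` column stores per-sample normalization factors.
#' @param feature_lengths optional named numeric vector of feature lengths in
#'   bp (required for FPKM/length-aware TPM).
#' @return An object of class `triad_counts`: a list with elements `counts`,
#'   `samples` and `feature_lengths`.
#' @export
triad_counts <- function(counts, sample_meta, feature_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature ids as row names")
  if (is.null(colnames(counts))) stop("counts must have sample ids as column names")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage)) stop("counts contain non-numeric values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  mode(counts) <- "integer"
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  req <- c("sample", "genotype", "stage", "replicate")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss)) stop("sample_meta missing columns: ", paste(miss, collapse = ", "))
  absent <- setdiff(colnames(counts), sample_meta$sample)
  if (length(absent)) {
    stop("samples in matrix missing from sample sheet: ", paste(absent, collapse = ", "))
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- NULL
  bad_gt <- setdiff(unique(sample_meta$genotype), c("P1", "F1", "P2", "MPV"))
  if (length(bad_gt)) stop("unknown genotype label(s): ", paste(bad_gt, collapse = ", "))
  if (!is.null(feature_lengths)) {
    feature_lengths <- feature_lengths[rownames(counts)]
    if (anyNA(feature_lengths) || any(feature_lengths <= 0)) {
      stop("feature_lengths must be positive and cover every feature")
    }
  }
  structure(list(counts = counts, samples = sample_meta,
                 feature_lengths = feature_lengths),
            class = "triad_counts")
}

#' @export
print.triad_counts <- function(x, ...) {
  cat(sprintf("triad_counts: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$genotype, x$samples$stage)
  print(tab)
  invisible(x)
}

#' @export
dim.triad_counts <- function(x) dim(x$counts)

#' Subset a triad by stage and/or genotype
#'
#' @param tc a `triad_counts` object.
#' @param stage optional stage label to keep.
#' @param genotype optional genotype label(s) to keep.
#' @return A `triad_counts` with the selected sample columns.
#' @export
subset_triad <- function(tc, stage = NULL, genotype = NULL) {
  stopifnot(inherits(tc, "triad_counts"))
  keep <- rep(TRUE, nrow(tc$samples))
  if (!is.null(stage))    keep <- keep & tc$samples$stage %in% stage
  if (!is.null(genotype)) keep <- keep & tc$samples$genotype %in% genotype
  if (!any(keep)) stop("no samples left after subsetting")
  triad_counts(tc$counts[, keep, drop = FALSE],
               tc$samples[keep, , drop = FALSE],
               tc$feature_lengths)
}
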