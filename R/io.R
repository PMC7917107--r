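#' Read a count matrix and its sample sheet
#'
#' Counts are a tab-separated matrix with feature ids in the first column and
#' sample ids in the header; the sheet is a TSV with columns `sample`,
#' `genotype`, `stage`, `replicate`. Cells must be non-negative integers; a
#' fractional cell is rejected naming its feature and sample, as is a sample
#' missing from the sheet.
#'
#' @param path counts TSV.
#' @param sample_sheet_path sample sheet TSV.
#' @param feature_lengths optional named lengths passed through.
#' @return a [triad_counts()] object.
#' @export
read_count_matrix <- function(path, sample_sheet_path, feature_lengths = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (anyDuplicated(raw[[1]])) {
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(raw[[1]][duplicated(raw[[1]])]), collapse = ", "))
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- raw[[1]]
  num <- matrix(suppressWarnings(as.numeric(mat)), nrow(mat), ncol(mat))
  if (anyNA(num) || any(num != round(num))) {
    bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count '%s' at feature '%s', sample '%s'",
                 mat[bad[1], bad[2]], rownames(mat)[bad[1]], colnames(mat)[bad[2]]))
  }
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE,
                             comment.char = "#")
  storage.mode(num) <- "integer"
  dimnames(num) <- dimnames(mat)
  triad_counts(num, sheet, feature_lengths)
}

#' Write a count matrix and sample sheet
#'
#' @param tc a [triad_counts()] object.
#' @param path counts TSV destination.
#' @param sample_sheet_path sample sheet TSV destination.
#' @param comment optional header comment lines (written prefixed with `#`).
#' @return invisibly, the paths.
#' @export
write_count_matrix <- function(tc, path, sample_sheet_path, comment = NULL) {
  df <- data.frame(feature_id = rownames(tc$counts), tc$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_results(df, path, comment = comment)
  write_results(tc$samples[, c("sample", "genotype", "stage", "replicate")],
                sample_sheet_path)
  invisible(c(path, sample_sheet_path))
}

#' Read a FASTA file into a named sequence vector
#'
#' Ids are the first whitespace token of each header; sequences are
#' uppercased. Duplicate ids and empty sequences are rejected. U and T are
#' both accepted (and treated equivalently by the pairing code).
#'
#' @param path FASTA file.
#' @return named uppercase character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write a named sequence vector as FASTA
#'
#' @param seqs named character vector.
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Tab-separated with a header row and stable column order; numeric columns
#' are rounded to 6 significant digits; missing values are written as `NA`.
#' Optional comment lines (e.g. seed, method, coordinate convention) go above
#' the header prefixed with `#`.
#'
#' @param table data.frame.
#' @param path destination.
#' @param comment character vector of comment lines, or `NULL`.
#' @return invisibly, `path`.
#' @export
write_results <- function(table, path, comment = NULL) {
  for (j in seq_along(table)) {
    if (is.double(table[[j]])) {
      table[[j]] <- signif(table[[j]], 6)
      table[[j]][is.nan(table[[j]])] <- NA_real_
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path file path.
#' @return data.frame (comment lines skipped, `NA` strings as missing).
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}

#' Write degradome profiles as a long TSV
#'
#' Columns `transcript`, `position` (1-based, 5'-end coordinate), `count`;
#' positions with zero tags are omitted. Transcript lengths are recorded in
#' header comments so profiles round-trip exactly.
#'
#' @param profiles named list of per-position integer vectors.
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(names(profiles), function(tid) {
    nz <- which(profiles[[tid]] > 0)
    if (!length(nz)) return(NULL)
    data.frame(transcript = tid, position = nz, count = profiles[[tid]][nz],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(transcript = character(),
                                      position = integer(), count = integer())
  lens <- paste0("length ", names(profiles), "=", vapply(profiles, length, integer(1)))
  write_results(tab, path,
                comment = c("degradome 5'-end tag profile; positions 1-based inclusive", lens))
  invisible(path)
}

#' Read degradome profiles written by [write_profiles()]
#'
#' @param path file path.
#' @return named list of per-position integer vectors.
#' @export
read_profiles <- function(path) {
  header <- readLines(path)
  header <- header[startsWith(header, "# length ")]
  kv <- strsplit(sub("^# length ", "", header), "=")
  lens <- stats::setNames(as.integer(vapply(kv, `[[`, character(1), 2)),
                          vapply(kv, `[[`, character(1), 1))
  tab <- read_results(path)
  build_profile(tab, lens)
}
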