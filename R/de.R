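#' Differential-calling thresholds
#'
#' The study calls a miRNA differential at raw `P <= 0.05` with fold-change
#' `>= 1.5`, and a gene differential at BH-adjusted `P <= 0.05` with the same
#' fold cutoff; both bounds are inclusive.
#'
#' @param min_fold minimum fold change, `> 1` (default 1.5).
#' @param max_p significance cutoff in (0, 1) (default 0.05).
#' @param use_adjusted use BH-adjusted p (`TRUE`, mRNA convention) or raw p
#'   (`FALSE`, miRNA convention).
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(min_fold = 1.5, max_p = 0.05, use_adjusted = FALSE) {
  if (min_fold <= 1) stop("min_fold must be > 1")
  if (max_p <= 0 || max_p >= 1) stop("max_p must be in (0, 1)")
  structure(list(min_fold = min_fold, max_p = max_p, use_adjusted = use_adjusted),
            class = "call_thresholds")
}

#' Method-of-moments NB dispersion per feature
#'
#' On size-factor-normalized counts, the raw estimate is
#' `alpha = max(0, (s2 - m)/m^2)` with `s2` the replicate-pooled within-group
#' variance and `m` the overall normalized mean, then shrunk 50/50 toward the
#' lightly trimmed mean of all raw estimates and floored at 1e-8. The trim is
#' 2%: enough to drop outlier features, while heavier symmetric trims pull
#' the center of the right-skewed moment distribution down and de-calibrate
#' the Wald test. Features with zero mean in both groups are untestable
#' (`NA`).
#'
#' @param counts_A,counts_B integer matrices (features x replicates) for the
#'   two groups, aligned rows.
#' @param sf_A,sf_B per-sample size factors.
#' @return numeric vector of dispersions (NA = untestable).
#' @export
estimate_dispersion <- function(counts_A, counts_B, sf_A = rep(1, ncol(counts_A)),
                                sf_B = rep(1, ncol(counts_B))) {
  if (ncol(counts_A) < 2 || ncol(counts_B) < 2) stop("need >= 2 replicates per group")
  kA <- sweep(as.matrix(counts_A), 2, sf_A, "/")
  kB <- sweep(as.matrix(counts_B), 2, sf_B, "/")
  nA <- ncol(kA); nB <- ncol(kB)
  mA <- rowMeans(kA); mB <- rowMeans(kB)
  vA <- apply(kA, 1, stats::var); vB <- apply(kB, 1, stats::var)
  s2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  m <- (nA * mA + nB * mB) / (nA + nB)
  raw <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), NA_real_)
  # light trim: the raw moment estimates are right-skewed, so symmetric
  # trimming beyond a few percent biases the shrinkage target downward
  mid <- mean(raw, trim = 0.02, na.rm = TRUE)
  if (!is.finite(mid)) mid <- 0
  pmax(1e-8, 0.5 * raw + 0.5 * mid)
}

#' Two-group negative-binomial Wald test
#'
#' Group means are compared on the size-factor-normalized scale with a
#' pseudocount `c` (default 0.5): `log2fc = log2((mB + c)/(mA + c))`. The
#' standard error comes from the delta method on the NB mean-variance
#' relation, `Var(log2 mean) = (mu + alpha*mu^2) / (n * mu^2 * ln(2)^2)`
#' evaluated at the pseudocount-augmented group means, and the two-sided p is
#' normal. Untestable features (dispersion `NA`) propagate `p = NA`.
#'
#' @inheritParams estimate_dispersion
#' @param alpha per-feature NB dispersion; estimated with
#'   [estimate_dispersion()] when missing.
#' @param pseudocount added to normalized group means (bounds log2fc for
#'   zero counts).
#' @param comparison label stored in the result (e.g. `"F1_vs_P1"`).
#' @return data.frame of class `de_result`: `feature_id`, `mean_A`, `mean_B`,
#'   `log2fc` (B over A), `dispersion`, `p_raw`, `p_adj` (BH), `comparison`.
#' @export
nb_wald_test <- function(counts_A, counts_B, sf_A = rep(1, ncol(counts_A)),
                         sf_B = rep(1, ncol(counts_B)), alpha = NULL,
                         pseudocount = 0.5, comparison = "B_vs_A") {
  counts_A <- as.matrix(counts_A); counts_B <- as.matrix(counts_B)
  if (is.null(alpha)) alpha <- estimate_dispersion(counts_A, counts_B, sf_A, sf_B)
  kA <- sweep(counts_A, 2, sf_A, "/")
  kB <- sweep(counts_B, 2, sf_B, "/")
  nA <- ncol(kA); nB <- ncol(kB)
  mA <- rowMeans(kA); mB <- rowMeans(kB)
  c0 <- pseudocount
  log2fc <- log2((mB + c0) / (mA + c0))
  varlog <- function(mu, n) (mu + alpha * mu^2) / (n * mu^2 * log(2)^2)
  se <- sqrt(varlog(mA + c0, nA) + varlog(mB + c0, nB))
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[is.na(alpha)] <- NA_real_
  ids <- rownames(counts_A)
  if (is.null(ids)) ids <- sprintf("feat_%04d", seq_along(p))
  res <- data.frame(feature_id = ids, mean_A = mA, mean_B = mB,
                    log2fc = log2fc, dispersion = alpha,
                    p_raw = p, p_adj = bh_adjust(p),
                    comparison = comparison,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; `NA` values are excluded from the number of tests
#' and returned as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differential features at thresholds
#'
#' A feature is called when `2^|log2fc| >= min_fold` and the selected p
#' (raw or BH-adjusted) is `<= max_p`; both bounds inclusive. Direction is
#' the sign of `log2fc` (`"up"` = higher in group B).
#'
#' @param results a `de_result` data.frame from [nb_wald_test()].
#' @param thresholds a [call_thresholds()].
#' @return the called subset with a `direction` column appended.
#' @export
call_differential <- function(results, thresholds = call_thresholds()) {
  flags <- differential_flags(results, thresholds)
  out <- results[flags$called, , drop = FALSE]
  out$direction <- flags$direction[flags$called]
  rownames(out) <- NULL
  out
}

#' Per-feature called/direction flags (full-length companion of
#' [call_differential()], convenient for classification).
#' @inheritParams call_differential
#' @return data.frame with `feature_id`, `called` (logical) and `direction`.
#' @export
differential_flags <- function(results, thresholds = call_thresholds()) {
  p <- if (thresholds$use_adjusted) results$p_adj else results$p_raw
  fold <- 2^abs(results$log2fc)
  called <- !is.na(p) & p <= thresholds$max_p & fold >= thresholds$min_fold
  data.frame(feature_id = results$feature_id, called = called,
             direction = ifelse(results$log2fc > 0, "up",
                                ifelse(results$log2fc < 0, "down", "none")),
             stringsAsFactors = FALSE)
}

#' Append mid-parent-value pseudo-samples to a triad
#'
#' The hybrid's additive expectation is represented as r pseudo-replicates:
#' pseudo-replicate i is the rounded average of the size-factor-normalized
#' counts of P1 replicate i and P2 replicate i at the given stage. Pseudo
#' size factors are 1 and the genotype label is `"MPV"`, so the pseudo-group
#' drops into the same NB test code path as any real group. Real samples get
#' their stage-level median-of-ratios factors recorded in
#' `samples$size_factor`.
#'
#' @param tc a [triad_counts()] object.
#' @param stage stage to build pseudo-samples for.
#' @return a `triad_counts` restricted to the stage, with MPV columns
#'   appended and a `size_factor` metadata column.
#' @export
make_mpv_pseudosamples <- function(tc, stage) {
  st <- subset_triad(tc, stage = stage)
  if ("size_factor" %in% names(st$samples)) {
    sf <- st$samples$size_factor      # caller-supplied factors take precedence
  } else {
    sf <- size_factors(st)
    st$samples$size_factor <- sf
  }
  p1 <- which(st$samples$genotype == "P1")
  p2 <- which(st$samples$genotype == "P2")
  if (!length(p1) || !length(p2)) stop("both parents required at stage ", stage)
  if (length(p1) != length(p2)) {
    warning("unequal parental replicate counts; pairing by sorted replicate index up to the smaller")
  }
  p1 <- p1[order(st$samples$replicate[p1])]
  p2 <- p2[order(st$samples$replicate[p2])]
  r <- min(length(p1), length(p2))
  mpv <- matrix(0L, nrow(st$counts), r,
                dimnames = list(rownames(st$counts),
                                paste("MPV", stage, seq_len(r), sep = "_")))
  for (i in seq_len(r)) {
    mpv[, i] <- as.integer(round((st$counts[, p1[i]] / sf[p1[i]] +
                                  st$counts[, p2[i]] / sf[p2[i]]) / 2))
  }
  meta <- rbind(st$samples,
                data.frame(sample = colnames(mpv), genotype = "MPV", stage = stage,
                           replicate = seq_len(r), size_factor = 1,
                           stringsAsFactors = FALSE))
  triad_counts(cbind(st$counts, mpv), meta, st$feature_lengths)
}

#' Run one triad comparison at a stage
#'
#' Convenience wrapper: subsets the two genotype groups at a stage, applies
#' stage-level size factors (stored ones if present, else median-of-ratios
#' over the stage), and runs [nb_wald_test()]. Group A is the reference, so
#' `log2fc > 0` means higher in `group_b`.
#'
#' @param tc a [triad_counts()] (possibly MPV-augmented).
#' @param stage stage label.
#' @param group_a,group_b genotype labels (`"P1"`, `"F1"`, `"P2"`, `"MPV"`).
#' @return a `de_result` data.frame tagged `"<group_b>_vs_<group_a>"`.
#' @export
triad_de <- function(tc, stage, group_a, group_b) {
  st <- subset_triad(tc, stage = stage)
  if ("size_factor" %in% names(st$samples)) {
    sf <- st$samples$size_factor
  } else {
    sf <- size_factors(st)
  }
  ia <- which(st$samples$genotype == group_a)
  ib <- which(st$samples$genotype == group_b)
  if (!length(ia)) stop("no samples for genotype ", group_a, " at stage ", stage)
  if (!length(ib)) stop("no samples for genotype ", group_b, " at stage ", stage)
  nb_wald_test(st$counts[, ia, drop = FALSE], st$counts[, ib, drop = FALSE],
               sf[ia], sf[ib],
               comparison = paste0(group_b, "_vs_", group_a))
}
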