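test_that("moment dispersion is near zero for Poisson and near truth for NB", {
  set.seed(21)
  n <- 1000
  mu <- 10^runif(n, 1, 3)
  pois <- function() sapply(1:3, function(j) rpois(n, mu))
  a_pois <- estimate_dispersion(pois(), pois())
  expect_lte(median(a_pois), 0.01)
  nb <- function(reps) sapply(seq_len(reps), function(j) rnbinom(n, mu = mu, size = 1 / 0.2))
  a_nb <- estimate_dispersion(nb(10), nb(10))
  expect_gte(median(a_nb), 0.1)
  expect_lte(median(a_nb), 0.3)
})

test_that("degenerate dispersion inputs floor or flag correctly", {
  A <- matrix(5L, 4, 3, dimnames = list(paste0("f", 1:4), NULL))
  a <- estimate_dispersion(A, A)          # zero variance: raw estimate <= 0
  expect_true(all(a >= 1e-8))
  expect_lte(max(a), 1e-6)
  Z <- matrix(0L, 1, 3); rownames(Z) <- "z"
  expect_true(is.na(estimate_dispersion(Z, Z)[1]))
  expect_error(estimate_dispersion(A[, 1, drop = FALSE], A), "replicates")
})

test_that("identical groups give log2fc 0 and p 1", {
  A <- matrix(c(100L, 100L, 100L, 7L, 9L, 8L), 2, 3, byrow = TRUE,
              dimnames = list(c("f1", "f2"), NULL))
  res <- nb_wald_test(A, A, alpha = c(0, 0))
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$p_raw, c(1, 1))
})

test_that("the Wald statistic reproduces an independently coded evaluation", {
  A <- matrix(100L, 1, 3, dimnames = list("f1", NULL))
  B <- matrix(200L, 1, 3, dimnames = list("f1", NULL))
  res <- nb_wald_test(A, B, alpha = 0)
  # independent evaluation straight from the published formulas
  c0 <- 0.5
  lfc <- log2(200.5 / 100.5)
  se <- sqrt(100.5 / (3 * 100.5^2 * log(2)^2) + 200.5 / (3 * 200.5^2 * log(2)^2))
  p <- 2 * pnorm(-abs(lfc / se))
  expect_equal(res$log2fc, lfc)
  expect_equal(res$p_raw, p)
  expect_equal(res$log2fc, 1, tolerance = 0.01)
})

test_that("swapping groups negates log2fc and preserves p", {
  set.seed(5)
  A <- matrix(rnbinom(300, mu = 80, size = 20), 100, 3,
              dimnames = list(sprintf("f%03d", 1:100), NULL))
  B <- matrix(rnbinom(300, mu = 160, size = 20), 100, 3,
              dimnames = list(sprintf("f%03d", 1:100), NULL))
  ab <- nb_wald_test(A, B, alpha = rep(0.05, 100))
  ba <- nb_wald_test(B, A, alpha = rep(0.05, 100))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_raw, ba$p_raw)
})

test_that("the null rejection rate is calibrated near the nominal level", {
  set.seed(31)
  n <- 2000
  mu <- 10^runif(n, 1, 3)
  A <- sapply(1:3, function(j) rnbinom(n, mu = mu, size = 1 / 0.05))
  B <- sapply(1:3, function(j) rnbinom(n, mu = mu, size = 1 / 0.05))
  rownames(A) <- rownames(B) <- sprintf("f%04d", 1:n)
  frac <- mean(nb_wald_test(A, B)$p_raw <= 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment matches the hand example and its defining properties", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(9)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  # NA excluded from the number of tests: m = 2, not 3
  expect_equal(bh_adjust(c(0.01, NA, 0.02)), c(0.02, NA, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential calls use inclusive fold and p bounds", {
  mk <- function(lfc, p) {
    r <- data.frame(feature_id = "f", mean_A = 10, mean_B = 10 * 2^lfc,
                    log2fc = lfc, dispersion = 0.05, p_raw = p, p_adj = p,
                    comparison = "F1_vs_P1")
    class(r) <- c("de_result", "data.frame")
    r
  }
  thr <- call_thresholds(min_fold = 1.5, max_p = 0.05)
  expect_equal(nrow(call_differential(mk(log2(1.49), 0.001), thr)), 0)
  hit <- call_differential(mk(log2(1.5), 0.05), thr)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$direction, "up")
  expect_equal(call_differential(mk(-1, 0.01), thr)$direction, "down")
  expect_error(call_thresholds(min_fold = 0.9), "min_fold")
  expect_error(call_thresholds(max_p = 0), "max_p")
})

test_that("MPV pseudo-samples average the parents replicate by replicate", {
  tc <- flat_triad(100, 250, 300)
  tc$samples$size_factor <- 1         # unit factors: pure replicate averaging
  aug <- make_mpv_pseudosamples(tc, "S")
  mpv_cols <- aug$samples$genotype == "MPV"
  expect_equal(sum(mpv_cols), 3)
  expect_true(all(aug$counts[, mpv_cols] == 200L))
  expect_true(all(aug$samples$size_factor[mpv_cols] == 1))
  # identical parents: MPV equals either parent
  tc2 <- flat_triad(120, 80, 120)
  tc2$samples$size_factor <- 1
  aug2 <- make_mpv_pseudosamples(tc2, "S")
  expect_true(all(aug2$counts[, aug2$samples$genotype == "MPV"] == 120L))
})

test_that("F1 vs MPV separates planted additive from planted nonadditive features", {
  set.seed(13)
  n <- 400
  nonadd <- seq_len(120)          # minority of features nonadditive, rest additive
  mu <- 10^runif(n, 1.5, 3)
  f1_mu <- mu
  # |log2fc| = 2 relative to the mid-parent, balanced directions as planted
  # in the triad simulations (one-sided shifts would defeat any global
  # normalization, median-of-ratios included)
  f1_mu[nonadd] <- mu[nonadd] * rep(c(4, 0.25), 60)
  mk <- function(m) {
    out <- sapply(1:3, function(j) rnbinom(n, mu = m, size = 1 / 0.05))
    rownames(out) <- sprintf("f%04d", 1:n)
    out
  }
  cts <- cbind(mk(mu), mk(f1_mu), mk(mu))
  colnames(cts) <- paste(rep(c("P1", "F1", "P2"), each = 3), "S", rep(1:3, 3), sep = "_")
  tc <- triad_counts(cts, data.frame(sample = colnames(cts),
                                     genotype = rep(c("P1", "F1", "P2"), each = 3),
                                     stage = "S", replicate = rep(1:3, 3)))
  de <- triad_de(make_mpv_pseudosamples(tc, "S"), "S", "MPV", "F1")
  called <- differential_flags(de, call_thresholds())$called
  # additive features behave as the null for F1 vs MPV
  expect_lt(mean(called[-nonadd]), 0.15)
  # planted nonadditive features are recalled
  expect_gte(mean(called[nonadd]), 0.8)
})

test_that("recall is monotone in the planted effect size", {
  set.seed(17)
  n <- 300
  mu <- 10^runif(n, 1.5, 3)
  recall_at <- function(lfc) {
    A <- sapply(1:3, function(j) rnbinom(n, mu = mu, size = 1 / 0.05))
    B <- sapply(1:3, function(j) rnbinom(n, mu = mu * 2^lfc, size = 1 / 0.05))
    rownames(A) <- rownames(B) <- sprintf("f%03d", 1:n)
    mean(differential_flags(nb_wald_test(A, B), call_thresholds())$called)
  }
  r <- vapply(c(0.5, 1, 2), recall_at, numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_gte(r[3], 0.8)
})
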