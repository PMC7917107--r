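# Independent rule-table oracle: evaluates the classification rules in their
# stated priority order from scratch, as data rather than control flow.
oracle_pattern <- function(s_pp, s_f1, s_f2, p1, f1, p2) {
  rules <- list(
    list(fires = s_pp && !s_f1 && s_f2 && p1 != p2,
         label = function() if (p1 > p2) "ELD-P1-high" else "ELD-P1-low"),
    list(fires = s_pp && s_f1 && !s_f2 && p1 != p2,
         label = function() if (p2 > p1) "ELD-P2-high" else "ELD-P2-low"),
    list(fires = s_f1 && s_f2 && f1 > p1 && f1 > p2,
         label = function() "transgressive-up"),
    list(fires = s_f1 && s_f2 && f1 < p1 && f1 < p2,
         label = function() "transgressive-down"),
    list(fires = s_pp && s_f1 && s_f2 && f1 > min(p1, p2) && f1 < max(p1, p2),
         label = function() "additive"),
    list(fires = !s_pp && !s_f1 && !s_f2,
         label = function() "conserved"))
  for (r in rules) if (r$fires) return(list(label = r$label(), ambiguous = FALSE))
  list(label = "conserved", ambiguous = TRUE)
}

test_that("the classifier matches the rule-table oracle over all call combinations", {
  mean_sets <- list(c(100, 100, 10), c(10, 100, 100), c(100, 10, 100),
                    c(10, 50, 100), c(100, 50, 10), c(100, 300, 100),
                    c(100, 30, 100), c(50, 50, 50), c(100, 120, 10),
                    c(10, 5, 100))
  for (s_pp in c(TRUE, FALSE)) for (s_f1 in c(TRUE, FALSE)) for (s_f2 in c(TRUE, FALSE)) {
    for (m in mean_sets) {
      got <- classify_triad(s_pp, s_f1, s_f2,
                            log2(m[2] / m[1]), log2(m[2] / m[3]),
                            m[1], m[2], m[3])
      want <- oracle_pattern(s_pp, s_f1, s_f2, m[1], m[2], m[3])
      expect_identical(got, want,
                       label = sprintf("calls (%d,%d,%d) means (%g,%g,%g)",
                                       s_pp, s_f1, s_f2, m[1], m[2], m[3]))
    }
  }
})

test_that("the classifier assigns exactly one valid label on random inputs", {
  set.seed(23)
  for (i in 1:300) {
    sig <- runif(3) < 0.5
    m <- 10^runif(3, 0, 3)
    got <- classify_triad(sig[1], sig[2], sig[3],
                          log2(m[2] / m[1]), log2(m[2] / m[3]), m[1], m[2], m[3])
    expect_length(got$label, 1)
    expect_true(got$label %in% pattern_labels)
  }
})

test_that("canonical worked examples classify as expected", {
  # parents differ, F1 indistinguishable from the high parent P1
  expect_equal(classify_triad(TRUE, FALSE, TRUE, log2(1), log2(10), 100, 100, 10)$label,
               "ELD-P1-high")
  # hybrid significantly above both parents
  expect_equal(classify_triad(FALSE, TRUE, TRUE, log2(3), log2(3), 100, 300, 100)$label,
               "transgressive-up")
  # nothing significant
  expect_equal(classify_triad(FALSE, FALSE, FALSE, 0.1, -0.1, 100, 105, 95)$label,
               "conserved")
  # mean tie between significantly different parents: flagged, not guessed
  tie <- classify_triad(TRUE, FALSE, TRUE, 0, 0, 100, 100, 100)
  expect_true(tie$ambiguous)
})

test_that("pattern summaries tally labels, nonadditive calls and ELD direction", {
  calls <- fake_calls(c("conserved", "conserved", "ELD-P1-high", "ELD-P2-low",
                        "transgressive-up"),
                      nonadd_dir = c(NA, "up", "down", "down", "up"))
  s <- summarize_patterns(calls)
  expect_equal(sum(s$label_counts), 5)
  expect_equal(unname(s$label_counts["conserved"]), 2)
  expect_equal(s$n_nonadditive_up, 2)
  expect_equal(s$n_nonadditive_down, 2)
  expect_equal(s$n_high_eld, 1)
  expect_equal(s$n_low_eld, 1)
  # all conserved: zero everywhere
  s0 <- summarize_patterns(fake_calls(rep("conserved", 4)))
  expect_equal(sum(s0$label_counts[-1]), 0)
  expect_equal(s0$n_nonadditive_up + s0$n_nonadditive_down, 0)
  expect_true(is.na(s0$pct_high_eld))
})

test_that("high-parental ELD shares reproduce the published S and H ratios", {
  s_calls <- fake_calls(rep(c("ELD-P1-high", "ELD-P1-low"), c(1663, 2384 - 1663)))
  expect_equal(round(summarize_patterns(s_calls)$pct_high_eld), 70)
  h_calls <- fake_calls(rep(c("ELD-P2-high", "ELD-P2-low"), c(915, 1103 - 915)))
  expect_equal(round(summarize_patterns(h_calls)$pct_high_eld), 83)
})

test_that("stage overlap intersects feature sets with optional filters", {
  a <- fake_calls(c("conserved", "ELD-P1-high", "transgressive-up"),
                  ids = c("x", "y", "z"), nonadd_dir = c(NA, "down", "up"))
  b <- fake_calls(c("ELD-P1-high", "conserved", "transgressive-up"),
                  ids = c("y", "q", "z"), nonadd_dir = c("down", NA, NA), stage = "H")
  expect_setequal(stage_overlap(a, b), c("y", "z"))
  expect_equal(stage_overlap(a, b, labels = "ELD-P1-high"), "y")
  expect_equal(stage_overlap(a, b, nonadditive_only = TRUE), "y")
  expect_length(stage_overlap(a, fake_calls("conserved", ids = "none")), 0)
})

test_that("a planted cross-stage overlap is recovered exactly without noise", {
  labels <- rep("transgressive-up", 30)
  shared <- sprintf("feat_%02d", 1:17)
  a <- fake_calls(labels, ids = c(shared, sprintf("sa_%02d", 1:13)),
                  nonadd_dir = rep("up", 30))
  b <- fake_calls(labels, ids = c(shared, sprintf("sb_%02d", 1:13)),
                  nonadd_dir = rep("up", 30), stage = "H")
  expect_setequal(stage_overlap(a, b, nonadditive_only = TRUE), shared)
})

test_that("well-powered planted classes are recovered from simulated triads", {
  cfg <- triad_sim_config(n_features = 600, seed = 19)
  sim <- gen_triad_counts(cfg)
  calls <- classify_patterns(sim$counts, "S")
  # exactly one label per feature, all features classified
  expect_equal(nrow(calls), 600)
  expect_true(all(calls$label %in% pattern_labels))
  acc <- per_class_accuracy(calls, sim$truth)
  # classes whose planted fold separations are well above the call threshold
  strong <- c("conserved", "ELD-P1-high", "ELD-P1-low", "ELD-P2-high", "ELD-P2-low")
  expect_true(all(acc[strong] >= 0.8))
  # nonadditive tallies come from the F1-vs-MPV comparison: ELD and
  # transgressive classes dominate them, conserved features do not
  s <- summarize_patterns(calls)
  expect_gt(s$n_nonadditive_up + s$n_nonadditive_down, 0)
})
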