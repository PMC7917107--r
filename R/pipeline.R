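#' Simulate expression for miRNA-target pairs with a planted correlation
#'
#' Log2 expression of each pair member is bivariate normal with correlation
#' `r_true` across samples; values are returned on the linear scale, so
#' [pair_correlations()] (which works on `log2(x + 1)`) recovers `r_true` up
#' to sampling noise.
#'
#' @param n_pairs number of miRNA-target pairs.
#' @param r_true planted correlation (e.g. -0.6 for an anticorrelated pair).
#' @param n_samples number of shared samples.
#' @param seed integer seed.
#' @param log2_mean,log2_sd mean and sd of log2 expression (defaults 8 and 1).
#' @return list with `mirna` and `gene` matrices (pairs x samples, shared
#'   column names) and `pairs` (data.frame `mirna_id`, `target_id`).
#' @export
gen_correlated_pairs <- function(n_pairs, r_true, n_samples, seed = 1,
                                 log2_mean = 8, log2_sd = 1) {
  stopifnot(abs(r_true) <= 1, n_samples >= 3)
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n_samples))
  z1 <- matrix(stats::rnorm(n_pairs * n_samples), n_pairs)
  eps <- matrix(stats::rnorm(n_pairs * n_samples), n_pairs)
  z2 <- r_true * z1 + sqrt(1 - r_true^2) * eps
  mir <- 2^(log2_mean + log2_sd * z1)
  gene <- 2^(log2_mean + log2_sd * z2)
  dimnames(mir) <- list(sprintf("mir_%03d", seq_len(n_pairs)), samples)
  dimnames(gene) <- list(sprintf("tx_%03d", seq_len(n_pairs)), samples)
  list(mirna = mir, gene = gene,
       pairs = data.frame(mirna_id = rownames(mir), target_id = rownames(gene),
                          stringsAsFactors = FALSE))
}

default_run_config <- function() {
  list(
    seed = 1,
    out_dir = "results",
    stages = c("simulate", "phenotypes", "detest", "classify", "degradome", "integrate"),
    sim = list(n_features = 600, n_reps = 3, effect_log2fc = 2, dispersion = 0.05),
    phenotype = list(traits = c("GW", "PH", "SLW", "LN", "LL", "LW"),
                     n_plants = 20, planted_mph = 92, planted_bph = 55,
                     noise_cv = 0.1),
    degradome = list(n_transcripts = 12, n_mirnas = 6, n_planted_sites = 6,
                     tag_count = 10, background_tag_rate = 0.1),
    de = list(min_fold = 1.5, max_p = 0.05, use_adjusted = FALSE)
  )
}

#' Validate a pipeline run configuration
#'
#' @param config named list (missing keys are filled from the defaults) or a
#'   path to a YAML file.
#' @return character vector of problems; empty when the config is runnable.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) return(sprintf("config file '%s' does not exist", config))
    config <- yaml::read_yaml(config)
  }
  config <- utils::modifyList(default_run_config(), config)
  problems <- character()
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    problems <- c(problems, "seed: must be a single integer")
  }
  bad_stage <- setdiff(config$stages, default_run_config()$stages)
  if (length(bad_stage)) {
    problems <- c(problems, paste0("stages: unknown stage(s) ",
                                   paste(bad_stage, collapse = ", ")))
  }
  if (config$de$min_fold <= 1) problems <- c(problems, "de.min_fold: must be > 1")
  if (config$de$max_p <= 0 || config$de$max_p >= 1) {
    problems <- c(problems, "de.max_p: must be in (0, 1)")
  }
  if (!is.null(config$counts_path) && !file.exists(config$counts_path)) {
    problems <- c(problems, sprintf("counts_path: '%s' does not exist", config$counts_path))
  }
  if (!is.null(config$sample_sheet_path) && !file.exists(config$sample_sheet_path)) {
    problems <- c(problems, sprintf("sample_sheet_path: '%s' does not exist", config$sample_sheet_path))
  }
  if (!is.null(config$sim$class_proportions) &&
      abs(sum(unlist(config$sim$class_proportions)) - 1) > 1e-9) {
    problems <- c(problems, "sim.class_proportions: must sum to 1")
  }
  ph <- config$phenotype
  if (any(rep_len(ph$planted_bph, length(ph$traits)) >
          rep_len(ph$planted_mph, length(ph$traits)))) {
    problems <- c(problems, "phenotype.planted_bph: must not exceed planted_mph")
  }
  problems
}

config_checksum <- function(config) {
  config$out_dir <- NULL   # analysis parameters only, not the output location
  txt <- paste(deparse(config[sort(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full triad heterosis pipeline on simulated inputs
#'
#' Executes the requested stages in dependency order: simulate counts for the
#' S and H stages with planted pattern classes, simulate phenotypes and
#' degradome inputs, run the four triad comparisons per stage, classify the
#' eight expression patterns, categorize degradome target sites, and pair
#' miRNA/target expression. All tables are written under `out_dir` with the
#' seed and a config checksum in their header comments; `report.txt`
#' summarizes counts per comparison, pattern tallies, category tallies and
#' recovery against the planted truth. Re-running with the same config and
#' seed reproduces identical outputs.
#'
#' @param config named list overriding the defaults, or a YAML file path.
#' @return invisibly, a list with the report lines and the key in-memory
#'   results (`truth`, `patterns`, `sites`, `heterosis`, `correlations`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_run_config(config)
  if (length(problems)) stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  config <- utils::modifyList(default_run_config(), config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(sprintf("seed=%d", as.integer(config$seed)),
           sprintf("config=%s", config_checksum(config)))
  out <- function(name) file.path(config$out_dir, name)
  report <- c("triad heterosis pipeline report", hdr)
  state <- list()
  thr <- call_thresholds(config$de$min_fold, config$de$max_p, config$de$use_adjusted)

  if ("simulate" %in% config$stages) {
    for (stage in c("S", "H")) {
      sim_args <- config$sim
      sim_args$seed <- as.integer(config$seed) + (stage == "H")
      if (!is.null(sim_args$class_proportions)) {
        sim_args$class_proportions <- unlist(sim_args$class_proportions)
      }
      cfg <- do.call(triad_sim_config, sim_args)
      sim <- gen_triad_counts(cfg, stage = stage)
      state$triads[[stage]] <- sim$counts
      state$truth[[stage]] <- sim$truth
      write_count_matrix(sim$counts, out(sprintf("counts_%s.tsv", stage)),
                         out(sprintf("samples_%s.tsv", stage)), comment = hdr)
      write_results(sim$truth, out(sprintf("truth_%s.tsv", stage)), comment = hdr)
    }
    report <- c(report, sprintf("simulate: %d features x 2 stages, dispersion %.3g",
                                config$sim$n_features, config$sim$dispersion))
  }

  if ("phenotypes" %in% config$stages) {
    ph <- config$phenotype
    tbl <- gen_phenotypes(ph$traits, ph$n_plants, ph$planted_mph, ph$planted_bph,
                          noise_cv = ph$noise_cv, seed = as.integer(config$seed) + 11)
    state$heterosis <- heterosis_report(tbl)
    write_results(tbl, out("phenotypes.tsv"), comment = hdr)
    write_results(state$heterosis, out("heterosis_report.tsv"), comment = hdr)
    report <- c(report, sprintf("phenotypes: planted MPH %s%%, recovered mean %.1f%% over %d traits",
                                paste(unique(ph$planted_mph), collapse = "/"),
                                mean(state$heterosis$MPH), nrow(state$heterosis)))
  }

  if ("detest" %in% config$stages || "classify" %in% config$stages) {
    if (is.null(state$triads)) stop("stage 'detest' requires stage 'simulate'")
    for (stage in names(state$triads)) {
      aug <- make_mpv_pseudosamples(state$triads[[stage]], stage)
      for (cmp in list(c("P1", "F1"), c("P2", "F1"), c("P2", "P1"), c("MPV", "F1"))) {
        de <- triad_de(aug, stage, cmp[1], cmp[2])
        called <- call_differential(de, thr)
        write_results(de, out(sprintf("de_%s_%s.tsv", de$comparison[1], stage)),
                      comment = hdr)
        report <- c(report, sprintf("detest %s %s: %d/%d called (%d up, %d down)",
                                    stage, de$comparison[1], nrow(called), nrow(de),
                                    sum(called$direction == "up"),
                                    sum(called$direction == "down")))
      }
    }
  }

  if ("classify" %in% config$stages) {
    for (stage in names(state$triads)) {
      calls <- classify_patterns(state$triads[[stage]], stage, thr)
      state$patterns[[stage]] <- calls
      write_results(calls, out(sprintf("patterns_%s.tsv", stage)), comment = hdr)
      smry <- summarize_patterns(calls)
      report <- c(report,
                  sprintf("classify %s: %s", stage,
                          paste(names(smry$label_counts), smry$label_counts,
                                sep = "=", collapse = " ")),
                  sprintf("classify %s: nonadditive up=%d down=%d; high-ELD %.1f%% of ELD",
                          stage, smry$n_nonadditive_up, smry$n_nonadditive_down,
                          smry$pct_high_eld))
      truth <- state$truth[[stage]]
      acc <- per_class_accuracy(calls, truth)
      report <- c(report, sprintf("classify %s recovery: %s", stage,
                                  paste(names(acc), sprintf("%.2f", acc),
                                        sep = "=", collapse = " ")))
    }
    if (length(state$patterns) == 2) {
      ov <- stage_overlap(state$patterns[[1]], state$patterns[[2]],
                          nonadditive_only = TRUE)
      report <- c(report, sprintf("classify: %d nonadditive features shared by both stages",
                                  length(ov)))
    }
  }

  if ("degradome" %in% config$stages) {
    dg <- config$degradome
    n_sites <- dg$n_planted_sites
    planted <- data.frame(
      mirna_id = sprintf("mir_%03d", rep_len(seq_len(dg$n_mirnas), n_sites)),
      transcript_id = sprintf("tx_%03d", rep_len(seq_len(dg$n_transcripts), n_sites)),
      cleavage_position = 60L + 7L * seq_len(n_sites),
      tag_count = dg$tag_count, stringsAsFactors = FALSE)
    cfg <- degradome_sim_config(n_transcripts = dg$n_transcripts,
                                n_mirnas = dg$n_mirnas, planted_sites = planted,
                                background_tag_rate = dg$background_tag_rate,
                                seed = as.integer(config$seed) + 23)
    sim <- gen_degradome(cfg)
    write_fasta(sim$mirnas, out("mirnas.fa"))
    write_fasta(sim$transcripts, out("transcripts.fa"))
    write_profiles(sim$profiles, out("degradome_profiles.tsv"))
    sites <- do.call(rbind, lapply(names(sim$mirnas), function(mid) {
      do.call(rbind, lapply(names(sim$transcripts), function(tid) {
        find_target_sites(sim$mirnas[[mid]], sim$transcripts[[tid]],
                          mirna_id = mid, transcript_id = tid)
      }))
    }))
    cat_sites <- suppressMessages(categorize_sites(sites, sim$profiles))
    state$sites <- cat_sites
    state$planted_sites <- sim$planted_sites
    write_results(cat_sites, out("sites_categorized.tsv"),
                  comment = c(hdr, "coordinates 1-based inclusive; cleavage = position paired with miRNA position 10"))
    tx1 <- sim$planted_sites$transcript_id[1]
    write_results(tplot_table(sim$profiles[[tx1]],
                              cat_sites[cat_sites$transcript_id == tx1, , drop = FALSE]),
                  out("tplot_example.tsv"), comment = c(hdr, paste0("transcript=", tx1)))
    hit <- merge(sim$planted_sites, cat_sites,
                 by.x = c("mirna_id", "transcript_id", "cleavage_position"),
                 by.y = c("mirna_id", "transcript_id", "predicted_cleavage"))
    report <- c(report,
                sprintf("degradome: %d candidate sites, categories %s", nrow(cat_sites),
                        paste(names(table(cat_sites$category)), table(cat_sites$category),
                              sep = ":", collapse = " ")),
                sprintf("degradome: %d/%d planted sites recovered as category 0",
                        sum(hit$category == 0), nrow(sim$planted_sites)))
  }

  if ("integrate" %in% config$stages) {
    pc <- gen_correlated_pairs(n_pairs = 10, r_true = -0.6, n_samples = 18,
                               seed = as.integer(config$seed) + 31)
    state$correlations <- pair_correlations(pc$mirna, pc$gene, pc$pairs)
    write_results(state$correlations, out("pair_correlations.tsv"), comment = hdr)
    assays <- cbind(data.frame(A663_6 = c(0.5, 1.0), A646_6 = c(0.5, 0.2)),
                    chlorophyll(c(0.5, 1.0), c(0.5, 0.2)))
    write_results(assays, out("chlorophyll_example.tsv"), comment = hdr)
    report <- c(report, sprintf("integrate: mean pair correlation %.2f over %d planted anticorrelated pairs",
                                mean(state$correlations$r), nrow(state$correlations)))
  }

  writeLines(report, out("report.txt"))
  invisible(list(report = report, truth = state$truth, patterns = state$patterns,
                 sites = state$sites, heterosis = state$heterosis,
                 correlations = state$correlations))
}

#' Per-class recovery of planted pattern classes
#'
#' @param calls `pattern_calls` from [classify_patterns()].
#' @param truth truth table from [gen_triad_counts()].
#' @return named numeric vector: fraction of planted features of each class
#'   recovered with the planted label.
#' @export
per_class_accuracy <- function(calls, truth) {
  merged <- merge(truth, as.data.frame(calls)[, c("feature_id", "label")],
                  by = "feature_id")
  vapply(split(merged, merged$planted_class),
         function(d) mean(d$label == d$planted_class), numeric(1))
}
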