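#' The eight P1-hybrid-P2 expression pattern labels
#'
#' `conserved` (no significant difference anywhere), `additive` (hybrid at the
#' mid-parent, parents differ), four expression-level-dominance (ELD) variants
#' in which the hybrid matches one parent while the parents differ (`high`/
#' `low` says whether the matched parent is the higher- or lower-expressing
#' one), and two transgressive classes in which the hybrid lies significantly
#' outside the parental range.
#' @export
pattern_labels <- c("conserved", "additive",
                    "ELD-P1-high", "ELD-P1-low", "ELD-P2-high", "ELD-P2-low",
                    "transgressive-up", "transgressive-down")

#' Configuration for simulating a P1/F1/P2 count triad
#'
#' Counts are drawn from a negative binomial with `Var = mu + dispersion*mu^2`
#' (Poisson when `dispersion = 0`), matching the distributional assumption of
#' the NB differential test downstream. Planted group means are analytic:
#' ELD classes place the F1 mean exactly on the matched parent, `additive`
#' places it at the mid-parent, and transgressive classes place it one half
#' `effect_log2fc` beyond the extreme parent, so recovery targets can be
#' computed in closed form.
#'
#' @param n_features number of features to simulate.
#' @param n_reps biological replicates per genotype (default 3, the study
#'   design: 3 genotypes x 2 stages x 3 replicates).
#' @param class_proportions named numeric vector over [pattern_labels]
#'   summing to 1; unnamed classes get proportion 0.
#' @param base_mean_log_range log10 range for the baseline expression mean.
#' @param effect_log2fc planted log2 separation between high and low parent
#'   (default 2).
#' @param dispersion NB dispersion alpha >= 0 (default 0.05).
#' @param library_size_factors per-sample positive multipliers, length
#'   `3 * n_reps` (P1, F1, P2 order) or scalar; default all 1.
#' @param seed integer seed; identical config + seed reproduces identical
#'   output.
#' @return A list of class `triad_sim_config`.
#' @export
triad_sim_config <- function(n_features = 1000, n_reps = 3,
                             class_proportions = c(conserved = 0.3, additive = 0.1,
                                                   `ELD-P1-high` = 0.1, `ELD-P1-low` = 0.1,
                                                   `ELD-P2-high` = 0.1, `ELD-P2-low` = 0.1,
                                                   `transgressive-up` = 0.1,
                                                   `transgressive-down` = 0.1),
                             base_mean_log_range = c(1, 3),
                             effect_log2fc = 2, dispersion = 0.05,
                             library_size_factors = 1, seed = 1) {
  if (n_features < 1) stop("n_features must be positive")
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (effect_log2fc <= 0) stop("effect_log2fc must be positive")
  bad <- setdiff(names(class_proportions), pattern_labels)
  if (length(bad)) stop("unknown pattern class in class_proportions: ",
                        paste(bad, collapse = ", "))
  neg <- names(class_proportions)[class_proportions < 0]
  if (length(neg)) stop("negative class proportion for: ", paste(neg, collapse = ", "))
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop(sprintf("class_proportions must sum to 1 (got %.12g)", sum(class_proportions)))
  }
  if (any(library_size_factors <= 0)) stop("library_size_factors must be positive")
  structure(list(n_features = n_features, n_reps = n_reps,
                 class_proportions = class_proportions,
                 base_mean_log_range = base_mean_log_range,
                 effect_log2fc = effect_log2fc, dispersion = dispersion,
                 library_size_factors = library_size_factors, seed = seed),
            class = "triad_sim_config")
}

# planted (mu_P1, mu_F1, mu_P2) for one feature given its class and baseline.
# h = 2^(effect/2); "high_is_p1" resolves the arbitrary parent orientation for
# classes where either parent could be the high one.
planted_means <- function(class, base, h, high_is_p1) {
  hi <- base * h
  lo <- base / h
  switch(class,
    "conserved"          = c(base, base, base),
    "additive"           = if (high_is_p1) c(hi, (hi + lo) / 2, lo) else c(lo, (hi + lo) / 2, hi),
    "ELD-P1-high"        = c(hi, hi, lo),
    "ELD-P1-low"         = c(lo, lo, hi),
    "ELD-P2-high"        = c(lo, hi, hi),
    "ELD-P2-low"         = c(hi, lo, lo),
    "transgressive-up"   = if (high_is_p1) c(hi, hi * h, lo) else c(lo, hi * h, hi),
    "transgressive-down" = if (high_is_p1) c(hi, lo / h, lo) else c(lo, lo / h, hi),
    stop("unknown class: ", class))
}

#' Simulate a count triad with planted expression patterns
#'
#' @param cfg a [triad_sim_config()].
#' @param stage stage label stamped into the sample metadata (default `"S"`).
#' @return A list with `counts` (a [triad_counts()] object) and `truth`
#'   (data.frame: `feature_id`, `planted_class`, `mu_P1`, `mu_F1`, `mu_P2`).
#' @export
gen_triad_counts <- function(cfg, stage = "S") {
  stopifnot(inherits(cfg, "triad_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_features
  props <- cfg$class_proportions[cfg$class_proportions > 0]
  # largest-remainder apportionment so class counts hit n exactly
  raw <- props * n
  n_class <- floor(raw)
  rem <- n - sum(n_class)
  if (rem > 0) {
    order_rem <- order(raw - floor(raw), decreasing = TRUE)
    n_class[order_rem[seq_len(rem)]] <- n_class[order_rem[seq_len(rem)]] + 1
  }
  classes <- rep(names(n_class), n_class)
  h <- 2^(cfg$effect_log2fc / 2)
  base <- 10^stats::runif(n, cfg$base_mean_log_range[1], cfg$base_mean_log_range[2])
  high_is_p1 <- stats::runif(n) < 0.5
  mu <- t(vapply(seq_len(n),
                 function(i) planted_means(classes[i], base[i], h, high_is_p1[i]),
                 numeric(3)))
  colnames(mu) <- c("P1", "F1", "P2")

  r <- cfg$n_reps
  sf <- rep_len(cfg$library_size_factors, 3L * r)
  genotype <- rep(c("P1", "F1", "P2"), each = r)
  sample_ids <- paste(genotype, stage, rep(seq_len(r), 3), sep = "_")
  counts <- matrix(0L, n, 3L * r,
                   dimnames = list(sprintf("feat_%04d", seq_len(n)), sample_ids))
  for (j in seq_len(3L * r)) {
    m <- sf[j] * mu[, genotype[j]]
    counts[, j] <- if (cfg$dispersion == 0) stats::rpois(n, m)
                   else stats::rnbinom(n, mu = m, size = 1 / cfg$dispersion)
  }
  meta <- data.frame(sample = sample_ids, genotype = genotype, stage = stage,
                     replicate = rep(seq_len(r), 3),
                     stringsAsFactors = FALSE)
  truth <- data.frame(feature_id = rownames(counts), planted_class = classes,
                      mu_P1 = mu[, "P1"], mu_F1 = mu[, "F1"], mu_P2 = mu[, "P2"],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(counts = triad_counts(counts, meta), truth = truth)
}

#' Simulate plant-level phenotypes with planted heterosis
#'
#' Parent and hybrid population means are solved from the planted mid-parent
#' (MPH) and better-parent (BPH) heterosis percentages: with `rho = (1 +
#' MPH/100)/(1 + BPH/100)`, the better parent is set at `base`, the lower
#' parent at `base * (2 - rho)/rho`, and the hybrid at `MP * (1 + MPH/100)`,
#' so the noiseless population recovers the planted indices exactly.
#' Individual plants are drawn Normal with coefficient of variation
#' `noise_cv`.
#'
#' @param traits character vector of trait names (the study measures GW, PH,
#'   SLW, LN, LL, LW).
#' @param n_plants plants per genotype.
#' @param planted_mph named percent MPH per trait (scalar recycled).
#' @param planted_bph named percent BPH per trait (scalar recycled); must not
#'   exceed `planted_mph`.
#' @param noise_cv coefficient of variation of plant-to-plant noise.
#' @param seed integer seed.
#' @param base_value better-parent trait mean (default 100, arbitrary units).
#' @return data.frame with columns `plant_id`, `genotype`, `trait`, `value`.
#' @export
gen_phenotypes <- function(traits, n_plants, planted_mph, planted_bph,
                           noise_cv = 0.1, seed = 1, base_value = 100) {
  mph <- rep_len(planted_mph, length(traits)); names(mph) <- traits
  bph <- rep_len(planted_bph, length(traits)); names(bph) <- traits
  if (any(bph > mph)) {
    stop("planted_bph exceeds planted_mph for trait(s): ",
         paste(traits[bph > mph], collapse = ", "))
  }
  if (n_plants < 2) stop("n_plants must be at least 2")
  set.seed(seed)
  out <- vector("list", length(traits))
  for (k in seq_along(traits)) {
    rho <- (1 + mph[k] / 100) / (1 + bph[k] / 100)  # BP/MP ratio
    if (rho >= 2) stop(sprintf("infeasible MPH/BPH pair for trait %s (lower parent mean would be <= 0)", traits[k]))
    bp <- base_value
    lp <- base_value * (2 - unname(rho)) / unname(rho)
    mp <- (bp + lp) / 2
    f1 <- mp * (1 + unname(mph[k]) / 100)
    mu <- c(P1 = bp, F1 = f1, P2 = lp)
    vals <- unlist(lapply(names(mu), function(g) {
      if (noise_cv == 0) rep(mu[[g]], n_plants)
      else stats::rnorm(n_plants, mu[[g]], noise_cv * mu[[g]])
    }))
    out[[k]] <- data.frame(
      plant_id = paste0(rep(names(mu), each = n_plants), "_", seq_len(n_plants)),
      genotype = rep(names(mu), each = n_plants),
      trait = traits[k], value = vals, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Configuration for simulating degradome inputs
#'
#' @param n_transcripts number of transcripts.
#' @param transcript_length_range integer range of transcript lengths (bp).
#' @param n_mirnas number of miRNAs.
#' @param mirna_length mature miRNA length (default 21 nt).
#' @param planted_sites data.frame with columns `mirna_id`, `transcript_id`,
#'   `cleavage_position` (1-based, the transcript position paired with miRNA
#'   position 10), `tag_count` (>= 1). At each planted site the transcript
#'   window is overwritten with the reverse complement of the miRNA (perfect
#'   pairing) and `tag_count` degradome tags are placed at the cleavage
#'   position.
#' @param background_tag_rate mean Poisson background tags per transcript
#'   position (default 0.1).
#' @param seed integer seed.
#' @return A list of class `degradome_sim_config`.
#' @export
degradome_sim_config <- function(n_transcripts = 20,
                                 transcript_length_range = c(300, 600),
                                 n_mirnas = 10, mirna_length = 21,
                                 planted_sites = NULL,
                                 background_tag_rate = 0.1, seed = 1) {
  if (mirna_length < 15) stop("mirna_length implausibly short")
  if (background_tag_rate < 0) stop("background_tag_rate must be >= 0")
  if (!is.null(planted_sites)) {
    req <- c("mirna_id", "transcript_id", "cleavage_position", "tag_count")
    miss <- setdiff(req, names(planted_sites))
    if (length(miss)) stop("planted_sites missing columns: ", paste(miss, collapse = ", "))
    if (any(planted_sites$tag_count < 1)) stop("planted tag_count must be >= 1")
  }
  structure(list(n_transcripts = n_transcripts,
                 transcript_length_range = transcript_length_range,
                 n_mirnas = n_mirnas, mirna_length = mirna_length,
                 planted_sites = planted_sites,
                 background_tag_rate = background_tag_rate, seed = seed),
            class = "degradome_sim_config")
}

random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulate miRNAs, transcripts and degradome tag profiles
#'
#' Background tags are Poisson per position; planted cleavage sites carry
#' their configured tag counts on top of the background, and the transcript
#' sequence around each planted site is the perfect reverse complement of its
#' miRNA so the site scores 0 under [score_alignment()].
#'
#' @param cfg a [degradome_sim_config()].
#' @return list with `mirnas` and `transcripts` (named uppercase sequence
#'   vectors), `profiles` (named list of per-position integer tag counts) and
#'   `planted_sites` (the input table, or an empty table).
#' @export
gen_degradome <- function(cfg) {
  stopifnot(inherits(cfg, "degradome_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$mirna_length
  mirnas <- vapply(seq_len(cfg$n_mirnas),
                   function(i) random_seq(L, c("A", "C", "G", "U")), character(1))
  names(mirnas) <- sprintf("mir_%03d", seq_len(cfg$n_mirnas))
  lens <- sample(seq(cfg$transcript_length_range[1], cfg$transcript_length_range[2]),
                 cfg$n_transcripts, replace = TRUE)
  transcripts <- vapply(lens, function(n) random_seq(n, c("A", "C", "G", "T")),
                        character(1))
  names(transcripts) <- sprintf("tx_%03d", seq_len(cfg$n_transcripts))

  sites <- cfg$planted_sites
  if (is.null(sites)) {
    sites <- data.frame(mirna_id = character(), transcript_id = character(),
                        cleavage_position = integer(), tag_count = integer(),
                        stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sites))) {
    mid <- sites$mirna_id[i]; tid <- sites$transcript_id[i]
    if (!mid %in% names(mirnas)) stop("planted site references unknown miRNA: ", mid)
    if (!tid %in% names(transcripts)) stop("planted site references unknown transcript: ", tid)
    cleave <- sites$cleavage_position[i]
    start <- cleave - (L - 10)          # window start so that position pairs miRNA pos 10
    end <- start + L - 1
    if (start < 1 || end > nchar(transcripts[[tid]])) {
      stop(sprintf("planted site outside transcript: %s @ %s position %d", mid, tid, cleave))
    }
    substr(transcripts[[tid]], start, end) <- reverse_complement(mirnas[[mid]], out = "DNA")
  }
  profiles <- lapply(names(transcripts), function(tid) {
    n <- nchar(transcripts[[tid]])
    prof <- if (cfg$background_tag_rate == 0) integer(n)
            else stats::rpois(n, cfg$background_tag_rate)
    here <- sites[sites$transcript_id == tid, , drop = FALSE]
    for (i in seq_len(nrow(here))) {
      p <- here$cleavage_position[i]
      prof[p] <- prof[p] + here$tag_count[i]
    }
    as.integer(prof)
  })
  names(profiles) <- names(transcripts)
  list(mirnas = mirnas, transcripts = transcripts, profiles = profiles,
       planted_sites = sites)
}
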