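#' Mid-parent heterosis percentage
#'
#' `MPH = 100 * (F1 - MP) / MP` with `MP = (P1 + P2) / 2`, the percent
#' deviation of the hybrid from the parental average.
#'
#' @param mean_f1,mean_p1,mean_p2 genotype trait means.
#' @return MPH in percent.
#' @export
compute_mph <- function(mean_f1, mean_p1, mean_p2) {
  mp <- (mean_p1 + mean_p2) / 2
  if (any(mp <= 0)) stop("mid-parent mean must be positive")
  100 * (mean_f1 - mp) / mp
}

#' Better-parent heterosis percentage
#'
#' `BPH = 100 * (F1 - BP) / BP` with `BP = max(P1, P2)`, the percent
#' deviation of the hybrid from the better-performing parent. For positive
#' means `BPH <= MPH` since `BP >= MP`.
#'
#' @inheritParams compute_mph
#' @return BPH in percent.
#' @export
compute_bph <- function(mean_f1, mean_p1, mean_p2) {
  bp <- pmax(mean_p1, mean_p2)
  if (any(bp <= 0)) stop("better-parent mean must be positive")
  100 * (mean_f1 - bp) / bp
}

#' Per-trait heterosis report
#'
#' For each trait (within each stage/location group when such columns are
#' present): genotype means, mid-parent and better-parent values, MPH and
#' BPH, and a two-sample t-test of the F1 plants against the better parent's
#' plants (Student's equal-variance test by default, Welch optional).
#' Zero-variance comparisons return `p = NA`.
#'
#' @param tbl phenotype data.frame with columns `genotype` (P1/F1/P2),
#'   `trait`, `value`, and optionally `stage` and/or `location`.
#' @param welch use Welch's unequal-variance t-test.
#' @return data.frame with one row per trait (x group): `trait`, grouping
#'   columns, `mean_P1`, `mean_P2`, `mean_F1`, `MP`, `BP`, `MPH`, `BPH`,
#'   `t_p_value_F1_vs_BP`.
#' @export
heterosis_report <- function(tbl, welch = FALSE) {
  group_cols <- intersect(c("stage", "location"), names(tbl))
  key <- do.call(paste, c(tbl[c("trait", group_cols)], sep = "\r"))
  rows <- lapply(split(tbl, key), function(d) {
    present <- unique(d$genotype)
    miss <- setdiff(c("P1", "F1", "P2"), present)
    if (length(miss)) {
      stop(sprintf("trait '%s': missing genotype(s) %s", d$trait[1],
                   paste(miss, collapse = ", ")))
    }
    mP1 <- mean(d$value[d$genotype == "P1"])
    mP2 <- mean(d$value[d$genotype == "P2"])
    mF1 <- mean(d$value[d$genotype == "F1"])
    bp_label <- if (mP1 >= mP2) "P1" else "P2"
    f1v <- d$value[d$genotype == "F1"]
    bpv <- d$value[d$genotype == bp_label]
    p <- if (stats::sd(f1v) == 0 && stats::sd(bpv) == 0) NA_real_ else
      tryCatch(stats::t.test(f1v, bpv, var.equal = !welch)$p.value,
               error = function(e) NA_real_)
    out <- data.frame(trait = d$trait[1], stringsAsFactors = FALSE)
    for (g in group_cols) out[[g]] <- d[[g]][1]
    cbind(out, data.frame(mean_P1 = mP1, mean_P2 = mP2, mean_F1 = mF1,
                          MP = (mP1 + mP2) / 2, BP = max(mP1, mP2),
                          MPH = compute_mph(mF1, mP1, mP2),
                          BPH = compute_bph(mF1, mP1, mP2),
                          t_p_value_F1_vs_BP = p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations between traits
#'
#' Traits are matched by plant: each plant contributes one value per trait.
#' Zero-variance traits produce `NA` entries with a warning.
#'
#' @param tbl phenotype data.frame with `plant_id`, `trait`, `value`.
#' @return symmetric correlation matrix (traits x traits), unit diagonal.
#' @export
trait_correlations <- function(tbl) {
  traits <- unique(tbl$trait)
  plants <- unique(tbl$plant_id)
  wide <- matrix(NA_real_, length(plants), length(traits),
                 dimnames = list(plants, traits))
  wide[cbind(match(tbl$plant_id, plants), match(tbl$trait, traits))] <- tbl$value
  complete <- stats::complete.cases(wide)
  if (sum(complete) < 3) stop("need >= 3 plants measured for every trait")
  wide <- wide[complete, , drop = FALSE]
  sds <- apply(wide, 2, stats::sd)
  if (any(sds == 0)) warning("zero-variance trait(s): ",
                             paste(traits[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(wide))
  diag(r) <- 1
  r
}
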