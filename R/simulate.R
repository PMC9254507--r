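#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a 20 + 20 donor paired-design label-free proteomics
#' study: ~5700 proteins with log-normal abundances, roughly a third of
#' them responding to T cell activation, a handful carrying a
#' disease-group effect per condition, a small contaminant subset and a
#' flagged susceptibility-gene subset. See the methods vignette for the
#' rationale behind each default.
#'
#' @param n_donors_per_group Donors per disease group; each donor
#'   contributes an unstimulated and a stimulated sample.
#' @param n_proteins Total protein rows, contaminants included.
#' @param frac_contaminant Fraction of rows flagged as contaminants.
#' @param frac_activation_de Fraction of non-contaminant proteins with a
#'   true stimulation effect.
#' @param frac_disease_de_unstim,frac_disease_de_stim Fractions with a
#'   true MS-vs-HC effect in the unstimulated / stimulated condition.
#' @param effect_size_log2 Mean absolute log2 shift of planted effects;
#'   signs are random.
#' @param effect_dist Distribution of planted-effect magnitudes:
#'   `"gamma"` (default; Gamma with shape 4 and mean `effect_size_log2`,
#'   giving a realistic spread of fold changes) or `"fixed"` (every
#'   planted effect has magnitude exactly `effect_size_log2`, used for
#'   calibration scenarios).
#' @param baseline_mean_log2,baseline_sd_log2 Across-protein distribution
#'   of baseline log2 abundance.
#' @param residual_sd_log2 Within-protein residual noise SD (log2).
#' @param donor_sd_log2 SD of the per-donor random effect (log2).
#' @param mnar_midpoint_log2,mnar_steepness Logistic left-censoring
#'   missingness: a cell of log2 abundance `x` is missing with
#'   probability `plogis((mnar_midpoint_log2 - x) / mnar_steepness)`.
#' @param frac_susceptibility_genes Fraction of non-contaminant proteins
#'   whose gene is flagged as a susceptibility gene.
#' @param seed Integer RNG seed; identical configs give identical cohorts.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_donors_per_group = 20,
                       n_proteins = 5704,
                       frac_contaminant = 0.027,
                       frac_activation_de = 0.32,
                       frac_disease_de_unstim = 0.003,
                       frac_disease_de_stim = 0.006,
                       effect_size_log2 = 1.5,
                       effect_dist = c("gamma", "fixed"),
                       baseline_mean_log2 = 25,
                       baseline_sd_log2 = 3,
                       residual_sd_log2 = 0.6,
                       donor_sd_log2 = 0.3,
                       mnar_midpoint_log2 = 20,
                       mnar_steepness = 1,
                       frac_susceptibility_genes = 0.017,
                       seed = 1L) {
  cfg <- list(n_donors_per_group = n_donors_per_group,
              n_proteins = n_proteins,
              frac_contaminant = frac_contaminant,
              frac_activation_de = frac_activation_de,
              frac_disease_de_unstim = frac_disease_de_unstim,
              frac_disease_de_stim = frac_disease_de_stim,
              effect_size_log2 = effect_size_log2,
              effect_dist = match.arg(effect_dist),
              baseline_mean_log2 = baseline_mean_log2,
              baseline_sd_log2 = baseline_sd_log2,
              residual_sd_log2 = residual_sd_log2,
              donor_sd_log2 = donor_sd_log2,
              mnar_midpoint_log2 = mnar_midpoint_log2,
              mnar_steepness = mnar_steepness,
              frac_susceptibility_genes = frac_susceptibility_genes,
              seed = as.integer(seed))
  props <- c("frac_contaminant", "frac_activation_de",
             "frac_disease_de_unstim", "frac_disease_de_stim",
             "frac_susceptibility_genes")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("`", p, "` must be a proportion in [0, 1]")
    }
  }
  for (p in c("n_donors_per_group", "n_proteins")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 ||
        v != round(v)) {
      stop("`", p, "` must be a positive integer")
    }
    cfg[[p]] <- as.integer(v)
  }
  for (p in c("effect_size_log2", "baseline_sd_log2", "residual_sd_log2",
              "donor_sd_log2", "mnar_steepness")) {
    if (cfg[[p]] < 0) stop("`", p, "` must be non-negative")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic paired-design proteomics cohort
#'
#' Simulates a complete (no missing cells) abundance matrix for
#' `2 * n_donors_per_group` donors, each measured unstimulated and
#' stimulated. On the log2 scale each cell is
#' baseline + donor effect + planted activation effect (stimulated
#' samples) + planted disease effect (MS samples, per condition) +
#' residual noise. The returned ground truth records the exact planted
#' effects, contaminant flags and susceptibility-gene flags.
#'
#' @param config A [sim_config()].
#' @param scale Return scale: `"linear"` (default, so the full pipeline
#'   including the log2 transform is exercised) or `"log2"`.
#'
#' @return A list with elements `matrix` (an [abundance_matrix()]),
#'   `meta` (sample metadata data frame) and `truth` (data frame with
#'   per-protein planted effects and flags).
#' @export
generate_cohort <- function(config = sim_config(),
                            scale = c("linear", "log2")) {
  stopifnot(inherits(config, "sim_config"))
  scale <- match.arg(scale)
  n_p <- config$n_proteins
  n_d <- config$n_donors_per_group

  with_rng(config$seed, {
    donors <- c(sprintf("MS%02d", seq_len(n_d)), sprintf("HC%02d", seq_len(n_d)))
    groups <- rep(c("MS", "HC"), each = n_d)
    meta <- data.frame(
      sample_id = paste0(rep(donors, each = 2), "_",
                         rep(c("unstim", "stim"), times = 2 * n_d)),
      donor_id = rep(donors, each = 2),
      group = rep(groups, each = 2),
      condition = rep(c("unstimulated", "stimulated"), times = 2 * n_d),
      stringsAsFactors = FALSE
    )

    accession <- sprintf("SP%05d", seq_len(n_p))
    gene_symbol <- sprintf("GENE%05d", seq_len(n_p))
    n_cont <- round(config$frac_contaminant * n_p)
    is_cont <- seq_len(n_p) %in% sample.int(n_p, n_cont)

    # planted subsets are drawn from non-contaminant rows only
    clean <- which(!is_cont)
    pick <- function(frac) {
      k <- round(frac * length(clean))
      if (k == 0) integer() else sample(clean, k)
    }
    draw_eff <- function(rows) {
      eff <- numeric(n_p)
      if (length(rows) && config$effect_size_log2 > 0) {
        mag <- switch(config$effect_dist,
                      gamma = rgamma(length(rows), shape = 4,
                                     rate = 4 / config$effect_size_log2),
                      fixed = rep(config$effect_size_log2, length(rows)))
        eff[rows] <- mag * sample(c(-1, 1), length(rows), replace = TRUE)
      }
      eff
    }
    act_rows <- pick(config$frac_activation_de)
    act_ms <- draw_eff(act_rows)
    # activation responses correlate between groups but may differ; here the
    # same planted shift is used for both groups (disease effects are separate)
    act_hc <- act_ms
    dis_unstim <- draw_eff(pick(config$frac_disease_de_unstim))
    dis_stim <- draw_eff(pick(config$frac_disease_de_stim))

    baseline <- rnorm(n_p, config$baseline_mean_log2, config$baseline_sd_log2)
    donor_eff <- setNames(rnorm(2 * n_d, 0, config$donor_sd_log2), donors)

    n_s <- nrow(meta)
    x <- matrix(baseline, n_p, n_s)
    is_stim <- meta$condition == "stimulated"
    is_ms <- meta$group == "MS"
    for (j in seq_len(n_s)) {
      mu <- donor_eff[meta$donor_id[j]]
      col <- x[, j] + mu
      if (is_stim[j]) col <- col + (if (is_ms[j]) act_ms else act_hc)
      if (is_ms[j]) col <- col + (if (is_stim[j]) dis_stim else dis_unstim)
      x[, j] <- col
    }
    x <- x + matrix(rnorm(n_p * n_s, 0, config$residual_sd_log2), n_p, n_s)
    colnames(x) <- meta$sample_id

    n_sus <- round(config$frac_susceptibility_genes * length(clean))
    is_sus <- seq_len(n_p) %in% (if (n_sus) sample(clean, n_sus) else integer())

    truth <- data.frame(
      accession = accession,
      gene_symbol = gene_symbol,
      is_contaminant = is_cont,
      is_susceptibility_gene = is_sus,
      activation_effect_ms_log2 = act_ms,
      activation_effect_hc_log2 = act_hc,
      disease_effect_unstim_log2 = dis_unstim,
      disease_effect_stim_log2 = dis_stim,
      stringsAsFactors = FALSE
    )

    proteins <- truth[, c("accession", "gene_symbol", "is_contaminant")]
    if (scale == "linear") x <- 2^x
    mat <- abundance_matrix(x, proteins, scale = scale,
                            log = sprintf("simulated cohort: %d proteins, %d donors/group, seed %d",
                                          n_p, n_d, config$seed))
    list(matrix = mat, meta = validate_sample_meta(meta), truth = truth)
  })
}

#' Inject intensity-dependent (left-censored) missingness
#'
#' Each cell is independently set missing with probability
#' `plogis((mnar_midpoint_log2 - x) / mnar_steepness)` where `x` is the
#' cell's log2 abundance, so low-abundance measurements are lost
#' preferentially — the missing-not-at-random pattern that motivates
#' downshifted-normal imputation. Observed cells are unchanged.
#'
#' @param mat An [abundance_matrix()] (linear or log2 scale).
#' @param config A [sim_config()] supplying the logistic parameters.
#' @param seed Seed for the missingness draws; defaults to one derived
#'   from `config$seed`.
#' @return The matrix with missing cells set to `NA`.
#' @export
inject_missingness <- function(mat, config,
                               seed = derive_seed(config$seed, "missingness")) {
  stopifnot(inherits(mat, "abundance_matrix"), inherits(config, "sim_config"))
  x <- mat$values
  xl <- if (mat$scale == "linear") log2(x) else x
  p_miss <- stats::plogis((config$mnar_midpoint_log2 - xl) / config$mnar_steepness)
  with_rng(seed, {
    drop <- matrix(runif(length(x)) < p_miss, nrow(x), ncol(x))
    x[drop] <- NA_real_
  })
  mat$values <- x
  append_log(mat, sprintf("injected MNAR missingness: %d of %d cells (%.1f%%)",
                          sum(is.na(x)), length(x), 100 * mean(is.na(x))))
}

#' Write a simulated cohort to disk
#'
#' Writes the wide abundance TSV, the sample metadata TSV, the ground
#' truth TSV and a susceptibility gene-set file (one symbol per line)
#' into a directory, in the formats the pipeline readers consume.
#'
#' @param cohort Result of [generate_cohort()] (optionally after
#'   [inject_missingness()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             meta = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "ground_truth.tsv"),
             gene_set = file.path(dir, "susceptibility_genes.txt"))
  write_abundance_table(cohort$matrix, paths[["abundance"]])
  write.table(cohort$meta, paths[["meta"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c("# simulated susceptibility gene set",
               cohort$truth$gene_symbol[cohort$truth$is_susceptibility_gene]),
             paths[["gene_set"]])
  invisible(paths)
}
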