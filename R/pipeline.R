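#' Pipeline configuration
#'
#' Bundles every threshold and seed of the full analysis. Thresholds are
#' checked to lie in (0, 1]; every randomized stage derives its own seed
#' from `seed` and the stage name, so one master seed reproduces a run.
#'
#' @param alpha_activation Adjusted-p threshold for the paired activation
#'   analyses; default 0.01.
#' @param alpha_group Adjusted-p threshold for the MS-vs-HC analyses;
#'   default 0.05.
#' @param valid_fraction Stratum-wise valid-value fraction; default 0.7.
#' @param impute_width,impute_downshift Downshifted-normal imputation
#'   parameters; defaults 0.3 and 1.8.
#' @param n_iterations,n_per_group,alpha_de,alpha_pc1 Resampling
#'   validation parameters; defaults 100, 10, 0.05, 0.05.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_activation = 0.01, alpha_group = 0.05,
                            valid_fraction = 0.7, impute_width = 0.3,
                            impute_downshift = 1.8, n_iterations = 100,
                            n_per_group = 10, alpha_de = 0.05,
                            alpha_pc1 = 0.05, seed = 1L) {
  cfg <- list(alpha_activation = alpha_activation, alpha_group = alpha_group,
              valid_fraction = valid_fraction, impute_width = impute_width,
              impute_downshift = impute_downshift,
              n_iterations = n_iterations, n_per_group = n_per_group,
              alpha_de = alpha_de, alpha_pc1 = alpha_pc1,
              seed = as.integer(seed))
  for (p in c("alpha_activation", "alpha_group", "valid_fraction",
              "alpha_de", "alpha_pc1")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1) {
      stop("`", p, "` must lie in (0, 1]")
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: preprocessing (contaminant removal, log2,
#' valid-value filter, seeded imputation); paired activation DE on all
#' donors, HC-only and MS-only; Welch MS-vs-HC DE per condition; PCA of
#' each condition's significant proteins; split-cohort resampling
#' validation per condition; the Venn partition of the HC-only and
#' MS-only activation sets; susceptibility gene-set enrichment of the
#' all-donor activation set; and, when a clinical table is given, the
#' cohort summary. When `out_dir` is given, every result table is
#' written as TSV alongside a JSON summary and the resolved
#' configuration.
#'
#' @param mat A raw [abundance_matrix()] (linear or log2 scale).
#' @param meta Sample metadata.
#' @param gene_set Optional character vector of susceptibility gene
#'   symbols (see [read_gene_set()]).
#' @param clinical Optional clinical table (see [read_clinical_table()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `pipeline_result` with elements `preprocessed`,
#'   `activation` (list all/hc/ms of `de_result`), `group_de` (list
#'   unstimulated/stimulated), `pca` (list per condition, `NULL` when no
#'   protein is significant), `validation` (list per condition), `venn`,
#'   `enrichment` (contingency + test, or `NULL`), `cohort_summary` and
#'   `counts`.
#' @export
run_full_pipeline <- function(mat, meta, gene_set = NULL, clinical = NULL,
                              config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  meta <- validate_sample_meta(meta)
  stage <- "preprocess"
  res <- try({
    pre <- preprocess(mat, meta, min_frac = config$valid_fraction,
                      width = config$impute_width,
                      downshift = config$impute_downshift,
                      seed = derive_seed(config$seed, "impute"))

    stage <- "activation DE"
    donors_of <- function(g) unique(meta$donor_id[meta$group == g])
    activation <- list(
      all = paired_t_test(pre, meta, alpha = config$alpha_activation),
      hc = paired_t_test(pre, meta, donors = donors_of("HC"),
                         alpha = config$alpha_activation),
      ms = paired_t_test(pre, meta, donors = donors_of("MS"),
                         alpha = config$alpha_activation)
    )

    stage <- "group DE"
    group_de <- list(
      unstimulated = welch_test(pre, meta, "unstimulated",
                                alpha = config$alpha_group),
      stimulated = welch_test(pre, meta, "stimulated",
                              alpha = config$alpha_group)
    )

    stage <- "PCA"
    pca <- lapply(names(group_de), function(cond) {
      sig <- significant_set(group_de[[cond]], config$alpha_group)
      if (!length(sig)) return(NULL)
      ids <- meta$sample_id[meta$condition == cond]
      run_pca(pre, proteins = sig, samples = ids)
    })
    names(pca) <- names(group_de)

    stage <- "resampling validation"
    validation <- lapply(names(group_de), function(cond) {
      run_validation(pre, meta, cond, n_iterations = config$n_iterations,
                     n_per_group = config$n_per_group,
                     alpha_de = config$alpha_de,
                     alpha_pc1 = config$alpha_pc1,
                     seed = derive_seed(config$seed, paste0("validate-", cond)))
    })
    names(validation) <- names(group_de)

    stage <- "venn partition"
    venn <- venn_partition(
      significant_set(activation$hc, config$alpha_activation),
      significant_set(activation$ms, config$alpha_activation),
      activation$hc, activation$ms)

    stage <- "enrichment"
    enrichment <- NULL
    if (!is.null(gene_set)) {
      tab <- build_contingency(pre$proteins,
                               significant_set(activation$all,
                                               config$alpha_activation),
                               gene_set)
      enrichment <- list(table = tab, test = chi_squared_test(tab))
    }

    stage <- "cohort summary"
    cohort_summary <- if (is.null(clinical)) NULL else summarize_cohort(clinical)

    list(preprocessed = pre, activation = activation, group_de = group_de,
         pca = pca, validation = validation, venn = venn,
         enrichment = enrichment, cohort_summary = cohort_summary,
         counts = list(
           n_proteins_input = nrow(mat$values),
           n_proteins_analyzed = nrow(pre$values),
           n_activation_de = sum(activation$all$significant),
           n_group_de = vapply(group_de, function(r) sum(r$significant),
                               integer(1))
         ),
         config = config)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message)
  }
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat("  proteins analyzed: ", x$counts$n_proteins_analyzed, " of ",
      x$counts$n_proteins_input, "\n", sep = "")
  cat("  activation DE (adj p <= ", x$config$alpha_activation, "): ",
      x$counts$n_activation_de, "\n", sep = "")
  cat("  MS vs HC DE (adj p <= ", x$config$alpha_group, "): unstimulated ",
      x$counts$n_group_de[["unstimulated"]], ", stimulated ",
      x$counts$n_group_de[["stimulated"]], "\n", sep = "")
  for (cond in names(x$validation)) {
    cat("  validation (", cond, "): PC1 separation in ",
        round(100 * x$validation[[cond]]$summary$proportion_significant),
        "% of iterations\n", sep = "")
  }
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(out_dir, ...)
  write_abundance_table(res$preprocessed, f("preprocessed_abundance.tsv"))
  for (nm in names(res$activation)) {
    write_de_result(res$activation[[nm]], f(paste0("de_activation_", nm, ".tsv")))
  }
  for (nm in names(res$group_de)) {
    write_de_result(res$group_de[[nm]], f(paste0("de_ms_vs_hc_", nm, ".tsv")))
    pca <- res$pca[[nm]]
    if (!is.null(pca)) {
      write.table(data.frame(sample_id = rownames(pca$scores), pca$scores,
                             check.names = FALSE),
                  f(paste0("pca_scores_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(accession = rownames(pca$loadings),
                             pca$loadings,
                             influential_pc1 = pca$influential_flags[, 1],
                             influential_pc2 = if (ncol(pca$loadings) > 1)
                               pca$influential_flags[, 2] else NA,
                             check.names = FALSE),
                  f(paste0("pca_loadings_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(res$validation[[nm]]$iterations,
                f(paste0("validation_iterations_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    counts = res$counts,
    venn = as.list(res$venn$counts),
    validation = lapply(res$validation, function(v) v$summary),
    enrichment = if (!is.null(res$enrichment)) res$enrichment$test,
    cohort_summary = res$cohort_summary,
    config = unclass(res$config)
  )
  jsonlite::write_json(summary, f("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}
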