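#' Randomly split a cohort into discovery and replication halves
#'
#' Samples `n_per_group` donors per group uniformly without replacement
#' for the discovery half; the replication half is the complement.
#' Splitting is by donor (not sample), which prevents leakage should both
#' conditions ever be analyzed together.
#'
#' @param meta Sample metadata.
#' @param n_per_group Donors per group in the discovery half; default 10.
#' @param seed Integer seed.
#' @return List with character vectors `discovery` and `replication`
#'   (donor ids).
#' @export
split_cohort <- function(meta, n_per_group = 10, seed = 1L) {
  meta <- validate_sample_meta(meta, require_full_strata = FALSE)
  donors <- unique(meta[, c("donor_id", "group")])
  disc <- with_rng(seed, {
    unlist(lapply(c("MS", "HC"), function(g) {
      pool <- donors$donor_id[donors$group == g]
      if (length(pool) < 2 * n_per_group) {
        stop("group ", g, " has ", length(pool), " donors; need >= ",
             2 * n_per_group)
      }
      sample(pool, n_per_group)
    }))
  })
  list(discovery = disc, replication = setdiff(donors$donor_id, disc))
}

#' Welch test of PC1 scores between two groups
#'
#' Two-sided Welch t-test on first-principal-component scores between
#' the groups, the replication-half test of the split-cohort validation.
#' Zero variance in both groups with equal means returns p = 1 (the
#' pipeline's degenerate-tie rule).
#'
#' @param scores Numeric vector of PC1 scores.
#' @param labels Group label per score (two levels).
#' @return Two-sided p-value.
#' @export
pc1_group_test <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("need exactly 2 groups")
  a <- scores[labels == lev[1]]
  b <- scores[labels == lev[2]]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 samples")
  tt <- row_welch_t(matrix(a, 1), matrix(b, 1))
  tt$p
}

#' Split-cohort resampling validation
#'
#' Repeats `n_iterations` times: (1) split donors into discovery and
#' replication halves; (2) Welch MS-vs-HC differential expression on the
#' discovery samples of the given condition, Benjamini-Hochberg within
#' the iteration, significant at `adj_p <= alpha_de`; (3) if no protein
#' is significant, record a zero-protein iteration (counted as
#' non-significant); (4) otherwise refit PCA on the replication samples
#' restricted to the significant proteins and (5) Welch-test PC1 scores
#' between MS and HC replication samples. The summary
#' `proportion_significant` is the fraction of all iterations with
#' replication PC1 p `<= alpha_pc1`. Per-protein recurrence counts how
#' often each protein was discovery-significant.
#'
#' @param mat An imputed [abundance_matrix()] on log2 scale.
#' @param meta Sample metadata.
#' @param condition `"unstimulated"` or `"stimulated"`.
#' @param n_iterations Number of resampling iterations; default 100.
#' @param n_per_group Discovery donors per group; default 10.
#' @param alpha_de Discovery significance threshold (adjusted p); 0.05.
#' @param alpha_pc1 Replication PC1 significance threshold; 0.05.
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @return An object of class `resampling_result`: `iterations` (data
#'   frame: iteration, seed, n_significant, pc1_p), `recurrence` (named
#'   sorted counts) and `summary` (proportion_significant,
#'   median_n_significant, range_n_significant,
#'   n_zero_protein_iterations).
#' @export
run_validation <- function(mat, meta, condition, n_iterations = 100,
                           n_per_group = 10, alpha_de = 0.05,
                           alpha_pc1 = 0.05, seed = 1L) {
  stopifnot(inherits(mat, "abundance_matrix"), n_iterations >= 1)
  meta <- validate_sample_meta(meta, require_full_strata = FALSE)
  condition <- match.arg(condition, c("unstimulated", "stimulated"))
  cmeta <- meta[meta$condition == condition, , drop = FALSE]

  recurrence <- setNames(integer(nrow(mat$values)), mat$proteins$accession)
  iter <- data.frame(iteration = seq_len(n_iterations),
                     seed = NA_integer_, n_significant = NA_integer_,
                     pc1_p = NA_real_)
  for (i in seq_len(n_iterations)) {
    s <- derive_seed(seed, paste0("split", i))
    iter$seed[i] <- s
    halves <- split_cohort(cmeta, n_per_group = n_per_group, seed = s)
    disc_ids <- cmeta$sample_id[cmeta$donor_id %in% halves$discovery]
    repl <- cmeta[cmeta$donor_id %in% halves$replication, , drop = FALSE]
    stopifnot(length(intersect(disc_ids, repl$sample_id)) == 0)

    de <- welch_test(mat, cmeta, condition, samples = disc_ids,
                     alpha = alpha_de)
    sig <- significant_set(de, alpha_de)
    iter$n_significant[i] <- length(sig)
    recurrence[sig] <- recurrence[sig] + 1L
    if (length(sig) == 0) next # zero-protein iteration: no PC1 test
    pca <- run_pca(mat, proteins = sig, samples = repl$sample_id)
    iter$pc1_p[i] <- pc1_group_test(pca$scores[, 1],
                                    repl$group[match(rownames(pca$scores),
                                                     repl$sample_id)])
  }
  hit <- !is.na(iter$pc1_p) & iter$pc1_p <= alpha_pc1
  out <- list(
    iterations = iter,
    recurrence = sort(recurrence, decreasing = TRUE),
    summary = list(
      condition = condition,
      n_iterations = n_iterations,
      proportion_significant = mean(hit),
      median_n_significant = median(iter$n_significant),
      range_n_significant = range(iter$n_significant),
      n_zero_protein_iterations = sum(iter$n_significant == 0)
    )
  )
  class(out) <- "resampling_result"
  out
}

#' Per-protein recurrence across resampling iterations
#'
#' @param result A `resampling_result`.
#' @return Named integer vector, sorted decreasing: for each protein, the
#'   number of iterations in which it was discovery-significant.
#' @export
recurrence_table <- function(result) {
  stopifnot(inherits(result, "resampling_result"))
  result$recurrence
}

#' @export
print.resampling_result <- function(x, ...) {
  s <- x$summary
  cat("resampling validation (", s$condition, "): ", s$n_iterations,
      " iterations\n", sep = "")
  cat("PC1 group separation significant in ",
      round(100 * s$proportion_significant), "% of iterations\n", sep = "")
  cat("discovery-significant proteins per iteration: median ",
      s$median_n_significant, " (range ", s$range_n_significant[1], "-",
      s$range_n_significant[2], "); ", s$n_zero_protein_iterations,
      " zero-protein iteration(s)\n", sep = "")
  invisible(x)
}
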