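# Vectorized row-wise t machinery -------------------------------------------
#
# Testing thousands of proteins inside a 100-iteration resampling loop makes
# per-row stats::t.test() calls the bottleneck, so the t statistics are
# computed from row means/variances directly (cross-checked against
# stats::t.test in the test suite). Degenerate zero-variance rows follow the
# pipeline rule: all values identical across both groups -> p = 1, fc = 0;
# zero variance but distinct means -> perfect separation, p = 0.

row_means_vars <- function(x) {
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (ncol(x) - 1)
  list(m = m, v = v)
}

# one-sample t on each row of a matrix of differences
row_one_sample_t <- function(d) {
  n <- ncol(d)
  mv <- row_means_vars(d)
  se <- sqrt(mv$v / n)
  t <- mv$m / se
  df <- rep(n - 1, nrow(d))
  p <- 2 * pt(-abs(t), df)
  zero <- mv$v == 0
  t[zero] <- ifelse(mv$m[zero] == 0, 0, sign(mv$m[zero]) * Inf)
  p[zero] <- ifelse(mv$m[zero] == 0, 1, 0)
  list(estimate = mv$m, t = t, df = df, p = p)
}

# Welch t on rows, columns split into two groups
row_welch_t <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  a <- row_means_vars(xa); b <- row_means_vars(xb)
  se2 <- a$v / na + b$v / nb
  t <- (a$m - b$m) / sqrt(se2)
  df <- se2^2 / ((a$v / na)^2 / (na - 1) + (b$v / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  zero <- se2 == 0
  eq <- zero & a$m == b$m
  t[eq] <- 0; p[eq] <- 1; df[zero] <- na + nb - 2
  t[zero & !eq] <- sign(a$m - b$m)[zero & !eq] * Inf
  p[zero & !eq] <- 0
  list(estimate = a$m - b$m, t = t, df = df, p = p,
       mean_a = a$m, mean_b = b$m, sd_a = sqrt(a$v), sd_b = sqrt(b$v))
}

row_medians <- function(x) apply(x, 1, median)

de_result <- function(proteins, comparison, groups, mean_a, mean_b,
                      median_a, median_b, sd_a, sd_b, log2_fc, t, df, p,
                      alpha) {
  adj_p <- bh_adjust(p)
  res <- data.frame(
    accession = proteins$accession,
    gene_symbol = proteins$gene_symbol,
    mean_a = mean_a, mean_b = mean_b,
    median_a = median_a, median_b = median_b,
    sd_a = sd_a, sd_b = sd_b,
    log2_fc = log2_fc, t = t, df = df,
    p_value = p, adj_p = adj_p,
    significant = adj_p <= alpha,
    stringsAsFactors = FALSE
  )
  attr(res, "comparison") <- comparison
  attr(res, "groups") <- groups
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}

#' Paired t-test for the stimulation contrast
#'
#' For each protein, a two-sided paired Student's t-test on the per-donor
#' (stimulated - unstimulated) log2 differences; equivalently a
#' one-sample t-test on the difference vector. `log2_fc` is the mean
#' paired difference (stimulated minus unstimulated). Benjamini-Hochberg
#' adjustment is applied across proteins within this analysis only.
#'
#' @param mat An imputed [abundance_matrix()] on log2 scale.
#' @param meta Sample metadata.
#' @param donors Donor ids to include (e.g. all donors, or only MS / only
#'   HC donors for the stratified activation analyses). Default: all
#'   donors with both conditions present.
#' @param alpha Significance threshold on the adjusted p (inclusive);
#'   default 0.01.
#' @return A `de_result` data frame; group `a` is stimulated, group `b`
#'   unstimulated.
#' @export
paired_t_test <- function(mat, meta, donors = unique(meta$donor_id),
                          alpha = 0.01) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (mat$scale != "log2") stop("tests expect log2 scale")
  if (anyNA(mat$values)) stop("matrix must be imputed (no missing cells)")
  meta <- validate_sample_meta(meta)
  if (length(donors) < 2) stop("need at least 2 donors for a paired test")
  sid <- function(cond) {
    idx <- match(paste(donors, cond), paste(meta$donor_id, meta$condition))
    if (anyNA(idx)) {
      stop("donor(s) missing a ", cond, " sample: ",
           paste(donors[is.na(idx)], collapse = ", "))
    }
    meta$sample_id[idx]
  }
  stim <- mat$values[, sid("stimulated"), drop = FALSE]
  unstim <- mat$values[, sid("unstimulated"), drop = FALSE]
  d <- stim - unstim
  tt <- row_one_sample_t(d)
  mv_s <- row_means_vars(stim); mv_u <- row_means_vars(unstim)
  de_result(mat$proteins, comparison = "stimulated vs unstimulated (paired)",
            groups = c(a = "stimulated", b = "unstimulated"),
            mean_a = mv_s$m, mean_b = mv_u$m,
            median_a = row_medians(stim), median_b = row_medians(unstim),
            sd_a = sqrt(mv_s$v), sd_b = sqrt(mv_u$v),
            log2_fc = tt$estimate, t = tt$t, df = tt$df, p = tt$p,
            alpha = alpha)
}

#' Welch t-test for a group contrast within one condition
#'
#' For each protein, a two-sided Welch (unequal-variance) t-test between
#' the two groups' samples of the given condition, with
#' Welch-Satterthwaite degrees of freedom. `log2_fc` is
#' mean(`group_a`) - mean(`group_b`). Benjamini-Hochberg adjustment is
#' applied within this analysis only.
#'
#' @inheritParams paired_t_test
#' @param condition `"unstimulated"` or `"stimulated"`.
#' @param group_a,group_b Group labels; defaults `"MS"` vs `"HC"`.
#' @param samples Optional restriction to a subset of sample ids (used by
#'   the resampling validation); default all samples of the condition.
#' @param alpha Significance threshold on the adjusted p (inclusive);
#'   default 0.05.
#' @return A `de_result` data frame.
#' @export
welch_test <- function(mat, meta, condition, group_a = "MS", group_b = "HC",
                       samples = NULL, alpha = 0.05) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (mat$scale != "log2") stop("tests expect log2 scale")
  if (anyNA(mat$values)) stop("matrix must be imputed (no missing cells)")
  meta <- validate_sample_meta(meta, require_full_strata = FALSE)
  condition <- match.arg(condition, c("unstimulated", "stimulated"))
  sel <- meta[meta$condition == condition, , drop = FALSE]
  if (!is.null(samples)) sel <- sel[sel$sample_id %in% samples, , drop = FALSE]
  ids_a <- sel$sample_id[sel$group == group_a]
  ids_b <- sel$sample_id[sel$group == group_b]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("each group needs >= 2 samples in condition '", condition, "'")
  }
  xa <- mat$values[, ids_a, drop = FALSE]
  xb <- mat$values[, ids_b, drop = FALSE]
  tt <- row_welch_t(xa, xb)
  de_result(mat$proteins,
            comparison = sprintf("%s vs %s (%s)", group_a, group_b, condition),
            groups = c(a = group_a, b = group_b),
            mean_a = tt$mean_a, mean_b = tt$mean_b,
            median_a = row_medians(xa), median_b = row_medians(xb),
            sd_a = tt$sd_a, sd_b = tt$sd_b,
            log2_fc = tt$estimate, t = tt$t, df = tt$df, p = tt$p,
            alpha = alpha)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, applied within one analysis
#' stratum only (never across strata).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Significant accession set of a DE result
#'
#' @param result A `de_result`.
#' @param alpha Threshold on the adjusted p-value, inclusive (`<=`).
#' @return Character vector of accessions.
#' @export
significant_set <- function(result, alpha = attr(result, "alpha")) {
  stopifnot(inherits(result, "de_result"))
  result$accession[result$adj_p <= alpha]
}

#' Venn partition of two significant sets
#'
#' Splits two DE significant sets over a shared protein universe into
#' shared and exclusive accessions, and flags, per shared protein,
#' whether the fold-change direction agrees between the two analyses.
#'
#' @param set_a,set_b Character accession sets.
#' @param results_a,results_b Optional `de_result`s from which direction
#'   concordance of the shared proteins is computed.
#' @return A list of class `venn_partition` with elements `shared`,
#'   `exclusive_first`, `exclusive_second`, `concordant` (named logical
#'   over `shared`, or `NULL` when results are not supplied) and `counts`.
#' @export
venn_partition <- function(set_a, set_b, results_a = NULL, results_b = NULL) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  shared <- intersect(set_a, set_b)
  out <- list(shared = shared,
              exclusive_first = setdiff(set_a, set_b),
              exclusive_second = setdiff(set_b, set_a),
              concordant = NULL)
  if (!is.null(results_a) && !is.null(results_b) && length(shared)) {
    fa <- results_a$log2_fc[match(shared, results_a$accession)]
    fb <- results_b$log2_fc[match(shared, results_b$accession)]
    out$concordant <- setNames(sign(fa) == sign(fb), shared)
  }
  out$counts <- c(shared = length(out$shared),
                  exclusive_first = length(out$exclusive_first),
                  exclusive_second = length(out$exclusive_second))
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn partition: shared ", x$counts[["shared"]],
      ", exclusive ", x$counts[["exclusive_first"]], " / ",
      x$counts[["exclusive_second"]], "\n", sep = "")
  if (!is.null(x$concordant)) {
    cat("direction-concordant shared proteins: ", sum(x$concordant), " of ",
        length(x$concordant), "\n", sep = "")
  }
  invisible(x)
}

#' Write a DE result table
#'
#' Tab-separated output with the familiar result-table layout: accession,
#' gene symbol, p, adjusted p, log2 fold change, per-group medians and
#' SDs.
#'
#' @param result A `de_result`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_de_result <- function(result, path) {
  stopifnot(inherits(result, "de_result"))
  g <- attr(result, "groups")
  out <- data.frame(
    accession = result$accession,
    gene_symbol = result$gene_symbol,
    p_value = result$p_value,
    adj_p = result$adj_p,
    log2_fc = result$log2_fc,
    stringsAsFactors = FALSE
  )
  out[[paste0("median_log2_", g[["a"]])]] <- result$median_a
  out[[paste0("sd_", g[["a"]])]] <- result$sd_a
  out[[paste0("median_log2_", g[["b"]])]] <- result$median_b
  out[[paste0("sd_", g[["b"]])]] <- result$sd_b
  out$significant <- result$significant
  write.table(out[order(out$p_value), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
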