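#' Remove contaminant-flagged proteins
#'
#' Drops every row whose `is_contaminant` flag is set and logs the count,
#' the first step of the fixed preprocessing order
#' (contaminants -> log2 -> valid-value filter -> imputation).
#'
#' @param mat An [abundance_matrix()].
#' @return The matrix restricted to non-contaminant rows.
#' @export
remove_contaminants <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  keep <- !mat$proteins$is_contaminant
  out <- mat
  out$values <- mat$values[keep, , drop = FALSE]
  out$proteins <- mat$proteins[keep, , drop = FALSE]
  rownames(out$proteins) <- NULL
  append_log(out, sprintf("removed %d contaminant proteins (%d retained)",
                          sum(!keep), sum(keep)))
}

#' Log2-transform observed abundances
#'
#' Replaces every observed cell by its log2; missing cells stay missing.
#' Errors (naming the offending cell) on non-positive observed values,
#' which cannot arise from valid normalized abundances.
#'
#' @param mat An [abundance_matrix()] on linear scale.
#' @return The matrix on log2 scale.
#' @export
log2_transform <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (mat$scale != "linear") stop("matrix is already on log2 scale")
  bad <- which(!is.na(mat$values) & mat$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive abundance at protein '",
         mat$proteins$accession[bad[1, 1]], "', sample '",
         colnames(mat$values)[bad[1, 2]], "'")
  }
  mat$values <- log2(mat$values)
  mat$scale <- "log2"
  append_log(mat, "log2 transformed")
}

#' Optional per-sample median centering
#'
#' Subtracts each sample column's observed median (log2 scale), equalizing
#' sample medians. Off by default in the pipeline: input abundances are
#' assumed already normalized upstream.
#'
#' @param mat An [abundance_matrix()] on log2 scale.
#' @return The centered matrix.
#' @export
median_center <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (mat$scale != "log2") stop("median centering expects log2 scale")
  med <- apply(mat$values, 2, median, na.rm = TRUE)
  mat$values <- sweep(mat$values, 2, med)
  append_log(mat, "median-centered per sample")
}

#' Filter proteins by stratum-wise valid values
#'
#' Retains a protein iff, in at least one of the four group x condition
#' strata, the fraction of samples with an observed value is at least
#' `min_frac` (inclusive).
#'
#' @param mat An [abundance_matrix()].
#' @param meta Sample metadata (see [validate_sample_meta()]).
#' @param min_frac Minimum observed fraction within a stratum; default 0.7.
#' @return The filtered matrix.
#' @export
filter_valid_values <- function(mat, meta, min_frac = 0.7) {
  stopifnot(inherits(mat, "abundance_matrix"),
            min_frac >= 0, min_frac <= 1)
  meta <- validate_sample_meta(meta)
  if (!all(colnames(mat$values) %in% meta$sample_id)) {
    stop("matrix has sample columns absent from metadata")
  }
  strata <- expand.grid(group = c("MS", "HC"),
                        condition = c("unstimulated", "stimulated"),
                        stringsAsFactors = FALSE)
  keep <- rep(FALSE, nrow(mat$values))
  for (i in seq_len(nrow(strata))) {
    ids <- stratum_samples(meta, strata$group[i], strata$condition[i])
    ids <- intersect(ids, colnames(mat$values))
    if (length(ids) == 0) stop("empty stratum: ", strata$group[i], " / ",
                               strata$condition[i])
    frac <- rowMeans(!is.na(mat$values[, ids, drop = FALSE]))
    keep <- keep | frac >= min_frac
  }
  out <- mat
  out$values <- mat$values[keep, , drop = FALSE]
  out$proteins <- mat$proteins[keep, , drop = FALSE]
  rownames(out$proteins) <- NULL
  append_log(out, sprintf(
    "valid-value filter (>= %g%% in >= 1 stratum): %d retained, %d dropped",
    100 * min_frac, sum(keep), sum(!keep)))
}

#' Impute missing abundances from a downshifted normal distribution
#'
#' Models detection-limit missingness: per sample column with observed
#' mean `m` and SD `s`, each missing cell is drawn independently from
#' `Normal(m - downshift * s, (width * s)^2)`. Defaults (width 0.3,
#' downshift 1.8) follow standard proteomics practice for left-censored
#' label-free data. Observed cells are bit-identical before and after.
#'
#' @param mat An [abundance_matrix()] on log2 scale.
#' @param width Imputation SD as a multiple of the column's observed SD.
#' @param downshift Shift below the column's observed mean, in observed SDs.
#' @param seed Integer seed; same seed and input give identical draws.
#' @return The matrix with no missing cells.
#' @export
impute_downshifted_normal <- function(mat, width = 0.3, downshift = 1.8,
                                      seed = 1L) {
  stopifnot(inherits(mat, "abundance_matrix"), width > 0, downshift >= 0)
  if (mat$scale != "log2") stop("imputation expects log2 scale")
  x <- mat$values
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2)) {
    stop("sample column(s) with < 2 observed values: ",
         paste(colnames(x)[n_obs < 2], collapse = ", "))
  }
  n_missing <- sum(is.na(x))
  with_rng(seed, {
    for (j in seq_len(ncol(x))) {
      miss <- which(is.na(x[, j]))
      if (!length(miss)) next
      obs <- x[!is.na(x[, j]), j]
      m <- mean(obs)
      s <- sd(obs)
      x[miss, j] <- rnorm(length(miss), m - downshift * s, width * s)
    }
  })
  mat$values <- x
  append_log(mat, sprintf(
    "imputed %d missing cells (downshifted normal, width %g, downshift %g, seed %d)",
    n_missing, width, downshift, seed))
}

#' Run the full preprocessing chain
#'
#' Contaminant removal, log2 transform (skipped when the input is already
#' log2), stratum-wise valid-value filtering and downshifted-normal
#' imputation, in that fixed order.
#'
#' @inheritParams filter_valid_values
#' @inheritParams impute_downshifted_normal
#' @param median_center_samples Apply per-sample median centering after
#'   the log2 transform; default `FALSE`.
#' @return An analysis-ready [abundance_matrix()]: log2 scale, filtered,
#'   no missing cells.
#' @export
preprocess <- function(mat, meta, min_frac = 0.7, width = 0.3,
                       downshift = 1.8, seed = 1L,
                       median_center_samples = FALSE) {
  mat <- remove_contaminants(mat)
  if (mat$scale == "linear") mat <- log2_transform(mat)
  if (median_center_samples) mat <- median_center(mat)
  mat <- filter_valid_values(mat, meta, min_frac = min_frac)
  impute_downshifted_normal(mat, width = width, downshift = downshift,
                            seed = seed)
}
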