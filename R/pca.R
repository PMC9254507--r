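#' Influential-loading cutoff under uniform contribution
#'
#' If all `p` variables contributed equally to a unit-norm principal
#' component loading vector, each loading would have magnitude
#' `sqrt(1/p)`. Loadings at or above this value are called influential.
#'
#' @param n_variables Number of PCA variables (proteins); must be >= 1.
#' @return `sqrt(1 / n_variables)`.
#' @export
influential_loading_cutoff <- function(n_variables) {
  if (!is.numeric(n_variables) || length(n_variables) != 1 ||
      is.na(n_variables) || n_variables < 1) {
    stop("`n_variables` must be a positive count")
  }
  sqrt(1 / n_variables)
}

#' Flag influential loadings
#'
#' @param loadings Numeric loading vector of one component.
#' @param cutoff Influence cutoff, typically
#'   [influential_loading_cutoff()] of the number of variables.
#' @return A list with `flags` (logical, `|loading| >= cutoff`, inclusive
#'   up to a small numerical tolerance so exact-boundary loadings such as
#'   uniform `1/sqrt(p)` contributions are flagged) and `n_influential`.
#' @export
flag_influential <- function(loadings, cutoff) {
  stopifnot(is.numeric(loadings), is.numeric(cutoff), cutoff >= 0)
  flags <- abs(loadings) >= cutoff - 1e-10
  list(flags = flags, n_influential = sum(flags))
}

#' Principal component analysis of selected proteins across samples
#'
#' Samples are observations and the selected proteins are variables,
#' centered and (by default) scaled to unit variance, so the analysis is
#' an eigendecomposition of the correlation structure. Loading columns
#' are unit-norm and orthogonal. A deterministic sign convention is
#' applied: each component is flipped, if needed, so that its
#' largest-magnitude loading is positive. The uniform-contribution cutoff
#' and per-loading influence flags are attached.
#'
#' @param mat An imputed [abundance_matrix()] on log2 scale.
#' @param proteins Accessions to use as variables; default all.
#' @param samples Sample ids to use as observations; default all columns.
#' @param standardize Scale variables to unit variance (default `TRUE`).
#' @return An object of class `pca_result` with elements `scores`
#'   (samples x components), `loadings` (proteins x components),
#'   `variance_explained`, `n_variables`, `cutoff` and
#'   `influential_flags`.
#' @export
run_pca <- function(mat, proteins = mat$proteins$accession,
                    samples = colnames(mat$values), standardize = TRUE) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (anyNA(mat$values)) stop("matrix must be imputed (no missing cells)")
  missing_p <- setdiff(proteins, mat$proteins$accession)
  if (length(missing_p)) {
    stop("protein(s) not in matrix: ", paste(missing_p, collapse = ", "))
  }
  if (length(samples) < 2) stop("PCA needs >= 2 samples")
  if (length(proteins) < 1) stop("PCA needs >= 1 protein")
  x <- t(mat$values[proteins, samples, drop = FALSE])
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance protein(s): ",
         paste(proteins[v == 0], collapse = ", "))
  }
  pc <- prcomp(x, center = TRUE, scale. = standardize)
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  cutoff <- influential_loading_cutoff(length(proteins))
  out <- list(scores = pc$x,
              loadings = pc$rotation,
              variance_explained = pc$sdev^2 / sum(pc$sdev^2),
              n_variables = length(proteins),
              cutoff = cutoff,
              influential_flags = abs(pc$rotation) >= cutoff - 1e-10,
              standardized = standardize)
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result: ", nrow(x$scores), " samples, ", x$n_variables,
      " variables\n", sep = "")
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(x$variance_explained)))], 1)
  cat("variance explained (%): ", paste(ve, collapse = ", "),
      if (length(x$variance_explained) > 3) ", ...", "\n", sep = "")
  cat("influence cutoff sqrt(1/p): ", signif(x$cutoff, 4), "\n", sep = "")
  invisible(x)
}
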