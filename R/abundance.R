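#' Construct a protein abundance matrix
#'
#' The central container of the pipeline: a proteins x samples numeric
#' matrix with `NA` marking missing (unquantified) cells, per-protein
#' annotation, a scale flag (`"linear"` or `"log2"`) and a provenance log
#' recording every transform applied.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns.
#'   `NA` entries are missing cells. Row names are ignored; accessions come
#'   from `proteins`.
#' @param proteins Data frame with columns `accession` (unique, character),
#'   `gene_symbol` (character) and `is_contaminant` (logical), one row per
#'   row of `values`.
#' @param scale Either `"linear"` or `"log2"`; the scale `values` is on.
#' @param log Character vector of provenance messages.
#'
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values`, `proteins`, `scale` and `log`.
#' @export
abundance_matrix <- function(values, proteins, scale = c("linear", "log2"),
                             log = character()) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.data.frame(proteins))
  req <- c("accession", "gene_symbol", "is_contaminant")
  if (!all(req %in% names(proteins))) {
    stop("`proteins` must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(proteins) != nrow(values)) {
    stop("`proteins` has ", nrow(proteins), " rows but `values` has ",
         nrow(values))
  }
  if (anyDuplicated(proteins$accession)) {
    stop("duplicate accession(s): ",
         paste(unique(proteins$accession[duplicated(proteins$accession)]),
               collapse = ", "))
  }
  if (is.null(colnames(values))) {
    stop("`values` must have sample ids as column names")
  }
  rownames(values) <- proteins$accession
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  rownames(proteins) <- NULL
  structure(list(values = values, proteins = proteins, scale = scale,
                 log = as.character(log)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix: ", nrow(x$values), " proteins x ",
      ncol(x$values), " samples (", x$scale, " scale)\n", sep = "")
  cat("missing cells: ", sum(is.na(x$values)), " (",
      round(100 * mean(is.na(x$values)), 2), "%)\n", sep = "")
  cat("contaminant-flagged proteins: ", sum(x$proteins$is_contaminant),
      "\n", sep = "")
  if (length(x$log)) cat("log:\n", paste0("  - ", x$log, "\n"), sep = "")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

append_log <- function(mat, msg) {
  mat$log <- c(mat$log, msg)
  mat
}

#' Validate a sample metadata table
#'
#' Checks the cohort design table tying sample ids to donors, disease
#' group (`MS` / `HC`) and stimulation condition (`unstimulated` /
#' `stimulated`). Each donor may contribute at most one sample per
#' condition; the four group x condition strata must all be non-empty for
#' stratified analyses.
#'
#' @param meta Data frame with columns `sample_id`, `donor_id`, `group`,
#'   `condition`.
#' @param require_full_strata If `TRUE` (default) error when any of the
#'   four strata is empty.
#' @return `meta`, invisibly, with columns coerced to character.
#' @export
validate_sample_meta <- function(meta, require_full_strata = TRUE) {
  req <- c("sample_id", "donor_id", "group", "condition")
  if (!all(req %in% names(meta))) {
    stop("`meta` must have columns: ", paste(req, collapse = ", "))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (cc in req) meta[[cc]] <- as.character(meta[[cc]])
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(meta$group %in% c("MS", "HC"))) {
    stop("group must be 'MS' or 'HC'")
  }
  if (!all(meta$condition %in% c("unstimulated", "stimulated"))) {
    stop("condition must be 'unstimulated' or 'stimulated'")
  }
  if (anyDuplicated(meta[, c("donor_id", "condition")])) {
    stop("a donor has more than one sample in the same condition")
  }
  if (require_full_strata) {
    tab <- table(meta$group, meta$condition)
    if (any(tab == 0)) stop("empty group x condition stratum")
  }
  invisible(meta)
}

# sample ids of one stratum, in metadata order
stratum_samples <- function(meta, group, condition) {
  meta$sample_id[meta$group == group & meta$condition == condition]
}
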