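delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a wide protein abundance table
#'
#' Expects a TSV (or CSV, by extension) with columns `Accession`,
#' `GeneSymbol`, `Contaminant` (true/false) followed by one numeric
#' column per sample. Empty cells are missing values. When metadata is
#' supplied, every sample column must appear in it.
#'
#' @param path File path.
#' @param meta Optional sample metadata for validation.
#' @param scale Scale the stored values are on; default `"linear"`.
#' @return An [abundance_matrix()].
#' @export
read_abundance_table <- function(path, meta = NULL,
                                 scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- read.delim(path, sep = delim_for(path), check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = "character")
  req <- c("Accession", "GeneSymbol", "Contaminant")
  if (!all(req %in% names(df))) {
    stop("abundance table must start with columns: ",
         paste(req, collapse = ", "))
  }
  sample_cols <- setdiff(names(df), req)
  if (!length(sample_cols)) stop("no sample columns found")
  if (anyDuplicated(df$Accession)) {
    stop("duplicate accession(s): ",
         paste(unique(df$Accession[duplicated(df$Accession)]), collapse = ", "))
  }
  if (!is.null(meta)) {
    meta <- validate_sample_meta(meta, require_full_strata = FALSE)
    extra <- setdiff(sample_cols, meta$sample_id)
    if (length(extra)) {
      stop("sample column(s) not in metadata: ", paste(extra, collapse = ", "))
    }
  }
  vals <- matrix(NA_real_, nrow(df), length(sample_cols),
                 dimnames = list(NULL, sample_cols))
  for (j in seq_along(sample_cols)) {
    raw <- trimws(df[[sample_cols[j]]])
    empty <- !nzchar(raw)
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      stop("non-numeric abundance '", raw[bad[1]], "' at row ", bad[1],
           " (", df$Accession[bad[1]], "), column '", sample_cols[j], "'")
    }
    vals[, j] <- ifelse(empty, NA_real_, num)
  }
  proteins <- data.frame(
    accession = df$Accession,
    gene_symbol = df$GeneSymbol,
    is_contaminant = tolower(trimws(df$Contaminant)) %in%
      c("true", "t", "1", "yes"),
    stringsAsFactors = FALSE
  )
  abundance_matrix(vals, proteins, scale = scale,
                   log = paste("read from", path))
}

#' Write a wide protein abundance table
#'
#' Inverse of [read_abundance_table()]: missing cells are written as
#' empty strings (never 0 or an NA literal), numeric values with 17
#' significant digits so a write-read round trip is bit-identical.
#'
#' @param mat An [abundance_matrix()].
#' @param path Output path (`.tsv` or `.csv`).
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(mat, path) {
  stopifnot(inherits(mat, "abundance_matrix"))
  x <- mat$values
  chr <- matrix("", nrow(x), ncol(x), dimnames = dimnames(x))
  obs <- !is.na(x)
  chr[obs] <- sprintf("%.17g", x[obs])
  out <- data.frame(Accession = mat$proteins$accession,
                    GeneSymbol = mat$proteins$gene_symbol,
                    Contaminant = tolower(mat$proteins$is_contaminant),
                    chr, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `donor_id`, `group`, `condition`.
#'
#' @param path File path.
#' @return Validated metadata data frame.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE)
  validate_sample_meta(df, require_full_strata = FALSE)
}

#' Read a clinical cohort table
#'
#' TSV with columns `patient_id`, `age`, `disease_duration`, `edss`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_clinical_table <- function(path) {
  read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE)
}

#' Bundled example tables
#'
#' Small plain-text tables shipped with the package: the clinical
#' characteristics of a published 20-patient MS cohort
#' (`"clinical"`), and the reported PC1/PC2 loadings of the proteins
#' found differentially abundant between MS patients and healthy
#' controls in that cohort's stimulated (`"loadings_stimulated"`, 33
#' proteins) and unstimulated (`"loadings_unstimulated"`, 18 proteins)
#' CD4+ T cells.
#'
#' @param which One of `"clinical"`, `"loadings_stimulated"`,
#'   `"loadings_unstimulated"`.
#' @return A data frame.
#' @export
lfq_example <- function(which = c("clinical", "loadings_stimulated",
                                  "loadings_unstimulated")) {
  which <- match.arg(which)
  file <- switch(which,
                 clinical = "ms_cohort_clinical.tsv",
                 loadings_stimulated = "pc_loadings_stimulated.tsv",
                 loadings_unstimulated = "pc_loadings_unstimulated.tsv")
  path <- system.file("extdata", file, package = "lfqpipe", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
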