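#' Read a gene-set file
#'
#' Plain text, one gene symbol per line; `#` starts a comment; symbols
#' are trimmed, uppercased and deduplicated.
#'
#' @param path File path.
#' @return Character vector of unique uppercase symbols.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  sym <- toupper(trimws(lines))
  sym <- unique(sym[nzchar(sym)])
  if (!length(sym)) stop("gene set is empty: ", path)
  sym
}

#' Build the 2x2 DE-by-gene-set contingency table
#'
#' Cross-classifies every protein of the universe by (row) membership in
#' the differentially expressed set and (column) whether its gene symbol
#' belongs to the gene set. Classification is at the protein level: a
#' gene represented by two protein entries contributes two counts.
#' Proteins lacking a gene symbol are counted as non-members.
#'
#' @param universe Data frame with columns `accession` and `gene_symbol`
#'   (e.g. the `proteins` slot of the post-filter matrix).
#' @param de_set Character accessions of the DE proteins (subset of the
#'   universe).
#' @param gene_set Character vector of gene symbols (see
#'   [read_gene_set()]); matching is by exact uppercase symbol.
#' @return A 2x2 integer matrix of class `contingency_2x2` with rows
#'   `not_de` / `de` and columns `not_in_set` / `in_set`.
#' @export
build_contingency <- function(universe, de_set, gene_set) {
  stopifnot(is.data.frame(universe),
            all(c("accession", "gene_symbol") %in% names(universe)))
  if (!all(de_set %in% universe$accession)) {
    stop("de_set contains accessions outside the universe")
  }
  gene_set <- toupper(gene_set)
  sym <- toupper(ifelse(is.na(universe$gene_symbol), "",
                        universe$gene_symbol))
  n_blank <- sum(!nzchar(sym))
  in_set <- nzchar(sym) & sym %in% gene_set
  is_de <- universe$accession %in% de_set
  tab <- matrix(c(sum(!is_de & !in_set), sum(!is_de & in_set),
                  sum(is_de & !in_set), sum(is_de & in_set)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("not_de", "de"),
                                c("not_in_set", "in_set")))
  storage.mode(tab) <- "integer"
  attr(tab, "n_missing_symbol") <- n_blank
  class(tab) <- c("contingency_2x2", class(tab))
  tab
}

#' Pearson chi-squared test of a 2x2 table
#'
#' One-degree-of-freedom Pearson chi-squared test of independence, with
#' Yates continuity correction by default, plus the sample odds ratio
#' (ad/bc) for direction.
#'
#' @param table A 2x2 count matrix (e.g. from [build_contingency()]).
#' @param continuity_correction Apply the Yates correction; default
#'   `TRUE`.
#' @return List with `statistic`, `df`, `p_value` and `odds_ratio`.
#' @export
chi_squared_test <- function(table, continuity_correction = TRUE) {
  tab <- unclass(table)
  attr(tab, "n_missing_symbol") <- NULL
  if (!is.matrix(tab) || any(dim(tab) != 2) || any(tab < 0)) {
    stop("`table` must be a 2x2 matrix of non-negative counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in contingency table")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = continuity_correction))
  list(statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = ct$p.value,
       odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
}

#' Summarize a clinical cohort table
#'
#' Arithmetic mean with min-max range for age and disease duration,
#' median with range for the EDSS disability score.
#'
#' @param clinical Data frame with numeric columns `age`,
#'   `disease_duration` and `edss` (one row per patient).
#' @return List with `n`, `mean_age`, `range_age`,
#'   `mean_disease_duration`, `range_disease_duration`, `median_edss`,
#'   `range_edss`.
#' @export
summarize_cohort <- function(clinical) {
  stopifnot(is.data.frame(clinical), nrow(clinical) >= 1)
  num <- function(col) {
    if (!col %in% names(clinical)) stop("missing column: ", col)
    v <- clinical[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      id <- if ("patient_id" %in% names(clinical))
        clinical$patient_id[bad] else paste("record", bad)
      stop("non-numeric ", col, " for ", id)
    }
    v
  }
  age <- num("age"); dur <- num("disease_duration"); edss <- num("edss")
  list(n = nrow(clinical),
       mean_age = mean(age), range_age = range(age),
       mean_disease_duration = mean(dur),
       range_disease_duration = range(dur),
       median_edss = median(edss), range_edss = range(edss))
}
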