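# Independent oracles and small fixture builders used across the suite.

# brute-force Benjamini-Hochberg step-up: adj p of the i-th ordered value
# is min over j >= i of p_(j) * m / j, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  adj[order(o)]
}

# exhaustive conditional (hypergeometric) two-sided p for a 2x2 table:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed that of the observed table
fisher_enum <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # col 1 total
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# abundance matrix from a bare numeric matrix (proteins x samples)
toy_matrix <- function(values, scale = "log2", contaminant = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  n <- nrow(values)
  if (is.null(contaminant)) contaminant <- rep(FALSE, n)
  abundance_matrix(
    values,
    data.frame(accession = sprintf("P%03d", seq_len(n)),
               gene_symbol = sprintf("G%03d", seq_len(n)),
               is_contaminant = contaminant,
               stringsAsFactors = FALSE),
    scale = scale
  )
}

# balanced paired-design metadata: n donors per group, both conditions
toy_meta <- function(n_per_group = 4) {
  donors <- c(sprintf("MS%02d", seq_len(n_per_group)),
              sprintf("HC%02d", seq_len(n_per_group)))
  data.frame(
    sample_id = paste0(rep(donors, each = 2), "_",
                       rep(c("unstim", "stim"), 2 * n_per_group)),
    donor_id = rep(donors, each = 2),
    group = rep(c("MS", "HC"), each = 2 * n_per_group),
    condition = rep(c("unstimulated", "stimulated"), 2 * n_per_group),
    stringsAsFactors = FALSE
  )
}

# small fully-processed synthetic cohort for downstream tests
small_cohort <- function(seed = 1, n_proteins = 300, ...) {
  cfg <- sim_config(n_proteins = n_proteins, seed = seed, ...)
  co <- generate_cohort(cfg)
  co$matrix <- inject_missingness(co$matrix, cfg)
  co$processed <- preprocess(co$matrix, co$meta,
                             seed = derive_seed(seed, "impute"))
  co
}
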