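test_that("contaminant removal keeps exactly the unflagged rows", {
  m0 <- toy_matrix(matrix(1:20, 10, 2), contaminant = rep(FALSE, 10))
  expect_identical(remove_contaminants(m0)$values, m0$values)

  flags <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m1 <- toy_matrix(matrix(rnorm(20), 10, 2), contaminant = flags)
  out <- remove_contaminants(m1)
  expect_equal(nrow(out$values), 7)
  expect_false(any(m1$proteins$accession[flags] %in% out$proteins$accession))

  co <- generate_cohort(sim_config(n_proteins = 500, seed = 4))
  removed <- nrow(co$matrix$values) - nrow(remove_contaminants(co$matrix)$values)
  expect_equal(removed, sum(co$truth$is_contaminant))
})

test_that("log2 transform is exact, preserves the mask, rejects non-positives", {
  m <- toy_matrix(rbind(c(8, 1), c(NA, NA), c(4, 16)), scale = "linear")
  out <- log2_transform(m)
  expect_equal(out$values[1, ], c(S1 = 3, S2 = 0))
  expect_true(all(is.na(out$values[2, ])))
  expect_equal(out$values[3, ], c(S1 = 2, S2 = 4))
  expect_equal(out$scale, "log2")

  bad <- toy_matrix(rbind(c(8, 1), c(2, -3)), scale = "linear")
  expect_error(log2_transform(bad), "P002.*S2")
})

test_that("valid-value filter applies the inclusive stratum-wise rule", {
  meta <- toy_meta(20)  # four strata of 20 samples each
  n_s <- nrow(meta)
  ms_unstim <- meta$sample_id[meta$group == "MS" &
                                meta$condition == "unstimulated"]
  # protein 1: observed in exactly 14/20 of one stratum, 0 elsewhere -> kept
  # protein 2: observed in 13/20 of every stratum -> dropped
  # protein 3: complete -> kept
  v <- matrix(NA_real_, 3, n_s, dimnames = list(NULL, meta$sample_id))
  v[1, ms_unstim[1:14]] <- 20
  for (g in c("MS", "HC")) for (cc in c("unstimulated", "stimulated")) {
    ids <- meta$sample_id[meta$group == g & meta$condition == cc]
    v[2, ids[1:13]] <- 21
  }
  v[3, ] <- 22
  out <- filter_valid_values(toy_matrix(v), meta, min_frac = 0.7)
  expect_setequal(out$proteins$accession, c("P001", "P003"))

  # complete matrix: everything retained
  full <- toy_matrix(matrix(rnorm(5 * n_s), 5,
                            dimnames = list(NULL, meta$sample_id)))
  expect_equal(nrow(filter_valid_values(full, meta)$values), 5)
})

test_that("valid-value filter is monotone in min_frac", {
  meta <- toy_meta(5)
  set.seed(31)
  v <- matrix(rnorm(40 * nrow(meta)), 40,
              dimnames = list(NULL, meta$sample_id))
  v[sample(length(v), length(v) * 0.4)] <- NA
  m <- toy_matrix(v)
  kept <- lapply(c(0.9, 0.7, 0.5, 0.3), function(f) {
    filter_valid_values(m, meta, min_frac = f)$proteins$accession
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  }
})

test_that("filter errors on an empty stratum", {
  meta <- toy_meta(3)
  meta <- meta[!(meta$group == "HC" & meta$condition == "stimulated"), ]
  v <- matrix(rnorm(2 * nrow(meta)), 2, dimnames = list(NULL, meta$sample_id))
  expect_error(filter_valid_values(toy_matrix(v), meta), "stratum")
})

test_that("imputation draws from the downshifted normal and is seeded", {
  # column with observed mean 25, SD 1 and 10^4 missing cells
  v <- matrix(NA_real_, 10003, 1, dimnames = list(NULL, "S1"))
  v[1:3, 1] <- c(24, 25, 26)
  m <- toy_matrix(v)
  out <- impute_downshifted_normal(m, seed = 77)
  imp <- out$values[-(1:3), 1]
  expect_equal(mean(imp), 25 - 1.8, tolerance = 4 * 0.3 / sqrt(1e4) / 23.2)
  expect_equal(sd(imp), 0.3, tolerance = 4 * 0.3 / sqrt(2e4) / 0.3)
  # observed cells bit-identical, nothing missing, deterministic
  expect_identical(out$values[1:3, 1], m$values[1:3, 1])
  expect_false(anyNA(out$values))
  expect_identical(impute_downshifted_normal(m, seed = 77)$values, out$values)
  expect_false(identical(impute_downshifted_normal(m, seed = 78)$values,
                         out$values))
})

test_that("imputation is the identity on complete matrices", {
  m <- toy_matrix(matrix(rnorm(30, 25), 10, 3))
  expect_identical(impute_downshifted_normal(m, seed = 1)$values, m$values)
})

test_that("imputation requires >= 2 observed values per column", {
  v <- matrix(c(25, NA, NA, 24, 25, 26), 3, 2,
              dimnames = list(NULL, c("bad", "ok")))
  expect_error(impute_downshifted_normal(toy_matrix(v), seed = 1), "bad")
})

test_that("the preprocessing chain runs in fixed order and logs it", {
  co <- small_cohort(seed = 12, n_proteins = 200)
  pre <- co$processed
  expect_equal(pre$scale, "log2")
  expect_false(anyNA(pre$values))
  expect_false(any(pre$proteins$is_contaminant))
  expect_match(pre$log[length(pre$log) - 2], "log2")
  expect_match(pre$log[length(pre$log) - 1], "valid-value")
  expect_match(pre$log[length(pre$log)], "imputed")
  # observed (post-filter) entries never modified by imputation
  filt <- filter_valid_values(log2_transform(remove_contaminants(co$matrix)),
                              co$meta)
  obs <- !is.na(filt$values)
  expect_identical(pre$values[obs], filt$values[obs])
})
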