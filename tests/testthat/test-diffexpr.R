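test_that("paired t matches the one-sample t oracle per protein", {
  meta <- toy_meta(5)
  diffs <- c(1.0, 1.2, 0.8, 1.1, 0.9)
  donors <- sprintf("MS%02d", 1:5)   # paired analysis on the 5 MS donors
  unstim_ids <- paste0(donors, "_unstim")
  stim_ids <- paste0(donors, "_stim")
  set.seed(21)
  v <- matrix(rnorm(4 * nrow(meta), 25), 4,
              dimnames = list(NULL, meta$sample_id))
  v[1, stim_ids] <- v[1, unstim_ids] + diffs
  m <- toy_matrix(v)
  res <- paired_t_test(m, meta, donors = donors)
  # textbook computation on the five differences
  expect_equal(res$t[1], mean(diffs) / (sd(diffs) / sqrt(5)))
  expect_equal(res$df[1], 4)
  expect_equal(res$p_value[1], t.test(diffs)$p.value)
  expect_equal(res$log2_fc[1], mean(diffs))
  # every row agrees with stats::t.test on its own difference vector
  for (i in 2:4) {
    d <- v[i, stim_ids] - v[i, unstim_ids]
    expect_equal(res$p_value[i], t.test(d)$p.value)
    expect_equal(res$log2_fc[i], unname(mean(d)))
  }
})

test_that("paired t degenerate case: identical conditions give p = 1", {
  meta <- toy_meta(3)
  v <- matrix(25, 2, nrow(meta), dimnames = list(NULL, meta$sample_id))
  v[2, ] <- rep(c(20, 21, 22, 23, 24, 25), each = 2)[seq_len(nrow(meta))]
  # force stim == unstim for both proteins
  stim <- meta$sample_id[meta$condition == "stimulated"]
  unstim <- meta$sample_id[meta$condition == "unstimulated"]
  v[, stim] <- v[, unstim]
  res <- paired_t_test(toy_matrix(v), meta)
  expect_equal(res$p_value, c(1, 1))
  expect_equal(res$log2_fc, c(0, 0))
})

test_that("paired t rejects incomplete pairs and tiny cohorts", {
  meta <- toy_meta(3)
  v <- matrix(rnorm(2 * nrow(meta), 25), 2,
              dimnames = list(NULL, meta$sample_id))
  m <- toy_matrix(v)
  expect_error(paired_t_test(m, meta[-2, ]), "missing")
  expect_error(paired_t_test(m, meta, donors = "MS01"), "2 donors")
})

test_that("Welch test matches stats::t.test and finds a planted shift", {
  meta <- toy_meta(6)
  set.seed(33)
  v <- matrix(rnorm(20 * nrow(meta), 25), 20,
              dimnames = list(NULL, meta$sample_id))
  ms_stim <- meta$sample_id[meta$group == "MS" & meta$condition == "stimulated"]
  hc_stim <- meta$sample_id[meta$group == "HC" & meta$condition == "stimulated"]
  v[7, ms_stim] <- v[7, ms_stim] + 3
  res <- welch_test(toy_matrix(v), meta, "stimulated")
  expect_equal(which.min(res$p_value), 7L)
  expect_equal(res$log2_fc[7], 3, tolerance = 0.5)
  for (i in c(1, 7, 12)) {
    tt <- t.test(v[i, ms_stim], v[i, hc_stim])
    expect_equal(res$p_value[i], tt$p.value)
    expect_equal(res$t[i], unname(tt$statistic))
    expect_equal(res$df[i], unname(tt$parameter))
  }
})

test_that("Welch hand check: {1,2,3,4} vs the same values shifted by 10", {
  meta <- toy_meta(4)
  ms <- meta$sample_id[meta$group == "MS" & meta$condition == "unstimulated"]
  hc <- meta$sample_id[meta$group == "HC" & meta$condition == "unstimulated"]
  v <- matrix(1, 1, nrow(meta), dimnames = list(NULL, meta$sample_id))
  v[1, ms] <- c(1, 2, 3, 4) + 10
  v[1, hc] <- c(1, 2, 3, 4)
  # equal variances, equal n: Welch t = 10 / sqrt(2 * var / 4), df = 6
  res <- welch_test(toy_matrix(v), meta, "unstimulated")
  expect_equal(res$t[1], 10 / sqrt(2 * var(c(1, 2, 3, 4)) / 4))
  expect_equal(res$df[1], 6)
  expect_equal(res$p_value[1], t.test(v[1, ms], v[1, hc])$p.value)
  # and equals Student's t in this equal-variance, equal-n limit
  expect_equal(res$p_value[1],
               t.test(v[1, ms], v[1, hc], var.equal = TRUE)$p.value)
})

test_that("Welch degenerate case: equal values in both groups give p = 1", {
  meta <- toy_meta(3)
  v <- matrix(5, 1, nrow(meta), dimnames = list(NULL, meta$sample_id))
  res <- welch_test(toy_matrix(v), meta, "stimulated")
  expect_equal(res$p_value[1], 1)
  expect_equal(res$log2_fc[1], 0)
})

test_that("Welch test rejects groups of size < 2", {
  meta <- toy_meta(3)
  meta <- meta[!(meta$group == "HC" & meta$donor_id != "HC01"), ]
  v <- matrix(rnorm(nrow(meta)), 1, dimnames = list(NULL, meta$sample_id))
  expect_error(welch_test(toy_matrix(v), meta, "stimulated"), ">= 2 samples")
})

test_that("B-H adjustment equals the brute-force step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.01)), "\\[0, 1\\]")
})

test_that("DE results satisfy the adjusted-p and fold-change invariants", {
  co <- small_cohort(seed = 6, n_proteins = 150)
  res <- welch_test(co$processed, co$meta, "stimulated")
  expect_true(all(res$adj_p >= res$p_value))
  o <- order(res$p_value)
  expect_true(all(diff(res$adj_p[o]) >= -1e-12))
  expect_true(all(sign(res$log2_fc) == sign(res$mean_a - res$mean_b)))
})

test_that("significant_set is inclusive at the threshold", {
  res <- structure(
    data.frame(accession = c("A", "B", "C"),
               adj_p = c(0.01, 0.05, 0.051)),
    class = c("de_result", "data.frame"))
  expect_setequal(significant_set(res, 0.05), c("A", "B"))
  expect_length(significant_set(res[0, ], 0.05), 0)
})

test_that("a strongly planted cohort is recovered at adj p <= 0.01", {
  co <- small_cohort(seed = 14, n_proteins = 300, frac_activation_de = 0.2,
                     effect_size_log2 = 2, effect_dist = "fixed",
                     residual_sd_log2 = 0.5)
  res <- paired_t_test(co$processed, co$meta, alpha = 0.01)
  planted <- co$truth$accession[co$truth$activation_effect_ms_log2 != 0]
  planted <- intersect(planted, res$accession)
  hits <- significant_set(res, 0.01)
  expect_gte(mean(planted %in% hits), 0.9)
})

test_that("null cohorts yield essentially no activation discoveries", {
  for (seed in c(101, 202, 303)) {
    co <- small_cohort(seed = seed, n_proteins = 250,
                       frac_activation_de = 0, frac_disease_de_unstim = 0,
                       frac_disease_de_stim = 0)
    res <- paired_t_test(co$processed, co$meta)
    expect_lte(mean(res$adj_p <= 0.01), 0.01)
  }
})

test_that("venn partition obeys its set identities", {
  ident <- venn_partition(c("a", "b"), c("a", "b"))
  expect_length(ident$exclusive_first, 0)
  expect_length(ident$exclusive_second, 0)

  disj <- venn_partition(c("a", "b"), c("c"))
  expect_length(disj$shared, 0)
  expect_setequal(disj$exclusive_first, c("a", "b"))
  expect_setequal(disj$exclusive_second, "c")

  set.seed(55)
  for (i in 1:20) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    vp <- venn_partition(a, b)
    expect_length(intersect(vp$shared, vp$exclusive_first), 0)
    expect_length(intersect(vp$shared, vp$exclusive_second), 0)
    expect_setequal(c(vp$shared, vp$exclusive_first, vp$exclusive_second),
                    union(a, b))
    expect_equal(length(vp$shared) + length(vp$exclusive_first), length(a))
  }
})

test_that("venn concordance flags agree with fold-change signs", {
  ra <- structure(data.frame(accession = c("x", "y", "z"),
                             log2_fc = c(1, -2, 3)),
                  class = c("de_result", "data.frame"))
  rb <- structure(data.frame(accession = c("x", "y", "z"),
                             log2_fc = c(2, 1, -1)),
                  class = c("de_result", "data.frame"))
  vp <- venn_partition(c("x", "y", "z"), c("x", "y", "z"), ra, rb)
  expect_equal(vp$concordant, c(x = TRUE, y = FALSE, z = FALSE))
})
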