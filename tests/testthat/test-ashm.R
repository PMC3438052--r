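test_that("zero-sum rows and columns are removed from the contingency table", {
  m <- matrix(c(5, 0, 3,
                2, 0, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "G"), c("m1", "m2", "m3")))
  red <- build_contingency_table(m)
  expect_equal(colnames(red), c("m1", "m3"))
  expect_equal(attr(red, "reduced_dim"), c(2L, 2L))
  expect_false(attr(red, "untestable"))

  # all reads on one allele: a single row remains, untestable
  one <- build_contingency_table(matrix(c(5, 3, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(nrow(one), 1L)
  expect_true(attr(one, "untestable"))

  # a full non-zero table is unchanged
  full <- matrix(1:6, 2, 3)
  expect_equal(unclass(build_contingency_table(full))[, ],
               full, ignore_attr = TRUE)

  # empty tensor flagged untestable
  expect_true(attr(build_contingency_table(matrix(0L, 0, 0)),
                   "untestable"))
})

test_that("omnibus test handles degenerate and identical-ratio tables", {
  even <- test_cross_dataset_imbalance(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(even$p_value, 1)
  single <- test_cross_dataset_imbalance(matrix(c(4, 9), 1, 2))
  expect_equal(single$p_value, 1)
  expect_equal(single$method, "untestable")
  expect_error(test_cross_dataset_imbalance(matrix(c(-1, 1, 1, 1), 2, 2)),
               "negative")
})

test_that("omnibus test equals 2x2 enumeration within the exact budget", {
  for (n in c(6, 12, 18, 24)) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      res <- test_cross_dataset_imbalance(matrix(c(a, b, c, d), 2, 2,
                                                 byrow = TRUE))
      expect_equal(res$p_value, fisher_2x2_oracle(a, b, c, d),
                   tolerance = 1e-9, label = paste(a, b, c, d))
      expect_false(res$approximate)
    }
  }
})

test_that("tables beyond the complexity budget fall back to flagged chi-squared", {
  big <- matrix(rpois(46, 30) + 1, 2, 23)
  res <- test_cross_dataset_imbalance(big, exact_max_total = 120)
  expect_equal(res$method, "chisq")
  expect_true(res$approximate)
  expect_equal(res$p_value,
               suppressWarnings(chisq.test(big, correct = FALSE)$p.value))
})

test_that("per-modification binomial imbalance matches its anchors", {
  tensor <- matrix(c(19, 7, 15, 0,
                     0, 7, 5, 0), 2, 4, byrow = TRUE,
                   dimnames = list(c("A", "G"),
                                   c("H3K4me3", "H3K9me3", "H3K27me3",
                                     "H3K36me3")))
  pm <- per_modification_imbalance(tensor, "A", "G")
  expect_equal(pm[modification == "H3K4me3", binomial_p], 2 * 0.5^19,
               tolerance = 1e-12)
  expect_equal(pm[modification == "H3K9me3", binomial_p], 1)
  expect_equal(pm[modification == "H3K27me3", binomial_p],
               binom_twosided_oracle(15, 5), tolerance = 1e-12)
  expect_equal(pm[modification == "H3K27me3", binomial_p], 0.04138947,
               tolerance = 1e-6)
  # zero coverage: p = 1, no favored allele
  expect_equal(pm[modification == "H3K36me3", binomial_p], 1)
  expect_true(is.na(pm[modification == "H3K36me3", favored_allele]))
  expect_true(is.na(pm[modification == "H3K9me3", favored_allele]))
  expect_equal(pm[modification == "H3K4me3", favored_allele], "A")
})

test_that("background selection applies the 35-read floor inclusively", {
  cov <- data.table(site_id = c("s35", "s34", "s100"),
                    total_coverage = c(35L, 34L, 100L))
  expect_setequal(select_background_sites(cov), c("s35", "s100"))
  # monotone: raising the threshold shrinks the set
  for (thr in c(10, 35, 60, 101)) {
    expect_true(all(select_background_sites(cov, thr + 1) %in%
                      select_background_sites(cov, thr)))
  }
})

test_that("HWE exact test matches the enumeration oracle", {
  cases <- list(c(25, 50, 25), c(20, 0, 20), c(50, 0, 0), c(3, 14, 6),
                c(0, 1, 0), c(12, 2, 9), c(1, 58, 1))
  for (g in cases) {
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 hwe_oracle(g[1], g[2], g[3]), tolerance = 1e-9,
                 label = paste(g, collapse = "/"))
  }
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
  expect_equal(hwe_exact_test(50, 0, 0), 1)       # monomorphic
  expect_lt(hwe_exact_test(20, 0, 20), 1e-10)     # duplication-like
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("HWE QC excludes p < 0.05 strictly and reports coverage", {
  calls <- data.table(site_id = c("a", "b", "c"),
                      omnibus_p = c(1e-9, 1e-9, 1e-9))
  # genotype counts engineered so a has p < 0.05 and b sits above it
  pop <- data.table(site_id = c("a", "b"),
                    hom_a = c(20L, 25L), het = c(0L, 50L),
                    hom_b = c(20L, 25L))
  cov <- data.table(site_id = c("a", "b", "c", "d"),
                    depth = c(10, 20, 30, 40))
  expect_message(
    out <- apply_qc(calls, pop, bis_coverage = cov),
    "not assessed")
  expect_false(out[site_id == "a", passed_qc])
  expect_true(out[site_id == "b", passed_qc])
  expect_true(out[site_id == "c", passed_qc])     # no pop data: unchanged
  expect_false(out[site_id == "a", significant])
  expect_true(out[site_id == "b", significant])
  qc <- attr(out, "coverage_qc")
  expect_equal(qc$mean_called, 20)
  expect_equal(qc$mean_genome, 25)
  expect_equal(qc$ratio, 0.8)

  # boundary: p exactly at the threshold is retained
  thr <- data.table(site_id = "t", omnibus_p = 1e-9)
  p_exact <- hwe_exact_test(3, 14, 6)
  out2 <- apply_qc(thr, data.table(site_id = "t", hom_a = 3L, het = 14L,
                                   hom_b = 6L), hwe_alpha = p_exact)
  expect_true(out2$passed_qc)
  out3 <- apply_qc(thr, data.table(site_id = "t", hom_a = 3L, het = 14L,
                                   hom_b = 6L),
                   hwe_alpha = p_exact * (1 + 1e-9))
  expect_false(out3$passed_qc)
})

test_that("row scaling leaves the omnibus independence structure alone", {
  # occupancy-shift immunity in miniature: scaling one allele's row of a
  # proportional table keeps it proportional, p stays 1-ish
  base <- matrix(c(8, 4, 12, 4, 2, 6), 2, 3, byrow = TRUE)
  scaled <- base * c(3, 1)
  p0 <- test_cross_dataset_imbalance(base)$p_value
  p1 <- test_cross_dataset_imbalance(scaled)$p_value
  expect_gt(p0, 0.99)
  expect_gt(p1, 0.99)
})

test_that("implanted cluster patterns are recovered at deep driver coverage", {
  # regression guard at driver depth 200, skew 0.9: expected recovery is
  # about 60% for single-driver and near 1 for two-driver patterns
  cfg <- sim_config(seed = 101, n_sites = 500, ashm_fraction = 1,
                    occupancy_shift_fraction = 0, false_het_fraction = 0,
                    asm_fraction = 0, ase_fraction = 0,
                    mean_driver_chip_depth = 200,
                    imprinted_enrichment_fold = 1)
  ds <- simulate_dataset(cfg)
  counts <- count_alleles(ds$chip_reads, ds$sites)
  res <- suppressMessages(call_ashm(counts, ds$sites))
  m <- merge(res$calls, ds$truth[, .(site_id, ashm_label)], by = "site_id")
  expect_gte(m[, mean(significant)], 0.5)
  expect_true(all(m$total_coverage >= 35))
})
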