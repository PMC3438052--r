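test_that("proximity distances use inclusive edge semantics", {
  regions <- data.table(chrom = "chrS", start = 50000L, end = 60000L,
                        label = "r", track = "imprinted")
  sites <- data.table(chrom = "chrS",
                      pos = c(40000L, 55000L, 70000L, 70001L))
  d <- distance_to_targets(sites, regions)
  expect_equal(d, c(10000, 0, 10000, 10001))
  f <- proximity_fraction(sites, regions, 10000)
  # exactly 10 kb away is included; a site inside a region always is
  expect_equal(f$count_in, 3L)
  expect_equal(f$proportion, 0.75)

  # monotone in the window
  fr <- vapply(c(1, 5000, 10000, 10001),
               function(w) proximity_fraction(sites, regions, w)$proportion,
               numeric(1))
  expect_true(all(diff(fr) >= 0))

  expect_warning(empty <- proximity_fraction(sites, regions[0], 1000),
                 "empty target")
  expect_equal(empty$proportion, 0)
})

test_that("proximity to point targets counts by construction", {
  targets <- data.table(chrom = "chrS", pos = c(100L, 5000L))
  sites <- data.table(chrom = "chrS",
                      pos = c(90L, 110L, 104L, 2000L, 4500L, 80000L,
                              rep(200000L, 6)))
  f <- proximity_fraction(sites, targets, 500)
  expect_equal(f$count_in, 4L)
  expect_equal(f$total, 12L)
  # 3 of 12 placed within the window when only the first target is used
  g <- proximity_fraction(sites, targets[1], 500)
  expect_equal(g$count_in, 3L)
  expect_equal(g$proportion, 0.25)
})

test_that("enrichment folds reproduce the screen's headline ratios", {
  # 9/51 ASHM sites near imprinted loci vs 0.6% of background
  imp <- enrichment_test(9, 51, 486, 81029)
  expect_equal(imp$fold, (9 / 51) / (486 / 81029), tolerance = 1e-12)
  expect_equal(imp$fold, 29.4, tolerance = 0.01)
  expect_lt(imp$p_value, 1e-15)

  # 7/51 near disease microindel+ASE loci vs 0.5% of background
  del <- enrichment_test(7, 51, 405, 81029)
  expect_equal(del$fold, 27.5, tolerance = 0.015)

  # identical proportions: fold 1, p about 1
  same <- enrichment_test(5, 100, 50, 1000)
  expect_equal(same$fold, 1)
  expect_gt(same$p_value, 0.9)

  # swapping in/out inverts the fold and keeps p
  a <- enrichment_test(9, 51, 486, 81029, method = "fisher")
  b <- enrichment_test(51 - 9, 51, 81029 - 486, 81029, method = "fisher")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
  expect_equal(a$fold * (b$fg_prop / b$bg_prop),
               a$fg_prop / a$bg_prop * b$fold, tolerance = 1e-9)
})

test_that("posterior odds calibration matches the stated scenario", {
  # prior fraction 0.001%, power 0.1, alpha 1e-7: ten to one
  expect_equal(posterior_odds(1e-5, 0.1, 1e-7), 10, tolerance = 1e-3)
  # power = alpha leaves the prior odds
  expect_equal(posterior_odds(0.2, 0.05, 0.05), 0.25, tolerance = 1e-12)
  # prior 0.5 gives power / alpha
  expect_equal(posterior_odds(0.5, 0.3, 0.01), 30, tolerance = 1e-12)
  expect_error(posterior_odds(0.5, 0.3, 0), "0,1")
  # linear in power, inverse in alpha
  expect_equal(posterior_odds(1e-4, 0.2, 1e-6),
               2 * posterior_odds(1e-4, 0.1, 1e-6))
  expect_equal(posterior_odds(1e-4, 0.1, 1e-6),
               10 * posterior_odds(1e-4, 0.1, 1e-5))
})

test_that("Bonferroni thresholds come out at the printed order of magnitude", {
  thr <- bonferroni_threshold(0.05, 3410426)
  expect_equal(thr, 0.05 / 3410426, tolerance = 1e-15)
  expect_equal(floor(log10(thr)), -8)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 500), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("Clopper-Pearson intervals match tail-probability bisection", {
  for (kn in list(c(0, 10), c(10, 10), c(5, 100), c(405, 81029))) {
    ci <- proportion_ci(kn[1], kn[2])
    expect_equal(unname(ci), clopper_pearson_oracle(kn[1], kn[2]),
                 tolerance = 1e-6, label = paste(kn, collapse = "/"))
  }
  expect_equal(unname(proportion_ci(0, 10)[1]), 0)
  expect_equal(unname(proportion_ci(10, 10)[2]), 1)
})

test_that("expected chance colocalisation is the independence product", {
  expect_equal(expected_colocalisation(51, 0.005), 0.255)
  expect_lte(expected_colocalisation(51, 0.005), 1)
})

test_that("sites_within composes proximity filters", {
  sites <- data.table(site_id = paste0("s", 1:4), chrom = "chrS",
                      pos = c(100L, 900L, 5000L, 9000L))
  ase <- data.table(chrom = "chrS", pos = c(150L, 5100L))
  del <- data.table(chrom = "chrS", start = 1L, end = 1000L,
                    label = "d", track = "deletion_syndrome")
  both <- sites_within(sites_within(sites, ase, 200), del, 250)
  expect_equal(both$site_id, "s1")
  expect_equal(nrow(sites_within(sites, ase[0], 200)), 0L)
})

test_that("implanted imprinted enrichment is estimated at the configured fold", {
  # placement-level check on one large replicate (the multi-replicate
  # sampling-interval check lives in the acceptance suite)
  cfg <- sim_config(seed = 55, n_sites = 20000, ashm_fraction = 0.02,
                    imprinted_enrichment_fold = 10,
                    mean_chip_depth = 0.01, mean_bis_depth = 0.01,
                    mean_rna_depth = 0.01, asm_fraction = 0,
                    ase_fraction = 0, occupancy_shift_fraction = 0,
                    false_het_fraction = 0)
  ds <- simulate_dataset(cfg)
  imp <- ds$annotations[track == "imprinted"]
  fg <- ds$truth[grepl("cluster", ashm_label)]
  f <- proximity_fraction(fg, imp, 10000)
  b <- proximity_fraction(ds$truth, imp, 10000)
  est <- f$proportion / b$proportion
  expect_gt(est, 6)
  expect_lt(est, 15)
})
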