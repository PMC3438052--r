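test_that("identical seeds give identical datasets, different seeds differ", {
  a <- simulate_dataset(tiny_config(seed = 5))
  b <- simulate_dataset(tiny_config(seed = 5))
  c <- simulate_dataset(tiny_config(seed = 6))
  for (el in c("sites", "chip_reads", "bis_obs", "expression",
               "annotations", "population", "truth")) {
    expect_identical(a[[el]], b[[el]], label = el)
  }
  expect_false(identical(a$sites$pos, c$sites$pos))
})

test_that("invalid configuration fields name the offending field", {
  expect_error(sim_config(skew = 1.2), "skew")
  expect_error(sim_config(n_sites = 0), "n_sites")
  expect_error(sim_config(cluster_pattern_weights = rep(0.2, 6)),
               "cluster_pattern_weights")
  expect_error(sim_config(cpg_disrupting_fraction = 0.5,
                          epiallele_fraction = 0.1),
               "epiallele_fraction")
  expect_error(sim_config(ashm_fraction = 0.3, false_het_fraction = 0.4,
                          occupancy_shift_fraction = 0.4),
               "sum")
  expect_error(sim_config(ashm_fraction = 0.2,
                          imprinted_enrichment_fold = 10),
               "imprinted_enrichment_fold")
})

test_that("null sites draw alleles symmetrically (binomial 0.5)", {
  set.seed(0)
  cfg <- sim_config(seed = 17, n_sites = 10000, n_modifications = 4,
                    ashm_fraction = 0, occupancy_shift_fraction = 0,
                    false_het_fraction = 0, asm_fraction = 0,
                    ase_fraction = 0, sequencing_error_rate = 0,
                    mean_chip_depth = 1)
  ds <- simulate_dataset(cfg)
  counts <- ds$chip_reads[
    , .(n = .N), by = .(site_id, observed_base)]
  tr <- ds$truth
  m <- merge(counts, tr[, .(site_id, allele_a)], by = "site_id")
  n_a <- m[observed_base == allele_a, sum(n)]
  total <- m[, sum(n)]
  # aggregate allele-A fraction within 3 binomial SEs of 0.5, and the
  # goodness-of-fit test does not reject at alpha 0.01
  se <- sqrt(0.25 / total)
  expect_lt(abs(n_a / total - 0.5), 3 * se)
  expect_gt(binom.test(n_a, total, 0.5)$p.value, 0.01)
})

test_that("cluster-5 sites skew only H3K9me3 in expectation", {
  cfg <- sim_config(seed = 23, n_sites = 600, ashm_fraction = 0.5,
                    cluster_pattern_weights = c(0, 0, 0, 0, 1, 0),
                    occupancy_shift_fraction = 0, false_het_fraction = 0,
                    asm_fraction = 0, ase_fraction = 0,
                    sequencing_error_rate = 0, mean_chip_depth = 20,
                    mean_driver_chip_depth = 20,
                    imprinted_enrichment_fold = 1)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth[ashm_label == "cluster5"]
  m <- merge(ds$chip_reads, tr[, .(site_id, allele_a, allele_b, allele_hi)],
             by = "site_id")
  # fraction of reads on the designated (high) allele, per modification
  m[, hi_base := fifelse(allele_hi == "a", allele_a, allele_b)]
  frac <- m[observed_base == hi_base | observed_base ==
              fifelse(allele_hi == "a", allele_b, allele_a),
            .(f = mean(observed_base == hi_base), n = .N),
            by = dataset_id]
  driver <- frac[dataset_id == "H3K9me3"]
  others <- frac[dataset_id != "H3K9me3"]
  expect_gt(driver$f, 0.85)
  # every non-driver modification stays within 4 SEs of 0.5
  expect_true(all(abs(others$f - 0.5) < 4 * sqrt(0.25 / others$n)))
})

test_that("false-het sites emit a single allele up to sequencing error", {
  cfg <- sim_config(seed = 2, n_sites = 300, ashm_fraction = 0,
                    occupancy_shift_fraction = 0, false_het_fraction = 1,
                    asm_fraction = 0, ase_fraction = 0,
                    sequencing_error_rate = 0)
  ds <- simulate_dataset(cfg)
  m <- merge(ds$chip_reads, ds$truth[, .(site_id, true_allele)],
             by = "site_id")
  expect_true(all(m$observed_base == m$true_allele))
  expect_true(all(ds$truth$genotype == "hom"))
  expect_true(all(ds$sites$p_het >= 0.5))
})

test_that("CpG-disrupting ASM links methylation to the intact allele", {
  cfg <- sim_config(seed = 9, n_sites = 300, ashm_fraction = 0,
                    occupancy_shift_fraction = 0, false_het_fraction = 0,
                    asm_fraction = 0.5, cpg_disrupting_fraction = 1,
                    epiallele_fraction = 0, ase_fraction = 0,
                    sequencing_error_rate = 0, cpg_meth_linkage = 1)
  ds <- simulate_dataset(cfg)
  cpg <- ds$truth[asm_label == "cpg_snp"]
  obs <- ds$bis_obs[site_id %in% cpg$site_id & strand == "+"]
  obs <- merge(obs, cpg[, .(site_id, pos)], by = "site_id")
  adj <- obs[query_pos == pos - 1L]
  expect_gt(nrow(adj), 0)
  # methylated calls occur exactly on reads carrying the intact G allele
  expect_true(all(adj[methylated == TRUE, allele_carried == "G"]))
  expect_true(all(adj[allele_carried == "G", methylated]))
})

test_that("epiallele sites carry both alleles with differential methylation", {
  cfg <- sim_config(seed = 12, n_sites = 400, ashm_fraction = 0,
                    occupancy_shift_fraction = 0, false_het_fraction = 0,
                    asm_fraction = 0.5, cpg_disrupting_fraction = 0,
                    epiallele_fraction = 1, ase_fraction = 0,
                    sequencing_error_rate = 0,
                    epiallele_meth_levels = c(0.9, 0.1))
  ds <- simulate_dataset(cfg)
  epi <- ds$truth[asm_label == "epiallele"]
  obs <- merge(ds$bis_obs[site_id %in% epi$site_id],
               epi[, .(site_id, allele_a, allele_b)], by = "site_id")
  prop <- obs[allele_carried == allele_a | allele_carried == allele_b,
              .(m = mean(methylated)),
              by = .(carrier_a = allele_carried == allele_a)]
  expect_equal(nrow(prop), 2)          # both alleles present in reads
  expect_equal(abs(diff(prop$m)), 0.8, tolerance = 0.05)
})

test_that("asm_fraction = 0 leaves per-allele methylation balanced", {
  cfg <- sim_config(seed = 4, n_sites = 2000, ashm_fraction = 0,
                    occupancy_shift_fraction = 0, false_het_fraction = 0,
                    asm_fraction = 0, ase_fraction = 0, mean_bis_depth = 4,
                    sequencing_error_rate = 0)
  ds <- simulate_dataset(cfg)
  obs <- merge(ds$bis_obs, ds$truth[, .(site_id, allele_a)], by = "site_id")
  prop <- obs[, .(m = mean(methylated), n = .N),
              by = .(carrier_a = allele_carried == allele_a)]
  expect_lt(abs(diff(prop$m)), 4 * sqrt(0.5 / min(prop$n)))
})

test_that("ASE linkage places the configured fraction of ASHM sites near ASE", {
  cfg <- sim_config(seed = 31, n_sites = 4000, ashm_fraction = 0.05,
                    ase_fraction = 0.05, ase_link_fraction = 0.2,
                    ase_link_distance = 10000, mean_chip_depth = 0.1,
                    mean_bis_depth = 0.1, mean_rna_depth = 0.1,
                    imprinted_enrichment_fold = 1)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth
  ashm <- tr[grepl("cluster", ashm_label)]
  ase <- tr[ase_label == TRUE]
  d <- distance_to_targets(ashm, ase[, .(chrom, pos)])
  frac <- mean(d <= 10000)
  # 0.2 by construction plus a small chance-background contribution
  expect_gt(frac, 0.12)
  expect_lt(frac, 0.35)
})

test_that("degenerate skew 1.0 sends all ASE reads to one allele", {
  cfg <- sim_config(seed = 8, n_sites = 200, skew = 1, ashm_fraction = 0,
                    occupancy_shift_fraction = 0, false_het_fraction = 0,
                    asm_fraction = 0, ase_fraction = 0.5,
                    ase_link_fraction = 0)
  ds <- simulate_dataset(cfg)
  e <- merge(ds$expression, ds$truth[, .(site_id, ase_label)],
             by = "site_id")
  expect_true(all(e[ase_label == TRUE, pmin(count_a, count_b) == 0]))
})

test_that("fixtures round-trip losslessly and follow coordinate conventions", {
  ds <- simulate_dataset(tiny_config(seed = 14, n_sites = 80))
  dir <- withr::local_tempdir()
  write_fixtures(ds, dir)
  back <- read_dataset(dir)
  for (el in c("sites", "chip_reads", "bis_obs", "expression",
               "population", "known_polymorphisms", "truth")) {
    expect_equal(as.data.frame(back[[el]]), as.data.frame(ds[[el]]),
                 label = el)
  }
  expect_equal(as.data.frame(back$annotations),
               as.data.frame(ds$annotations))
  expect_equal(nrow(back$truth), 80)

  # BED half-open convention: [999, 2000) is 1-based 1000..2000
  bedfile <- file.path(dir, "one.bed")
  writeLines("chrS\t999\t2000\tr1", bedfile)
  reg <- read_bed(bedfile)
  expect_equal(reg$start, 1000L)
  expect_equal(reg$end, 2000L)
  write_bed(reg, bedfile)
  expect_equal(readLines(bedfile), "chrS\t999\t2000\tr1")
})

test_that("unwritable fixture paths raise an I/O error", {
  ds <- simulate_dataset(tiny_config(seed = 1, n_sites = 10))
  expect_error(write_fixtures(ds, "/proc/definitely/not/writable"),
               "I/O error")
})
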