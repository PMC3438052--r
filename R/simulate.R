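#' @title Synthetic multi-assay allele-resolved data with known truth
#' @name simulate_dataset
#'
#' @description
#' Generates a seeded synthetic dataset emulating everything the screen
#' consumes: a candidate heterozygote table with imputation probabilities,
#' per-read allele-resolved ChIP observations for up to 23 histone
#' modifications, bisulfite read observations with strand and methylation
#' calls, RNA and PolII allele counts, annotation tracks (imprinted loci and
#' deletion-syndrome regions), population genotype counts for HWE testing,
#' and a truth table recording every implanted effect.
#'
#' Implanted structure:
#' * ASHM sites draw reads at their driver modification(s) with allele
#'   fraction `skew` on a randomly designated allele (pattern 2 places
#'   H3K4me3 skew on one allele and H3K27me3 skew on the other, and so on
#'   for the six cluster patterns); all other modifications are balanced.
#' * Occupancy-shift sites apply the same skew to *every* modification.
#' * False-het sites are truly homozygous: every read carries one allele,
#'   apart from sequencing error.
#' * CpG-disrupting ASM sites have methylation fully linked to the
#'   CpG-intact (G) allele at the base directly adjacent to the SNP;
#'   epiallele sites show differential methylation with both alleles intact
#'   at a position 10 bp away.
#' * ASE sites are placed within `ase_link_distance` of a configured
#'   fraction of ASHM sites; ASHM sites are placed near imprinted regions
#'   at a rate solving for the configured fold enrichment.
#' * Null sites are symmetric binomial(0.5) in every assay.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ashm_dataset` with elements `sites`,
#'   `chip_reads`, `bis_obs`, `expression`, `annotations`, `population`,
#'   `known_polymorphisms`, `truth`, and `config`.
#' @seealso [write_fixtures()], [read_dataset()]
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 42, n_sites = 50))
#' ds$truth[, table(ashm_label)]
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  truth <- .simulate_truth(config)
  annotations <- attr(truth, "annotations")
  setattr(truth, "annotations", NULL)
  sites <- .sites_from_truth(truth, config)

  chip_reads <- .simulate_chip_reads(sites, truth, config)
  bis_obs <- simulate_bisulfite_observations(sites, truth, config)
  expression <- simulate_expression_counts(sites, truth, config)
  population <- .simulate_population_genotypes(sites, truth, config)
  known <- sites[, .(chrom, pos)]

  structure(list(
    sites = sites, chip_reads = chip_reads, bis_obs = bis_obs,
    expression = expression, annotations = annotations,
    population = population, known_polymorphisms = known,
    truth = truth, config = config
  ), class = "ashm_dataset")
}

# window used for the imprinted-enrichment implant (the 10 kb proximity
# scale at which the configured fold is defined)
.IMPRINT_WINDOW <- 10000

# Assign labels, positions, alleles and designated skew alleles; also
# generates the annotation tracks (positions depend on them).
.simulate_truth <- function(config) {
  n <- config$n_sites
  L <- config$chrom_length

  regions <- .simulate_annotations(config)
  imprinted <- regions[track == "imprinted"]

  n_ashm <- round(config$ashm_fraction * n)
  n_occ  <- round(config$occupancy_shift_fraction * n)
  n_hom  <- round(config$false_het_fraction * n)
  n_asm  <- round(config$asm_fraction * n)
  n_ase  <- round(config$ase_fraction * n)

  idx <- sample.int(n)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- head(idx, k)
    idx <<- idx[-seq_len(min(k, length(idx)))]
    out
  }
  i_ashm <- take(n_ashm); i_occ <- take(n_occ); i_hom <- take(n_hom)
  i_asm <- take(n_asm);  i_ase <- take(n_ase)

  ashm_label <- rep("none", n)
  if (n_ashm > 0) {
    ashm_label[i_ashm] <- sample(names(ashm_cluster_patterns()), n_ashm,
                                 replace = TRUE,
                                 prob = config$cluster_pattern_weights)
  }
  ashm_label[i_occ] <- "occupancy_shift"

  genotype <- rep("het", n)
  genotype[i_hom] <- "hom"

  asm_label <- rep("none", n)
  if (n_asm > 0) {
    asm_label[i_asm] <- ifelse(
      runif(n_asm) < config$cpg_disrupting_fraction, "cpg_snp", "epiallele")
  }

  ase_label <- rep(FALSE, n)
  ase_label[i_ase] <- TRUE

  # positions: ASHM sites near imprinted regions at the implant rate,
  # linked ASE sites near ASHM sites, everything else uniform
  pos <- .runif_int(n, L)
  if (n_ashm > 0 && nrow(imprinted) > 0 &&
      config$imprinted_enrichment_fold != 1) {
    fp <- .merge_intervals(
      pmax(1, imprinted$start - .IMPRINT_WINDOW),
      pmin(L, imprinted$end + .IMPRINT_WINDOW))
    q <- sum(fp$end - fp$start + 1) / L
    f <- config$imprinted_enrichment_fold
    a <- n_ashm / n
    fg_target <- f * q * (1 - a) / (1 - f * a)
    fg_target <- min(1, max(q, fg_target))
    p_fg <- (fg_target - q) / (1 - q)
    in_fp <- runif(n_ashm) < p_fg
    pos[i_ashm[in_fp]] <- .sample_in_intervals(sum(in_fp), fp)
  }
  if (n_ase > 0 && n_ashm > 0 && config$ase_link_fraction > 0) {
    n_link <- min(n_ase, round(config$ase_link_fraction * n_ashm))
    if (n_link > 0) {
      anchors <- sample(i_ashm, n_link)
      d <- round(runif(n_link, -config$ase_link_distance,
                       config$ase_link_distance))
      pos[i_ase[seq_len(n_link)]] <- pmin(L, pmax(1, pos[anchors] + d))
    }
  }
  # candidate SNP positions must be distinct
  while (anyDuplicated(pos)) {
    dup <- duplicated(pos)
    pos[dup] <- (pos[dup] %% L) + 1
  }

  # alleles: CpG-disrupting ASM sites carry the intact guanine as allele A
  bases <- c("A", "C", "G", "T")
  allele_a <- character(n); allele_b <- character(n)
  is_cpg <- asm_label == "cpg_snp"
  allele_a[is_cpg] <- "G"
  allele_b[is_cpg] <- sample(c("A", "C", "T"), sum(is_cpg), replace = TRUE)
  k <- sum(!is_cpg)
  a1 <- sample(bases, k, replace = TRUE)
  shift <- sample.int(3, k, replace = TRUE)
  a2 <- bases[((match(a1, bases) - 1 + shift) %% 4) + 1]
  allele_a[!is_cpg] <- a1
  allele_b[!is_cpg] <- a2

  truth <- data.table(
    site_id = paste0(config$chrom, ":", pos),
    chrom = config$chrom,
    pos = as.integer(pos),
    genotype = genotype,
    ashm_label = ashm_label,
    asm_label = asm_label,
    ase_label = ase_label,
    allele_a = allele_a,
    allele_b = allele_b,
    true_allele = ifelse(genotype == "hom",
                         ifelse(runif(n) < 0.5, allele_a, allele_b),
                         NA_character_),
    allele_hi = sample(c("a", "b"), n, replace = TRUE),
    meth_class = ifelse(runif(n) < config$unmethylated_site_fraction,
                        "unmethylated", "methylated")
  )
  truth[, near_imprinted := .min_region_distance(
    pos, regions[track == "imprinted"]) <= .IMPRINT_WINDOW]
  truth[, near_deletion := .min_region_distance(
    pos, regions[track == "deletion_syndrome"]) <= 250000]
  setattr(truth, "annotations", regions)
  truth[]
}

.sites_from_truth <- function(truth, config) {
  n <- nrow(truth)
  src <- ifelse(runif(n) < config$imputed_fraction, "imputed", "array")
  p_het <- ifelse(src == "array", 1, runif(n, 0.45, 1))
  # false hets are defined as homozygotes that slipped through at p >= 0.5
  hom <- truth$genotype == "hom"
  src[hom] <- "imputed"
  p_het[hom] <- runif(sum(hom), 0.5, 1)
  sites <- data.table(
    site_id = truth$site_id, chrom = truth$chrom, pos = truth$pos,
    allele_a = truth$allele_a, allele_b = truth$allele_b,
    p_het = p_het, source = src, validated = NA
  )
  setkey(sites, site_id)
  sites[]
}

.simulate_annotations <- function(config) {
  L <- config$chrom_length
  mk <- function(k, size, track, prefix) {
    if (k == 0) {
      return(data.table(chrom = character(0), start = integer(0),
                        end = integer(0), label = character(0),
                        track = character(0)))
    }
    start <- .runif_int(k, max(1, L - size))
    data.table(chrom = config$chrom, start = as.integer(start),
               end = as.integer(pmin(L, start + size - 1)),
               label = paste0(prefix, seq_len(k)), track = track)
  }
  rbind(
    mk(config$n_imprinted_regions, config$imprinted_region_size,
       "imprinted", "imprinted_"),
    mk(config$n_deletion_regions, config$deletion_region_size,
       "deletion_syndrome", "deletion_")
  )
}

.simulate_chip_reads <- function(sites, truth, config) {
  mods <- histone_modifications(config$n_modifications)
  n <- nrow(truth)
  m <- length(mods)
  patterns <- ashm_cluster_patterns()

  # per site x modification allele-A read fraction and mean depth: driver
  # modifications of ASHM sites are skewed and deeply covered (the mark is
  # present there), everything else sits at the flat background depth
  frac_hi <- matrix(0.5, n, m, dimnames = list(NULL, mods))
  lambda <- matrix(config$mean_chip_depth, n, m,
                   dimnames = list(NULL, mods))
  for (cl in names(patterns)) {
    rows <- which(truth$ashm_label == cl)
    if (!length(rows)) next
    pa <- intersect(patterns[[cl]]$a, mods)
    pb <- intersect(patterns[[cl]]$b, mods)
    frac_hi[rows, pa] <- config$skew
    frac_hi[rows, pb] <- 1 - config$skew
    lambda[rows, c(pa, pb)] <- config$mean_driver_chip_depth
  }
  occ <- which(truth$ashm_label == "occupancy_shift")
  frac_hi[occ, ] <- config$skew
  frac_a <- ifelse(truth$allele_hi == "a", 1, 0) * frac_hi +
    ifelse(truth$allele_hi == "a", 0, 1) * (1 - frac_hi)
  hom <- which(truth$genotype == "hom")
  frac_a[hom, ] <- ifelse(truth$true_allele[hom] == truth$allele_a[hom], 1, 0)

  depth <- rpois(n * m, as.vector(lambda))
  site_ix <- rep(rep(seq_len(n), m), depth)
  mod_ix <- rep(rep(seq_len(m), each = n), depth)
  N <- length(site_ix)
  carries_a <- rbinom(N, 1L, as.vector(frac_a)[rep(seq_len(n * m), depth)])
  true_base <- ifelse(carries_a == 1L, truth$allele_a[site_ix],
                      truth$allele_b[site_ix])
  data.table(
    site_id = truth$site_id[site_ix],
    dataset_id = mods[mod_ix],
    observed_base = .apply_seq_error(true_base, config$sequencing_error_rate),
    base_quality = .sample_quality(N, config$base_quality_distribution),
    strand = sample(c("+", "-"), N, replace = TRUE)
  )
}

#' Simulate bisulfite read observations
#'
#' Draws per-read methylation observations for every candidate site, strand
#' by strand. Reads at CpG-disrupting ASM sites are methylated only when
#' they carry the CpG-intact allele (up to the configured linkage), at a
#' query position directly adjacent to the SNP; epiallele sites carry both
#' alleles with differential methylation 10 bp away; all other sites share
#' one methylation level between alleles. Truly homozygous sites emit a
#' single allele apart from sequencing error.
#'
#' @param sites Candidate site table (from [simulate_dataset()]).
#' @param truth Truth table for the same sites.
#' @param config The [sim_config()] used.
#' @return `data.table` with columns `site_id`, `strand`, `allele_carried`,
#'   `query_pos`, `methylated`, `base_quality` (one row per read).
#' @export
simulate_bisulfite_observations <- function(sites, truth, config) {
  n <- nrow(truth)
  depth <- rpois(2L * n, config$mean_bis_depth)
  site_ix <- rep(rep(seq_len(n), 2L), depth)
  strand <- rep(rep(c("+", "-"), each = n), depth)
  N <- length(site_ix)

  is_het <- truth$genotype[site_ix] == "het"
  carries_a <- ifelse(is_het, rbinom(N, 1L, 0.5),
                      as.integer(truth$true_allele[site_ix] ==
                                   truth$allele_a[site_ix]))
  allele <- ifelse(carries_a == 1L, truth$allele_a[site_ix],
                   truth$allele_b[site_ix])
  allele <- .apply_seq_error(allele, config$sequencing_error_rate)

  lab <- truth$asm_label[site_ix]
  cpg_plus <- lab == "cpg_snp" & strand == "+"
  epi <- lab == "epiallele"

  query_pos <- truth$pos[site_ix] + 10L
  query_pos[cpg_plus] <- truth$pos[site_ix][cpg_plus] - 1L

  base_p <- ifelse(truth$meth_class[site_ix] == "unmethylated",
                   0.01, config$meth_baseline)
  p_meth <- base_p
  p_meth[cpg_plus] <- ifelse(allele[cpg_plus] == "G",
                             config$cpg_meth_linkage,
                             1 - config$cpg_meth_linkage)
  p_meth[epi] <- ifelse(carries_a[epi] == 1L,
                        config$epiallele_meth_levels[1],
                        config$epiallele_meth_levels[2])

  data.table(
    site_id = truth$site_id[site_ix],
    strand = strand,
    allele_carried = allele,
    query_pos = as.integer(query_pos),
    methylated = runif(N) < p_meth,
    base_quality = .sample_quality(N, config$base_quality_distribution)
  )
}

#' Simulate RNA and PolII allele counts
#'
#' One row per site per assay. ASE sites draw allele-A counts with the
#' configured skew toward the designated allele; homozygous sites emit a
#' single allele; all other sites are binomial(0.5).
#'
#' @inheritParams simulate_bisulfite_observations
#' @return `data.table` with columns `site_id`, `assay` (`RNA`/`PolII`),
#'   `count_a`, `count_b`.
#' @export
simulate_expression_counts <- function(sites, truth, config) {
  n <- nrow(truth)
  frac_hi <- ifelse(truth$ase_label, config$skew, 0.5)
  frac_a <- ifelse(truth$allele_hi == "a", frac_hi, 1 - frac_hi)
  hom <- truth$genotype == "hom"
  frac_a[hom] <- ifelse(truth$true_allele[hom] == truth$allele_a[hom], 1, 0)
  out <- lapply(c("RNA", "PolII"), function(assay) {
    depth <- rpois(n, config$mean_rna_depth)
    ca <- rbinom(n, depth, frac_a)
    data.table(site_id = truth$site_id, assay = assay,
               count_a = ca, count_b = depth - ca)
  })
  rbindlist(out)
}

.simulate_population_genotypes <- function(sites, truth, config) {
  n <- nrow(truth)
  p <- runif(n, 0.2, 0.8)
  violate <- runif(n) < config$hwe_violation_fraction
  counts <- matrix(0L, n, 3L)
  for (i in seq_len(n)) {
    probs <- if (violate[i]) {
      c(p[i], 0, 1 - p[i])            # duplication-like: no heterozygotes
    } else {
      c(p[i]^2, 2 * p[i] * (1 - p[i]), (1 - p[i])^2)
    }
    counts[i, ] <- rmultinom(1L, config$pop_n, probs)
  }
  data.table(site_id = truth$site_id, hom_a = counts[, 1],
             het = counts[, 2], hom_b = counts[, 3])
}

# ---- small shared helpers ----

.runif_int <- function(n, max) {
  if (n == 0) return(integer(0))
  as.integer(floor(runif(n, 1, max + 1)))
}

.sample_quality <- function(n, dist) {
  sample(as.numeric(names(dist)), n, replace = TRUE, prob = dist)
}

# replace a base with one of the other three with probability `rate`
.apply_seq_error <- function(base, rate) {
  if (rate <= 0 || !length(base)) return(base)
  bases <- c("A", "C", "G", "T")
  err <- runif(length(base)) < rate
  k <- sum(err)
  if (k > 0) {
    shift <- sample.int(3, k, replace = TRUE)
    base[err] <- bases[((match(base[err], bases) - 1 + shift) %% 4) + 1]
  }
  base
}

.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.table(start = c(out_s, ms), end = c(out_e, me))
}

.sample_in_intervals <- function(n, intervals) {
  if (n == 0) return(integer(0))
  w <- intervals$end - intervals$start + 1
  i <- sample.int(nrow(intervals), n, replace = TRUE, prob = w)
  as.integer(floor(runif(n, intervals$start[i], intervals$end[i] + 1)))
}

# minimum edge distance from positions to a region set (0 when inside)
.min_region_distance <- function(pos, regions) {
  if (nrow(regions) == 0) return(rep(Inf, length(pos)))
  d <- rep(Inf, length(pos))
  for (i in seq_len(nrow(regions))) {
    di <- pmax(0, pmax(regions$start[i] - pos, pos - regions$end[i]))
    d <- pmin(d, di)
  }
  d
}
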