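#' Histone-modification dataset labels
#'
#' The default panel of 23 well-studied histone modifications profiled by
#' ChIP-sequencing in the screen. The first `n` are used when a simulation
#' requests fewer datasets.
#'
#' @param n Number of modifications (1--23).
#' @return Character vector of modification labels.
#' @export
#' @examples
#' histone_modifications(5)
histone_modifications <- function(n = 23) {
  mods <- c(
    "H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac", "H3K9me3", "H3K27ac",
    "H3K27me3", "H3K36me3", "H3K79me1", "H3K79me2", "H4K20me1",
    "H2AK5ac", "H2BK5ac", "H2BK12ac", "H2BK15ac", "H2BK20ac",
    "H2BK120ac", "H3K4ac", "H3K14ac", "H3K18ac", "H3K23ac", "H3K56ac",
    "H4K91ac"
  )
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > length(mods)) {
    stop("n_modifications must be a single integer in 1..", length(mods))
  }
  mods[seq_len(n)]
}

#' ASHM cluster patterns
#'
#' The six recurrent patterns of allele-specific histone modification used
#' by the simulator: for each pattern, the modification(s) preferentially
#' associated with the reference ("A") allele and, where present, with the
#' opposite ("B") allele. Pattern 2, for example, places H3K4me3 on one
#' allele and H3K27me3 on the other; pattern 5 skews only H3K9me3.
#'
#' @return A list of six elements, each `list(a = <mods>, b = <mods>)`.
#' @export
ashm_cluster_patterns <- function() {
  list(
    cluster1 = list(a = "H3K4me3",  b = character(0)),
    cluster2 = list(a = "H3K4me3",  b = "H3K27me3"),
    cluster3 = list(a = "H3K27me3", b = character(0)),
    cluster4 = list(a = "H3K36me3", b = character(0)),
    cluster5 = list(a = "H3K9me3",  b = character(0)),
    cluster6 = list(a = "H3K9me3",  b = "H3K36me3")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.check_prop <- function(value, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(value) || anyNA(value)) {
    stop("configuration error: '", name, "' must be numeric", call. = FALSE)
  }
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (any(value < lo | value > hi)) {
    stop("configuration error: '", name, "' must lie in [",
         if (allow_zero) "0" else "(0", ",",
         if (allow_one) "1]" else "1)", call. = FALSE)
  }
  invisible(value)
}

.check_count <- function(value, name, min = 1) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < min || value != round(value)) {
    stop("configuration error: '", name, "' must be an integer >= ", min,
         call. = FALSE)
  }
  invisible(as.integer(value))
}

.check_pos <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0) {
    stop("configuration error: '", name, "' must be a positive number",
         call. = FALSE)
  }
  invisible(value)
}

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic multi-assay
#' generator. Defaults describe a sparse, genome-like regime: shallow
#' per-modification ChIP coverage summing to roughly 46 reads per site over
#' 23 modifications (so the 35-read background filter has teeth), bisulfite
#' coverage of 16 reads per strand (32x across both strands), and implanted
#' effect sizes (allele fraction 0.9 at driver modifications) alongside the
#' two confounders the omnibus design must reject: occupancy shifts and
#' false-positive heterozygotes.
#'
#' @param seed Integer RNG seed; the same seed yields byte-identical output.
#' @param n_sites Number of candidate heterozygous sites.
#' @param n_modifications Number of histone-modification datasets (<= 23).
#' @param chrom Chromosome name of the single synthetic chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param mean_chip_depth Mean ChIP reads per site per modification (Poisson).
#' @param mean_driver_chip_depth Mean ChIP reads at the *driver*
#'   modification(s) of ASHM sites. Immunoprecipitation coverage is high
#'   where a mark is actually present, so driver modifications are covered
#'   much more deeply than the flat cross-modification background; the
#'   omnibus test only has power against single-driver patterns in this
#'   regime.
#' @param mean_bis_depth Mean bisulfite reads per site per strand (Poisson).
#' @param mean_rna_depth Mean RNA/PolII reads per site per assay (Poisson).
#' @param ashm_fraction Proportion of sites carrying an implanted ASHM
#'   cluster pattern.
#' @param cluster_pattern_weights Length-6 vector of proportions (summing to
#'   1) assigning ASHM sites to the six cluster patterns.
#' @param skew Allele fraction at driver modifications of ASHM sites (and at
#'   ASE sites); 0.5 means no imbalance.
#' @param occupancy_shift_fraction Proportion of sites at which *every*
#'   modification is skewed identically (nucleosome-occupancy confounder).
#' @param false_het_fraction Proportion of sites that are truly homozygous
#'   despite an imputed heterozygote probability >= 0.5.
#' @param asm_fraction Proportion of sites carrying allele-specific
#'   methylation (either mechanism).
#' @param cpg_disrupting_fraction Proportion of ASM sites driven by a
#'   CpG-disrupting SNP (methylation mechanically linked to one allele).
#' @param epiallele_fraction Proportion of ASM sites that are epialleles
#'   (both alleles' DNA intact; methylation differs). Must sum to 1 with
#'   `cpg_disrupting_fraction`.
#' @param ase_fraction Proportion of sites with allele-specific expression.
#' @param ase_link_fraction Fraction of ASHM sites that receive a linked ASE
#'   site within `ase_link_distance`.
#' @param ase_link_distance Linkage distance in bp for ASE placement.
#' @param sequencing_error_rate Per-base probability that a read reports a
#'   base other than the allele it carries.
#' @param base_quality_distribution Named numeric vector of Phred values to
#'   sampling weights; the default two-point \{Q10: 0.1, Q30: 0.9\} exercises
#'   the quality-13 filter.
#' @param meth_baseline Methylation level at methylated null positions.
#' @param unmethylated_site_fraction Fraction of sites whose methylation
#'   query position is essentially unmethylated (exercises the
#'   at-least-partial-methylation rule).
#' @param cpg_meth_linkage Methylation probability on reads carrying the
#'   CpG-intact allele at CpG-disrupting ASM sites.
#' @param epiallele_meth_levels Length-2 vector: methylation probability on
#'   each allele at epiallele sites.
#' @param n_imprinted_regions,imprinted_region_size Geometry of the
#'   imprinted-locus annotation track.
#' @param imprinted_enrichment_fold Implanted fold enrichment of ASHM sites
#'   within 10 kb of imprinted regions, measured against the all-sites
#'   background. Requires `imprinted_enrichment_fold * ashm_fraction < 1`.
#' @param n_deletion_regions,deletion_region_size Geometry of the
#'   deletion-syndrome annotation track (placed uniformly, no implant).
#' @param hwe_violation_fraction Proportion of sites whose population
#'   genotype counts violate Hardy-Weinberg equilibrium (duplication-like
#'   artefact used by the QC filter).
#' @param pop_n Number of population individuals genotyped per site.
#' @param imputed_fraction Fraction of candidate sites that are imputed (the
#'   rest are array-genotyped with p_het = 1).
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_sites = 100)
#' cfg$skew
sim_config <- function(seed = 1L,
                       n_sites = 1000L,
                       n_modifications = 23L,
                       chrom = "chrS",
                       chrom_length = 2e7,
                       mean_chip_depth = 2,
                       mean_driver_chip_depth = 60,
                       mean_bis_depth = 16,
                       mean_rna_depth = 20,
                       ashm_fraction = 0.05,
                       cluster_pattern_weights = rep(1 / 6, 6),
                       skew = 0.9,
                       occupancy_shift_fraction = 0.05,
                       false_het_fraction = 0.05,
                       asm_fraction = 0.05,
                       cpg_disrupting_fraction = 0.8,
                       epiallele_fraction = 0.2,
                       ase_fraction = 0.05,
                       ase_link_fraction = 0.2,
                       ase_link_distance = 10000,
                       sequencing_error_rate = 0.001,
                       base_quality_distribution = c("10" = 0.1, "30" = 0.9),
                       meth_baseline = 0.7,
                       unmethylated_site_fraction = 0.3,
                       cpg_meth_linkage = 0.98,
                       epiallele_meth_levels = c(0.95, 0.05),
                       n_imprinted_regions = 5L,
                       imprinted_region_size = 20000,
                       imprinted_enrichment_fold = 10,
                       n_deletion_regions = 4L,
                       deletion_region_size = 100000,
                       hwe_violation_fraction = 0.02,
                       pop_n = 60L,
                       imputed_fraction = 0.9) {
  cfg <- list(
    seed = .check_count(seed, "seed", min = 0),
    n_sites = .check_count(n_sites, "n_sites"),
    n_modifications = .check_count(n_modifications, "n_modifications"),
    chrom = chrom,
    chrom_length = .check_pos(chrom_length, "chrom_length"),
    mean_chip_depth = .check_pos(mean_chip_depth, "mean_chip_depth"),
    mean_driver_chip_depth = .check_pos(mean_driver_chip_depth,
                                        "mean_driver_chip_depth"),
    mean_bis_depth = .check_pos(mean_bis_depth, "mean_bis_depth"),
    mean_rna_depth = .check_pos(mean_rna_depth, "mean_rna_depth"),
    ashm_fraction = .check_prop(ashm_fraction, "ashm_fraction"),
    cluster_pattern_weights = cluster_pattern_weights,
    skew = .check_prop(skew, "skew"),
    occupancy_shift_fraction =
      .check_prop(occupancy_shift_fraction, "occupancy_shift_fraction"),
    false_het_fraction = .check_prop(false_het_fraction, "false_het_fraction"),
    asm_fraction = .check_prop(asm_fraction, "asm_fraction"),
    cpg_disrupting_fraction =
      .check_prop(cpg_disrupting_fraction, "cpg_disrupting_fraction"),
    epiallele_fraction = .check_prop(epiallele_fraction, "epiallele_fraction"),
    ase_fraction = .check_prop(ase_fraction, "ase_fraction"),
    ase_link_fraction = .check_prop(ase_link_fraction, "ase_link_fraction"),
    ase_link_distance = .check_pos(ase_link_distance, "ase_link_distance"),
    sequencing_error_rate =
      .check_prop(sequencing_error_rate, "sequencing_error_rate"),
    base_quality_distribution = base_quality_distribution,
    meth_baseline = .check_prop(meth_baseline, "meth_baseline"),
    unmethylated_site_fraction =
      .check_prop(unmethylated_site_fraction, "unmethylated_site_fraction"),
    cpg_meth_linkage = .check_prop(cpg_meth_linkage, "cpg_meth_linkage"),
    epiallele_meth_levels = epiallele_meth_levels,
    n_imprinted_regions =
      .check_count(n_imprinted_regions, "n_imprinted_regions", min = 0),
    imprinted_region_size = .check_pos(imprinted_region_size,
                                       "imprinted_region_size"),
    imprinted_enrichment_fold = .check_pos(imprinted_enrichment_fold,
                                           "imprinted_enrichment_fold"),
    n_deletion_regions =
      .check_count(n_deletion_regions, "n_deletion_regions", min = 0),
    deletion_region_size = .check_pos(deletion_region_size,
                                      "deletion_region_size"),
    hwe_violation_fraction =
      .check_prop(hwe_violation_fraction, "hwe_violation_fraction"),
    pop_n = .check_count(pop_n, "pop_n"),
    imputed_fraction = .check_prop(imputed_fraction, "imputed_fraction")
  )

  w <- cfg$cluster_pattern_weights
  if (!is.numeric(w) || length(w) != 6L || anyNA(w) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-8) {
    stop("configuration error: 'cluster_pattern_weights' must be 6 ",
         "non-negative proportions summing to 1", call. = FALSE)
  }
  if (abs(cfg$cpg_disrupting_fraction + cfg$epiallele_fraction - 1) > 1e-8) {
    stop("configuration error: 'cpg_disrupting_fraction' and ",
         "'epiallele_fraction' must sum to 1 (they partition ASM sites)",
         call. = FALSE)
  }
  q <- cfg$base_quality_distribution
  if (!is.numeric(q) || is.null(names(q)) || any(q < 0) || sum(q) <= 0 ||
      anyNA(suppressWarnings(as.numeric(names(q))))) {
    stop("configuration error: 'base_quality_distribution' must be a named ",
         "numeric vector of Phred values to weights", call. = FALSE)
  }
  e <- cfg$epiallele_meth_levels
  if (!is.numeric(e) || length(e) != 2L || any(e < 0 | e > 1)) {
    stop("configuration error: 'epiallele_meth_levels' must be two ",
         "probabilities", call. = FALSE)
  }
  tot <- cfg$ashm_fraction + cfg$occupancy_shift_fraction +
    cfg$false_het_fraction + cfg$asm_fraction + cfg$ase_fraction
  if (tot > 1) {
    stop("configuration error: site-label fractions (ashm_fraction + ",
         "occupancy_shift_fraction + false_het_fraction + asm_fraction + ",
         "ase_fraction) must sum to at most 1", call. = FALSE)
  }
  if (cfg$imprinted_enrichment_fold * cfg$ashm_fraction >= 1 &&
      cfg$n_imprinted_regions > 0 && cfg$ashm_fraction > 0 &&
      cfg$imprinted_enrichment_fold > 1) {
    stop("configuration error: 'imprinted_enrichment_fold' x 'ashm_fraction'",
         " must be < 1 for the fold to be attainable against an all-sites ",
         "background", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Pipeline thresholds
#'
#' Central container for every numeric threshold used by the screen:
#' imputation probability and bisulfite read support for heterozygote
#' validation, the Phred base-quality floor, significance cut-offs for the
#' ASHM omnibus, ASM and ASE tests, the 35-read ChIP coverage floor for the
#' background set, the Hardy-Weinberg QC alpha, proximity windows, and the
#' adjacency distance used to classify ASM mechanism.
#'
#' @param p_het_min Minimum imputed heterozygote probability.
#' @param min_bis_reads_per_allele Minimum bisulfite reads per allele.
#' @param min_base_quality Phred floor; bases below are ignored.
#' @param ashm_alpha Significance threshold for the ASHM omnibus test.
#' @param asm_alpha Significance threshold for the ASM Fisher test.
#' @param ase_alpha Significance threshold for the ASE/ASP binomial test.
#' @param min_chip_coverage Total ChIP reads required for the background set.
#' @param hwe_alpha Hardy-Weinberg exclusion threshold.
#' @param windows Proximity windows (bp) for enrichment analyses.
#' @param adjacency_bp Distance (bp) within which a polymorphism counts as
#'   directly adjacent to an ASM call.
#' @return A validated list of class `pipeline_thresholds`.
#' @export
pipeline_thresholds <- function(p_het_min = 0.5,
                                min_bis_reads_per_allele = 2L,
                                min_base_quality = 13,
                                ashm_alpha = 1e-7,
                                asm_alpha = 1e-8,
                                ase_alpha = 1e-7,
                                min_chip_coverage = 35L,
                                hwe_alpha = 0.05,
                                windows = c(10000, 250000, 500000, 1e6),
                                adjacency_bp = 1L) {
  for (a in c(ashm_alpha, asm_alpha, ase_alpha, hwe_alpha)) {
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1) {
      stop("configuration error: significance thresholds must lie in (0,1)",
           call. = FALSE)
    }
  }
  .check_prop(p_het_min, "p_het_min")
  .check_count(min_bis_reads_per_allele, "min_bis_reads_per_allele", min = 0)
  .check_count(min_chip_coverage, "min_chip_coverage", min = 0)
  .check_count(adjacency_bp, "adjacency_bp", min = 0)
  if (!is.numeric(min_base_quality) || min_base_quality < 0) {
    stop("configuration error: 'min_base_quality' must be >= 0",
         call. = FALSE)
  }
  if (!is.numeric(windows) || any(windows <= 0)) {
    stop("configuration error: 'windows' must be positive distances",
         call. = FALSE)
  }
  structure(list(
    p_het_min = p_het_min,
    min_bis_reads_per_allele = as.integer(min_bis_reads_per_allele),
    min_base_quality = min_base_quality,
    ashm_alpha = ashm_alpha,
    asm_alpha = asm_alpha,
    ase_alpha = ase_alpha,
    min_chip_coverage = as.integer(min_chip_coverage),
    hwe_alpha = hwe_alpha,
    windows = windows,
    adjacency_bp = as.integer(adjacency_bp)
  ), class = "pipeline_thresholds")
}

#' Load a pipeline configuration file
#'
#' Reads a flat key-value (YAML) configuration file holding any mixture of
#' [sim_config()] and [pipeline_thresholds()] keys. Absent keys take their
#' defaults; unknown keys are an error. The fully resolved configuration is
#' echoed to the message stream.
#'
#' @param path Path to a YAML key-value file (may be empty).
#' @return `list(sim = <sim_config>, thresholds = <pipeline_thresholds>)`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration error: file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("configuration error: malformed config file '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    stop("configuration error: config file must contain key: value pairs",
         call. = FALSE)
  }
  sim_keys <- names(formals(sim_config))
  thr_keys <- names(formals(pipeline_thresholds))
  unknown <- setdiff(names(raw), c(sim_keys, thr_keys))
  if (length(unknown)) {
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sim <- do.call(sim_config, raw[intersect(names(raw), sim_keys)])
  thr <- do.call(pipeline_thresholds, raw[intersect(names(raw), thr_keys)])
  msg <- c("resolved configuration:",
           paste0("  ", names(sim), " = ",
                  vapply(sim, function(x) paste(format(x), collapse = ","),
                         character(1))),
           paste0("  ", names(thr), " = ",
                  vapply(thr, function(x) paste(format(x), collapse = ","),
                         character(1))))
  message(paste(msg, collapse = "\n"))
  list(sim = sim, thresholds = thr)
}
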