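#' Reduce an allele-by-dataset table for the omnibus test
#'
#' Removes rows (alleles) and columns (datasets) that sum to zero,
#' recording the original and reduced dimensions. Empty tables are flagged
#' untestable.
#'
#' @param tensor Allele-by-dataset count matrix from [site_tensor()].
#' @return The reduced matrix with attributes `original_dim`,
#'   `reduced_dim`, `untestable`.
#' @export
build_contingency_table <- function(tensor) {
  tensor <- as.matrix(tensor)
  orig <- dim(tensor)
  if (length(tensor) == 0 || sum(tensor) == 0) {
    out <- matrix(0L, 0, 0)
    attr(out, "original_dim") <- orig
    attr(out, "reduced_dim") <- c(0L, 0L)
    attr(out, "untestable") <- TRUE
    return(out)
  }
  out <- tensor[rowSums(tensor) > 0, colSums(tensor) > 0, drop = FALSE]
  attr(out, "original_dim") <- orig
  attr(out, "reduced_dim") <- dim(out)
  attr(out, "untestable") <- nrow(out) < 2 || ncol(out) < 2
  out
}

#' Omnibus cross-dataset allelic-imbalance test
#'
#' Two-sided exact test for independence of allele and dataset on a reduced
#' contingency table: significance means the proportion of reads carrying a
#' particular allele differs between at least two datasets. Tables with
#' fewer than two rows or columns (true homozygotes expose a single allele
#' row) are untestable and return p = 1. The exact network algorithm is
#' used while the complexity budget allows (table total at most
#' `exact_max_total`); beyond it, or if the exact computation fails, a
#' Pearson chi-squared approximation (no continuity correction) is returned
#' and flagged approximate.
#'
#' @param table Reduced table from [build_contingency_table()] (a plain
#'   matrix is reduced on the fly).
#' @param exact_max_total Largest table total for which the exact route is
#'   attempted (default 120).
#' @param workspace Workspace passed to the exact network algorithm.
#' @return List with `p_value`, `method` (`"exact"`, `"chisq"`, or
#'   `"untestable"`), and `approximate` (logical).
#' @export
#' @examples
#' test_cross_dataset_imbalance(matrix(c(5, 5, 5, 5), 2, 2))$p_value
test_cross_dataset_imbalance <- function(table, exact_max_total = 120,
                                         workspace = 2e6) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (is.null(attr(table, "reduced_dim"))) {
    table <- build_contingency_table(table)
  }
  if (isTRUE(attr(table, "untestable"))) {
    return(list(p_value = 1, method = "untestable", approximate = FALSE))
  }
  total <- sum(table)
  if (total <= exact_max_total) {
    p <- tryCatch(
      fisher.test(table, workspace = workspace)$p.value,
      error = function(e) NULL)
    if (!is.null(p)) {
      return(list(p_value = min(1, p), method = "exact",
                  approximate = FALSE))
    }
  }
  p <- suppressWarnings(chisq.test(table, correct = FALSE)$p.value)
  list(p_value = if (is.na(p)) 1 else p, method = "chisq",
       approximate = TRUE)
}

#' Per-modification allelic imbalance
#'
#' Two-sided binomial test of each dataset's counts for the site's two
#' validated alleles against the expected 50/50 ratio. Datasets with zero
#' coverage on both alleles yield p = 1 and no favored allele; the favored
#' allele is the one with the larger count (ties favor neither).
#'
#' @param tensor Allele-by-dataset count matrix ([site_tensor()]).
#' @param allele_a,allele_b The site's two validated alleles (row names).
#' @param datasets Datasets to report (default: the tensor's columns).
#' @return `data.table` with `modification`, `count_a`, `count_b`,
#'   `binomial_p`, `favored_allele`.
#' @export
per_modification_imbalance <- function(tensor, allele_a, allele_b,
                                       datasets = colnames(tensor)) {
  get_row <- function(allele) {
    if (allele %in% rownames(tensor)) tensor[allele, , drop = TRUE]
    else setNames(rep(0L, ncol(tensor)), colnames(tensor))
  }
  ca <- get_row(allele_a)
  cb <- get_row(allele_b)
  out <- data.table(
    modification = datasets,
    count_a = as.integer(ca[datasets]),
    count_b = as.integer(cb[datasets])
  )
  out[is.na(count_a), count_a := 0L]
  out[is.na(count_b), count_b := 0L]
  out[, binomial_p := mapply(function(a, b) {
    if (a + b == 0) 1 else binom.test(a, a + b, 0.5)$p.value
  }, count_a, count_b)]
  out[, favored_allele := fifelse(count_a > count_b, allele_a,
                                  fifelse(count_b > count_a, allele_b,
                                          NA_character_))]
  out[]
}

#' Select the high-coverage background site set
#'
#' Every validated site whose summed histone-modification coverage is at
#' least `min_total_coverage` reads. This set is the denominator for all
#' enrichment analyses: enrichment at called sites is measured relative to
#' heterozygous positions at which the phenomenon was detectable at all.
#'
#' @param coverage Per-site coverage from [chip_coverage()] (or an
#'   `allele_counts` table, summed on the fly).
#' @param min_total_coverage Coverage floor (default 35, inclusive).
#' @return Character vector of background `site_id`s.
#' @export
select_background_sites <- function(coverage, min_total_coverage = 35L) {
  cov <- as.data.table(coverage)
  if (!"total_coverage" %in% names(cov)) {
    cov <- chip_coverage(cov)
  }
  cov[total_coverage >= min_total_coverage, site_id]
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on genotype counts: conditional on the observed
#' allele counts, sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Deviation from HWE at a called SNP flags genotyping artefacts such as
#' hidden duplications and copy-number variation. Monomorphic samples
#' return p = 1.
#'
#' @param hom_a,het,hom_b Genotype counts (AA, AB, BB), or a length-3
#'   vector as the first argument.
#' @return Exact p-value.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(20, 0, 20)
hwe_exact_test <- function(hom_a, het = NULL, hom_b = NULL) {
  if (is.null(het) && length(hom_a) == 3L) {
    het <- hom_a[2]; hom_b <- hom_a[3]; hom_a <- hom_a[1]
  }
  counts <- c(hom_a, het, hom_b)
  if (anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("all-zero genotype counts", call. = FALSE)
  n_a <- 2 * hom_a + het
  n_b <- 2 * hom_b + het
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each heterozygote count given allele
  # counts (Levene's distribution)
  logp <- vapply(hets, function(h) {
    ha <- (n_a - h) / 2
    hb <- (n_b - h) / 2
    lgamma(n + 1) - lgamma(ha + 1) - lgamma(h + 1) - lgamma(hb + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

#' Apply Hardy-Weinberg and coverage QC to ASHM calls
#'
#' Computes the exact HWE p-value per called SNP from population genotype
#' counts and sets `passed_qc = FALSE` where it falls below `hwe_alpha`
#' (strict inequality: p equal to the threshold is retained). Calls without
#' population data are recorded as not assessed and left unchanged. The
#' coverage QC compares mean bisulfite depth at called sites against the
#' genome-wide mean and *reports* the ratio (duplicated regions show excess
#' depth) without filtering; it is attached as the `coverage_qc` attribute.
#'
#' @param calls ASHM call table (needs `site_id`; `significant` is
#'   recomputed when `omnibus_p` is present).
#' @param population_genotypes Table `site_id`, `hom_a`, `het`, `hom_b`.
#' @param hwe_alpha Exclusion threshold (default 0.05).
#' @param bis_coverage Optional table `site_id`, `depth` of bisulfite
#'   coverage used for the report.
#' @param ashm_alpha Significance threshold used when recomputing
#'   `significant`.
#' @return `calls` with `hwe_p` and `passed_qc` columns (and updated
#'   `significant`), plus a `coverage_qc` attribute when coverage was
#'   supplied.
#' @export
apply_qc <- function(calls, population_genotypes, hwe_alpha = 0.05,
                     bis_coverage = NULL, ashm_alpha = 1e-7) {
  calls <- as.data.table(calls)
  calls[, passed_qc := TRUE]
  if (is.null(population_genotypes) || nrow(population_genotypes) == 0) {
    message("no population genotype data: HWE QC not assessed")
    calls[, hwe_p := NA_real_]
  } else {
    pop <- as.data.table(population_genotypes)
    pop <- pop[, .(site_id, hwe_p = mapply(hwe_exact_test, hom_a, het,
                                           hom_b))]
    calls <- merge(calls, pop, by = "site_id", all.x = TRUE, sort = FALSE)
    n_missing <- sum(is.na(calls$hwe_p))
    if (n_missing > 0) {
      message(n_missing, " call(s) without population genotypes: ",
              "HWE QC not assessed for them")
    }
    calls[!is.na(hwe_p) & hwe_p < hwe_alpha, passed_qc := FALSE]
  }
  if ("omnibus_p" %in% names(calls)) {
    calls[, significant := omnibus_p < ashm_alpha & passed_qc]
  }
  if (!is.null(bis_coverage) && nrow(bis_coverage) > 0) {
    cov <- as.data.table(bis_coverage)
    called_mean <- cov[site_id %chin% calls$site_id, mean(depth)]
    genome_mean <- cov[, mean(depth)]
    setattr(calls, "coverage_qc", list(
      mean_called = called_mean, mean_genome = genome_mean,
      ratio = called_mean / genome_mean))
  }
  calls[]
}

#' Call allele-specific histone modification
#'
#' Runs the full ASHM procedure over an allele-count table: per site, the
#' alleles-by-modifications contingency table is built, zero margins are
#' removed, the omnibus exact test is applied, and per-modification
#' binomial imbalances are computed for the site's two validated alleles.
#' Total ChIP coverage and the untestable/approximate status are recorded.
#' Hardy-Weinberg QC is applied afterwards with [apply_qc()].
#'
#' @param counts `allele_counts` table from [count_alleles()].
#' @param sites Validated site table (only rows with `validated == TRUE`
#'   are tested when the column is present).
#' @param ashm_alpha Omnibus significance threshold (default 1e-7).
#' @param min_total_coverage Background coverage floor (default 35).
#' @param exact_max_total Complexity budget of the exact omnibus route.
#' @param per_modification Also compute the per-modification binomial
#'   imbalances (needed for clustering; switch off for omnibus-only
#'   screens).
#' @return List with `calls` (one row per tested site: `omnibus_p`,
#'   `method`, `total_coverage`, `n_alleles`, `n_datasets`, `untestable`,
#'   `passed_qc`, `significant`) and `per_modification` (long table of
#'   binomial results for profile building).
#' @export
call_ashm <- function(counts, sites, ashm_alpha = 1e-7,
                      min_total_coverage = 35L, exact_max_total = 120,
                      per_modification = TRUE) {
  sites <- as.data.table(sites)
  if ("validated" %in% names(sites) && !all(is.na(sites$validated))) {
    sites <- sites[validated == TRUE]
  }
  cov <- chip_coverage(counts)
  test_ids <- sites$site_id
  calls <- vector("list", length(test_ids))
  per_mod <- vector("list", length(test_ids))
  for (i in seq_along(test_ids)) {
    sid <- test_ids[i]
    tensor <- site_tensor(counts, sid, sites)
    tab <- build_contingency_table(tensor)
    res <- test_cross_dataset_imbalance(tab, exact_max_total)
    srow <- sites[site_id == sid]
    calls[[i]] <- data.table(
      site_id = sid,
      omnibus_p = res$p_value,
      method = res$method,
      n_alleles = attr(tab, "reduced_dim")[1],
      n_datasets = attr(tab, "reduced_dim")[2],
      untestable = res$method == "untestable",
      total_coverage = sum(tensor)
    )
    if (per_modification && nrow(tab) >= 1 && ncol(tensor) >= 1) {
      pm <- per_modification_imbalance(tensor, srow$allele_a,
                                       srow$allele_b)
      pm[, site_id := sid]
      per_mod[[i]] <- pm
    }
  }
  calls <- rbindlist(calls)
  per_mod <- rbindlist(per_mod)
  calls[, passed_qc := TRUE]
  calls[, significant := omnibus_p < ashm_alpha & passed_qc]
  message("ASHM: tested ", nrow(calls), " site(s); ",
          sum(calls$total_coverage >= min_total_coverage),
          " at >= ", min_total_coverage, "x coverage; ",
          sum(calls$significant), " significant at ",
          format(ashm_alpha))
  list(calls = calls[], per_modification = per_mod)
}
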