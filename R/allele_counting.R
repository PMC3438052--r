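#' Count alleles per site and dataset under the base-quality filter
#'
#' Aggregates per-read observations into per-site, per-dataset allele
#' counts. Observations with Phred quality below `min_base_quality` are
#' ignored. Bases matching neither site allele are retained as additional
#' allele rows (up to the four possible bases), preserving the
#' alleles-by-datasets table shape used by the omnibus test.
#'
#' @param reads Read-observation table (`site_id`, `dataset_id`,
#'   `observed_base`, `base_quality`, `strand`).
#' @param sites Validated site table (`site_id`, `allele_a`, `allele_b`).
#' @param min_base_quality Phred floor (default 13; bases with quality
#'   < 13 are ignored).
#' @param datasets Permitted dataset labels; observations with a
#'   `dataset_id` outside this set are an error. Defaults to the full
#'   23-modification panel.
#' @return A long count table of class `allele_counts`: `site_id`, `base`,
#'   `dataset_id`, `n`. Use [site_tensor()] for the per-site matrix view
#'   and [chip_coverage()] for per-site totals.
#' @export
count_alleles <- function(reads, sites, min_base_quality = 13,
                          datasets = histone_modifications()) {
  reads <- as.data.table(reads)
  bad <- setdiff(unique(reads$dataset_id), datasets)
  if (length(bad)) {
    stop("unknown dataset_id(s): ", paste(bad, collapse = ", "),
         "; permitted labels: ", paste(datasets, collapse = ", "),
         call. = FALSE)
  }
  keep <- reads[base_quality >= min_base_quality &
                  site_id %chin% sites$site_id]
  counts <- keep[, .(n = .N), by = .(site_id, base = observed_base,
                                     dataset_id)]
  setkey(counts, site_id)
  setattr(counts, "class", c("allele_counts", class(counts)))
  setattr(counts, "datasets", datasets)
  counts
}

#' Per-site allele-by-dataset count matrix
#'
#' Materialises one site's counts as a matrix with one row per observed
#' allele (site alleles first) and one column per dataset that has any
#' reads. Sites with no reads yield a 0-row matrix.
#'
#' @param counts An `allele_counts` table from [count_alleles()].
#' @param site A `site_id`.
#' @param sites Optional site table used to order the site's own alleles
#'   first.
#' @return Integer matrix, rows = alleles, columns = datasets.
#' @export
site_tensor <- function(counts, site, sites = NULL) {
  x <- counts[site_id == site]
  if (nrow(x) == 0) {
    return(matrix(0L, 0, 0))
  }
  alleles <- sort(unique(x$base))
  if (!is.null(sites)) {
    own <- unlist(sites[site_id == site, .(allele_a, allele_b)])
    alleles <- c(intersect(own, alleles), setdiff(alleles, own))
  }
  ds <- sort(unique(x$dataset_id))
  m <- matrix(0L, length(alleles), length(ds),
              dimnames = list(alleles, ds))
  m[cbind(match(x$base, alleles), match(x$dataset_id, ds))] <- x$n
  m
}

#' Total ChIP coverage per site
#'
#' Sum of allele counts over all histone-modification datasets, the
#' quantity the 35-read background filter is applied to.
#'
#' @param counts An `allele_counts` table.
#' @return `data.table` with `site_id`, `total_coverage`.
#' @export
chip_coverage <- function(counts) {
  counts[, .(total_coverage = sum(n)), by = site_id]
}

#' Extract usable methylation observations
#'
#' Applies the strand-aware exclusion rules to raw bisulfite read
#' observations:
#' * heterozygous sites whose two alleles are C/T are excluded on the plus
#'   strand, and G/A sites on the minus strand (bisulfite C-to-T conversion
#'   makes the alleles indistinguishable on that strand);
#' * methylation is never called at a known polymorphic position;
#' * bases below the quality floor are ignored.
#'
#' @param bisulfite_reads Raw observation table from
#'   [simulate_bisulfite_observations()] or an external adapter
#'   (`site_id`, `strand`, `allele_carried`, `query_pos`, `methylated`,
#'   `base_quality`).
#' @param sites Candidate site table (`site_id`, `allele_a`, `allele_b`).
#' @param known_polymorphic_positions Table with `chrom`, `pos` of known
#'   SNPs (1-based); methylation query positions falling on these are
#'   dropped.
#' @param min_base_quality Phred floor (default 13).
#' @return Filtered `MethylObservation` table with the site's `chrom`
#'   joined in.
#' @export
extract_methylation_observations <- function(bisulfite_reads, sites,
                                             known_polymorphic_positions,
                                             min_base_quality = 13) {
  obs <- as.data.table(bisulfite_reads)
  obs <- merge(obs, sites[, .(site_id, chrom, allele_a, allele_b)],
               by = "site_id", sort = FALSE)
  obs <- obs[base_quality >= min_base_quality]
  pair <- paste(pmin(obs$allele_a, obs$allele_b),
                pmax(obs$allele_a, obs$allele_b))
  ambiguous <- (pair == "C T" & obs$strand == "+") |
    (pair == "A G" & obs$strand == "-")
  obs <- obs[!ambiguous]
  if (!is.null(known_polymorphic_positions) &&
      nrow(known_polymorphic_positions)) {
    known <- as.data.table(known_polymorphic_positions)
    key <- paste0(known$chrom, ":", known$pos)
    obs <- obs[!paste0(chrom, ":", query_pos) %chin% key]
  }
  obs[, .(site_id, chrom, strand, allele_carried, query_pos, methylated,
          base_quality, allele_a, allele_b)]
}
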