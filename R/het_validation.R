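#' Bisulfite allele support per candidate site
#'
#' Counts, per site, the bisulfite reads carrying each of the site's two
#' alleles. Methylation status and strand are ignored; only the allele
#' carried matters. Observations should already have passed the extraction
#' rules of [extract_methylation_observations()] (quality floor and
#' exclusion of C/T-ambiguous strands), so conversion-ambiguous reads never
#' contribute support.
#'
#' @param methyl_obs Methylation observation table (`site_id`,
#'   `allele_carried`, ...).
#' @param sites Candidate site table with `allele_a` / `allele_b`.
#' @return `data.table` with columns `site_id`, `n_a`, `n_b` (one row per
#'   site present in `methyl_obs`).
#' @export
bisulfite_allele_support <- function(methyl_obs, sites) {
  obs <- merge(methyl_obs[, .(site_id, allele_carried)],
               sites[, .(site_id, allele_a, allele_b)], by = "site_id")
  obs[, .(n_a = sum(allele_carried == allele_a),
          n_b = sum(allele_carried == allele_b)), by = site_id]
}

#' Filter imputed heterozygote candidates by bisulfite allele support
#'
#' Retains candidates with an imputed heterozygote probability of at least
#' `p_min` *and* at least `min_reads_per_allele` bisulfite reads carrying
#' each of the two alleles. Sites missing from the support table are
#' treated as having zero support and excluded (a message reports how
#' many). Candidates failing validation are flagged `validated = FALSE` and
#' must be dropped from all downstream calling.
#'
#' With `require_imputation = FALSE` the probability criterion is skipped:
#' sites are accepted on read support alone, the mode used when no
#' genotyping-array/imputation input exists and putative heterozygotes are
#' identified directly from bisulfite data at known-polymorphism positions.
#'
#' @param candidates Candidate `HetSite` table (`site_id`, `p_het`, ...).
#' @param bis_support Per-site allele support from
#'   [bisulfite_allele_support()].
#' @param p_min Minimum heterozygote probability (default 0.5, inclusive).
#' @param min_reads_per_allele Minimum reads per allele (default 2,
#'   inclusive).
#' @param require_imputation Apply the `p_het` criterion? (default `TRUE`).
#' @return The candidate table with a logical `validated` column.
#' @export
#' @examples
#' sites <- data.table::data.table(
#'   site_id = c("s1", "s2"), chrom = "chrS", pos = c(10L, 20L),
#'   allele_a = "A", allele_b = "G", p_het = c(0.5, 0.49),
#'   source = "imputed")
#' support <- data.table::data.table(site_id = c("s1", "s2"),
#'                                   n_a = c(2L, 100L), n_b = c(2L, 100L))
#' filter_het_sites(sites, support)[, .(site_id, validated)]
filter_het_sites <- function(candidates, bis_support, p_min = 0.5,
                             min_reads_per_allele = 2L,
                             require_imputation = TRUE) {
  stopifnot(is.data.frame(candidates), is.data.frame(bis_support))
  out <- as.data.table(candidates)
  sup <- as.data.table(bis_support)
  out <- merge(out[, setdiff(names(out), c("n_a", "n_b", "validated")),
                   with = FALSE],
               sup[, .(site_id, n_a, n_b)],
               by = "site_id", all.x = TRUE, sort = FALSE)
  n_missing <- sum(is.na(out$n_a))
  if (n_missing > 0) {
    message(n_missing, " candidate site(s) missing from bisulfite support; ",
            "treated as zero support and excluded")
    out[is.na(n_a), `:=`(n_a = 0L, n_b = 0L)]
  }
  out[, validated := n_a >= min_reads_per_allele &
        n_b >= min_reads_per_allele]
  if (require_imputation) {
    out[, validated := validated & p_het >= p_min]
  }
  out[]
}

#' Evaluate heterozygote calling against truth genotypes
#'
#' Treats `validated == TRUE` as a positive heterozygote call and computes
#' the confusion counts over all supplied candidates, with the derived
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, and positive
#' predictive value `tp/(tp+fp)`.
#'
#' @param calls Candidate table carrying a `validated` column (from
#'   [filter_het_sites()]).
#' @param truth_genotypes Table with `site_id` and `genotype`
#'   (`"het"`/`"hom"`) covering every candidate.
#' @return List of class `het_call_performance` with fields `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `ppv`.
#' @export
evaluate_het_calls <- function(calls, truth_genotypes) {
  calls <- as.data.table(calls)
  if (nrow(calls) == 0) {
    stop("empty candidate set: nothing to evaluate", call. = FALSE)
  }
  truth <- as.data.table(truth_genotypes)
  j <- merge(calls[, .(site_id, validated)],
             truth[, .(site_id, genotype)], by = "site_id")
  if (nrow(j) < nrow(calls)) {
    stop("truth genotypes must cover all candidate positions",
         call. = FALSE)
  }
  tp <- j[, sum(validated & genotype == "het")]
  fp <- j[, sum(validated & genotype != "het")]
  tn <- j[, sum(!validated & genotype != "het")]
  fn <- j[, sum(!validated & genotype == "het")]
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 1,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  ), class = "het_call_performance")
}

#' @export
print.het_call_performance <- function(x, ...) {
  cat(sprintf(
    "heterozygote calling: tp=%d fp=%d tn=%d fn=%d\n  sensitivity %.1f%%  specificity %.1f%%  ppv %.1f%%\n",
    x$tp, x$fp, x$tn, x$fn, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$ppv))
  invisible(x)
}
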