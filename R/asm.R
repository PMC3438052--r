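#' Fisher exact test for one ASM 2x2 table
#'
#' Two-sided Fisher exact test on an allele-by-methylation-status table
#' (two-sidedness by summation of hypergeometric probabilities no larger
#' than the observed table's). Tables with a zero margin are untestable and
#' return p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts, rows = alleles,
#'   columns = methylated/unmethylated.
#' @return Two-sided p-value.
#' @export
#' @examples
#' test_asm_site(matrix(c(10, 0, 0, 10), 2, 2))
test_asm_site <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(1)
  }
  fisher.test(table)$p.value
}

#' Call strand-specific allele-specific methylation
#'
#' For every (site, strand, query position) group, compares methylation
#' proportions between reads carrying each of the site's two alleles with a
#' two-sided Fisher exact test. Only positions of at least partial
#' methylation are tested (groups with zero methylated reads are skipped).
#' Reads carrying a base matching neither allele are ignored.
#'
#' @param methyl_obs Extracted methylation observations from
#'   [extract_methylation_observations()].
#' @param asm_alpha Significance cut-off (default 1e-8, the
#'   Bonferroni-scale threshold).
#' @return `data.table` of ASM calls: `site_id`, `chrom`, `strand`,
#'   `query_pos`, the 2x2 counts (`a_meth`, `a_unmeth`, `b_meth`,
#'   `b_unmeth`), `p_value`, `significant`.
#' @export
call_asm <- function(methyl_obs, asm_alpha = 1e-8) {
  obs <- as.data.table(methyl_obs)
  obs <- obs[allele_carried == allele_a | allele_carried == allele_b]
  tab <- obs[, .(
    a_meth = sum(methylated & allele_carried == allele_a),
    a_unmeth = sum(!methylated & allele_carried == allele_a),
    b_meth = sum(methylated & allele_carried == allele_b),
    b_unmeth = sum(!methylated & allele_carried == allele_b)
  ), by = .(site_id, chrom, strand, query_pos)]
  tab <- tab[a_meth + b_meth > 0]      # at least partial methylation
  if (nrow(tab) == 0) {
    tab[, `:=`(p_value = numeric(0), significant = logical(0))]
    return(tab[])
  }
  tab[, p_value := mapply(function(am, au, bm, bu) {
    test_asm_site(matrix(c(am, au, bm, bu), 2, 2, byrow = TRUE))
  }, a_meth, a_unmeth, b_meth, b_unmeth)]
  tab[, significant := p_value < asm_alpha]
  tab[]
}

#' Flag ASM calls directly adjacent to polymorphisms
#'
#' Marks calls whose methylation query position lies within `max_distance`
#' bp of a heterozygote candidate with `p_het >= p_min`. Calls carrying the
#' flag are attributable to CpG-disrupting SNPs (the polymorphic guanine of
#' a CpG motif); unflagged significant calls are epiallele candidates.
#'
#' @param asm_calls Calls from [call_asm()].
#' @param het_sites Heterozygote candidate table (`chrom`, `pos`, `p_het`).
#' @param max_distance Adjacency distance in bp (default 1, the CpG-partner
#'   base).
#' @param p_min Minimum `p_het` for a polymorphism to count (default 0.5).
#' @return `asm_calls` with a logical `adjacent_polymorphism` column.
#' @export
annotate_adjacent_polymorphism <- function(asm_calls, het_sites,
                                           max_distance = 1L, p_min = 0.5) {
  calls <- as.data.table(asm_calls)
  hets <- as.data.table(het_sites)[p_het >= p_min]
  if (nrow(calls) == 0) {
    calls[, adjacent_polymorphism := logical(0)]
    return(calls[])
  }
  calls[, adjacent_polymorphism := FALSE]
  for (cn in unique(calls$chrom)) {
    hp <- sort(hets[chrom == cn, pos])
    if (!length(hp)) next
    qp <- calls[chrom == cn, query_pos]
    i <- findInterval(qp, hp)
    lo <- pmax(i, 1L)
    d <- pmin(abs(qp - hp[lo]),
              abs(qp - hp[pmin(i + 1L, length(hp))]))
    calls[chrom == cn, adjacent_polymorphism := d <= max_distance]
  }
  calls[]
}
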