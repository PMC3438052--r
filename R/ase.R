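#' Two-sided binomial allelic-imbalance test
#'
#' Tests allele counts against the expected 50/50 ratio. Two-sidedness is
#' by minimum-likelihood summation: the p-value is the sum of the
#' probabilities of all outcomes no more likely than the observed one.
#' When one count is zero this reduces to the closed form `2 * 0.5^n`
#' (capped at 1).
#'
#' @param count_a,count_b Reads carrying each allele.
#' @return Two-sided p-value.
#' @export
#' @examples
#' binomial_imbalance_test(19, 0)   # 2 * 0.5^19 = 3.8e-6
#' binomial_imbalance_test(15, 5)
binomial_imbalance_test <- function(count_a, count_b) {
  if (anyNA(c(count_a, count_b)) || count_a < 0 || count_b < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- count_a + count_b
  if (n == 0) {
    stop("zero total reads: site is untestable", call. = FALSE)
  }
  binom.test(count_a, n, 0.5)$p.value
}

#' Call allele-specific expression and PolII binding
#'
#' One binomial test per site per assay for every site with at least one
#' read (counts are assumed to have been derived under the base-quality
#' filter). RNA and PolII share the identical procedure, distinguished only
#' by the assay label.
#'
#' @param expression_counts Table `site_id`, `assay`, `count_a`, `count_b`.
#' @param sites Validated site table; only validated sites are tested when
#'   a `validated` column is present.
#' @param ase_alpha Significance threshold (default 1e-7).
#' @return `data.table` of calls: `site_id`, `assay`, `count_a`, `count_b`,
#'   `p_value`, `significant`.
#' @export
call_ase <- function(expression_counts, sites = NULL, ase_alpha = 1e-7) {
  counts <- as.data.table(expression_counts)
  if (!is.null(sites)) {
    sites <- as.data.table(sites)
    if ("validated" %in% names(sites) && !all(is.na(sites$validated))) {
      sites <- sites[validated == TRUE]
    }
    counts <- counts[site_id %chin% sites$site_id]
  }
  counts <- counts[count_a + count_b >= 1]
  out <- copy(counts)
  out[, p_value := mapply(binomial_imbalance_test, count_a, count_b)]
  out[, significant := p_value < ase_alpha]
  out[]
}

#' Assign inversion haplotype labels from marker SNPs
#'
#' Labels a pair of phased haplotypes as the direct (H1) and inverted (H2)
#' structural haplotypes using a table of inversion-marking SNPs. Markers
#' whose phased alleles match neither listed orientation are dropped and
#' counted; each haplotype is labelled by majority vote over the usable
#' markers, and the concordance of the vote is reported.
#'
#' @param phased_genotypes Table `marker_id`, `hap1_allele`, `hap2_allele`
#'   (the two phased haplotypes of the sample).
#' @param marker_table Table `marker_id`, `h1_allele`, `h2_allele`.
#' @return List of class `haplotype_assignment`: `hap1_label`,
#'   `hap2_label`, `n_markers_used`, `n_markers_concordant`,
#'   `n_markers_dropped`.
#' @export
assign_inversion_haplotypes <- function(phased_genotypes, marker_table) {
  ph <- as.data.table(phased_genotypes)
  mk <- as.data.table(marker_table)
  j <- merge(ph, mk, by = "marker_id")
  if (nrow(j) == 0) {
    stop("no usable markers: phased genotypes cover no marker SNP",
         call. = FALSE)
  }
  # orientation vote per marker: does hap1 carry the H1 allele (and hap2
  # the H2 allele), or the reverse? anything else is unusable
  direct <- j$hap1_allele == j$h1_allele & j$hap2_allele == j$h2_allele
  reversed <- j$hap1_allele == j$h2_allele & j$hap2_allele == j$h1_allele
  usable <- direct | reversed
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message(n_dropped, " marker(s) with alleles matching neither listed ",
            "orientation dropped")
  }
  n_used <- sum(usable)
  if (n_used == 0) {
    stop("no usable markers after dropping allele mismatches",
         call. = FALSE)
  }
  votes_direct <- sum(direct)
  hap1_is_h1 <- votes_direct >= n_used / 2
  structure(list(
    hap1_label = if (hap1_is_h1) "H1" else "H2",
    hap2_label = if (hap1_is_h1) "H2" else "H1",
    n_markers_used = n_used,
    n_markers_concordant = max(votes_direct, n_used - votes_direct),
    n_markers_dropped = n_dropped
  ), class = "haplotype_assignment")
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(sprintf(
    "haplotype assignment: hap1 = %s, hap2 = %s (%d/%d markers concordant, %d dropped)\n",
    x$hap1_label, x$hap2_label, x$n_markers_concordant, x$n_markers_used,
    x$n_markers_dropped))
  invisible(x)
}
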