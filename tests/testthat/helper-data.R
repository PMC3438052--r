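# shared fixtures built in code

library(data.table)

# a small site table with explicit alleles
make_sites <- function(pos, allele_a = "A", allele_b = "G", p_het = 1,
                       chrom = "chrS", source = "array") {
  n <- length(pos)
  data.table(
    site_id = paste0(chrom, ":", pos), chrom = chrom, pos = as.integer(pos),
    allele_a = rep_len(allele_a, n), allele_b = rep_len(allele_b, n),
    p_het = rep_len(p_het, n), source = rep_len(source, n),
    validated = NA, key = "site_id"
  )
}

# read observations for one site, one dataset: counts named by base
make_reads <- function(site_id, dataset_id, bases, quality = 30,
                       strand = "+") {
  data.table(
    site_id = site_id, dataset_id = dataset_id, observed_base = bases,
    base_quality = rep_len(quality, length(bases)),
    strand = rep_len(strand, length(bases))
  )
}

# a tiny config that keeps simulations fast
tiny_config <- function(seed = 1, n_sites = 200, ...) {
  sim_config(seed = seed, n_sites = n_sites, ...)
}
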