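# ashmscreen

Chromatin state can differ between the two copies of a chromosome in the
same nucleus. At a heterozygous SNP, sequencing reads can be assigned to
the allele they carry, turning ChIP-seq, whole-genome bisulfite and
RNA-seq data into a within-sample comparison of the two chromosome
copies. `ashmscreen` implements a statistically rigorous screen for:

- **ASHM** — allele-specific histone modification, where nucleosomes on
  the two copies carry *different spectra* of marks;
- **ASM** — allele-specific DNA methylation, strand-resolved;
- **ASE / ASP** — allele-specific expression and PolII binding.

It is written for epigenomics analysts who have allele-resolved read
observations at candidate heterozygous sites (e.g. extracted from
alignments of ENCODE/Roadmap-style data) and want calls that survive the
two confounders that wreck naive per-assay tests.

## The core statistic

For each validated heterozygote, allele-resolved read counts for up to 23
histone modifications form a contingency table

```
            mod_1  mod_2 ... mod_23
allele A    n_A1   n_A2      n_A23
allele B    n_B1   n_B2      n_B23     (up to 4 allele rows)
```

Zero-sum rows and columns are removed and the reduced table is tested for
independence of allele and dataset with an exact test (network algorithm;
Pearson χ², flagged `approximate`, beyond a complexity budget). A
significant result means the allele proportion differs **between at least
two modification datasets**. By construction:

- a *nucleosome-occupancy shift* (more nucleosomes on one copy, identical
  marks) scales whole allele rows and stays null;
- a *false-positive heterozygote* (truly homozygous site) leaves a single
  allele row — untestable, never significant.

Around it sit heterozygote validation (imputed p(het) ≥ 0.5 **and** ≥ 2
bisulfite reads per allele), a Phred < 13 base filter, a ≥ 35-read
high-coverage background set for enrichment, exact Hardy–Weinberg QC
(α = 0.05) against duplication artefacts, per-modification binomial tests
(two-sided, vs 0.5), clustering of signed −log₁₀ p profiles by 1 − r²
with automatic cut and driver identification, strand-specific ASM Fisher
tests at α = 1e-8 with adjacent-polymorphism annotation, binomial ASE/ASP
tests at α = 1e-7, proximity enrichment with Clopper–Pearson intervals,
and posterior-odds / Bonferroni calibration helpers.

A seeded synthetic-data generator (`simulate_dataset()`) emulates all the
inputs with known truth — implanted cluster patterns, occupancy-shift and
false-het confounders, CpG-disrupting versus epiallele ASM, ASE linked to
ASHM within 10 kb, and implanted proximity enrichment — so the whole
pipeline is testable without external data.

## Worked example

```r
library(ashmscreen)

cfg <- sim_config(seed = 42, n_sites = 300, mean_driver_chip_depth = 200,
                  imprinted_enrichment_fold = 5)
ds  <- simulate_dataset(cfg)
dir <- file.path(tempdir(), "demo")
write_fixtures(ds, dir)
res <- run_pipeline(dir, file.path(dir, "out"), seed = 42)
```

The stage log shows the filtering funnel:

```
[validate-hets: 300 candidate sites]
[validate-hets: 262 validated]
[count-alleles: 262 covered sites, 229 at >= 35x]
ASHM: tested 262 site(s); 229 at >= 35x coverage; 7 significant at 1e-07
[cluster: 5 cluster(s) over 7 significant sites]
```

262 of 300 candidates survive validation (false hets and low-support
sites drop out); 229 clear the 35-read coverage floor; 7 reach the 1e-7
omnibus threshold, all of them implanted ASHM truth sites:

```r
res$ashm[significant == TRUE,
         .(site_id, omnibus_p, total_coverage, passed_qc)]
#>          site_id    omnibus_p total_coverage passed_qc
#> 1: chrS:10746402 2.475324e-11            203      TRUE
#> 2: chrS:11410828 2.464063e-45            392      TRUE
#> 3: chrS:12036566 9.873697e-32            373      TRUE
#> ...

print(res$clusters)
#> cluster result: 5 cluster(s), cut height 0.204
#>   cluster 2 (1 sites): H3K27me3+,H3K4me3-
#>   cluster 3 (2 sites): H3K36me3+,H3K9me3-
#>   ...
```

Cluster 2 is the classic bivalent-style pattern — the repressive
H3K27me3 mark on one allele and the activating H3K4me3 on the other;
`+`/`−` record the allele side within a cluster (orientation is
arbitrary per site and compared up to a global flip).

Calibration helpers reproduce the screen's printed anchors:

```r
binomial_imbalance_test(19, 0)      # 3.814697e-06 — strong, yet > 1e-7
posterior_odds(1e-5, 0.1, 1e-7)     # 10.0001 — 10:1 odds a call is real
bonferroni_threshold(0.05, 3410426) # 1.466e-08 — the ASM cut-off scale
```

A command-line wrapper ships in `inst/cli/ashm-screen`
(`simulate | validate-hets | count-alleles | call-asm | call-ashm |
call-ase | cluster | enrich | run`).

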