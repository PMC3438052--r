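---
title: "Screening for allele-specific chromatin state: models, thresholds, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for allele-specific chromatin state: models, thresholds, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ashmscreen)
library(data.table)
```

## The problem

Chromatin state is usually profiled as if both copies of a chromosome were
identical, but at a heterozygous SNP the reads of a ChIP-seq, bisulfite or
RNA-seq experiment can be assigned to the allele they carry, turning each
assay into a within-sample case/control comparison between the two
chromosome copies. This package implements a screen for three phenomena at
such sites:

* **ASHM** — allele-specific histone modification: the two copies carry
  different *spectra* of histone marks;
* **ASM** — allele-specific DNA methylation;
* **ASE / ASP** — allele-specific expression and PolII binding.

The statistical difficulty is that the obvious test (per-assay binomial
imbalance) is confounded twice over. A *nucleosome-occupancy shift* — more
nucleosomes on one copy, with identical marks — skews every
histone-modification dataset at the site identically, and would light up
every per-mark test. A *false-positive heterozygote* — a truly homozygous
site that slipped through imputation — yields reads of a single allele and
looks maximally imbalanced in every assay.

## The omnibus ASHM test

Both confounders are rejected by construction with a cross-dataset test.
For each validated heterozygous site an alleles-by-modifications
contingency table (up to 4 x 23) is assembled from base-quality-filtered
reads; rows and columns summing to zero are removed, and the reduced table
is tested for independence of allele and dataset with a Fisher exact test.
Significance therefore means that the allele proportion differs *between at
least two modification datasets*:

* an occupancy shift scales whole allele rows and leaves independence
  intact;
* a homozygote leaves a single allele row, which is untestable (p = 1);
* sequencing errors occur at similar rates in every dataset and do not
  create dataset-dependent allele proportions.

Per-modification binomial tests against the expected 50/50 ratio are still
computed — not as the call criterion but as the *description* of each
significant site, feeding the clustering below.

### Exact versus approximate computation

`fisher.test()`'s network algorithm computes the exact r x c p-value but
its cost explodes with the table total. The omnibus routine uses the exact
route when the total is at most `exact_max_total` (default 120, where the
computation takes milliseconds on the sparse 2-4 row tables the screen
produces) and otherwise falls back to a Pearson chi-squared statistic
without continuity correction, flagged `approximate` in the output. The
flag matters: a Monte-Carlo p-value could never resolve significance near
1e-7, and a call that rests on an approximation should say so. On the
sparse default tables (about 46 reads over 23 columns) the chi-squared
fallback cannot even numerically reach 1e-7 on a two-allele table — the
statistic is bounded by the table total while the df ~ 22 critical value is
about 80 — so the confounder-immunity property does not depend on the
approximation behaving well in its far tail.

### Power: why driver depth matters

The omnibus test spreads its degrees of freedom over every dataset, so a
single modification skewed at fraction 0.9 against 22 balanced ones
contributes roughly `0.64 x d` to a chi-squared statistic with ~22 df,
where `d` is the driver's read depth. Reaching p < 1e-7 (critical value
~80) therefore needs driver coverage of the order of 100-200 reads, or two
marks skewed to opposite alleles (which roughly doubles the signal). This
is not a defect of the implementation but a property of the design: it
buys confounder immunity with power, which is why genome-scale screens of
this kind find tens, not thousands, of sites. The synthetic generator
mirrors the biology that makes real discoveries possible —
immunoprecipitation coverage is deep precisely where a mark is present —
through `mean_driver_chip_depth` (default 60) as distinct from the flat
cross-modification background `mean_chip_depth` (default 2, i.e. about 46
reads summed over 23 marks). Recovery-oriented analyses in the test suite
run at driver depth 200 and skew 0.9, where expected recovery is ~60% for
single-driver patterns and near 1 for two-driver patterns.

## Heterozygote validation

Imputed heterozygote candidates are accepted only with an imputation
probability of at least 0.5 *and* at least two bisulfite reads carrying
each allele (both thresholds inclusive, both configurable). Support
counting ignores methylation and strand but honours the conversion
ambiguity rules below. Candidates that fail are dropped from every
downstream stage. When no array/imputation input exists, the same read
support criterion alone can be applied (`require_imputation = FALSE`).
`evaluate_het_calls()` scores the procedure against truth genotypes as
sensitivity, specificity and PPV over all supplied candidates.

## Strand-specific ASM

Bisulfite conversion turns unmethylated C into T, so on a given strand a
C/T polymorphism cannot be distinguished from methylation state: C/T sites
are excluded on the plus strand and G/A sites on the minus strand (the
same rule read through the complement), and methylation is never called at
a known polymorphic position. Remaining observations are tested per
(site, strand, query position) with a two-sided Fisher exact test of
methylated/unmethylated counts between the reads carrying each allele,
restricted to positions of at least partial methylation. The significance
cut-off (default 1e-8) is the Bonferroni scale for millions of tested
positions; `bonferroni_threshold(0.05, 3410426)` ~ 1.5e-8 reproduces that
calibration.

Significant calls directly adjacent (default 1 bp) to a polymorphism with
p_het >= 0.5 are flagged: these are CpG-disrupting SNPs, where loss of the
guanine abolishes methylation on one allele and the "allele-specific
methylation" is a trivial consequence of sequence. Unflagged calls are
epiallele candidates — methylation differences with both alleles' DNA
intact. The adjacency distance of 1 bp operationalises the CpG mechanism:
the methylated cytosine sits immediately 5' of the polymorphic guanine.

A power note: a strand-specific 2 x 2 Fisher test at `m` reads per allele
cannot produce p below `2 / C(2m, m)`, so at 16 reads per strand (the 32x
whole-genome regime) the 1e-8 threshold is unreachable — at least 16 reads
per allele on one strand are needed. Recovery analyses therefore simulate
40 reads per strand; the default `mean_bis_depth = 16` represents the
genome-wide sequencing average, not the regime in which ASM is callable.

## ASE and PolII binding

RNA and PolII allele counts share one code path: a two-sided binomial test
against 0.5 using minimum-likelihood summation, which reduces to
`2 * 0.5^n` when all `n` reads carry one allele. The worked anchor: 19
reads on a single allele give p = 3.8e-6 — persuasive, yet above the 1e-7
screen threshold, illustrating that the strict cut-off trades sensitivity
for genome-wide robustness. The posterior-odds calibration quantifies the
trade: with a prior fraction of 0.001% truly associated sites and power
0.1, a 1e-7 threshold leaves 10:1 odds that a significant site is real
(`posterior_odds(1e-5, 0.1, 1e-7)`).

## Clustering and driver identification

Each significant ASHM site is summarised as a signed profile over
modifications: magnitude `-log10` of the per-modification binomial p
(zero when untested, capped at 1e-300 against underflow), sign indicating
which allele the modification favors. The reference allele per site is the
one favored by the site's most significant modification — an arbitrary but
deterministic orientation; all downstream steps are invariant to flipping
it. Sites are clustered hierarchically (average linkage by default) on the
dissimilarity `1 - r^2` of profile pairs, the squaring making the measure
orientation-blind. The log base affects only scale and cancels in `r^2`;
base 10 is used for readable outputs.

The dendrogram cut is chosen by progressively lowering it (raising the
cluster count) until a further cut would produce two clusters driven by
the same modifications. A cluster's drivers are the modifications
significant below `driver_p_threshold` (default 0.01) on a consistent
allele side in at least half its sites — after sign-aligning member
profiles against the cluster's strongest site, since mutually flipped
profiles co-cluster under `r^2`. Driver patterns are compared up to a
global sign flip (the allele labels of a cluster have no absolute
meaning). With the six canonical implanted patterns — H3K4me3 alone;
H3K4me3 opposite H3K27me3; H3K27me3, H3K36me3 or H3K9me3 alone; H3K9me3
opposite H3K36me3 — the scan recovers exactly six clusters with those
driver sets.

## QC: Hardy-Weinberg and coverage

Hidden duplications and copy-number variation masquerade as heterozygotes
whose population genotype counts violate Hardy-Weinberg equilibrium. Each
called SNP is tested with the exact conditional HWE test (enumeration of
heterozygote counts given allele counts); calls below `hwe_alpha = 0.05`
(strict inequality) fail QC. This is deliberately conservative — by chance
5% of true SNPs fall below the threshold. The second, report-only QC
compares mean bisulfite depth at called sites with the genome-wide mean:
duplicated regions attract excess coverage, so a ratio near or below 1 is
reassuring; the check reports and does not filter.

## Enrichment and proximity

Enrichment of a call set near an annotation track (imprinted loci,
deletion-syndrome regions) is measured against the *high-coverage
background*: validated heterozygous sites with at least 35 summed ChIP
reads (inclusive), i.e. sites at which ASHM was detectable had it existed.
Called sites are not excluded from the background; at realistic call rates
(tens among tens of thousands) their contribution is negligible. Distance
to a region is the edge distance (0 inside, inclusive window comparison);
point targets use the absolute position difference. The 2 x 2 test is
Yates-corrected chi-squared by default with Fisher's exact test available
where expected counts are tiny; both the method and window are recorded
per output row. `sites_within()` composes proximity filters, e.g.
significant-ASE-within-10 kb AND deletion-region-within-250 kb.

## The synthetic generator

`simulate_dataset()` produces every input the screen consumes, with truth
labels: site tables with imputation probabilities, per-read ChIP
observations for 23 modifications, bisulfite observations with strand and
methylation state, RNA/PolII counts, BED annotation tracks, and population
genotype counts. Design choices, made once:

* **Read depths are Poisson** around configurable means — the standard
  count model, and it keeps the 35-read background filter exercisable
  (defaults put ~4% of sites below it).
* **Skewed-allele designation is uniform at random** per site; the screen
  has no parent-of-origin information.
* **Base qualities are two-point** {Q10: 10%, Q30: 90%} — the minimal
  mechanism that exercises the Phred < 13 exclusion.
* **One synthetic chromosome** (20 Mb): all proximity logic is
  coordinate-local.
* **ASM mechanisms partition ASM sites**: `cpg_disrupting_fraction`
  (default 0.8) versus `epiallele_fraction` (0.2) must sum to 1. CpG sites
  carry the intact guanine as allele A and link methylation to it at the
  base directly adjacent to the SNP; epialleles show differential
  methylation (default levels 0.95/0.05) 10 bp away with both alleles
  present.
* **Imprinted-locus enrichment is implanted by solving for the measured
  fold**: foreground placement probability is chosen so that the expected
  ratio of the ASHM-site in-window proportion to the *all-sites*
  proportion equals `imprinted_enrichment_fold`. Because the background
  includes the foreground, a fold `F` is attainable only when
  `F x ashm_fraction < 1`; infeasible combinations are a configuration
  error. Default fold 10 at the default 5% ASHM fraction; fold-20 analyses
  use a 2% ASHM fraction, mirroring the real regime where calls are a tiny
  sliver of the background.
* **ASE linkage**: a configured fraction (default 0.2) of ASHM sites
  receives an ASE site within 10 kb; remaining ASE sites are uniform.
* **Confounders are first-class**: occupancy-shift sites skew every
  modification identically; false-het sites are homozygotes with imputed
  p_het >= 0.5 emitting a single allele plus sequencing error (rate
  0.001); a small fraction (2%) of population genotype vectors violate HWE
  in the duplication-like direction (no heterozygotes).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: raw sequence reads and alignment, mappability
and reference bias, duplicate reads, linkage disequilibrium between
neighbouring sites, correlated methylation along reads, and realistic
coverage heterogeneity beyond the driver/background split. Results on real
data additionally depend on imputation quality and allele-aware mapping,
which are upstream of this package.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately scaled
problem sizes: screens of 2,000 sites (versus millions in a genome),
confounder-immunity checks over 10,000 occupancy-shift and 10,000
false-het sites, cluster recovery over 72 implanted sites at driver depth
200, ASM recovery over 500 sites at 40 reads per strand, and enrichment
recovery pooled over 200 replicates of 2,000 placement-only sites with a
delete-one-replicate jackknife interval. Ties in the favored allele are
reported as no favored allele; zero-variance profiles get correlation 0
(logged); p-values are capped at 1e-300 before log transform; zero-margin
2 x 2 tables are untestable (p = 1); and every random quantity derives
from the single configured seed, making whole datasets byte-identical
under a fixed seed.

## Known limitations

* The omnibus test's power for single-driver patterns depends steeply on
  driver coverage (see above); shallow screens are biased toward
  two-driver discoveries.
* The background set's 35-read floor is a detectability proxy, not a
  power match per modification.
* Epialleles adjacent to *unknown* polymorphisms would be misclassified —
  on real data the flag is a lower bound on SNP-driven ASM.
* The exact HWE test assumes a single randomly mating population.
* Cut selection for clustering is heuristic; bootstrap stability is out
  of scope.

## A minimal run

```{r demo, eval = TRUE}
cfg <- sim_config(seed = 42, n_sites = 300, mean_driver_chip_depth = 200,
                  imprinted_enrichment_fold = 5)
ds <- simulate_dataset(cfg)
dir <- file.path(tempdir(), "screen-demo")
write_fixtures(ds, dir)
res <- run_pipeline(dir, file.path(dir, "out"), seed = 42)
res$ashm[significant == TRUE,
         .(site_id, omnibus_p, total_coverage, passed_qc)]
```
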