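---
title: "QTL-seq bulked-segregant mapping with bulkscan: models and methods"
author: "bulkscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL-seq bulked-segregant mapping with bulkscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkscan)
```

## The mapping problem

Bulked-segregant analysis with whole-genome sequencing (QTL-seq) locates
quantitative trait loci by comparing pooled allele frequencies between two
groups of phenotypically extreme individuals drawn from a segregating
population. The workflow bulkscan implements is the one used to map a
major heat-tolerance QTL at the flowering stage in rice: an F2 population
from a cross between a tolerant cultivar (HHZ) and a sensitive one (9311)
is phenotyped through F2:3 family means of spikelet fertility after heat
stress, the 50 most tolerant and 50 most sensitive plants are pooled into
two DNA bulks, both bulks and both parents are resequenced, and the
genome is scanned for regions where the bulks' allele frequencies diverge.

At a biallelic SNP where the parents are opposite homozygotes, the
**SNP-index** of a pool is the fraction of its reads carrying the
tolerant-parent (HHZ) allele. At loci unlinked to the trait both bulks are
random samples of the F2 population, so the expected index is 0.5 in each
pool. At a locus linked to tolerance the tolerant bulk is enriched for the
HHZ allele (index near 1) and the sensitive bulk depleted (near 0). The
scan statistic is

    delta(SNP-index) = index(T-pool) - index(S-pool),

averaged over 500 kb sliding windows advanced in 5 kb steps, with a
resampling-based 99.9% confidence threshold and two auxiliary screening
criteria: a candidate window must also have a T-pool index of at least 0.7
and an S-pool index of at most 0.3. Overlapping significant windows merge
into candidate regions, which are intersected with GFF3 gene models;
candidate genes can then be compared between genotypes by qPCR with the
2^-ddCt method.

## Phenotype model

Spikelet fertility is scored from grain counts as
`(N_FG + N_PG) / (N_FG + N_PG + N_EG) * 100`, counting partially filled
grains as filled. `summarize_fertility()` reports sample moments (n-1
denominator; at n = 365 the distinction from the population SD is below
reporting precision) and a CV that is scale-invariant;
`cv_from_moments()` exposes the two-moment consistency check used to
compare a reported mean/SD pair with a reported CV. Bulk selection is by
strict rank order with ties broken by plant id, so a rerun on the same
table always selects the same plants.

## The synthetic-data generator

Real pooled resequencing data cannot be shipped with the package, so every
stage is exercised against a simulator whose defaults reproduce the
statistical structure of the mapping study:

* **Population**: 365 F2 plants; bulks of 50; twelve rice chromosomes
  (23-45 Mb). Meioses place crossovers as a Poisson process at 1 per
  100 cM with 250 kb/cM (about 1500 cM genome-wide, the conventional rice
  scale), i.e. Haldane's model without interference - interference is
  immaterial at the 500 kb window scale.
* **QTL**: one additive locus at chr08:4.0 Mb with `a = 0.201` on the
  fertility proportion scale, i.e. half the parental difference
  (54.5% vs 14.3%); dominance defaults to 0.
* **Phenotypes**: the study phenotypes F2:3 families but pools F2 leaf
  DNA. Each F2 plant's phenotype is therefore the mean genetic value of
  12 selfed F3 progeny (heterozygotes segregate 1:2:1) plus one
  family-level environmental deviate, clamped to [0, 1]. The residual SD
  defaults to 0.115, tuned once so that the total phenotypic SD under the
  default QTL is about 0.1847, the study's reported value; the reported
  mean (0.50) is the baseline. Grain counts add binomial counting noise:
  200 spikelets per plant, filled counts split 9:1 into fully vs partially
  filled. Panicle size and the 9:1 split are invented knobs - the study
  reports only the fertility ratio.
* **Pooled reads**: plants contribute equimolar DNA (the study states the
  bulks were evenly mixed), so the true pool frequency at a SNP is the
  mean HHZ dosage over the bulk divided by 2. Site depths are Poisson
  (57x pools, 36x parents, the study's averages) and reads are binomial
  with a per-read miscall probability of 0.001, giving
  `E[index] = (1-2e)f + e`. The HHZ allele is randomly REF or ALT per
  site, forcing downstream code to orient alleles from parent genotypes.
* **Outputs**: VCF v4.2 (GT:AD:DP for HHZ, 9311, T_pool, S_pool), GFF3
  gene models (synthetic, non-overlapping, about one per 13 kb as in
  rice), TSV phenotype and bulk tables, and a JSON truth file with the
  planted QTL, true fertilities, bulk membership and per-stage seeds. One
  root seed drives named substreams per stage, so datasets are
  byte-identical across runs.

What the simulator does *not* emulate: read alignment artifacts, indels,
structural variants, reference bias, depth heterogeneity beyond Poisson,
segregation distortion, and multi-QTL genetic architectures unless
configured. Passing tests therefore demonstrate that the statistical
machinery is correct under the stated model, not that the pipeline is
robust to upstream artifacts - those are consumed, not produced, by this
package.

## Variant filtering

The study reports 627,717 "high-quality" and 33,205 "effective" SNPs but
not the criteria behind either count, and without the raw data those
counts cannot be reproduced; bulkscan instead makes the filter explicit
and auditable. Defaults: parents opposite homozygotes, parent depth >= 6,
pool depth in [8, 3x mean]. Each removed site is tallied under the first
rule it fails so the report conserves totals. Allele orientation comes
from parent A's homozygous genotype at each site, never from REF/ALT
status, so the SNP-index is always the HHZ-allele frequency. With the
adaptive upper depth bound fixed to a number, filtering is idempotent.

## Window scan

Windows are anchored at bp 1, advanced by the step, and truncated (not
dropped) at chromosome ends; each SNP contributes to every covering
window, and window values are unweighted means over contained SNPs - the
plain window mean, not tricube-weighted smoothing or G' statistics from
other BSA formulations. The window mean of per-SNP delta values equals the
difference of the per-pool window means over the same SNP set, so only
`mean_delta` is reported alongside both pool means. Windows with fewer
than 3 SNPs are flagged unusable and excluded from region calling (a
single-SNP window would otherwise put a spike through the threshold);
they are retained in the output for inspection. The implementation is
checked for exact equality against a brute-force mask-and-mean oracle.

## The resampling null and its linkage structure

The confidence threshold simulates the null of no linkage: each replicate
draws two bulks of 50 F2 genotypes at an unlinked locus (pooled allele
count Binomial(2x50, 1/2)), samples reads binomially at the observed
depths, and records |delta|. Thresholds are the upper quantiles of this
distribution at 95/99/99.9%, computed per window at the window's median
pool depths and shared across windows with identical (n_snps, depth)
shape, so the threshold curve is deterministic under one seed.

One modelling decision deserves emphasis. A window mean over `n` SNPs is
*not* an average of `n` independent draws: SNPs 500 kb apart are tightly
linked (2 cM here), so the bulk-composition component of their indices is
essentially one shared draw per window, and only read noise averages
down. The window null therefore draws the bulk frequencies once per
replicate and shares them across the window's sites, with independent
read sampling per site. Treating the sites as fully independent would
shrink thresholds by roughly `1/sqrt(n)` and inflate the realised
window-level exceedance far above the nominal 0.1%; the shared-draw null
keeps it at or below nominal (the package's null-calibration experiment
measures about 0.0005 at the validation scale, slightly conservative
because real bulks are drawn without replacement from a finite
population). More SNPs per window still lower the threshold - through the
read-noise component - so the qualitative behaviour users expect from
averaging is preserved.

The replicate count defaults to the study's 1,000, but the 99.9% quantile
of 1,000 draws is an extreme order statistic and noisy; the package warns
below 10,000 replicates and supports any count. Thresholds condition on
the window's median depth rather than per-site depths; at 57x the
difference is negligible.

## Region calling

A window is significant when `mean_delta` exceeds its 99.9% threshold and
meets the 0.7/0.3 pool-index criteria. The study states the pool-index
criteria for the mapped region as a whole, so both placements are
offered: per window (default) or per merged region
(`criteria = "region"`). Significant windows merge when their intervals
overlap or lie within `gap_max` (default twice the step - the study
reports a single contiguous interval, so the merge gap is an invented
knob). Region size is the endpoint difference in Mb, under which the
mapped interval 3,555,000-4,520,000 bp is 0.965 Mb. Merging is
deterministic and order-invariant; each region records its peak window
and mean pool indices.

## Validation experiments and their scale

The packaged experiments run on a scaled genome - three 10 Mb chromosomes
at 20 SNPs/Mb with the full population structure (365 F2, bulks of 50,
57x) - chosen so that twenty complete simulate-scan-call cycles run in a
few minutes while preserving the window, depth and bulk geometry of the
full karyotype:

* **Recovery** (`recovery_experiment()`): with the planted `a = 0.18` QTL
  the called region overlaps the true position on the correct chromosome
  in essentially every run.
* **Localisation**: the best region's *midpoint* is, however, a poor
  point estimate at this effect size. An `a = 0.18` QTL carries nearly
  the whole parental difference, so tail selection drives the bulk
  frequencies to about 0.88/0.12 at the QTL, and linkage decay over a
  10 Mb = 40 cM chromosome keeps the expected T-pool index above 0.7
  almost chromosome-wide. The merged region then spans most of the
  chromosome and its midpoint reflects chromosome geometry rather than
  QTL position (median error about 1 Mb), while the *peak-delta* position
  localises far better. This is a property of the estimand under a strong
  QTL, not a defect of the scan; the study's own much smaller interval
  (0.965 Mb) is consistent with a smaller realised single-locus effect in
  real data, where multiple QTLs and genotype-by-environment variance
  dilute any one locus's contribution.
* **Type-I control** (`null_calibration_experiment()`): on null genomes
  the fraction of windows above the 99.9% threshold stays at or below
  0.001 and the full screening criteria call no regions.
* **Estimator calibration** (`null_index_experiment()`): the mean
  observed SNP-index across independent null datasets matches
  `(1-2e)*0.5 + e = 0.5` within Monte-Carlo error; dataset means are used
  as replicates because sites within one dataset are linked and do not
  provide independent errors.

## qPCR comparison

`ddct()` implements 2^-ddCt with replicate-matched reference Ct values.
`relative_expression()` forms a dCt per technical replicate, normalises
against the calibrator condition's mean dCt, and returns the fold change
per replicate (the replicate spread is what the genotype t-test runs on);
a per-condition summary (mean fold, SD, n) is attached.
The calibrator condition is an explicit argument - the study does not
state its baseline, so the package defaults to the first timepoint of the
first (sensitive) genotype rather than guessing silently. Genotype
comparisons use the equal-variance Student's t-test (the era's default;
Welch by flag) with the conventional stars (* p < 0.05, ** p < 0.01).
Groups with zero variance cannot be t-tested; identical constant groups
report p = 1 and differing constant groups report NA rather than a
fabricated p-value. Primer-efficiency correction (Pfaffl) is out of
scope.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere except BED exports
  (0-based half-open).
* All randomness flows from one root seed through named substreams
  (`stage_seeds()`), so every artifact is reproducible and stages can be
  re-run independently.
* Quantiles use R's default type-7 definition.
* Degenerate inputs error early with named causes: empty bulks,
  unsorted VCFs, missing AD fields, all-zero grain counts (missing with a
  warning), fewer than `2 * bulk_size` scorable plants.
* The end-to-end driver `run_pipeline()` executes stages in dependency
  order from one YAML config and writes a JSON manifest (version, config
  snapshot, input checksums, seed, per-stage runtimes, outputs); reruns
  with the same config and seed are byte-identical.

## Known limitations

* The filter defaults stand in for the study's unpublished criteria; the
  headline SNP counts (627,717 / 33,205) are not reproducible targets.
* The null conditions on median window depth and an idealised F2
  (exact 1/4-1/2-1/4 segregation, infinite source population); both make
  thresholds slightly conservative.
* Multi-QTL F3 linkage within a family is ignored by the phenotype
  simulator when several QTLs share a chromosome.
* The scan handles SNPs only; indels in a candidate interval are counted
  by the annotation stage if present in the input, but no indel index is
  computed.
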