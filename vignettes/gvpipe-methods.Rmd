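---
title: "Integrated germline variant calling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated germline variant calling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvpipe)
```

## The problem

Germline variants (inherited single-nucleotide variants, as opposed to
somatic tumor mutations) are usually called from whole-exome sequencing of
a patient's normal tissue. Exome capture is uneven, so many sites in a
normal sample are covered by too few reads to genotype confidently. When
the same patient also has a tumor exome and tumor RNA-seq sample, those
data cover many of the same positions and can supply the missing genotype:
a germline variant is present in every cell, so a confident call in the
tumor DNA — or in tumor RNA — at a site that is merely under-covered in
the normal sample is evidence for the same inherited allele. Tumor-specific
mutations and RNA-editing artifacts do leak in through this route; they are
removed at the end by keeping only variants that are known population
polymorphisms.

`gvpipe` implements this integration end to end: per-sample candidate
calling (or ingest of caller VCFs), a coverage correction of genotype
status, a union status matrix across samples and data types, the
tumor-then-RNA rescue of unknown statuses, allele-frequency estimation,
a population minor-allele-frequency filter, and per-variant survival
association.

## The status model

Every (variant, sample) pair carries one of four statuses:
`Homozygous_ref`, `Heterozygous`, `Homozygous_alt`, `unknown`. The
coverage-correction rule (`determine_status()`) is:

* depth < `min_depth` reads → `unknown`, regardless of any call;
* depth ≥ `min_depth` and no alternate allele reported → `Homozygous_ref`;
* otherwise the caller's genotype stands.

`min_depth` defaults to 10 reads: with the caller's 3-supporting-read
minimum, ten reads give a reasonable chance that a real heterozygous
allele would have been sampled at least three times, while keeping enough
patients genotyped. The wording "fewer than ten reads" leaves depth
exactly 10 unassigned; we treat depth ≥ 10 as sufficient (the complement
of "fewer than ten"), and the threshold is configurable through
`status_policy()`.

The depth that governs this rule is the coverage table computed at union
positions (mapping quality > 30, no base-quality filter, no duplicate
removal — the behaviour of a plain depth-tool pass), not the caller's
reported `DP`; the latter is retained in the call records for provenance.
A position absent from a depth file is depth 0, matching depth tools that
omit zero-coverage rows.

## The candidate caller

`call_pileup()` is a deliberately simple count-based caller so the whole
pipeline can be exercised from pileup tables without BAM files; users with
BAMs should run a full variant caller and feed its VCFs in. Thresholds
(all configurable via `caller_params()`):

* mapping quality > 30 and base quality > 25, both strict inequalities;
* duplicate removal: within a site, one read per (start position, strand),
  keeping the highest base quality. Including strand in the key avoids
  collapsing legitimate reverse-strand coverage; it can be disabled;
* at least 3 reads supporting the variant and a variant allele fraction
  of at least 5%, computed on quality-surviving reads;
* only the most frequent non-reference base per site is considered
  (SNV-only scope), ties broken deterministically in base order A<C<G<T;
* heterozygous versus homozygous-alternate at VAF 0.75: genotyping is
  normally the caller's job and no cutoff is inherited from upstream, so
  we use the conventional diploid midpoint-plus-margin, configurable.

Whether the VAF should be computed before or after quality filtering is
ambiguous in principle; we compute it on the quality-surviving reads,
the same denominator as the emitted depth.

## Union, combination and chunked processing

Unique variants are collected per data type and unioned across
wxs-normal, wxs-tumor and rnaseq-tumor on the (CHROM, POS, REF, ALT) key;
this union is the single synchronization point between the per-data-type
halves of the pipeline. The multi-sample "VCF" of the combination step is
in fact a tab-separated status table (`CHROM POS REF ALT <samples…>`);
we keep that dialect. `process_chunked()` reproduces the 50,000-row
split-with-4-digit-suffix processing used on cohort-scale tables; it is an
equivalence-preserving implementation detail, and the suite asserts
byte-identical output against unchunked processing. Rows that are
`unknown` or `Homozygous_ref` in every sample carry no evidence of a
variant and are dropped (`filter_potential_snps()`).

BED export emits proper 0-based half-open intervals even though the
pipeline's internal coverage lookups use 1-based positions directly;
standard BED is what external depth tools expect, and no information is
lost either way.

## Rescue semantics

`fill_unknown()` processes each patient of the patient map:

1. baseline = the normal sample's status column (all-`unknown` when the
   patient has no normal sample — this is what lets the approach genotype
   patients with no normal exome at all);
2. cells still `unknown` take the matched tumor status when known;
3. cells still `unknown` then take the matched rnaseq status when known.

Known normal statuses are never modified; tumor always outranks rnaseq;
a variant absent from a donor matrix is `unknown` in that donor; the
final columns are patient identifiers rather than sample barcodes.
Unmatched barcodes are a hard error (sample-name/barcode mismatches are a
classic silent failure of this join). The potential-SNP filter is
re-applied after filling, and a per-patient report records the accounting
identity `unknowns_before = filled_from_tumor + filled_from_rnaseq +
unknowns_remaining`.

Somatic contamination introduced by tumor-derived fills is deliberately
not handled here: it is removed by the population MAF filter below.

## Allele frequency and the MAF filter

For one variant with genotyped patient counts #HR, #HT, #HA the cohort
allele frequency is

$$\mathrm{AF} = \frac{2\,\#HA + \#HT}{2(\#HR + \#HT + \#HA)}$$

— direct allele counting over genotyped patients. Patients with `unknown`
status appear in neither numerator nor denominator; with no genotyped
patients the AF is undefined and `allele_frequency()` errors (the matrix
version reports `NA`). `maf_filter()` keeps variants present in a
population allele-frequency table with min(AF, 1−AF) at or above the
threshold (default 0.05); variants absent from the table are removed
rather than imputed at AF 0, because the filter's purpose is to restrict
to known population polymorphisms. `af_concordance()` is the plain
Pearson correlation between AF vectors of two call sets over shared
variants.

## Survival association

Genotypes are encoded ordinally (0/1/2 = reference-homozygous /
heterozygous / alternate-homozygous) and modeled as a single additive
numeric term — an allele-dose effect — rather than as two indicator
contrasts. `unknown` genotypes are missing data (a coverage artifact, not
informative) and those patients are excluded per variant, never imputed.

`km_logrank()` wraps the product-limit estimator and the
Mantel-Haenszel log-rank test (`survival::survdiff` with `rho = 0`),
taking the p-value from a chi-square with (groups − 1) degrees of
freedom. `cox_multivariate()` fits the proportional-hazards model by
partial likelihood with Efron tie handling (the default of the fitting
routine this workflow standardises on), optionally adjusting for the
ordinal clinical covariates in `DEFAULT_COVARIATES`; complete cases only,
with the dropped count reported. Aneuploidy may be supplied as a fraction
or a percentage — the coefficient rescales accordingly and the inference
is unchanged. Bonferroni correction multiplies by the number of variants
actually tested. The test suite validates both routines against
independent brute-force oracles (direct O/E/variance evaluation at each
event time; the classical identity between the two-group log-rank
statistic and the Cox score test at β = 0).

## The synthetic cohort generator

`cohort_config()` / `emit_cohort()` generate everything the pipeline
reads, with the statistical structure the method assumes:

* **genotypes**: Hardy-Weinberg draws at true allele frequencies, by
  default Uniform(0.05, 0.5) — the frequency range that survives the MAF
  filter;
* **depth**: negative-binomial per (sample, variant), mean 60 / 80 / 30
  for normal / tumor / rnaseq. Negative-binomial rather than Poisson so
  the low-coverage tail is realistic: with dispersion size 1.0 about 15%
  of wxs-normal sites fall below 10 reads, which is what makes the rescue
  path do real work; rnaseq is deliberately shallower and more dispersed
  (size 0.8), mirroring why tumor DNA is consulted before RNA;
* **reads**: alternate counts Binomial(depth, v) with v = 0.5 (het),
  0.98 (hom-alt) and 0.005 sequencing error (hom-ref); per-read mapping
  and base qualities drawn so ~5% of reads fail the quality cuts;
  duplicates injected at rate 0.08 to exercise deduplication;
* **availability**: 5 of 7 patients have a normal sample, all have tumor
  and rnaseq samples — the cohort shape the pipeline is designed around,
  realised exactly as `round(p × n)` patients;
* **survival**: event times exponential with hazard
  h₀·exp(β·label) for a designated causal variant (default β = 0.7,
  h₀ = log(2)/24 per month, i.e. a 24-month baseline median),
  independent exponential censoring (rate 0.015/month, roughly a third
  of patients censored); covariates drawn independently within their
  ordinal ranges.

Everything is reproducible byte-for-byte from the config seed.
`simulate_status_matrices()` is a count-level shortcut (depths and alt
counts drawn directly, no read-level pileups) used for statistical
studies at hundreds of patients, where read-level simulation adds nothing
but time.

What the generator does **not** emulate: real read sequences or
alignment, capture-region structure (depth is independent across sites
rather than spatially correlated), linkage between variants (sites are
independent), RNA-specific artifacts (allele-specific expression,
RNA editing), ancestry structure, and informative censoring. Passing
tests therefore demonstrate the pipeline's logic and statistical
calibration under its own model assumptions — not robustness to
real-data artifacts, which is what the population MAF filter and the
caller upstream of this package are for.

## Numerical and scale choices

* The acceptance-style simulations use 500 patients × 200 variants for
  allele-frequency recovery (deep coverage, so the binomial sampling
  bound 3·√(p(1−p)/2n) applies cleanly), 100 replicate cohorts of 500
  patients for Cox recovery of β = 0.7, and 100 null cohorts of 300
  patients for log-rank calibration — sizes at which the parametric
  expectations are sharp but a full run stays in the tens of seconds.
* The default end-to-end cohort is 7 patients × 120 variants, the same
  shape as a realistic smoke-test subset of a large tumor cohort.
* Chunk equivalence is asserted byte-for-byte at the production chunk
  size (50,000 rows) on a 120,001-row table, covering the
  two-full-chunks-plus-remainder case.
* Ties in the caller's alt-allele choice break in base order; ties in
  duplicate removal break toward the first-encountered read; both make
  the pipeline deterministic for fixed inputs regardless of row order.

## Known limitations

* SNVs only: indels and structural variants are rejected at parse time.
* The built-in caller has no local realignment, strand-bias or position
  filters; it is a testing vehicle, not a replacement for a production
  caller.
* The per-variant survival scan refits the full Cox model per variant;
  at genome scale users would batch by chromosome and parallelise over
  variants (the fits are independent).
* Survival inference at the default 7-patient cohort size is exercised
  for plumbing, not power; meaningful association testing needs
  hundreds of patients, as the simulation studies use.
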