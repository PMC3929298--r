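---
title: "Detecting and testing de novo deletions in case-parent trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and testing de novo deletions in case-parent trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodel)
```

## The problem

A de novo deletion is a stretch of DNA present in two copies in both parents
but in one copy (hemizygous) or zero copies (homozygous) in their child.
SNP-array data summarize each marker by two quantities: the log R ratio
(LRR), a standardized log-scale total-intensity measure that sits near 0 at
two copies and drops under a deletion, and the B allele frequency (BAF),
the B allele's share of the signal, which clusters near 0, 0.5 and 1 for
AA/AB/BB genotypes at two copies. Given a cohort of case-parent trios
ascertained through an affected child (here: orofacial clefts, stratified as
cleft lip CL, cleft palate CP, or both CLP) and a cohort of control trios,
the question is whether de novo deletions occur more often in affected
children at some genomic location, and whether their physical extent differs
between groups.

Two well-known artifacts make this hard. *Genomic waves* are slowly varying,
GC-correlated intensity biases that mimic broad copy-number changes.
*DNA-source noise*: samples extracted from buccal swabs, mouthwash or saliva
are noisier than whole blood, and when sources are unevenly distributed
between cases and controls, false calls become confounded with case status.
The pipeline in this package is built around both problems.

## The minimum-distance caller

For each trio, the per-marker statistic is

d_i = the smaller (in absolute value) of (O_i − F_i) and (O_i − M_i),

where O, F, M are the offspring, father and mother LRR at marker i
(`minimum_distance()`). Any additive artifact shared by the three co-hybridized
samples — a genomic wave in particular — cancels in both differences, so the
track is wave-robust by construction. A true de novo deletion, by contrast,
shifts the offspring relative to *both* parents and survives in d.

The track is segmented per chromosome by circular binary segmentation
(`cbs_segment()`): recursively, the arc (i, j) maximizing a two-sample
contrast between the arc mean and the complement mean (common-variance
scaling) is found by exhaustive scan; the split is accepted when its
permutation p-value — obtained by shuffling the segment's values and
re-maximizing — is at most `alpha` (default 0.01, 1,000 shuffles, ties broken
by the earliest arc). Adjacent segments whose means differ by less than 0.1
are merged afterwards. Non-finite values are imputed by the chromosome
median first. The permutation loop stops early as soon as the exceedance
count proves the split cannot reach `alpha`; this changes no decision, only
the cost.

Candidate segments (mean d ≤ −0.25) are then classified by transparent
median/threshold rules (`call_state()`), in place of a model-based posterior
step: `332` (de novo hemizygous) needs the offspring median LRR ≤ −0.3,
both parent medians within ±0.15 of zero, and essentially no heterozygous
offspring BAF over the span (a true single-copy span has only A or B);
`331` (de novo homozygous) needs offspring median ≤ −2.0 and parents that
look copy-neutral in both LRR and BAF clusters (≥ 80% of markers).
Inherited patterns (`322`/`232` — one parent shares the deletion) are
recognized and *not* emitted as de novo. Final calls must span at least 10
probes. All cutoffs are `md_settings()` keys; the defaults are matched to
the generator's intensity model (deletion shift −0.45 at one copy, −3.5 at
zero copies) and to typical Illumina-scale values.

An orthogonal, genotype-only check is available in
`mendelian_inconsistencies()`: BAF-derived trio genotypes are scanned for
transmissions impossible under biallelic inheritance. Note its blind spot,
which the intensity-based caller does not share: at markers where the minor
allele is rare, a hemizygous child still reads as a plausible homozygote, so
short deletions over low-frequency markers can produce no inconsistencies
at all.

## From calls to components and association

Calls from different trios overlap only partially. `delineate_components()`
cuts the union of all call spans at every call boundary and keeps maximal
marker runs over which no trio's deletion membership (or state) changes —
the CNV components. Components are defined on marker indices, not base
pairs, so uneven marker spacing cannot create ambiguity; genomic
coordinates are attached afterwards. Components with fewer than five
carriers in cases and controls combined are not tested
(`min_count_filter()`).

Each remaining component is tested with a one-sided Fisher's exact test
(`fisher_one_sided()`): with the margins fixed, the hypergeometric
upper-tail probability that at least the observed number of carriers are
cases, computed in log space. The one-sidedness is a deliberate guard: the
control group is expected to be the noisier one (DNA sources), so excess
*control* false calls can only push p-values toward 1, never create a
spurious case signal.

Family-wise error over components is controlled by a permutation
max-statistic procedure (`permutation_fwer()`): case/control labels are
shuffled across all probands (carrier sets fixed; the observed component set
is reused in every permutation, since the filter is part of the observed
design), each component's −log10 p is recomputed, and the genome-wide
maximum recorded. The empirical 95th percentile of the null maxima (inverse
empirical CDF) is the genome-wide significance line shown in plots. Each
component's adjusted p is the add-one estimator
(1 + #{null max ≥ observed}) / (n_perm + 1), and significance is declared
when the adjusted p is at most the nominal 5%. With a continuous statistic
this is the same as crossing the threshold; with the discrete Fisher
statistic, null maxima tie at the threshold, and the threshold rule would
count a whole tie atom as rejections and inflate the family-wise rate — the
adjusted-p rule keeps the procedure exactly valid (it counts ties against
rejection, making it mildly conservative instead). The default is 10,000
permutations; 2,000 are adequate for decisions at the 5% level.

## Deletion widths

Widths are reported in kb under a fixed convention, (end − start + 1)/1000
on 1-based inclusive spans, with all calls pooled per group (not one width
per trio) — both choices are conventions that must be stated, since medians
and test statistics depend on them. Because false positives tend to be
short and can skew means, the group summary is the median
(`median_width_table()`), with the headline number the percent increase of
the cleft median over the control median, rounded to the nearest percent.
Two one-sided tests ask whether cleft deletions are stochastically larger:
a Kolmogorov-Smirnov test on D = max(F_control − F_cleft)
(`ks_one_sided()`) and a Wilcoxon rank-sum test (`wilcoxon_one_sided()`;
exact null distribution when the smaller sample has ≤ 10 tie-free
observations, full label enumeration for small tied samples, otherwise the
normal approximation with continuity and tie corrections). Finally,
`qq_null_envelope()` pools both samples, resplits them 10,000 times at the
original sizes, and builds a pointwise 95% band for the cleft-minus-control
quantile difference on a 99-point grid (0.01–0.99); where the observed QQ
curve leaves the band is reported alongside the tests.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate everything the pipeline needs:

* a 22-autosome marker panel with exponential inter-marker gaps (default
  mean 5 kb, the scale of a ~600k genome-wide array) and uniform population
  B-allele frequencies on [0.01, 0.99];
* parental genotypes from Hardy-Weinberg proportions, offspring by
  Mendelian transmission;
* LRR ~ Normal(mean(CN), sd(source)) with CN means 0 / −0.45 / −3.5 for
  2/1/0 copies — typical Illumina-scale values — and per-source SDs of
  0.12 (blood), 0.22 (buccal), 0.25 (mouthwash), 0.20 (saliva), chosen so
  that non-blood sources are visibly noisier;
* group-specific DNA-source mixes defaulting to the subject counts of the
  motivating study design (controls roughly 64% blood / 23% saliva, cases
  83% blood), which is what couples noise to case status;
* a shared smooth wave profile (three sinusoids, 0.5–5 Mb wavelengths,
  centered and unit-scaled) multiplied by a per-sample
  Normal(0, 0.05) amplitude;
* BAF clustered at genotype means with SD 0.03 at two copies, collapsed to
  the hemizygous A/B clusters at one copy, uniform at zero copies;
* planted loci (de novo hemizygous/homozygous, or inherited) carried
  per-trio with configurable group frequencies, recorded as truth with trio
  state codes `332`/`331`/`232`/`322`;
* full determinism: one global seed, with per-trio streams derived from
  (seed, trio index), so cohorts are bit-reproducible.

Case probands are assigned a cleft type from a configurable mix (default
0.30/0.28/0.42 for CL/CP/CLP); no per-type counts are published for the
motivating design, so this is a free parameter, not an estimate.

What the generator does *not* emulate: B-allele-specific intensity biases,
mosaic or fractional copy numbers, duplications, sex chromosomes,
wave profiles that differ between samples beyond amplitude, genotyping
error in parents, and relatedness between trios (some real control trios
share parents). Passing tests therefore demonstrate the pipeline's
correctness under an idealized but structurally faithful intensity model,
not its performance on raw array data.

## Quality control

`qc_filter()` applies the trio-exclusion rules before calling: a trio is
dropped whole when any member has whole-genome-amplified DNA, an external
QC flag, or an LRR median absolute deviation above 0.3. The MAD is the raw
`median(|x − median(x)|)` without the 1.4826 Gaussian consistency factor
("above 0.3" is read as strictly greater, so boundary samples are kept);
on Normal(0, σ) intensities the raw MAD is 0.6745 σ, so the default
threshold tolerates σ up to ≈ 0.44.

## A worked example

```{r example, eval = FALSE}
loci <- data.frame(chromosome = "2", start_marker = 20, width = 25,
                   case_freq = 0.25, control_freq = 0.01,
                   kind = "de_novo_hemi")
cfg <- sim_config(n_case_trios = 40, n_control_trios = 40,
                  markers_per_chrom = 60, planted_loci = loci, seed = 77)
res <- run_pipeline(cfg, tempfile("run"), n_perm = 2000, seed = 7)
print(res$assoc)
print(res$widths)
```

The run directory contains every stage's tab-separated table (QC report,
calls in a BED-like dialect, components, association results, width report,
rate and source summaries) plus a log of seeds and counts; re-running with
the same configuration reproduces all of them byte-identically.

## Numerical and design choices, in one place

* Minimum-distance ties (|O−F| = |O−M|) resolve to the father difference.
* CBS: arc statistic ties go to the lexicographically earliest (i, j);
  pruning merges the closest adjacent pair first, repeatedly; alpha 0.01,
  1,000 shuffles per split.
* The ≥10-probe rule is applied to final calls, after state classification.
* Component carrier counting ignores the `331`/`332` distinction (both are
  de novo deletions); the state mix is kept as an annotation.
* Fisher p-values are hypergeometric tails computed via `phyper` in log
  space; the permutation loop reuses a per-component lookup of all
  achievable p-values, which is exact, not an approximation.
* The permutation estimator is add-one, so adjusted p is never 0; the
  significance call uses adjusted p ≤ 5% (see above for why, under ties).
* Rounding for report tables is half-up: 2 decimals for per-child rates,
  3 for source proportions, nearest integer for percent width increase.
* Problem sizes used in the shipped tests — cohorts of 40–100 trios,
  panels of 50–100 markers per chromosome, 1,000–4,000 permutations — were
  chosen so the full suite exercises every stage end-to-end at desk scale;
  all of them scale up by configuration only.

## Limitations

The caller's decision rules are deliberately transparent rather than
model-based; a posterior-probability step could integrate BAF and LRR
evidence more efficiently for marginal calls. Sensitivity claims are tied
to the generator's intensity model (a −0.45 one-copy shift against
SD 0.12–0.25 noise over ≥ 20 markers is an easy regime; shorter or
shallower events will be missed). The association stage tests carrier
frequency only — it does not model per-trio call counts, and the
permutation exchanges proband labels, which assumes trios are independent.
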