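---
title: "brewtrack: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{brewtrack: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brewtrack)
```

This vignette is the package's own account of the methods it implements:
what each stage assumes, which parameters matter, what the synthetic-data
generator does and does not emulate, and where a genuinely open design
question was decided one way rather than another.

## The setting

A brewing fermentation sampled at several time points in two production
batches (an early and a late repitch), two replicates per sample, measured
by label-free shotgun proteomics; alongside, short-read sequencing of the
(largely tetraploid) strain summarised as windowed read depth and
per-variant allele counts. The package consumes tabular exports of that
design — peptide evidence, sample metadata, flat annotation tables, depth
and variant tables — never raw spectra or reads. Database searching, LFQ's
delayed normalization, read alignment, and variant calling are explicitly
out of scope; a documented column mapping makes real exports drop-in.

## Quantification

**ppm from spectral counts.** The theoretical peptide space of a protein is
its tryptic digest (cleave after K/R, not before P) with 0 missed
cleavages, deduplicated, filtered to 7–40 residues. The correction factor
is the reciprocal of the summed lengths of that set; a protein's per-sample
signal is `sum(PSM x peptide length) x correction_factor`, scaled to parts
per million of the sample total. Two choices deserve a note:

* *Operator order.* The defining sentence for this metric is ambiguous
  about whether PSMs are multiplied by peptide length before or after the
  correction factor. Both readings differ by a per-protein constant; we
  multiply each peptide's PSM count by its own length and then apply the
  factor, which makes the signal a length-normalized fraction of the
  protein (a protein observed completely, once, scores 1). The reading is
  documented here rather than asserted as the only possible one.
* *Unique peptides.* The theoretical space is deduplicated at the sequence
  level. Without deduplication a protein containing a repeated tryptic
  peptide would have its correction factor inflated relative to its
  observable evidence, breaking the invariant that under noise-free
  conditions ppm preserves the true abundance ranking.

Missed cleavages: the theoretical space uses 0 so overlapping peptides are
not double-counted; evidence peptides may carry up to 2 (typical search
settings) and are matched by exact sequence. Isoleucine and leucine are
distinct characters. Missing values are stored as `NA`, never 0, before any
log transform.

**iBAQ** divides the summed peptide intensity by the count of theoretical
in-range peptides, using the same 7–40 window as ppm (the classic 6–30
window is a `digest_params()` call away); one digestion parameterization
across metrics beats two silently different ones.

**Between-sample normalization** is median-ratio scaling to a geometric-mean
pseudo-reference over proteins detected in every sample (the DESeq
size-factor construction). It stands in for the delayed-normalization step
of LFQ pipelines, which is out of scope; it corrects a per-sample loading
constant and nothing subtler. It refuses to run with fewer than 3
universally detected proteins.

**Replicate handling.** `merge_replicates()` sums intensities across
replicates of a batch/time point — maximizing detections — and records a
detection flag per protein and time point. The strict rule (default)
requires presence in *all* replicates and withholds the merged value
otherwise; this is the rule differential expression expects upstream.
Clustering and correlation analyses use the permissive rule, where one
replicate suffices, trading a little noise for coverage.

## Differential expression

Values are log2-transformed (intensities are log-normal, so this
approximately normalizes) and centred on each sample's median of detected
values, which absorbs per-sample scale: DEP calls are invariant to
rescaling any sample's raw intensities, and the suite tests this.

The test is a two-sample t-test per protein; **Welch** by default because
with tiny group sizes the equal-variance assumption buys little and costs
robustness (`var_equal = TRUE` restores the pooled test). With n = 2 per
group the test is honest but unstable, and `test_contrast()` says so once
per call; simulation-based checks in this package use 4 replicates per
group. Zero-variance degeneracies are resolved by definition rather than
left as `NaN`: identical groups give p = 1, a nonzero difference with zero
within-group variance gives p = 0.

BH adjustment is applied **per contrast over the proteins tested in that
contrast**, matching per-comparison reporting of DEP counts; a global
adjustment across all 91 pairs of a 14-group design would answer a
different question. `bh_adjust()` is the package's own step-up
implementation (it is part of the tested surface) and the suite proves it
identical to both `p.adjust(, "BH")` and a brute-force evaluation of the
step-up definition on random vectors. The DEP definition is symmetric:
`|log2FC| >= 1` in either direction.

## Clustering and enrichment

Profiles are centred on their row mean and filtered to proteins moving at
least 2-fold from it (1.0 log2 units) at some time point; flat profiles
carry no shape information. The distance is **1 − Pearson correlation**
across time points — profile-shape clustering in the Morpheus tradition —
with Euclidean available when amplitude matters; the linkage is average.
Constant rows have undefined correlation; they are assigned distance 1
(uncorrelated) to every partner, with a warning, rather than crashing or
being silently dropped. Residual missing cells are imputed with the row
mean (0 after centring) and counted. Rows are sorted by protein id before
clustering so ties break identically on every run.

Clusters are extracted by **node depth from the root** (root = 0): the cut
at depth *d* collects every node at depth *d* plus any leaf that attaches
higher, so it yields at most 2^d clusters — the arithmetic that makes "8
clusters at depth 3" possible. Clusters exceeding 500 proteins are re-cut
at depth 5 within their subtree. Note what this cut does *not* promise:
node depth ignores merge heights, so a tight planted cluster sitting at
depth 2 will be split at depth 3 regardless of how low its internal merges
are. On well-separated data the spurious splits are tiny (the recovery
check below scores ARI ≈ 0.99 despite 8 labels for 6 planted clusters).

Enrichment is the one-sided hypergeometric upper tail per term with
overlap ≥ 1, BH across tested terms, passing at adjusted p < 0.05. The
default universe is the detected protein set, not the whole proteome —
detection bias otherwise manufactures enrichments — and is configurable.

## Co-regulation analyses

Sample similarity is all-by-all Pearson over proteins detected in both
samples of a pair, with the pair's n reported and pairs sharing fewer than
3 proteins flagged. Protein-pair correlations are computed across merged
time-point profiles for proteins detected in ≥ 2 time points (the
eligibility threshold), but a *pair* needs ≥ 3 shared points to be
meaningful — a two-point correlation is ±1 by construction — so such pairs
are flagged and excluded from distribution summaries. Eligibility and pair
validity are deliberately separate rules.

Complex and compartment profiles report the fraction of members detected
and the member-pair correlation distribution; multi-localized proteins are
duplicated into each compartment so no information is lost, and duplicated
pairs are deduplicated in global summaries. The interacting versus
non-interacting comparison uses a Wilcoxon rank-sum test with the median
difference as the reported shift — a rank-based choice because the claim
being probed is only that one distribution is more correlated, not any
parametric form.

## Pathway perturbation

DRPS for a reaction is the maximum over its entities of the entity's
between-sample range (max − min of the row-mean-normalized log2 profile);
multi-enzyme reactions thus score through their most perturbed isozyme, the
natural reading when any isozyme suffices to carry flux. DPPS is the root
mean square of a pathway's reaction DRPS values, with the divisor counting
**all** reactions including unmeasured ones (which score 0). That literal
reading penalizes sparsely measured pathways; `measured_only = TRUE` flips
the divisor for sensitivity analysis. The scores are scale-equivariant and
monotone in any entity's range, and both properties are tested.
`leave_out_rerank()` re-scores with chosen enzymes deleted from every
reaction, keeping emptied reactions in the divisor, so a pathway whose rank
was carried by shared enzymes falls honestly rather than shrinking its
denominator.

## Genome profiles

Depth windows are non-overlapping 1,000-bp tiles (a step parameter would
give true sliding; tiling is the default because window-level copy calls do
not benefit from overlap). Copy number is `ploidy x depth / genome-wide
median depth` — scale-invariant by construction — reported continuous and
rounded, with per-chromosome medians. Deletion candidates are maximal runs
of ≥ 3 copy-0 windows. Variant filtering uses minimum coverage 10, minimum
alternate count 2, minimum frequency 0, and drops mitochondrial records;
concatenated genome positions are cumulative chromosome offsets in the
supplied order, so they are strictly increasing along the genome.
LOH candidates are maximal runs of ≥ 10 consecutive variants with allele
frequency outside the heterozygous band [0.1, 0.9] — a conservative
formalization of the frequency-versus-position plot, not a reimplementation
of a likelihood-based caller. Windows are 0-based half-open; variant
positions are 1-based (VCF convention); both are documented in the I/O
help.

## The synthetic-data generator

`sim_config()` defaults describe the emulated study: 2 batches x 7 time
points (0–168 h, the last being a post-crash sample) x 2 replicates;
log-normal base abundances (natural-log mean 13, sd 1.8, an intensity-like
scale); replicate CV 0.1 (chosen to land replicate correlations in the
mid-0.9s, the concordance regime of good label-free data); a per-batch/time
biological component with sd 0.3 shared between replicates; logistic
detection in peptide log intensity centred at 9 so dropout concentrates in
the low-abundance tail, mirroring the observation that low-copy proteins go
undetected; and per-peptide ionization efficiencies (log-sd 0.8).

Planted structure: temporal clusters use harmonic archetypes (rise, fall,
mid peak, mid dip, two oscillations) spanning 4-fold, chosen mutually
orthogonal or anti-correlated so that profile-shape clustering sees
genuinely distinct classes; complexes draw members from the flat background
and share a latent temporal component weighted `sqrt(rho)`, so the target
within-complex correlation is `rho` in the latent component (observed
correlations sit slightly below it once replicate noise is added — with the
defaults, a target of 0.7 yields observed medians around 0.65).

PSM counts are the expectation `psm_rate x (log intensity − floor)`
rounded and floored at 1 — deterministic given the (noisy) intensity. A
Poisson draw was considered and rejected: the generator promises that the
zero-noise limit (`replicate_cv = 0`) produces byte-identical replicates
and that noise-free ppm preserves the true abundance ranking, and an
independent count draw satisfies neither. Detection draws share a quantile
stream between replicates of a batch/time point for the same reason.

The pseudo-genome is 4 chromosomes x 500 windows x 1,000 bp at ploidy 4 —
"largely tetraploid" at toy scale — with Poisson depth around
`baseline x copy/ploidy`, heterozygous sites on the tetraploid ladder
(0.25/0.5/0.75), and LOH blocks whose sites become alt-fixed or vanish
(ref-fixed sites are never emitted, as a variant caller would not report
them).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: retention-time or m/z structure, peptide
misidentification, protein-group ambiguity, batch effects beyond a scale
factor, missingness that is not abundance-driven, correlated noise across
proteins other than the planted components, mappability or GC bias in
depth, and linked-variant haplotype structure.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on generated data at
these sizes, chosen to make the Monte-Carlo checks statistically meaningful
while keeping a full run in the minutes range: 1,000 proteins x 50 (tests)
or 25 (script) replicates for the null false-discovery check; 200 proteins
x 50/25 replicates for 4-fold power; 600 proteins for cluster recovery;
300 proteins, 10 complexes of 5 at target correlation 0.7 for the
co-regulation shift; 20 pathways with 3 shared drivers for the leave-out
check; the default 2,000-window genome for copy/LOH recovery.

Conventions: ppm conservation is exact to floating point (the suite allows
1e-6 relative); equal-value ties in ranking are broken by id; `NA` p-values
pass through BH untouched; all generators are deterministic given
`sim_config(seed)`, and derived seeds stay within 32-bit integer range.

## Known limitations

The t-test with n = 2 is reported but fragile; no moderated-variance or
batch-effect model is provided by design. Node-depth cutting can split
tight clusters (see above). The DPPS entity aggregation (max over
isozymes) is one defensible reading of an under-specified rule, flagged as
such. LOH segmentation is run-length based and will fragment under sparse
variant density. Protein-group inference is out of scope: evidence is
taken at the protein ids given.
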