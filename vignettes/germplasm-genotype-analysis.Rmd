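---
title: "Clones, kin and ploidy in germplasm collections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clones, kin and ploidy in germplasm collections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonekin)
```

This vignette is the package's own account of the statistical machinery:
the models, the tunable parameters and why their defaults are what they
are, what the simulator does and does not emulate, and the numerical
choices a maintainer would want written down.

## The problem

A gene bank of a clonally propagated, highly heterozygous crop (apple is
the motivating case) accumulates three kinds of hidden structure:
grafted duplicates of one genotype (including somatic "sport" variants),
dense webs of parent–offspring relationships among historical cultivars,
and triploid accessions arising from unreduced gametes. All three
confound naive diversity analyses, and all three are recoverable from a
few thousand genome-wide SNPs.

## Genotype model and the filter cascade

Genotypes are alt-allele dosages in {0, 1, 2, NA} at bi-allelic SNPs.
`read_vcf()` performs the read-time filters (bi-allelic SNP records
only; genotypes below the depth floor set missing), and
`filter_cascade()` applies, in order:

1. **thinning** (`thin_bp = 10`): greedy left-to-right scan per
   chromosome, keeping a locus iff it is at least 10 bp (1-based
   distance) from the last kept locus. Greediness makes the result
   deterministic and order-free of any tie-breaking.
2. **missingness** (`max_missing = 0.2`): loci with > 20% missing calls
   are dropped first, then samples with > 20% missing over the
   *surviving* loci. The cap is applied in both dimensions because the
   20%-missing rule is stated per sample and per locus; computing sample
   missingness after the locus pass avoids penalising samples for loci
   that were about to disappear anyway.
3. **depth percentile cap** (`depth_percentile = 90`): loci whose mean
   depth exceeds the empirical 90th percentile are removed as likely
   collapsed paralogues. The percentile uses the linear-interpolation
   convention (`stats::quantile`, type 7) — survivor counts depend on
   this, so it is fixed and documented. This is the one filter that is
   *not* idempotent: re-applying it recomputes the order statistic on
   the survivors and necessarily trims again, which is inherent to any
   percentile rule, so the cascade applies it exactly once. Its identity
   cases (all depths equal; percentile 100) behave as expected.
4. **Hardy–Weinberg exact test** (`hwe_alpha = 1e-4`): the conditional
   exact test enumerates all heterozygote counts compatible with the
   observed allele counts (same parity as the rare-allele count) via the
   classical probability recurrence, and removes loci whose two-sided
   p-value is below 1e-4. Two-sided is the default because that is what
   the usual VCF-filtering tools compute; a one-sided excess-heterozygote
   alternative (`alternative = "excess.het"`) is available since excess
   heterozygosity is the signature of paralogue collapse.
5. **MAF** (`min_maf = 0.05`, strict): minor allele frequency is
   computed from integer allele counts, `min(ac, an − ac)/an`, never by
   folding the frequency in floating point — `1 − 0.95` is slightly
   above 0.05 in double precision and would leak loci through a strict
   threshold.

The cascade order follows the order in which the filters are
conventionally listed; no result in the package depends on the order
beyond the survivor counts in the logged `filter_report`.

## Method-of-moments identity by descent

For a pair of individuals, each locus contributes an identity-by-state
class: IBS2 (equal dosages), IBS0 (opposite homozygotes), IBS1
(otherwise), with missing-either loci excluded (pairwise-complete
deletion, matching the semantics of the classic `--genome`
implementation). Under random mating with allele frequency p, the
conditional probabilities of each IBS class given the latent IBD state
(sharing 0, 1 or 2 alleles identical by descent) are polynomial in p;
summed over loci they give expected class counts per IBD state. The
moments cascade solves for (ẑ0, ẑ1, ẑ2) in turn:

\[
\hat z_0 = \frac{N_{IBS0}}{E[IBS0|IBD0]},\qquad
\hat z_1 = \frac{N_{IBS1} - \hat z_0 E[IBS1|IBD0]}{E[IBS1|IBD1]},\qquad
\hat z_2 = \frac{N_{IBS2} - \hat z_0 E[IBS2|IBD0] - \hat z_1 E[IBS2|IBD1]}{N},
\]

then clamps each to [0, 1] and renormalizes to sum to one;
π̂ = ẑ1/2 + ẑ2. Design choices:

- **Plug-in frequencies, no small-sample bias correction.** The
  correction is O(1/n) in the sample count; every decision surface in
  the package (clone threshold 0.85, first-degree band width 0.09) is
  far wider than that. This is a deliberate, documented deviation from
  the classic implementation's internals.
- **Clamp-then-renormalize.** The raw linear solution can leave [0, 1]
  (sampling noise; small samples); clamping plus renormalization is
  deterministic and keeps π̂ ∈ [0, 1]. The unclamped solution is kept as
  an attribute and tested against an independent linear solve of the
  3×3 moment system. One consequence worth knowing: when frequencies
  are estimated from very few samples (e.g. a lone trio), ẑ2 can go
  negative and the constrained estimate collapses to exactly 0.5 for a
  parent–offspring pair; with frequencies from a realistic collection
  (dozens of samples) the estimator behaves smoothly.
- **One frequency estimate per matrix.** Frequencies are estimated once
  from the matrix being analysed (after the MAF filter, matching the
  stage order), and loci at boundary frequencies are excluded from both
  the counts and the expectations, so both always refer to the same
  locus set.

An identical error-free pair gives N_IBS0 = N_IBS1 = 0, hence ẑ2 = 1 and
π̂ = 1 *exactly*; a true parent–offspring pair has expected
(z0, z1, z2) = (0, 1, 0) and π̂ = 1/2.

## Relationship networks

Clonal edges use π̂ > 0.85 — strictly greater, the threshold as printed;
the margin below the theoretical π̂ = 1 absorbs genotyping error and
somatic mutation between grafted clones. First-degree edges use the
closed band [0.43, 0.52], a calibration obtained on known pedigrees at
a marker density of ~15k SNPs; the package treats the band as a
configurable parameter, not a universal constant, because its
generalization to other densities is not established. Pairs falling
between the bands (0.52 < π̂ ≤ 0.85) are neither dropped nor classified:
they are reported in an audit table (`audit_unclassified` in the run
report), since second-degree relatives and aunts/uncles of inbred lines
live there.

Components come from standard undirected connected-components (igraph).
Deduplication keeps one representative per clone group — seeded-random
by default (reproducible via the pipeline seed), lexicographic-minimum
as a fully deterministic alternative for documentation runs.

The pipeline order is fixed: clone network on all samples → dedupe →
ploidy exclusion → recompute IBD on unique diploids → first-degree
network. Recomputing IBD after exclusions matters because the plug-in
frequencies change when duplicates leave the matrix.

## Ploidy from heterozygosity

A triploid formed from an unreduced diploid gamete and a haploid gamete
is heterozygous wherever its three alleles are not identical; under
Hardy–Weinberg proportions that probability is 1 − p³ − q³ = 3pq,
against 2pq for a diploid — a ratio of exactly 3/2 at every allele
frequency. Per-individual heterozygosity is therefore bimodal in a
mixed-ploidy collection, and a diploid-style caller's collapsed calls
(AAB and ABB both read as heterozygous) preserve the signal.

The default classifier (`classify_valley()`) finds the exhaustive 1-D
two-means split of the observed heterozygosities and uses the boundary
pair as thresholds. A split is only accepted when the optimal
within-cluster sum of squares is below 20% of the total sum of squares:
two genuinely separated clusters leave a few percent within clusters,
while the best split of a single noise cluster still leaves well over a
third (≈ 1 − 2/π for a normal), so the cutoff sits in a wide empty
margin between the regimes; otherwise the input is flagged unimodal and
everything is called diploid with a warning. The fixed thresholds
(0.335, 0.345) are available via `classify_fixed()`; values strictly
between the thresholds are *ambiguous* and excluded from downstream
kinship analysis with a warning. There is no tetraploid class — a
heterozygosity far above the triploid cluster triggers a warning, never
a 4x call. In collections where triploids descend from a narrow diploid
base the two modes can merge; the simulator can produce that regime, and
the package then (correctly) refuses to split.

Observed ratios on real collections are expected *below* 1.5 — gene
banks are not equilibrium populations — so the package reports the
observed ratio rather than asserting the analytic one on data.

## PCA and group tests

Missing dosages are mean-imputed per locus (the deliberately simple
choice; an LD-kNN imputer is out of scope, so imputation accuracy is not
a claim this package makes), columns are centered and scaled by the
population (divide-by-n) standard deviation — the convention is stated
because the upstream tool's convention is not recoverable — and
zero-variance columns are dropped rather than divided by zero. PCA is a
plain SVD; explained fractions are squared singular values over their
total, and component signs are normalized (largest-magnitude loading
positive) so documented output is reproducible. Before PCA the pipeline
applies MAF > 0.01 and LD pruning (window 10 SNPs, step 3, r² > 0.5;
within a violating pair the lower-MAF locus is removed, ties broken
against the later position — the reference implementation's exact
internal rule is undocumented, so the package fixes its own
deterministic one and machine-checks the postcondition).

Group separation along a PC uses the Mann–Whitney U test: exact by
enumeration when the combined sample size is ≤ 12 with no ties (exact
enumeration is cheap there), otherwise the normal approximation with tie
and continuity corrections. All p-values in the five-PC comparisons are
Bonferroni-multiplied by 25 and capped at 1. Cross-marker concordance
(`correlate_pc_sets()`) reports Pearson r with t-distribution p-values
under the same correction; SSR-side scores enter as an external score
table, since SSR allele calling is outside this package.

## The simulator and what passing tests mean

`simulate_collection()` builds: unrelated founders with dosages
Binomial(2, p) at frequencies drawn i.i.d. U(0.05, 0.5); clone groups by
symmetric per-call corruption of one source founder (error rate 0.2% by
default — a single combined rate for genotyping error plus somatic
mutation, since the two are not separable in practice); offspring by
Mendelian sampling of one allele per parent per locus; triploids by the
unreduced + haploid gamete model collapsed to diploid-style calls; and
i.i.d. missingness (5%). The default configuration mirrors a diverse
collection of 349 accessions: 182 founders, 42 clone groups (31 pairs,
largest group 15; 77 duplicates), 24 crosses and 66 triploids (19%).
Clone sources, cross parents and triploid unreduced-gamete parents are
disjoint founder subsets, and each triploid has a distinct diploid
parent — two triploids sharing the unreduced gamete's parent would carry
the same full diploid genome and be indistinguishable from clones, which
would make the ground truth ambiguous rather than the inference wrong.

Deliberately **not** emulated: linkage (loci are unlinked; the LD pruner
is exercised on duplicated/correlated columns instead), selfing,
multi-generation pedigrees, aneuploidy, and read-level error structure
(depth-correlated miscalls). Consequently, passing truth-recovery tests
demonstrates that the estimators and thresholds are internally
consistent under the stated population model — not that the thresholds
are optimal for any particular real collection, where LD, population
structure and reference-genome artefacts widen every distribution.

Typical problem sizes used by the test suite — collections of 40–60
samples at 2,500–3,000 loci for end-to-end runs, 5,000 loci for
estimator calibration checks, 20 seeds for recovery properties — were
chosen as the smallest sizes at which the quantities under test are
stable; the relevant separations (clone π̂ near 1 vs. first-degree near
0.5 vs. unrelated near 0; heterozygosity modes 2pq vs 3pq) are many
standard errors wide there.

## Numerical and degenerate-input conventions

- Frequencies at 0 or 1 are uninformative for IBD and are skipped (with
  a warning) consistently in counts and expectations; a locus with no
  non-missing calls has *undefined* frequency (NA + warning), never a
  silent 0.
- Half-called VCF genotypes (`./1`) and anything containing `.` decode
  as missing; phased and unphased separators are equivalent.
- A pair with zero pairwise-complete loci yields an NA record with a
  warning, not an error, so one bad pair cannot abort a full run.
- The HWE recurrence rescales when unnormalized weights approach
  overflow, and the two-sided tail uses a 1 + 1e-9 relative tolerance
  when comparing configuration probabilities, the standard guard
  against ties broken by rounding.
- `write_vcf()` emits plain text (GT, optionally DP); a written matrix
  re-read with depth threshold 0 reproduces calls, coordinates and
  sample order exactly, including a header-only file for an empty locus
  set.

## Known limitations

The first-degree band cannot separate parent–offspring from full
siblings (both sit near π̂ = 0.5); orientation of parent vs offspring
needs historical metadata and is out of scope. Survivor counts of the
filter cascade on real data depend on conventions (percentile
interpolation, strictness at thresholds) that differ between tools, so
they are logged but not treated as reproduction targets. The
MoM estimator assumes a homogeneous reference population for its
frequencies; strong structure biases π̂ upward for within-subpopulation
pairs, which is one more reason the thresholds are configurable.
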