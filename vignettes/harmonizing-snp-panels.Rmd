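---
title: "Harmonizing independently genotyped SNP panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing independently genotyped SNP panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpharmony)
```

# The problem

Combining SNP genotype datasets produced by different studies promises
range-wide resolution no single study can afford, but the merge itself can
manufacture artifacts stronger than the biology. `snpharmony` treats the
merge as a statistical procedure with testable guarantees rather than a
bookkeeping step. This vignette describes the models and rules the package
implements, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic validation does and does not
demonstrate.

# Strand ambiguity and its resolution

A biallelic SNP reported on opposite strands by two platforms carries
complemented allele labels. For most allele pairs the complement is a
*different* pair, so the conflict is detected and repaired mechanically
during panel intersection: pairs that are reverse complements of the
reference panel's pair are relabelled, and when the designated
(dosage-counted) allele swaps in the process, dosages are recoded
g → 2 − g. For A/T and C/G SNPs ("ambiguous" loci) the complement is the
*same* pair, the labels are uninformative, and an undetected flip inverts
every genotype.

The package resolves ambiguous loci by allele-frequency comparison at
*geographic replicates*: the same biological population sampled
independently by two datasets, where true frequencies are shared and any
systematic inversion is visible. One subtlety is worth recording: a strand
flip leaves the stored allele *pair* of an ambiguous locus unchanged as a
set, so its entire observable effect is the dosage inversion g → 2 − g.
The simulator injects flips exactly this way, and `apply_strand_flip()`
implements the (involutive) correction the same way.

## Calibration of the MAF threshold

Frequency comparison can only identify a flip when the frequency is far
enough from 0.5 that "which allele is minor" is stable across sampling
noise. Rather than assume a safe zone, the procedure measures it on the
loci where truth is known — the unambiguous shared loci:

* at each replicate locale, loci are binned by the reference dataset's
  minor allele frequency into cumulative intervals MAF ≤ x,
  x ∈ {0.05, 0.10, …, 0.45};
* the error rate at x is the fraction of binned loci whose
  reference-minor allele exceeds frequency 0.5 in the other dataset —
  loci a frequency rule would mis-orient;
* confidence is 1 − error, averaged across locales;
* the selected threshold is the **largest** grid value with mean
  confidence ≥ 0.95 and per-locale confidence strictly > 0.95 (the
  strictness at locale level follows the published rule's wording; both
  comparisons are configurable via `confidence_requirement`).

On data with no cross-dataset artifacts every interval has zero error and
the rule deterministically selects the grid maximum, 0.45 — the package's
primary acceptance check, recomputed by `scripts/acceptance.R`.

## Resolution rule

Given threshold t, each ambiguous locus receives a verdict per locale from
the designated-allele frequencies f_ref, f_alt:

* MATCHED: both below t, or both above 1 − t;
* FLIPPED: one below t and the other above 1 − t;
* INCONCLUSIVE: either frequency inside [t, 1 − t], or undefined (no
  calls).

The band is symmetric around 0.5 because the designated allele is
arbitrary; this is the only reading under which the rule is well defined
for frequencies of either allele. The final decision demands a *consistent
consensus*: FLIP only if every locale says FLIPPED, KEEP_AS_IS only if
every locale says MATCHED, otherwise DISCARD. This is the strictest
reading of consensus; `consensus = "majority"` relaxes it to a majority of
conclusive verdicts for panels with many locales.

# Tiered locus QC

Per (locus, sampling location):

* **Missingness rule A** — discard when the call rate is ≤ 0.60 in any
  location. "Any sample" is interpreted as the locus-within-location call
  rate, the reading under which the rule composes with per-location
  genotype tables.
* **Missingness rule B** — discard when the missing fraction is ≥ 0.15 in
  more than five locations.
* **HWE** — exact conditional test of Hardy–Weinberg proportions (full
  enumeration of the heterozygote-count distribution given allele counts)
  at every location with ≥ 2 called individuals. The enumeration is O(n)
  per test and memoized over repeated count configurations, so it is used
  at every sample size; nothing is approximated. FDR control is
  Benjamini–Hochberg applied *jointly* across all locus × location tests
  (π0 = 1, hence conservative relative to estimators that fit π0, and
  fully deterministic). A locus is discarded when significant (q ≤ 0.05)
  in more than three locations.
* **Replicate FST screen** — per replicate pair, per-locus Weir–Cockerham
  θ between the two samples; the upper set is loci at or above the
  empirical 95th percentile (linear-interpolation quantile, ties
  included) *among loci with defined and positive θ*. A locus in the
  upper set of more than one pair is discarded. Requiring θ > 0 encodes
  what the screen is for — elevated divergence between samples that
  should be identical; non-positive estimates cannot be evidence of
  divergence, and the restriction makes the degenerate case (identical
  replicate samples, all θ ≤ 0) cleanly yield an empty outlier set.

## Stage order

The default order is: intersect → strand calibration and resolution →
missingness → HWE → replicate FST screen → merge. Running strand
resolution *first* is deliberate: an uncorrected flip makes its replicate
pair look maximally divergent, so with the screen first, genuinely
correctable loci land in every pair's upper-5% set and are discarded
instead of repaired — the screen would silently eat exactly the loci the
calibration machinery exists to save. The alternative order
(`stage_order = "qc_first"`) is retained for sensitivity analysis, since
published descriptions of such pipelines are rarely explicit about whether
calibration used post-QC loci.

Every shared locus receives exactly one final status (RETAINED /
DISCARDED) in the QC ledger, with the rule that fired and a detail string;
conservation (retained + discarded = shared) is asserted in the tests.

# Population-genetic statistics

* **Heterozygosity.** Ho is the heterozygote fraction among called
  individuals; He = 2pq; uHe = He·2n/(2n − 1). Location means are
  unweighted over loci with ≥ 1 call.
* **Weir–Cockerham θ (1984).** The unequal-sample-size estimator with
  variance components a (among populations), b (among individuals within
  populations), c (within individuals), including the observed
  heterozygosity term — chosen over simpler moment estimators because it
  remains unbiased at the modest per-location n (9–40) the pipeline
  targets. Multi-locus θ is the ratio of sums Σa / Σ(a+b+c) over loci
  with a defined denominator, never a mean of per-locus ratios. Negative
  estimates are reported as-is: clamping would bias replicate-pair
  diagnostics, whose expectation is ≤ 0 for identical populations.
  Undefined (both samples monomorphic for the same allele) is NA and
  excluded from sums.
* **Mantel isolation-by-distance test.** Pearson correlation of
  upper-triangle FST/(1 − FST) against distance; significance by joint
  row/column permutation with the add-one rule
  p = (1 + #{r\* ≥ r}) / (1 + N). One-tailed (greater) by default because
  isolation by distance predicts positive correlation; two-tailed by
  flag. When N covers the permutation group (N ≥ n! − 1, n ≤ 8) the test
  enumerates all permutations: the p-value is then exact, seed-free, and
  invariant under joint relabelling. The permutation count and tail were
  design choices (defaults 9,999 and one-tailed), both configurable.
* **Welch t.** Within- versus between-region pairwise FST values compared
  with the unequal-variance statistic and Satterthwaite degrees of
  freedom. Regional mean FST is computed over pairwise multi-locus
  values, matching how the contrast is used downstream.
* **Upper-quantile outlier sets.** `stats::quantile` type 7 (linear
  interpolation) with ≥-inclusion at the cut; the convention is stated in
  output metadata because discard sets depend on it.

# The synthetic-data generator

`emit_datasets()` emulates the structure of a multi-study range-wide
dataset; its defaults are the package's standard validation conditions:

| parameter | default | meaning |
|---|---|---|
| `n_loci` | 1000 | candidate shared loci |
| `n_populations` | 12 | demes on a line |
| `n_datasets` | 3 | contiguous geographic blocks; dataset 1 = reference |
| `per_pop_n` | 40 | diploids per sampling location |
| `fst_divergence` | 0.02 | per-step Balding–Nichols F of the frequency walk |
| `ancestral_maf_range` | (0.05, 0.5) | uniform ancestral MAF |
| `frac_ambiguous` | 0.20 | A/T, C/G loci |
| `frac_flipped` | 0.50 | of ambiguous loci flipped in non-reference datasets |
| `flip_maf_ceiling` | 0.35 | flips only where locale MAF permits resolution |
| `missing_rate` | 0.02 | per dataset |
| `replicate_locales` | 3 | demes sampled by both datasets 1 and 2 |
| `step_km` | 150 | deme spacing |

Population frequencies follow a stepping-stone random walk: each deme's
frequency is a Balding–Nichols Beta draw centred on its neighbour with
variance F·p(1 − p), clipped to [0.001, 0.999] to avoid fixation
degeneracies. Divergence therefore accumulates with distance, giving
isolation by distance by construction; `truth_pairwise_fst()` computes the
parametric pairwise FST implied by the true frequencies (the large-sample
limit of the Weir–Cockerham ratio-of-sums under within-deme HWE), which
the panel estimator recovers within ±0.02 in the tests. An island-model
variant (`structure = "island"`) draws demes independently for clean
Balding–Nichols parameter recovery.

Choices worth recording:

* **Per-location n = 40** sits at the top of the 9–40 range typical of
  such surveys; it keeps binomial frequency noise (sd ≈ 0.056 at
  MAF 0.35) small enough for locale verdicts to be conclusive.
* **One shared flip set** across non-reference datasets, because
  platform-induced strand conventions travel with the genotyping
  protocol, not with the dataset label; replicate pairs exist only
  against dataset 2, exactly as when one dataset has no spatial overlap
  with the others and must inherit its strand convention.
* **Flip eligibility at the locales.** Flips are injected only at
  ambiguous loci whose true MAF at every replicate locale is ≤
  `flip_maf_ceiling` (0.35). A flip at locale MAF near 0.5 is
  unidentifiable by frequency comparison *in principle* — no threshold
  can see it — so injecting it would test nothing about the resolution
  machinery; the generator's truth is restricted to the identifiable
  regime the ceiling defines.
* **Ascertainment** keeps loci with MAF ≥ `ascertainment_floor` in a
  discovery deme (default floor 0, i.e. off; validation scenarios use
  0.2 to emulate a common-marker panel discovered at one end of the
  range). Conditioning on discovery-deme polymorphism biases retained
  loci toward diversity near the discovery population, reproducing the
  observed-heterozygosity decline with distance that real
  discovery-panel data show.
* **`replicate_identical`** (default off) copies the reference replicate's
  genotypes into the alternate dataset instead of redrawing them; it
  exists purely for idealized no-noise checks (e.g. clean-data identity
  of the harmonization), not as a realistic condition.
* A single seeded RNG stream drives every stochastic step in documented
  order, so equal configurations are byte-identical.

## What the synthetic validation does not show

The generator draws unlinked loci under within-deme Hardy–Weinberg
proportions (optionally with inbreeding), with spatial structure limited
to a 1-D stepping stone and missingness missing-completely-at-random per
dataset. It does not emulate linkage or chromosomal inversions, genotyping
error other than strand flips, family structure, or informative
missingness. Passing tests therefore demonstrate correctness of the
*procedures* under the stated models, not robustness of the science to
every artifact of real array data; on real data the QC counters in the
ledger and the calibration table are the diagnostics to read first.

# Numerical and degenerate-input conventions

* Undefined frequencies (zero calls) propagate as inconclusive verdicts,
  never exceptions; monomorphic HWE tests return p = 1.
* The HWE exact p-value includes all heterozygote counts whose
  conditional probability is ≤ the observed within a 1 + 1e−12 relative
  tolerance, and is clipped to 1 against floating-point accumulation.
* Mantel inputs that are constant (zero variance in either
  upper-triangle vector, e.g. zero deme spacing) are a degenerate-input
  error, as is linearization with any FST ≥ 1.
* Calibration with an empty cumulative bin at some grid value leaves that
  value ineligible for selection; empty bins everywhere is an error.
* Welch t with zero variance in both groups and equal means is an error;
  with unequal means it returns ±Inf with p = 0 and a warning-free
  degenerate df of NA.
* Validation sizes: the test suite runs the full generator at its default
  1,000-locus, 12-deme scale for flip recovery (20 seeds) and false-flip
  control (50 seeds), 500-locus panels for FST recovery and
  isolation-by-distance power (100 seeds), and full enumeration of every
  HWE configuration to n = 50 — sizes chosen so each property is measured
  at the generator's stated study conditions.

# Known limitations

* Locus matching is by locus id only; there is no positional liftover, so
  datasets must share a naming scheme for the intersection to be
  meaningful.
* The Genepop dialect fixes allele codes 01–04 = A, C, G, T to keep
  nucleotide identity recoverable; a locus monomorphic in a written file
  necessarily loses its second allele on reload (the VCF path preserves
  it).
* Sample-level QC (duplicates, relatedness), imputation, and
  multi-allelic sites are out of scope.
* With fewer than ~20 defined per-locus FST values in a replicate pair
  the 95th-percentile cut is unstable; the screen warns and records the
  condition rather than refusing to run.
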