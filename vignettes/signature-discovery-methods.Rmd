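---
title: "Signature discovery from principal components: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature discovery from principal components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigPCA)
```

# The model

sigPCA treats an expression matrix (genes × samples, log-scale continuous
values) as a superposition of a few *modules* — groups of genes whose
expression co-varies because they serve a common function that is active in
a subset of samples — on a background of uninformative variation. PCA
recovers the major axes of covariation without knowing about function;
gene-set annotations describe function without knowing about this dataset.
The method intersects the two: genes are ranked by their loading on each
retained component (from both ends, since a component's extremes move in
opposite directions), and each ranking is scanned for annotation
enrichment with an exact nonparametric test. An enriched set, pruned to its
mutually correlated core, becomes a *signature*: a labeled gene list plus a
per-sample expression profile (the unweighted mean of the members'
standardized expression).

Two properties make this usable on real data. The test is exact and
rank-based — it assumes nothing about the distribution of expression
values beyond exchangeability under the null, so it applies equally to
microarray and RNA-Seq intensities after any monotone preprocessing. And
the per-test significance threshold is fixed rather than adapted to the
number of components, so adding components never changes the signatures
already found.

## The XL-mHG test

For one ranked list of N genes of which K carry the tested annotation, let
k(n) be the annotated count among the top n. The minimum-hypergeometric
statistic is the smallest hypergeometric tail probability
P(X ≥ k(n)), X ~ Hypergeom(N, K, n), over the *testable* cutoffs. Two
constraints define testability:

* **X** — at least X annotated genes must lie above the cutoff, with
  X = max(xMin, ⌈xFrac · K⌉); defaults xMin = 5, xFrac = 0.25. This stops
  a handful of extreme genes from carrying a whole set (for K = 30, at
  least ⌈0.25·30⌉ = 8 genes are required).
* **L** — only the first L ranks are tested; default ⌊N/8⌋ because each
  component is scanned from both ends, so each scan should cover well under
  half the list. Weak (say 1.5-fold) enrichment detectable only at very
  deep cutoffs is almost never biologically meaningful.

Because the tail probability rises as unannotated genes accumulate and
falls when an annotated gene arrives, the minimum is always attained at an
annotated gene's rank; the statistic costs K tail evaluations.

The exact p-value P(S ≤ s^mHG) under a uniform random arrangement is
computed by dynamic programming over the lattice of (rank, count) cells: a
random arrangement is a monotone path from (0,0) to (N,K), the
"significant region" is the set of testable cells whose tail is ≤ s^mHG,
and a path can enter the region only on an annotated step. Summing, over
region-boundary cells, the probability of reaching the diagonal
predecessor while avoiding the region times the probability of the
completing step yields the exact tail of the statistic in O(LK) time. The
recursion runs on path counts normalized by binomial coefficients, which
stay in [0,1] — no overflow, no log-space gymnastics. Cells are classified
"at or below s" with a relative tolerance of 1e-12, and the statistic's
minimization uses the same tolerance: both sides share arithmetic, so a
tie can never fall on different sides of the boundary. (Mathematically
equal tails reached through different cells can differ by a few ulp; the
enumeration oracle in the test suite canonicalizes its support with the
same tolerance for the same reason.)

The test suite verifies the dynamic program against exhaustive enumeration
of **every** arrangement for all N ≤ 12, all K, X ∈ {1,2,3} and
L ∈ {⌈N/2⌉, N}; the observed maximum absolute deviation is at the level of
double rounding (≈ 6e-16).

## Choosing the number of components, D

Each gene's values are permuted independently across samples, destroying
gene–gene correlation while preserving every gene's marginal distribution
and hence the total variance. The fraction of variance explained by the
*first* component of the permuted matrix, across nPerm = 15 permutations,
gives a null mean and sample sd (denominator n−1, as everywhere in the
package); real components are retained as the initial run with
z ≥ zThreshold = 2. Two deliberate choices:

* the first permuted component is the reference for *all* real components,
  which is conservative for later components (their null variance fractions
  are smaller);
* D is a contiguous prefix — components are consumed in variance order, so
  a passing component after a failing one is not tested (a warning is
  logged if one exists).

At the fixture scale used throughout (200 × 30 pure noise), the test
returns D = 0 in ≈ 95% of seeds, and D ≥ 1 in every seed when one strong
module (50 genes, 5 sd) is planted.

## Filters and signature construction

Significant terms (exact p ≤ alphaB = 1e-6) within one ranking are ordered
by fold enrichment (k\*/n\*)/(K/N) at the attaining cutoff — ties broken by
smaller p, then term id, for determinism — and re-tested with stronger
terms' driving genes deleted from the list (ranks close up; K is
recomputed; the term's original X and the configured L, capped at the
shrunken length, are reused). Terms that lose significance are redundant
consequences of annotation nesting and are dropped. Across components,
processed in order (positive direction before negative within a
component), a term transitively related to an already-used term is
suppressed.

Signature membership then proceeds seed-and-extend on standardized
expression: average the driving genes; seed with the X driving genes most
correlated with that average; admit each remaining driving gene whose
correlation with the seed is ≥ rCorr (default 0.5; −1 disables the filter,
which measurably lowers within-signature coherence on the fixtures). The
seed pool is restricted to driving genes — admitting arbitrary matrix
genes would break the promise that a signature's label describes its
members' annotation. Member genes all carry the term's annotation and
number at most k\*.

## Effect size

The enrichment literature attaches an effect size to this family of tests
without fixing a formula; this package uses the fold enrichment at the
attaining cutoff, (k\*/n\*)/(K/N) — the only effect size computable from
the quantities the test itself defines. It is used solely to *order* terms
in the local filter, so any monotone variant would give identical results;
the definition is isolated in `foldEnrichment()` should an alternative be
preferred.

# Parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `xFrac` | 0.25 | fraction of K | minimum enriched fraction of a set |
| `xMin` | 5 | genes | absolute floor on X |
| `lRank` | ⌊N/8⌋ | rank | deepest tested cutoff |
| `alphaB` | 1e-6 | probability | per-test threshold (≈ 0.05 / 2m for m ≈ 10⁴ sets) |
| `rCorr` | 0.5 | Pearson r | signature admission threshold |
| `zThreshold` | 2.0 | z-score | permutation test for D |
| `nPerm` | 15 | replicates | permutation test for D |
| `topNVariance` | NA | genes | optional variance filter |
| `seed` | 0 | integer | all randomness of a run |

Gene-set ingestion applies the curated-evidence filter (IDA, IGI, IMP,
ISO, ISS, IC, NAS, TAS — electronically inferred annotations are
excluded), propagates annotations up `is_a` edges (plus `part_of` for
cellular-component terms), keeps sets of 5–200 genes (inclusive), and
removes parent terms whose annotated set is identical to a *direct*
child's. Equality along a chain with a differing intermediate does not
remove the grandparent: only direct pairs are compared, the literal
reading of the parent/child rule, and the behavior is pinned by a
three-level test fixture.

# Numerical and degenerate-input choices

* Zero-variance genes are an error at standardization; callers apply the
  variance filter first. Duplicate gene rows are an error by default, with
  an opt-in keep-highest-mean policy for probeset-collapsed inputs.
* K = 0, X > K, or an empty testable set yields s = p = 1 — never an
  error — so the Bonferroni screen simply fails.
* Rank ties in loadings are broken alphabetically; variance-filter ties at
  the boundary keep the lexicographically smaller gene name; the attaining
  cutoff n\* is the smallest rank achieving the minimum, making the driving
  set minimal.
* PCA component signs are canonicalized (largest-magnitude loading made
  positive) so reruns and platforms agree; genes are centered but not
  rescaled before PCA — standardization is defined for signature
  expression, and the package exposes the choice by letting callers
  pre-standardize if desired.
* Bootstrap replicate seeds are `seed + replicate index`, so any single
  replicate is reproducible alone; resample sizes are fractions of n,
  rounded half-up with a floor of 2.

# What the synthetic generator does and does not emulate

`simulateDataset()` plants disjoint modules of mutually correlated genes —
an additive shift of `effect` noise-sd units in a contiguous block of
samples — in i.i.d. Gaussian noise, annotates each module with one term
(optionally contaminated with random genes), adds random decoy sets, and
links each planted term to a parent in a toy ontology. The defaults (800
genes × 60 samples; three 40-gene modules, each active in 30% of samples
at 3 sd; 500 decoys) are the study conditions used by the test suite and
the acceptance script; they were chosen once as a desk-scale analogue of a
sorted-population compendium and are not tuned per test.

What it does **not** emulate: heavy-tailed or platform-specific technical
noise, correlated backgrounds (batch structure), overlapping modules,
unbalanced module strength, or the deep nesting of a real ontology.
Passing tests on these fixtures demonstrate the machinery — exactness of
the test, calibration of D, filter contracts, determinism, bootstrap laws
— not performance on any particular real dataset, where variance
filtering and annotation quality dominate.

Problem sizes in the tests and acceptance script (200×30 for calibration,
800×60 for end-to-end, B = 10 bootstrap replicates, enumeration to N = 12)
were chosen so the whole suite completes in about a minute on one core
while keeping every check's statistical resolution meaningful.

# Known limitations

* Signatures are hard assignments; a gene can drive two components but is
  consumed by the first signature that claims it within a ranking.
* The global filter's relatedness is transitive ancestry — two siblings
  with heavily overlapping annotations are *not* mutually exclusive and
  can both appear.
* The permutation test calibrates only the count of components, not which
  genes load on them; an L adapted per component (e.g. from a per-gene
  association test) could improve power for subtle modules.
* No parallelism: single-threaded determinism is preferred; the per-PC
  enrichment scans are embarrassingly parallel if ever needed.
* With `dOverride` far above the permutation-test D, later components are
  noise; the fixed alphaB keeps false signatures rare but not impossible.
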