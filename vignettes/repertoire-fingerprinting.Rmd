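---
title: "Repertoire fingerprinting by V-J gene usage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repertoire fingerprinting by V-J gene usage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repfingerprint)
```

## The problem

Adaptive immune repertoire sequencing of antibody heavy chains yields, per
donor, millions of rearranged sequences annotated with their germline V and J
gene assignments and the CDRH3 loop. Comparing donors directly at the sequence
level is dominated by the combinatorial diversity of CDRH3; comparing them at
the level of **V-J germline gene-pair usage** gives a compact, reproducible
"fingerprint" of the repertoire that is informative about immunological state
(infection, vaccination, naivety of the compartment).

`repfingerprint` implements that fingerprinting workflow end to end:

1. **Ingest** AIRR Rearrangement tables and apply record-level quality
   filters: V and J germline alignment E-values strictly below `1e-6`, an
   in-frame junction, a productive rearrangement, no stop codons, and a
   defined CDR3 (`filter_spec()`).
2. **Collapse** the surviving records to unique *V3J clonotypes* — the triple
   (allele-stripped V gene, allele-stripped J gene, CDRH3 amino-acid
   sequence) — so the counting unit is unique clonotypes, never reads.
3. **Tabulate** clonotype counts over a fixed, ordered space of V-J pair
   names (306 pairs by default, mirroring the size of a common-pair set in
   deeply sequenced human repertoires).
4. **Subsample** each donor's count vector with replacement to a uniform
   depth of `1e5`, ten times, producing replicate count rows that simulate
   resequencing noise and equalize depth between donors.
5. **Normalize** per feature: replace zeros by a pseudocount of `0.01`, take
   `log10`, convert to a Z score across all replicate rows (population
   standard deviation), and transform back out of log space as `10^Z`.
6. **Embed** with PCA (column centering, no rescaling) and report per-pair
   loading weights and explained-variance ratios.
7. **Cluster** replicates in PC1+2 with K-means (`k = 2`, 10 restarts) and
   compare cohorts through donor-centroid Euclidean distances, against a
   bootstrap Repertoire Dissimilarity Index (RDI) baseline, using an exact
   two-sided Mann-Whitney rank test.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_evalue` | `1e-6` | strict upper bound on V and J alignment E-values |
| `depth` | `1e5` | multinomial subsample size per replicate (counts of unique clonotypes) |
| `n_replicates` | `10` | replicates per donor |
| `pseudocount` | `0.01` | stands in for never-observed pairs before `log10` |
| `n_components` | `2` | PCs retained for embedding, clustering and distances |
| `k`, `n_init` | `2`, `10` | K-means clusters and seeded restarts |
| `rdi_depth`, `rdi_n_boot` | `1e5`, `100` | RDI bootstrap subsample size and iterations |
| `noise_sigma` | `0.05` | fractional Gaussian noise for CDRH3 control-feature replicates |

## Normalization details

The Z score is computed **per feature (column) across all replicate rows of
the joint analysis matrix**, with the **population** standard deviation
(divide by *n*). Per-feature scaling is what makes loading weights comparable
across pairs whose raw counts differ by orders of magnitude; the population
convention is fixed so that results are exactly reproducible (either
convention is defensible; the choice only rescales Z by
$\sqrt{n/(n-1)}$). A zero-variance column cannot be Z-scored; its Z is
defined as 0 everywhere, so its back-transformed value is the constant 1 and
it contributes nothing to the PCA. Back-transforming (`10^Z`) de-emphasizes
pairs with very low or no counts — their Z scores sit mostly below zero and
compress toward zero in linear space — at the price of a strong right skew
for values above the column mean, which is important for interpreting the
synthetic-data design below.

Worked example: a column with counts `(1, 10, 100)` has logs `(0, 1, 2)`,
population standard deviation $\sqrt{2/3}$, Z scores
$(-\sqrt{3/2}, 0, +\sqrt{3/2})$, and back-transformed values
$(10^{-\sqrt{3/2}}, 1, 10^{\sqrt{3/2}}) \approx (0.0596, 1, 16.777)$.

## PCA, clustering and distances

PCA is the standard column-centered decomposition (`stats::prcomp`); no
further scaling is applied because the normalization already put features on
a common scale. Components are reported with explained-variance ratios; a
matrix with zero total variance yields a degenerate model with all ratios 0
and a warning rather than an error, so toy inputs remain usable. Loading
weights are reported with a sign convention (each component's largest-|weight|
entry made positive) because the sign of a principal axis is arbitrary.

K-means runs on PC1+2 with `n_init` seeded restarts, and cluster labels are
renumbered by the lexicographic order of the cluster centroids so that the
assignment is a pure function of the data and the seed.

Donor-level distances reduce each donor's replicate cloud to its **centroid**
in PC1+2 and take Euclidean distances between centroids. The centroid is the
simplest subject-level summary consistent with plotting one box per
subject-pair class; the alternative (mean over all replicate-pair distances)
is deliberately not the default but can be reconstructed from the embedding.

## The RDI baseline

The implemented RDI core is: subsample both donors with replacement to a
common depth, convert to frequency vectors, take the Euclidean norm of the
difference, and average over 100 bootstrap iterations. No baseline
subtraction or variance calibration is applied — the original method's exact
calibration constants are not recoverable from a usage-vector description, so
the package implements and documents the simplest faithful core and versions
it as such. Two numerical choices make it well behaved: the two donors of a
pair are put in a canonical (lexicographic) order before drawing so the index
is exactly symmetric, and each donor pair draws from an independent seed
stream so adding a pair never perturbs another.

## The exact Mann-Whitney test

Intra- versus inter-cohort distance comparisons at this scale involve as few
as 3 values against 15. A normal-approximation rank test is unreliable there,
so the test enumerates all `choose(n1+n2, n1)` assignments of the pooled
observed values (mid-ranks for ties) whenever that count is at most `1e6`,
and reports `min(1, 2 * min(P(U <= u), P(U >= u)))`. For 3 vs 15 that is 816
assignments and the smallest achievable two-sided p is `2/816 ≈ 0.00245`;
a reported p of order 0.01 is therefore meaningful at this design size.
Larger splits (e.g. 10 vs 15, 3.3 million assignments) fall back to the
normal approximation with tie correction and continuity correction.

## CDRH3 control features

The control feature set describes a repertoire by its CDRH3 loops instead of
V-J usage: a length histogram over bins 4–30, a net-charge histogram over
bins −6…+6, and the mean amino-acid composition (unweighted over clonotypes,
so long loops do not dominate). Design choices:

* **Charge model**: R/K = +1, D/E = −1, H = 0. Integer bins imply an integer
  charge model; histidine's partial protonation at physiological pH rounds
  to 0. A fractional model is out of scope.
* **Clamping**: lengths and charges outside the bin ranges are clamped to the
  edge bins rather than dropped, preserving histogram totals; clamp counts
  are reported.
* **Normalization**: histograms are divided by repertoire size by default
  (`normalize = TRUE`), since raw counts would separate donors by sequencing
  depth — exactly the nuisance signal the pipeline is designed to remove.
  Raw counts remain available.
* **Replicates**: instead of subsampling, replicates add multiplicative
  Gaussian noise (5% of each bin's value), matching the variation observed
  per V-J bin under subsampling at depth `1e5`
  ($\sqrt{306/10^5} \approx 5.5\%$ for a typical bin). Multiplicative noise
  keeps empty bins empty; additive noise would swamp them.

## The synthetic study generator

`generate_study()` draws a two-cohort study from a Dirichlet-multinomial
hierarchy: each cohort has a baseline usage profile over the 306 pairs; each
donor draws a personal profile from a Dirichlet centered on the (effect-
shifted) cohort profile with concentration `donor_concentration`; each donor
then draws `clonotypes_per_donor` unique clonotypes multinomially. The cohort
effect multiplies selected profile entries by `(1 + delta)` and renormalizes,
which keeps the profile valid for any `delta >= 0`.

Default study conditions (the shape used by the test suite and the
acceptance script): 3 unperturbed donors versus 5 perturbed donors, 306
pairs, a Zipf (1/rank) baseline profile, `delta` on the **20 most-used
pairs**, `clonotypes_per_donor = 1e7`, `donor_concentration = 1e6`,
subsampling depth `1e5` with 10 replicates. These values were fixed by a
variance-structure analysis of the normalization, not tuned by trial:

* The back-transform `10^Z` makes linear-space variance exponentially
  sensitive to a column's Z range. A column whose variance is pure
  subsampling noise is amplified to unit log-variance and occasionally
  produces single back-transformed outliers large enough to claim PC1. The
  pipeline is therefore designed (as its real-data counterpart was) for
  inputs in which **every common pair carries structure**, and the generator
  must put its cohort effect where it carries usage mass: shifting 20
  near-zero pairs changes nothing a repertoire-scale metric can see, whereas
  shifting the dominant pairs (57% of usage mass), with the renormalization
  spreading a compensating shift across all other pairs, gives the cohort
  contrast more variance than any single noise direction.
* K-means recovery of the cohorts requires the between-cohort sum of squares
  to exceed both the donor-contrast directions and the largest
  amplified-outlier direction. That bounds donor-level variability from
  above: with `donor_concentration = 1e6` and deep repertoires
  (`1e7` clonotypes, the order of the most deeply sequenced published
  repertoires), residual donor-level usage variation is ~0.1% (relative) on
  common pairs — a **cohort-dominated** regime in which the shared immune
  state is the main source of variation.

What the generator deliberately does **not** emulate: realistic
inter-individual usage variation (real donors differ by tens of percent on
many genes; the generator's donors are much tighter, so passing tests
demonstrate cohort recovery in the cohort-dominated regime, not robustness
to strong donor individuality), somatic hypermutation and clonal lineage
structure, read-level error, longitudinal dynamics, and light chains. CDR3
sequences are generated independently of V-J usage from a shared
length/composition model — which is exactly what makes them the negative
control: when only V-J usage carries the cohort effect, CDRH3-derived
features contain no cohort signal.

## Determinism and seeds

Every stochastic step (subsampling, RDI bootstrap, noise replicates, all
generator draws) runs under a local RNG state derived from a base seed and a
stable string hash of the donor (or donor-pair) label. Consequently results
are bit-for-bit reproducible from the recorded configuration, and adding a
donor to a study never changes another donor's draws. The global RNG state of
the calling session is never touched.

## Problem sizes used by the test suite

The suite validates the numerical primitives against independent oracles
(hand-coded normalization, covariance eigendecomposition, full rank-test
enumeration) on small random matrices, and the statistical guarantees on the
default synthetic study: 20 seeded studies at `delta = 1` for cohort
recovery, 20 at `delta = 0.5` for the fingerprint-versus-RDI comparison, 10
for the CDRH3 control, 30 for effect-size monotonicity, and 40 null studies
for the level of the rank test. These sizes give stable pass/fail behaviour
while keeping a full run in tens of seconds on one CPU.

## Known limitations

* The feature space of real analyses (the published 306 common-pair list)
  is supplement-bound upstream data; the package therefore treats the space
  as configurable (file, union, or intersection) and ships a synthetic
  306-pair space of real gene names for simulation.
* The RDI implemented here is the uncalibrated frequency-vector core; its
  absolute scale is not comparable to calibrated implementations, only its
  intra/inter contrast is used.
* At `donor_concentration` values giving realistic donor individuality, PC1+2
  separate donors rather than cohorts when the cohort effect is confined to
  20 pairs; cohort-level claims on real data should always be read against
  the per-donor replicate clouds in the embedding plot.
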