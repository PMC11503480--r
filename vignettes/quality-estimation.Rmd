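---
title: "Two-stage estimation of genome-bin completeness and contamination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage estimation of genome-bin completeness and contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magqc)
```

## The problem

Genomes reconstructed from metagenomes (MAGs) vary enormously in quality.
Before a MAG enters downstream analyses one wants to know two numbers: the
**completeness** (what fraction of the original genome is present) and the
**contamination** (how much foreign material was mixed in, expressed relative
to the complete length of the original genome). The classical approach counts
a few dozen universal single-copy genes, which cover only a small part of a
genome and cannot reliably separate incompleteness from contamination.

`magqc` implements a two-stage estimator that works on the full
protein-domain count profile of a bin — the vector of copy numbers of every
protein family detected in its sequences.

## Stage I: dynamic markers from nearest reference profiles

Let \(C_q^{(i)}\) and \(C_r^{(i)}\) be the counts of family \(i\) in a query
and a reference profile. References similar to the query are found by
K-nearest-neighbor search under the count-coincidence similarity

\[
\mathrm{sim}(C_q, C_r) =
\frac{\bigl|\{i : C_q^{(i)} = C_r^{(i)} \wedge C_q^{(i)} > 0\}\bigr|}
     {\sqrt{\bigl|\{j : C_r^{(j)} > 0\}\bigr| \cdot
            \bigl|\{k : C_q^{(k)} > 0\}\bigr|}},
\]

which counts families with *identical nonzero* counts, normalized by the
geometric mean of the two support sizes. Requiring exact equality means
mostly small counts contribute, making the measure robust against count
inflation by contaminants.

The **marker set** \(\mathcal{M}\) of a query consists of every family with
equal nonzero count across all \(K\) neighbors (markers are therefore not
restricted to single-copy families, and they are recomputed per query rather
than fixed per lineage). With agreed reference counts \(C_r^{(m)}\), stage I
reports

\[
\mathrm{cont} = \frac{1}{M} \sum_{m \in \mathcal{M}}
  \Bigl[\tfrac{C_q^{(m)}}{C_r^{(m)}} - 1\Bigr]_+,
\qquad
\mathrm{comp} = \frac{1}{M} \sum_{m \in \mathcal{M}}
  \tfrac{C_q^{(m)}}{C_r^{(m)}} - \mathrm{cont},
\]

with \([z]_+ = \max(z, 0)\). A query equal to a reference gives
\(\mathrm{comp} = 1, \mathrm{cont} = 0\) exactly. The raw completeness can
exceed 1 when query counts exceed reference counts asymmetrically; the
reported value is clamped at 1, while the unclamped value feeds the stage-II
features (the learner benefits from the full signal). Queries for which the
neighbors share no marker at all are reported as failures with a
machine-readable reason — the package never fabricates estimates.

Two guards surround the search:

* **Prefilter.** Queries whose presence fraction over *both* superkingdom
  universal marker sets falls below 10% are rejected: nearest-neighbor
  search over a nearly empty profile is meaningless.
* **Routing.** Stage II is trained on completeness 60–100% and contamination
  0–30% only. If the stage-I completeness is below 60% or the contamination
  above 30% (strict inequalities, exactly as worded), the stage-I estimates
  are final; otherwise stage II refines them.

## Stage II: count-ratio-histogram features and regression

The full profile space has thousands of dimensions. Stage II compresses a
query/reference comparison into a **count ratio histogram (CRH)**: the
distribution of the ratios \(C_q^{(i)} / C_r^{(i)}\) over all families in
either support. Bin centers are the exact rationals \(a/b\) with
\(a, b \in \{1, \dots, c_{\max}\}\); for \(c_{\max} = 4\) these are
\(1/4, 1/3, 1/2, 2/3, 3/4, 1, 4/3, 3/2, 2, 3, 4\). The two extreme bins are
overloaded: the left-most bin also collects families present only in the
reference, the right-most bin collects ratios above \(c_{\max}\) and
families present only in the query. Frequencies are normalized by the
number of families considered, so every histogram sums to 1. A clean,
complete bin gives a unit spike at 1; incompleteness moves mass into the
left flank, contamination into the right flank.

The stage-II feature vector of a query is the element-wise mean of the CRHs
against its \(K\) neighbors (each normalized before averaging),
concatenated with the two stage-I estimates. Separate regressors predict
completeness and contamination; the default operating point is a
single-hidden-layer perceptron with 100 units, \(K = 9\),
\(c_{\max} = 6\) / weight decay \(10^{-4}\) for completeness and
\(c_{\max} = 12\) / decay \(10^{-7}\) for contamination. KNN, random
forest, linear SVR and elastic-net regressors are available through the
same interface, and `grid_search()` scans hyperparameter ranges against a
validation split with a source-genome leakage guard.

### Numerical choices

* **Exact rational arithmetic.** Bin centers are kept as reduced
  numerator/denominator pairs; deduplication (2/4 vs 1/2) and the
  nearest-center assignment are integer computations, never floating-point
  comparisons. A ratio equidistant between two centers goes to the center
  closer to 1, biasing ties toward "clean" rather than inflating apparent
  artifacts.
* **Normalization denominator.** The histogram divides by
  \(|\mathrm{supp}(q) \cup \mathrm{supp}(r)|\); every family is binned
  exactly once, so frequencies sum to 1 by construction (checked to 1e-12
  in the tests).
* **No feature standardization.** CRH frequencies and the two stage-I
  estimates are already commensurate values in \([0,1]\). Dividing
  rarely-populated histogram bins by their near-zero standard deviation
  turns sampling noise into dominant inputs; in our held-out experiments
  this made the MLP *worse* than stage I, while the same features on their
  natural scale refine it substantially (scale-invariant random forests
  were unaffected either way, which isolated the cause). All regressors
  therefore see the natural scale.
* **Determinism.** Every stochastic fit is seeded from the configuration;
  the MLP uses a fixed iteration cap of 200 (the default cap of the widely
  used scikit-learn MLPRegressor family) rather than data-dependent early
  stopping, so a fixed seed reproduces identical weights.
* **Degenerate targets.** A constant training target collapses every
  learner to that constant; the wrapper short-circuits this case
  explicitly (ε-insensitive SVR would otherwise return an empty model).
* **Clipping.** Final stage-II predictions are clipped to completeness in
  \([0, 1]\) and contamination in \([0, 1]\) (the ceiling is
  configurable); stage-I contamination feeding the 30% routing rule is
  used unclamped.

## The reference database

`build_reference_db()` turns a profile collection into the search
database in four steps: (1) agglomerative clustering (average linkage on
Bray–Curtis dissimilarity between relative-frequency profiles, cut at 10%
dissimilarity) keeps one representative per cluster; (2) universal markers
are discovered per superkingdom — a family qualifies iff it occurs exactly
once in at least 95% of the representatives; (3) genomes whose
marker-presence completeness falls below 95% are discarded (guarding
against mislabelled incomplete genomes); (4) the survivors are re-clustered
with the same settings and the final representatives become the database.
Cluster representatives are medoids with a lexicographic tie-break, so the
whole build is deterministic. The linkage, distance, and the use of a
presence fraction (rather than the stage-I formula) for step (3) are
deliberate interpretations where the procedure admits choices; all three
are exposed in the configuration.

## The simulator and the synthetic world

`simulate_bin()` emulates a metagenomic binning outcome: completeness and
contamination targets are drawn uniformly from 60–100% and 0–30%, the query
genome is cut into 20-kb fragments (configurable; 0 = use native contigs),
query fragments are sampled without replacement to match the completeness,
and contaminant fragments are drawn from genomes whose canonical
tetranucleotide signature has Bray–Curtis similarity ≥ 0.80 to the query —
real binners confuse compositionally similar genomes, not arbitrary ones.
Contaminant genomes are consumed in random eligibility order until the
target is met. Fragment counts are rounded to the nearest integer, and the
recorded ground truth is the **realized** (fragment-quantized) value, so
evaluation is exact regardless of rounding convention. A trailing genome
fragment shorter than 25% of the fragment length is dropped (avoiding
zero-length contigs while limiting length bias).

`generate_synthetic_world()` provides a fully self-contained test corpus:
protein families are represented by distinct random 25-nt tokens planted
non-overlapping in random background, so the exact-match annotator
(`toy_annotate()`, both strands, overlapping matches) recovers each
genome's stored profile exactly. Genomes are organized in clades with
clade-specific accessory-family profiles and GC content, making both
profile similarity and tetramer similarity higher within clades — the
structure the nearest-neighbor search exploits in real data. Core families
are single-copy with probability 0.99 per genome, so universal-marker
discovery finds them; accessory counts mutate with probability 0.2 per
genome, keeping dereplicated same-clade genomes roughly 10–20% apart in
profile distance, as in a dereplicated reference corpus. Release dates are
spread over three windows per clade so a date-based split keeps every
clade represented in every part.

What the world does *not* emulate: translated ORF search and real domain
models (the annotation backend is an interface; the exact-token annotator
stands in), sequencing error, assembly artifacts, real contig-length
distributions, and the sheer scale of public reference corpora. Passing
tests on this world demonstrate the correctness of the machinery and the
learnability of the features under controlled conditions — not real-data
error rates.

## Evaluation harness

`date_split()` divides genomes by release date into three parts
(half-open intervals; an entry dated exactly on a split date goes to the
later part): the oldest part backs the reference database, the two recent
parts are used for training and validation in a two-fold cross-validation
(`cross_validate_2fold()`, with a source-genome leakage guard;
contaminants are always drawn from the bin's own part). Errors are
reported as mean/median absolute error in percentage points; signed errors
are predicted − truth, so positive means overestimation.

## Problem sizes used by the shipped tests

The end-to-end acceptance test uses a world of 60 genomes (150 core + 300
accessory families, 300-kb genomes, 6 clades), split 24/18/18 by release
date, with 20 bins per genome at 20-kb fragments — 360 training and 360
held-out bins. At this scale the stage-I estimator reaches a mean absolute
error of roughly 3.5–4 percentage points on held-out bins and the MLP
refinement roughly 2–3, reproducing the qualitative ordering (every
stage-II learner improves on stage I) that motivates the hybrid design.
These numbers are recomputed by the test suite at every run; they are not
constants of the package.

## Known limitations

* Stage I depends on the existence of reasonably close reference profiles;
  for genuinely novel lineages the dynamic marker set shrinks toward the
  universal core and the estimates inherit the classical single-copy
  limitations.
* The annotation backend contract (nonnegative integer counts per family)
  deliberately leaves open whether counts are per-hit or per-ORF; any
  consistent convention works as long as references and queries share it.
* Contamination above the configured ceiling (default 100%) is truncated;
  heavily chimeric bins are better caught by the routing rule than by the
  regression.
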