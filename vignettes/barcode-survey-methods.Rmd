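---
title: "Methods: barcode survey analysis with barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode survey analysis with barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

A regional barcode survey sequences a short mitochondrial marker (typically
a ~500–700 bp stretch of COI) from every specimen caught, and asks three
questions: how much sequence variation exists *within* each
morphologically-defined species, whether the *between*-species divergences
are separated from the within-species ones (the "barcoding gap" that makes
molecular identification reliable), and whether any specimen's molecular
identity contradicts its morphological label — which is how mislabeled
material, cryptic species and hybrids surface. This package implements that
analysis as a deterministic, seeded pipeline.

## Distance model

Distances are Kimura-2-parameter: with transition proportion $P$ (A↔G,
C↔T) and transversion proportion $Q$ over the compared sites,

$$d = -\tfrac12 \ln(1-2P-Q) - \tfrac14 \ln(1-2Q).$$

Sites where either sequence carries a gap or an IUPAC ambiguity code are
excluded pair by pair (pairwise deletion). K2P is the conventional choice
for barcode data: it corrects transitions and transversions separately,
which matters because mitochondrial markers are strongly
transition-biased, yet it needs no base-composition parameters.

Numerical edge cases are handled explicitly rather than silently:

* If $1-2P-Q \le 0$ or $1-2Q \le 0$ the distance is undefined
  (saturation). The pair is *flagged*, reported `NA`, excluded from
  means/ranges with a warning, and refuses to enter a neighbor-joining
  run. Nothing is clipped to an arbitrary large value.
* A pair with zero comparable sites is an error, not a zero.
* $d = 0$ exactly when $P = Q = 0$; identical sequences give exactly 0.

When $Q = 2P$ the K2P formula reduces algebraically to the Jukes–Cantor
distance $-\tfrac34\ln(1-\tfrac{4p}{3})$ with $p = P+Q$; the test suite
asserts this identity to machine precision, alongside a brute-force
site-counting oracle and a cross-check against `ape::dist.dna(model =
"K80")`.

Summary statistics (within- and between-species means, minima, maxima) are
**unweighted over haplotype pairs**: haplotype frequencies and sample
counts never enter the averages, so one common haplotype cannot mask
divergent rare ones. A single-haplotype species reports within-distance
0 with zero pairs, by convention.

## Haplotype collapsing

Within a group (species, or species × location), sequences identical over
all unambiguous positions are one haplotype. A sequence containing
ambiguity codes joins an existing unambiguous haplotype only if it is
compatible with *exactly one* of them at every ambiguous position;
otherwise it stands alone, flagged `ambiguous_only`. This replaces the
manual curation of dubious base calls with a deterministic rule: an
ambiguous read that could belong to two haplotypes is evidence for
neither.

Two further conventions:

* **Hybrid-suspect samples** (flagged at collection on morphology) are
  collapsed in a parallel group suffixed `*`. They appear in the distance
  matrix, tree and identification reports, but never in within-species
  averages — a hybrid's mitochondrion belongs to one parent species and
  would otherwise fabricate huge "within-species" distances.
* **Ordering and naming** are deterministic: haplotypes sort by
  descending count with ties broken by first appearance, and are named
  species-acronym + letter (`A`…`Z`, then `AA`, `AB`, …). The letter
  series runs across all groups of one species, so a species sampled at
  several locations still gets one coherent `A`–`D` series.

## Neighbor joining and bootstrap

The tree is standard agglomerative NJ on the K2P matrix: join the pair
minimizing $S(i,j) = (n-2)d_{ij} - R_i - R_j$, with the usual split
formulas for branch lengths. Two conventions make runs bit-reproducible
across platforms:

* ties in $S$ break by the lexicographically smallest label pair (an
  internal node carries the smallest leaf label of its subtree);
* a negative branch length is clamped to 0 with the deficit moved to its
  sibling edge, preserving the joined pair's distance.

On additive matrices NJ is exact; the tests verify recovery of random
additive matrices up to 12 taxa (path lengths to $10^{-10}$) and, at 4–5
taxa, against an exhaustive least-squares search over all unrooted
topologies.

Bootstrap support is the Felsenstein column bootstrap: each replicate
resamples alignment columns with replacement, recomputes the K2P matrix
and its NJ tree, and a bipartition's support is the fraction of retained
replicates containing it. The reported tree is the NJ tree of the
*original* data annotated with these supports — annotating the observed
tree is standard practice and avoids choosing among replicate topologies.
A replicate that produces a saturated pair is dropped and logged; more
than 10% dropped aborts the run, since supports from a heavily censored
replicate set would not be comparable. All resampling flows from one
seeded generator, recorded in the run manifest.

## Molecular identification

Each haplotype is compared against a local reference library (FASTA +
taxonomy table — a stand-in for querying a public barcode database).
Percent identity is computed over pairwise-deleted sites of the shared
region (minimum 200 sites); hits rank species-level by best identity, and
hits below `min_identity` (default 97%, a conventional barcoding screen;
the threshold is configurable) are dropped. Two or more species tying at
the top identity — compared at 4 decimals — yield an `AMBIGUOUS` call
rather than an arbitrary winner, because distinct species really do share
identical barcodes.

Flags are then per sample:

* `discrepancy`: molecular call ≠ morphological label. A same-genus,
  different-species call still counts, and so does `AMBIGUOUS`.
* `hybrid_evidence`: the sample was hybrid-suspect *and* its
  mitochondrial call differs from its label — the expected signature of a
  hybrid carrying the maternal parent's mitochondrion.

**Exclusion of cross-assigned haplotypes from species averages.** The
pipeline excludes from within/between summaries any haplotype molecularly
assigned to a *different species sampled in the same survey*. Such a
haplotype — a specimen labeled A carrying species B's mitochondrion — is a
mislabeling or introgression signal, and averaging it into species A's
statistics would corrupt both the within-species mean and the barcoding
gap. The rule is deliberately narrow: a haplotype assigned to a species
*outside* the survey (the classic case of a whole population keyed to the
wrong name in the reference library) is retained, because there the
survey's own grouping is internally consistent and excluding it would
silently delete a real species. Excluded haplotypes remain in the distance
matrix, the tree and all reports.

## The synthetic survey generator

The generator exists so that every stage has ground truth: it emits the
same FASTA/TSV dialect the readers consume, plus a truth object (species
tree, per-sample generating haplotype, planted-case ids, expected
between-species distances).

Design:

* **Substitution process.** Sequences evolve site-wise under the
  two-parameter model with exact transition probabilities (transition rate
  $\kappa$-fold each transversion rate, rates normalized so branch length
  is expected substitutions/site). Site-wise exact probabilities — rather
  than sprinkling a discrete number of mutations — handle multiple hits
  correctly, so `expected_k2p()` is exact: the K2P distance recomputed
  from the expected $(P, Q)$ at divergence $t$ equals $t$ identically,
  which is what anchors the estimator-recovery tests. Base composition is
  uniform, matching the model's assumption.
* **Species depths.** A random species tree is rescaled to a mean
  pairwise divergence of `between_divergence` (default 0.15
  substitutions/site), capped at 0.29 (the upper end of observed fish COI
  divergences, safely below saturation) and floored at `min_between`
  (default 0.02) by extending terminal branches — congeneric fish species
  below ~2% COI divergence are the exception, and a survey emulation
  should keep species identifiable.
* **Within-species variation.** Each species founder spawns haplotypes at
  expected `within_divergence` (default 0.002 ≈ one substitution in
  530 bp); draws that collide with an existing haplotype are redrawn, so
  the configured number of *distinct* haplotypes is honored. Sample
  counts are skewed — the first haplotype takes everything not allocated
  to singletons, giving the (5,1,1,1)-style frequency profiles real
  surveys show.
* **Geography.** A species may be split across locations whose founders
  sit at specified divergences from the species founder, so expected
  cross-population distance is the branch-length sum — the ground truth
  for the population-table tests.
* **Planted cases.** Hybrids copy a donor species' founder haplotype but
  keep the recipient's label and `hybrid_suspect = TRUE`; mislabeled
  ("reassignment") samples do the same with the flag off. Both must be
  flagged by the pipeline, and clean samples must never be.

`galilee_survey_config()` bundles the survey-scale conditions used
throughout the tests: 22 species with skewed sample sizes of 1–23 (173
samples), 1–4 haplotypes per species, one species split across three
locations with one slightly diverged population (0.003 substitutions/site),
two planted hybrids and one planted mislabel, L = 530 bp, $\kappa = 2$.

What the generator does *not* emulate: indels (coding-region barcodes are
effectively indel-free, so none are simulated and the analysis assumes
gap-free alignment), sequencing error and chromatogram noise, rate
variation among sites, and non-uniform base composition. Passing tests
therefore demonstrate correctness of the *analysis* under the model's
assumptions, not robustness to upstream data-quality problems — those are
assumed handled before input.

## Problem sizes and numerical tolerances

The test suite runs the full pipeline on the 22-species survey with 100
bootstrap replicates (the analysis scripts use 1000, the conventional
reporting depth; support estimates at B = 100 are sufficient for the
planted deep split, whose support is essentially 1). Estimator-recovery
checks use 200 replicate pairs at L = 530 and a 200,000-site pattern
check, both against 3-standard-error bands. Oracle agreement for K2P is
asserted at $10^{-12}$; additive-matrix recovery at $10^{-10}$; reported
tables round to 4 decimals, matching the conventional precision of
barcode-survey tables, while all comparisons in code use unrounded values.

## Known limitations

* Percent identity is computed over the common alignment frame of query
  and reference (common prefix after trimming); references on a different
  frame must be pre-aligned.
* The identification step is exact-match/identity-based; it does not
  model within-reference variation or compute placement probabilities.
* Saturated pairs abort tree construction by design; surveys mixing very
  deep divergences with this marker should resolve those pairs (e.g. by
  restricting the taxon set) rather than expect a silent workaround.
* Within-group means over haplotype pairs treat haplotypes, not
  individuals, as the unit — by design, but worth remembering when
  comparing with individual-weighted published numbers.
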