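# barcodegap

Analysis toolkit for multi-species DNA barcode surveys — the kind of study
that audits a regional fauna (here, freshwater fishes) by sequencing a
mitochondrial marker such as COI from every captured specimen, collapsing
the sequences into haplotypes, and asking whether barcode distances
separate species cleanly enough for molecular identification.

It is aimed at researchers running such surveys who want every step —
haplotype tables, distance summaries, trees, identification calls — to be
scripted, seeded and reproducible instead of assembled by hand across GUI
tools.

## What it computes

**Kimura 2-parameter (K2P) distances.** For an aligned sequence pair with
transition proportion *P* (A↔G, C↔T) and transversion proportion *Q* over
the compared sites (pairwise deletion of gaps and ambiguity codes),

    d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

Pairs where a logarithm argument is non-positive are flagged `SATURATED`
and excluded from summaries rather than clipped.

**Haplotype tables.** Within each species group, identical sequences are
one haplotype; sequences with ambiguity codes join a haplotype only when
compatible with exactly one. Haplotypes are named acronym + letter
(`GrA`, `GrB`, …) in descending-frequency order. Hybrid-suspect samples
collapse in a parallel `*` group so introgressed mitochondria never
inflate within-species variation.

**Barcoding gap.** Unweighted haplotype-pair means and ranges within and
between species, and whether the two ranges overlap — the criterion that
makes barcode identification trustworthy.

**Neighbor-joining tree with bootstrap.** Deterministic NJ (ties broken by
smallest label pair, negative branches clamped with the deficit moved to
the sibling) plus Felsenstein column-resampling bootstrap; supports are
written as integer percent node labels in Newick.

**Reference-library identification.** Percent identity of each haplotype
against a local reference library (a stand-in for BOLD-style databases),
with `AMBIGUOUS` calls on exact ties, discrepancy flags when molecular and
morphological identity disagree, and hybrid-evidence flags for
hybrid-suspect samples whose mitochondria match another species.

**Synthetic surveys.** A seeded generator produces whole surveys —
species tree, within-species haplotype clouds, skewed frequencies,
geographic subpopulations, planted hybrids and mislabeled samples — with
full ground truth, so the entire pipeline is testable without downloads.

## Worked example

A 22-species synthetic survey emulating a regional fish fauna (173
samples, skewed 1–23 samples per species, two planted hybrids, one planted
mislabeled sample):

```r
library(barcodegap)

sim <- simulate_survey(galilee_survey_config(seed = 42))
ref <- reference_from_truth(sim)
res <- run_pipeline(sim, reference = ref, out_dir = "survey_out",
                    bootstrap_B = 100, seed = 42)
res$gap
#> within:  0.0000-0.0057 (mean 0.0018)
#> between: 0.0211-0.2757 (mean 0.1679)
#> barcoding gap: no overlap (fold ratio 92.2)

res$flags[res$flags$discrepancy, ]
#>        id species haplotype called_species discrepancy hybrid_evidence
#> 129 ras01    sp18     Sp18D           sp08        TRUE           FALSE
#> 172 hyb01    sp06    Sp06B*           sp09        TRUE            TRUE
#> 173 hyb02    sp14    Sp14B*           sp04        TRUE            TRUE
```

Reading the output: within-species K2P distances stay below 0.01 while
between-species distances start above 0.02, so the ranges do not overlap —
a clear barcoding gap, with between-species divergence ~92× the
within-species mean. The three flagged samples are exactly the planted
cases: `ras01` carries a label contradicted by its sequence (a
mislabeling/introgression signal), and both hybrid-suspect samples carry
the mitochondrial haplotype of a different species, which is evidence of
hybrid origin.

The same steps, narrated one stage at a time and writing tables under
`results/`, are in `analysis/01_simulate_survey.R` …
`analysis/05_identification.R`.

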