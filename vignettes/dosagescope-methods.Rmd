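---
title: "Methods: CNV regions, peak detection and dosage-class analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV regions, peak detection and dosage-class analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosagescope)
```

# The problem

Pathogenic human copy number variants (CNVs) are typically very large
and contain many genes, so the clinical call attached to a CNV says
little about *which* gene inside it drives the phenotype. The working
model in `dosagescope` is gene dosage sensitivity: for some genes a
50% increase or decrease in copy number is deleterious — because the
product is in stoichiometric balance with partners (protein-complex
subunits, ohnologues), acts in a concentration-dependent way
(developmental morphogens), or is haploinsufficient. If dosage
sensitivity of enclosed genes causes CNV pathogenicity, those genes
should also show a dearth of duplication and loss across mammalian
evolution, which gives an annotation-independent signal usable to
rank candidate genes.

The package implements this analysis as a reusable pipeline over four
kinds of input: CNV calls with clinical interpretation (benign or
pathogenic, gain or loss), a protein-coding gene table with functional
attributes, per-species orthology annotations for a 13-mammal panel,
and a genome build giving chromosome lengths. A synthetic-data
generator emulates all of these so every stage is testable offline.

# Coordinates and ingestion

All internal coordinates are 0-based half-open; dbVar/Ensembl-style
tables (1-based inclusive) are converted at the reader boundary, and
BED output needs no conversion. Three ingestion rules are applied and
never revisited downstream:

* calls shorter than **50 bp** are dropped (the minimum CNV length in
  the kind of archive the pipeline targets);
* calls longer than **a tenth of their chromosome** are dropped — such
  giant calls swamp the gene counts and confound every per-gene
  statistic;
* only **autosomes** are analysed; sex chromosomes and mitochondria
  are silently discarded, and genome fractions use the sum of the
  GRCh37 autosome lengths bundled in `grch37_autosomes()`.

Records failing `start < end`, unknown autosome labels, or malformed
coordinates are errors (reported with their line number), not silent
drops.

# CNVRs, coverage and peak regions

Overlapping CNVs that share a clinical interpretation are merged into
CNV regions (CNVRs): maximal overlap-connected components, with
book-ended (end == start) calls merged, matching the default of
`bedtools merge`, the tool of record for this kind of interval
arithmetic. Duplications and deletions can be merged together
(`scope = "grouped"`) or separately (`gain_only` / `loss_only`); the
typed scopes are what the gene classification uses, since the
mechanism of pathogenicity may differ between a duplication and a
deletion of the same locus.

Within each CNVR, `coverage_profile()` computes CNV coverage — the
number of member CNVs over each base — as a step function by sweeping
the sorted member endpoints; adjacent equal-depth segments are fused,
and the invariant `sum(depth * width) = sum(member lengths)` is
asserted in the tests against per-base counting.

A **peak region** is any local maximum of coverage: a maximal
constant-depth plateau whose two neighbouring depths are both
*strictly* lower, with depth defined as 0 beyond the CNVR ends. This
plateau rule is a deliberate design choice: "higher than its flanks"
does not by itself say how to treat plateaus or the region edges, and
the strict-inequality, zero-flank formulation is the unique definition
that (a) is independent of input order, (b) gives at least one peak in
every CNVR, and (c) degenerates to "the entire CNV is the peak" when a
CNVR contains a single call. A coverage-threshold alternative was
rejected because it would discard rare-but-causal CNVs entirely and
would not refine high-coverage regions at all. Peak detection is
validated against a per-base brute-force oracle on over a thousand
random profiles.

# Gene classification

A gene intersects an interval if **one or more bases** overlap, on
either strand; half-open abutment is not an overlap. Classification
considers all CNVs simultaneously — full CNVs on the benign side
(the entire benign call is presumed benign) and **peak regions only**
on the pathogenic side — and reduces each gene's four membership flags
to a label:

| benign gain | benign loss | path gain peak | path loss peak | label |
|---|---|---|---|---|
| any benign only | | — | — | B |
| — | — | any pathogenic only | | P |
| gain | — | gain | any | X (same-type contradiction) |
| — | loss | any | loss | X |
| — | loss | gain | — | BL_PG |
| gain | — | — | loss | BG_PL |
| — | — | — | — | unclassified |

The same-type contradiction (X) dominates: a gene seen in both a
benign gain and a pathogenic gain is a likely passenger regardless of
any other membership. BL_PG and BG_PL require *exactly* that
cross-type pair — these are the biologically interpretable patterns
(BG_PL fits simple haploinsufficiency: loss is pathogenic, gain is
tolerated; BL_PG fits aggregation-prone or overexpression-sensitive
genes). The mapping is a pure function of the flags and is tested
against an independently written 16-row truth table.

A **solitary** Class P gene is the only Class P gene overlapping a
given pathogenic peak region — a candidate causative gene by
exclusion. `solitary_summary()` also reports genes that are solitary
for both a duplication and a deletion region, the strongest such
candidates.

# Copy-number conservation across mammals

For each gene inferred present in the mammalian common ancestor, the
13-species orthology profile is tallied: `one2one` = unchanged,
`one2many` = duplicated, no orthologue = presumed loss. A gene is
**conserved** when unchanged in all 13 genomes. Genes without the
ancestral flag are excluded from scoring (they are either young genes
or fast-evolving ones whose orthology cannot be traced; either way the
counts would be misleading).

Genes duplicated on the human lineage since the mammalian divergence
would make every non-sharing genome look "changed"; such recent
in-paralogues are grouped and the group's ancestral copy number of 1
is compared per species. Because a three-state status cannot express
"how many orthologues of the group does this species carry",
`group_recent_paralogues()` takes a long orthologue-*pair* table
(`human_gene`, `species`, `ortholog_id`) and counts distinct
orthologues per (group, species): 1 is `one2one`, more is `one2many`,
0 is `none`. Singleton groups reduce exactly to the per-gene scheme.
A residual `many2many` status in profile input is treated as an input
error rather than a fourth state.

`conservation_by_class()` compares the per-class distributions of the
unchanged count with the Fligner–Killeen scale test (the hypothesis is
about *variability* of copy number, and the counts are skewed and
bounded, so a rank-based scale test is appropriate) and the
conserved-by-class contingency table with an uncorrected Pearson
chi-squared test.

# The location-randomization null

Pathogenic CNVs are long, so they contain developmental genes more
often than benign CNVs for length reasons alone. The null model
corrects for this: each CNV keeps its chromosome, length, type and
interpretation and is re-placed uniformly in `[0, L - len]`.
Randomization is within-chromosome — cross-chromosome placement would
confound chromosome-level gene density — and placed CNVs may overlap
each other, since nothing in the data forbids overlapping calls.
Assembly gaps and centromeres are not masked; on real genomes this
makes the null slightly conservative territory-wise and is a
documented limitation. The empirical p-value uses the add-one rule
`(1 + #(null >= observed)) / (n_reps + 1)`, so it is never exactly 0;
the Z-score `(observed - mean) / sd` and its normal-approximation
p-value are reported alongside for comparison with headline claims.
Determinism is guaranteed given the seed.

The calibration test treats a random placement as the "observed" data
and checks that empirical p-values are uniform over 500 runs. The
statistic used there is total overlap in bp rather than the fraction
of CNVs with a hit: a statistic with a handful of attainable values
produces tied observed/null draws, for which the add-one p is
conservative by construction — a property of discrete permutation
tests, not of this implementation.

# The enrichment battery

Per-class attribute comparisons mirror the standard dosage-sensitivity
battery: boolean attributes (developmental, protein-complex member,
ohnologue, OMIM disease gene, and "haploinsufficient", defined as a
loss-of-function-intolerance probability above 0.9) are compared
across classes with uncorrected Pearson chi-squared tests plus
per-cell **adjusted residuals** `(obs - exp) / sqrt(exp (1 - r/N)
(1 - c/N))`, with |residual| > 2 flagging the driving cells; numeric
attributes (the haploinsufficiency proxy score and maximal expression
in RPKM) are compared pairwise with the Mann–Whitney U test
(tie-corrected normal approximation, no continuity correction). No
Yates correction is used anywhere: the +/-2 residual convention
presumes the uncorrected Pearson form. All p-values are
Bonferroni-corrected over the number of comparisons actually emitted
in the report, and that family size `m` is echoed in the output so the
correction is auditable. Term enrichment
(`hypergeom_enrichment()`) is an upper-tail hypergeometric test
against a *custom background* — e.g. solitary Class P genes against
all genes in full pathogenic CNVRs — with Bonferroni over the terms
tested; GO-graph propagation and web services are out of scope.

# The synthetic study design

`simulation_config()` defines the conditions every recovery test runs
under. A single latent boolean, `dosage_sensitive` (20% of genes),
drives all structure:

* attribute enrichments: developmental 0.9 vs 0.10, complex membership
  0.45 vs 0.20, ohnologue 0.45 vs 0.25, OMIM 0.22 vs 0.10, ancestral
  0.98 vs 0.88 (sensitive vs neutral);
* the haploinsufficiency proxy is drawn from U-shaped Beta
  distributions (Beta(0.5, 0.5) sensitive, Beta(0.3, 2) neutral),
  mirroring the bimodality of loss-of-function-intolerance scores;
  expression is log-normal with medians 20 vs 8 RPKM;
* orthology: per-species change probability `q_sensitive = 0.02` vs
  `q_neutral = 0.15`, changes split evenly between duplication and
  loss;
* CNVs: benign outnumber pathogenic 2:1 (400 vs 200 calls) but
  pathogenic calls are an order of magnitude longer (log-normal,
  median 600 kb vs 40 kb, truncated to [50 bp, 0.1 chromosome]);
  pathogenic CNVs are anchored on a random sensitive gene with
  probability `targeting = 0.8`; benign CNVs avoid sensitive genes
  with probability `avoidance = 0.8`.

The genome is 4 chromosomes of 50 Mb carrying 2,000 non-overlapping
genes. With these defaults the simulated data reproduce the
qualitative structure of the real study inputs: roughly 93% of
pathogenic CNVs contain a developmental gene against a null mean near
79%, giving randomization Z-scores around 5–6; Class P genes have a
higher median unchanged-species count than Class B; and the
dosage-sensitive-by-class contingency test is decisive. The
developmental enrichment and pathogenic length scale were calibrated
once so that the generated data show the containment contrast the
analysis is designed around (an observed containment far above the
null's reach), then frozen. With the signal switched off
(`q_sensitive = q_neutral`, no targeting or avoidance) the same
contrasts are null-calibrated — non-significant at the 1% level in
well over 90% of runs.

What the generator does *not* emulate: overlapping genes, hotspot
recombination structure, assembly gaps, length-dependent
interpretation bias within a stratum, and inter-CNV spacing
correlations. Passing recovery tests therefore show that the
machinery detects the modelled signal at realistic sizes — not that
real dbVar data would give any particular number.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full design at 2,000
genes, 600 CNVs and 500–1,000 randomization replicates; the oracle
comparisons use ~1,000 random small profiles, and calibration uses 500
permutation runs of 99 replicates. These sizes keep a full run in the
low minutes on one CPU while leaving every statistic far from its
detection boundary. Ties in rank tests use the tie-corrected normal
approximation; degenerate cases are flagged rather than guessed at
(zero-spread permutation nulls yield `z = NA` with a warning;
all-equal scale-test deviations return p = 1 with `degenerate = TRUE`;
gene-empty CNVs yield `NA` annotation fractions and are excluded from
medians rather than scored 0). Chromosome-length arithmetic is done in
doubles throughout — human coordinates exceed what a 32-bit integer
multiplication survives.

# Known limitations

* Clinical labels other than the literal "benign"/"pathogenic"
  (e.g. "likely benign") are rejected at ingest rather than coerced;
  how the original archives resolved multi-study conflicts is not
  modelled.
* The null does not mask unmappable genome; Z-scores on real data
  would be slightly anti-conservative in gap-rich regions.
* Conservation scoring trusts the orthology annotation; genuinely
  missing data and true gene loss are indistinguishable here.
* The Bonferroni family for the battery is the emitted table, which
  may be smaller or larger than the family used in any particular
  published analysis; both raw and corrected p-values are reported.
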