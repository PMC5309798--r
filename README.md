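# dosagescope

Gene dosage sensitivity as a lens on copy number variant (CNV)
pathogenicity.

Pathogenic human CNVs are typically megabases long and contain dozens
of genes, so a clinical "pathogenic" label does not say which gene
drives the phenotype. `dosagescope` implements an analysis built on
the dosage-sensitivity model — that a ~50% change in the copy number
of particular genes (complex subunits, morphogens, haploinsufficient
genes, ohnologues) is what makes a CNV harmful — and uses two
independent signals to home in on candidate genes:

1. **Recurrence.** Overlapping same-interpretation CNVs are merged
   into CNV regions (CNVRs), coverage (number of overlapping CNVs per
   base) is computed as a step function, and **peak regions** — local
   maxima of coverage, i.e. maximal plateaus strictly higher than both
   flanking depths (0 outside the CNVR) — proxy the recurrently
   affected critical region. A single-CNV region is its own peak, so
   rare variants are never discarded.
2. **Evolutionary copy-number conservation.** For each human gene
   present in the mammalian common ancestor, one-to-one / one-to-many
   / missing orthology across 13 mammalian genomes is tallied into
   unchanged / duplicated / lost counts; genes unchanged in all 13
   genomes are "conserved", an annotation-independent marker of dosage
   constraint.

Genes are classified by their CNV overlap pattern — full CNVs on the
benign side, peak regions on the pathogenic side: **Class B**
(benign-only), **Class P** (pathogenic-only), **Class X** (both
interpretations for the same CNV type; passengers), plus the
cross-type patterns **BL/PG** and **BG/PL**. A pathogenic peak region
whose only Class P gene is a single gene makes that gene a
**solitary** candidate, pathogenic by exclusion.

Supporting machinery: a length- and chromosome-preserving CNV
location-randomization null with permutation summaries (Z-score,
add-one empirical p); an enrichment battery (uncorrected Pearson
chi-squared with adjusted residuals, tie-corrected Mann–Whitney U,
Fligner–Killeen scale test, upper-tail hypergeometric term enrichment
with a custom background, all Bonferroni-corrected with the family
size echoed); and a synthetic-data generator that emulates the
dbVar/Ensembl-style inputs so the entire pipeline is testable without
network access.

## Worked example

Regions and peaks from the bundled synthetic dbVar-style table
(1-based inclusive on disk, converted to 0-based half-open at the
boundary; calls <50 bp or >10% of their chromosome are dropped at
ingest):

```r
library(dosagescope)
build <- genome_build("synthetic", c(`1` = 5e6, `2` = 5e6))
tsv <- system.file("extdata", "synthetic_cnvs_dbvar.tsv",
                   package = "dosagescope")
cnvs <- read_cnv_table(tsv, "dbvar_tsv", build)
path <- cnvs[cnvs$interpretation == "pathogenic", ]
regions <- merge_cnvrs(path, "grouped")
peaks <- find_peaks(regions, path)
genome_fraction(path, build)   # 0.272
genome_fraction(peaks, build)  # 0.179
```

This prints 12 CNVRs refined into 12 peak regions: the pathogenic
calls cover 27.2% of the toy genome but their peak regions only
17.9% — the refinement that makes per-gene analysis tractable.

The full pipeline on a default synthetic study (4 chromosomes x 50 Mb,
2,000 genes, 600 CNVs):

```r
res <- run_pipeline(sim_config = simulation_config(),
                    n_reps = 500, seed = 1)
table(res$assignments$label)
#>    B  BG_PL  BL_PG    P  unclassified   X
#>  197     13     19  629          1097  45
res$randomization
#> CNV location-randomization test
#>   observed: 0.935  null mean: 0.7916 (sd 0.02553, max 0.87)
#>   Z = 5.618, empirical p = 0.001996 (500 reps, seed 4)
```

93.5% of the simulated pathogenic CNVs contain a developmental gene;
random placement of the same CNVs never exceeds 87%, so the excess is
a location signal (Z = 5.6), not a length artefact. The conservation
summary shows the matching evolutionary signal — Class P genes have a
higher median number of unchanged genomes (12) than Class B genes
(11), and 200/588 Class P genes are fully conserved versus 18/173 for
Class B (`res$conservation_by_class$per_class`).

A thin command-line front end over the same functions is at
`inst/scripts/dosagescope.R` (subcommands `convert`, `simulate`,
`regions`, `peaks`, `all`).

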