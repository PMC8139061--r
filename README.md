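# sewerstates

Analysis of seasonal community states and human-source partitioning in
sewer microbiome time series.

Municipal wastewater carries a mixture of two bacterial assemblages: a
transient fraction shed by the human microbiome and a resident community
that grows in the sewer pipes themselves. On monthly 16S rRNA amplicon
sequence variant (ASV) tables, the resident fraction cycles with
wastewater temperature and assembles into two recurring seasonal states —
a cold spring configuration (February–June) and a warm fall configuration
(August–December) — while the human fraction stays small and aseasonal.
`sewerstates` is for microbial ecologists and wastewater-surveillance
groups who want to reproduce that style of analysis on their own ASV
tables, with every statistic testable against ground truth.

## What the package does

**Source partitioning.** ASVs are matched to a human-microbiome reference
by exact sequence identity (after uppercase/U→T normalization of both
sides; the reference is dereplicated and reduced to sequences occurring
≥ 10 times with subject and sample metadata). Matched ASVs then pass a
percentile threshold rule: if an ASV's 5th-percentile relative abundance
across wastewater samples (a robust minimum, zeros included) *exceeds*
its 95th-percentile abundance across reference samples (a robust
maximum), it is reclassified as a sewer resident:

    reclassify to sewer  ⟺  Q5_wastewater(p_i) > Q95_reference(p_i)

Unmatched ASVs are sewer residents by definition. Human-labeled reads are
summarised per sample and split across body-site bins (stool, oral, skin,
airways, urogenital, other).

**Community statistics.** Shannon diversity (nats), Bray-Curtis
dissimilarity, principal-coordinate analysis (Gower double-centering,
no negative-eigenvalue correction), one-way PERMANOVA with label
permutation, environmental vector fitting onto ordination axes, and
Mann-Whitney / Spearman tests. All dissimilarity statistics are
implemented from their definitions and cross-checked in the test suite
against brute-force oracles and `vegan`/`ape`.

**Seasonal dynamics.** Indicator-species analysis (IndVal = √(A·B)) over
all twelve consecutive three-month windows with a selection-corrected
permutation p, gap-aware autocorrelation with the 1.96/√n significance
bound, z-score hierarchical clustering of seasonal profiles, and the
spring/fall/mix month grouping.

**Synthetic studies.** A fully seeded generator produces a 60-month
monthly ASV table with temperature-tracking seasonal sewer taxa,
aseasonal human taxa at a configurable read fraction (0.11 treatment
plant / 0.36 neighborhood), "trap" taxa that must be reclassified, plus
matching sequences, metadata and a raw reference — so the whole pipeline
runs end to end with known truth.

## Worked example

```r
library(sewerstates)

cfg <- simulationConfig(seed = 7)          # 60-month treatment-plant study
study <- simulateStudy(cfg)
study$experiment
#> AsvExperiment: 240 ASVs x 60 samples
#>   depth: 20000-20000
#>   sequences: lengths 374-374
#>   sample metadata: date, month, month_index, season, temperature, ...

ref  <- buildReducedReference(study$referenceRecords)
part <- partitionSources(study$experiment, ref)
#> partition: 90 matched, 10 reclassified, 80 human / 160 sewer
mean(humanFraction(study$experiment, part))
#> [1] 0.110

rel <- relAbund(study$experiment)
ord <- pcoa(brayCurtis(rel))
cd  <- SummarizedExperiment::colData(study$experiment)
spearmanRho(ordCoordinates(ord)[, 1], cd$temperature)$rho
#> [1] -0.98

permanova(brayCurtis(rel), cd$season, nPerm = 999, seed = 1)
#> PERMANOVA: pseudo-F = 20.865, R2 = 0.423, p = 0.001 (999 permutations)

ind <- indicatorScreen(study$experiment, nPerm = 499, seed = 2)
head(ind[ind$significant, c("asv_id", "window", "stat", "p")])
#>   asv_id      window      stat     p
#>  ASV0027 Mar-Apr-May 0.9235026 0.002
#>  ASV0021 Mar-Apr-May 0.9008550 0.002
#>  ...
```

Reading these numbers: all ten trap taxa were reclassified by the
percentile rule, leaving exactly the 80 true human taxa labeled human;
the realized human read fraction matches the configured 11%; PCoA Axis 1
moves with wastewater temperature (|rho| = 0.98); the spring/fall/mix
grouping explains 42% of community variation at the permutation floor
p = 0.001; and the strongest indicators are cold-class taxa peaking in
the spring window Mar-Apr-May.

A full run — simulate, partition, statistics, seasonal analyses, TSV
outputs and a checksum manifest — is one call:

```r
runPipeline("results/run1", config = simulationConfig(seed = 7))
```

or, from a shell, `Rscript inst/scripts/run_pipeline.R --out results/run1
--seed 7` (the same script accepts `--asv-table/--metadata/--asv-fasta/
--reference-meta` to analyse your own files).

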