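---
title: "Partitioning and seasonal analysis of sewer microbiome time series"
author: "sewerstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning and seasonal analysis of sewer microbiome time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sewerstates)
```

## The scientific problem

Untreated wastewater carries two distinguishable bacterial assemblages: a
transient human-microbiome component washed in from households, and a
resident community that grows in the sewer conveyance system itself. The
two behave differently in time — the human fraction is roughly constant
through the year, while resident sewer taxa track the slow annual cycle of
wastewater temperature, assembling into two recurring community states
(a cold "spring" configuration and a warm "fall" configuration separated
by transition months). `sewerstates` implements the full analysis needed
to demonstrate this on monthly 16S rRNA amplicon sequence variant (ASV)
tables: source partitioning against a human-microbiome reference, then
ordination, permutation, indicator-species and autocorrelation statistics
on the partitioned time series. A seeded generator produces synthetic
studies with known ground truth so each stage can be validated end to end.

## Source partitioning model

An ASV is a candidate human-microbiome member only if its sequence is
*string-identical* (after uppercasing and U→T normalization) to a sequence
in a reduced human-microbiome reference. The reference is built by
dereplicating raw per-occurrence records and keeping sequences that occur
at least 10 times (boundary inclusive) with at least one subject and one
sample identifier. All unmatched ASVs are resident sewer organisms by
definition.

Exact identity is necessary but not sufficient: an organism can live in
both habitats, and index-hopping or low-level carryover can place sewer
reads on human-matching sequences. Matched ASVs are therefore screened by
a percentile threshold rule. For a matched ASV,

* the 5th percentile of its relative abundance across wastewater samples
  (a robust minimum; samples where it is absent contribute zeros), and
* the 95th percentile of its relative abundance across reference samples
  (a robust maximum)

are compared. If the wastewater minimum *strictly exceeds* the reference
maximum, the ASV is too consistently abundant in sewage to be explained by
human input, and it is reclassified to the sewer fraction. Ties stay
human, since the rule requires exceedance. Three numerical choices are
deliberate and recorded here because they change the outcome:

* **Quantile estimator.** Linear interpolation between order statistics
  (`stats::quantile` type 7), the default of the surrounding R ecosystem.
* **Zeros included.** An ASV absent from a sample contributes relative
  abundance 0. Excluding zeros would push nearly every matched ASV over
  the threshold and empty the human fraction, which contradicts the
  intended behaviour of a rule that moves only a small set of ASVs.
* **Reference abundance basis.** Within-reference-sample fractions of
  per-occurrence records, collected across samples with zeros where a
  sequence is absent.

Human-labeled read mass is summarised per sample (`humanFraction`) and
split across body-site bins (stool, oral, skin, airways, urogenital,
other) via a configurable label schema; an ASV whose reference records
span several sites is split proportionally to the sites' occurrence
counts, since a single read cannot be attributed more precisely.

## Community statistics

All dissimilarity-based statistics are written against their standard
definitions and checked in the test suite against both brute-force oracles
and the independent implementations in `vegan` and `ape`:

* **Shannon diversity** in natural-log units on relative abundances,
  without rarefaction (sample depth is constant in the simulated studies;
  for real data the user should verify depths are comparable).
* **Bray-Curtis dissimilarity** between sample pairs.
* **PCoA** by Gower double-centering of \(-d^2/2\) and a symmetric
  eigendecomposition. No Lingoes/Cailliez correction is applied; negative
  eigenvalues are reported but excluded from the proportion explained.
  Axis signs are fixed (largest-magnitude loading positive) so results
  are deterministic.
* **PERMANOVA** (one-way) from the sum-of-squared-dissimilarity
  partition, with group-label permutation and the +1 convention
  \(p = (1 + \#\{F^* \ge F\})/(1 + B)\), so p is never 0 and has
  resolution \(1/(B+1)\).
* **envfit**: least-squares fit of a numeric covariate onto the first two
  ordination axes (configurable); \(R^2\) is the squared multiple
  correlation, the arrow the unit vector of axis coefficients, and
  significance is by permutation of the covariate. Missing covariate
  values are dropped with a message.
* **Mann-Whitney U** and **Spearman rank correlation** delegate to
  `stats::wilcox.test` / `stats::cor.test`; the package chooses exact
  enumeration for pooled sizes ≤ 12 without ties and the tie-corrected
  normal approximation otherwise, and the t approximation for Spearman p.

## Seasonal dynamics

Calendar months are grouped as spring (February–June), fall
(August–December) and mix (January and July) for group-difference tests.
Indicator analysis runs over all twelve three-consecutive-month windows,
wrapping the year boundary; each window is tested one-vs-rest, because
overlapping windows cannot form a single partition of the samples. The
indicator value of an ASV for a window is \(\sqrt{A \cdot B}\) with
specificity \(A = \bar{x}_{in}/(\bar{x}_{in} + \bar{x}_{out})\) on group
means of relative abundance and fidelity \(B\) the in-group occupancy.
Only ASVs whose maximum relative abundance reaches 1% are screened, which
focuses the analysis on the predominant community members.

Because the reported window for each ASV is the *best of twelve* highly
correlated candidates, quoting that window's raw permutation p would
inflate significance roughly six-fold for aseasonal taxa. The screen
therefore computes the best-window p against the permutation null of the
*maximum* statistic across all windows (the same permutations evaluated on
every window). With this correction an aseasonal ASV is flagged at the
nominal rate, which the calibration tests verify; the per-window
uncorrected p-values remain available in `attr(result, "all_windows")`.

The autocorrelation function places each series on a complete monthly
grid, leaving unsampled months as explicit gaps: lag-k products are
summed over pairs where both points exist, while the mean and the
variance denominator use all observed points. The large-lag significance
bound is \(1.96/\sqrt{n}\) with \(n\) the number of observed points —
0.253 for a complete 60-month series, which the field conventionally
prints as ≈ 0.26. The bound is always computed, never hard-coded, so
series with missing months get the slightly wider bound their smaller
\(n\) implies. A significant lag-12 autocorrelation on monthly data is
the operational definition of annual seasonality used throughout.

Hierarchical clustering of seasonal profiles z-scores each ASV against
its own series (mean 0, sd 1), then applies average-linkage agglomeration
on Euclidean distances; constant series are excluded, and the leaf order
is deterministic.

## The synthetic study generator

The generator emulates the statistical structure the analysis assumes, at
desk scale, with every random draw governed by one master seed that fans
out to stages through `deriveSeed` (so results are bit-reproducible).

* **Temperature.** \(T(t) = 14 + 4\cos(2\pi(m_t - 10)/12) + \epsilon\),
  °C, peaking in October and bottoming in April with an ~8 °C annual
  range — the wastewater cycle that lags air temperature by about three
  months. Noise sd 0.3 °C.
* **Taxa.** Five classes: warm-seasonal and cold-seasonal sewer residents
  (log-linear in temperature, slope ±0.25 per °C), aseasonal sewer
  residents, aseasonal human-associated taxa, and "trap" taxa — sewer
  residents whose sequences also occur in the human reference and which
  the percentile rule must reclassify. Defaults: 15/15/120/80/10 taxa,
  60 monthly samples, depth 20 000.
* **Composition and counts.** Per-taxon lognormal multiplicative noise
  (sd 0.3); each sample's composition is renormalized so the expected
  human read fraction equals the target (0.11 for treatment-plant
  influent, 0.36 for neighborhood sewers); counts are drawn
  Dirichlet-multinomial with concentration 500, the overdispersion level
  typical of amplicon data.
* **Reference.** Every ASV gets a random 374-base sequence (the median
  merged amplicon length for this primer region; collisions are checked
  and regenerated). Human-class taxa receive ≥ 10 per-occurrence
  reference records spread over a 50-sample panel, with body-site labels
  drawn mostly from stool; trap taxa are confined to the largest number
  of panel samples that still leaves their interpolated 95th-percentile
  reference abundance exactly zero, which — combined with their ~1%
  consistent wastewater abundance — guarantees reclassification by
  construction. The generator refuses trap construction on panels too
  small for that guarantee (< 21 samples).

What the generator does **not** emulate: taxonomic structure, sequence
error and chimeras, varying sequencing depth, correlated environmental
covariates beyond temperature, multi-year trends, or the heavy-tailed
richness (tens of thousands of ASVs) of real influent. Passing the
recovery tests therefore shows the statistics do what they claim on data
with the assumed structure — not that the biological conclusions transfer
to any particular real system.

## Problem sizes and runtime choices

The packaged tests run the generator at two scales: compact configurations
(24 months, ~30 taxa, depth 5 000) for pipeline mechanics, and the default
60-month study for parameter-recovery checks. Permutation counts in tests
are 99–999; calibration suites use 200 replicates at 99 permutations,
enough to detect the miscalibrations worth catching (a doubling of the
nominal 5% rate) without burning minutes on Monte-Carlo precision the
assertions do not need. The acceptance script uses 9 999 permutations for
the seasonal PERMANOVA, matching the resolution needed to report small
p-values sensibly.

## Known limitations

* The percentile rule's behaviour depends on reference panel size and the
  abundance basis chosen for the reference; for real reference resources
  the normalization of per-sample abundances should be revisited.
* Mann-Whitney comparisons of Bray-Curtis values (as used in this kind of
  survey) treat pairwise dissimilarities as independent observations,
  which they are not; the package reproduces the practice but the p-values
  should be read as descriptive.
* One-vs-rest indicator windows are one of several defensible designs;
  a full partition-based analysis (as in `indicspecies::multipatt`'s
  combinatorial search) is out of scope.
* The ACF estimator is the plug-in moment estimator; no small-sample bias
  correction is applied, matching standard practice.
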