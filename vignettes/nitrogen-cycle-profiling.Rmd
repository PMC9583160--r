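---
title: "Profiling nitrogen-cycle genes across a soil metagenome survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling nitrogen-cycle genes across a soil metagenome survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroscape)
library(dplyr)
```

## The analysis problem

Shotgun metagenomes annotated against KEGG Orthology (KO) give, for every
sample, a table of GeneIDs with the KO each sequence was assigned to and an
*Estimated Copy* value — the expected number of sequences behind that
GeneID. Restricted to the nitrogen-cycle KOs, such tables answer two
ecological questions: which steps of the nitrogen cycle are genetically
possible at which sites, and which biogeochemical conditions accompany
them. `nitroscape` implements that analysis as a set of composable,
tested steps. This vignette explains the statistical choices behind each
step, what the synthetic-data generator does and does not emulate, and the
limitations a user should keep in mind.

## The gene catalog and KO-level resolution

The catalog (`nitrogen_catalog()`) maps 27 KOs to 19 proteins (operons)
across six pathways: nitrogen fixation, nitrification, denitrification,
dissimilatory nitrate reduction (DNR), assimilatory nitrate reduction
(ANR), and anammox. Annotation is KO-level, and some KOs cover several
paralogous genes indistinguishably — K00370 is *narG*, *narZ* and *nxrA* at
once, which is also why the NarGHI/NxrAB entry belongs to three pathways.
All statistics are therefore computed per KO; gene symbols are reported as
aliases, never as separate observational units. Any record whose KO is not
in the catalog is dropped at ingest (with a count in the log), so nothing
unresolvable can reach the statistics.

## Per-gene statistics

For each (sample, KO) cell, three statistics summarize the annotation
table:

* **abundance** — the sum of Estimated Copy over the KO's GeneIDs; the
  expected number of sequences of that gene in the sample. Raw sums are
  used: no normalization by sequencing depth or genome equivalents is
  applied, so cross-sample comparisons inherit whatever depth differences
  the survey has.
* **richness** — the number of distinct GeneIDs; a proxy for the genetic
  diversity of the function.
* **variance** — the sample variance (n − 1 denominator) of the Estimated
  Copy values. With fewer than two GeneIDs the variance is *undefined* and
  stored as `NA`, never as 0; downstream correlations drop such cells
  pairwise. Estimated Copy values need not be integral; the reader accepts
  any positive real.

The matrix is complete over the catalog: absent KOs get explicit zero rows,
which makes richness-0 cells first-class observations (a survey in which a
gene was never seen is information, not missing data). Totals are
conserved: the abundance column sums exactly to the Estimated Copy total of
the retained records, which the test suite asserts against a record-by-
record oracle.

## Operon completeness and prevalence

Detection of a single subunit gene does not demonstrate the genetic
potential to build the enzyme. A protein is therefore called **present** in
a sample only when *every* KO of its operon has richness ≥ 1 there
(`call_protein_presence()`); one subunit without the others leaves the
protein absent. No abundance threshold is applied on top of richness ≥ 1 —
detection is detection. Prevalence (`prevalence()`) is the percentage of
sites where an item was detected, printed to one decimal with halves
rounded away from zero, the convention in which 7 of 32 sites reads 21.9%.

## The correlation screen

Relationships between gene metrics, and between gene metrics and
covariates, are screened with the Pearson coefficient; the p-value is the
two-sided t-test, `t = r√((n−2)/(1−r²))` on n − 2 degrees of freedom.
Choices that matter:

* **Masking, not filtering.** Every pair is retained in the output with a
  `significant` flag at α = 0.05; masked exports (`cor_matrix_wide()`)
  blank the non-significant cells, mirroring how correlogram figures are
  usually drawn. By default p-values are unadjusted — the flag reproduces a
  per-pair p < 0.05 screen — and a Benjamini–Hochberg option is available
  but off, so users who want family-wise control must opt in.
* **Missing data** are dropped pairwise and `n` is reported per pair;
  undefined variances count as missing.
* **Degenerate pairs** (constant vector, n < 3) return `NA` rather than a
  fabricated value.
* Gene–gene correlations default to the raw scale; `metrics_wide()` offers
  `log1p` for users who prefer a damped scale, with no default claim that
  either is right.

## Discretization and association rules

Rule mining requires categorical items. Covariates are discretized on
empirical quantiles: a median split (labels `<50%`/`>50%`) or a
30th/70th-percentile split (`<30%`/`30-70%`/`>70%`). Quantiles use linear
interpolation between order statistics (`quantile()` type 7) and values
equal to a cut point go to the lower bin — a deterministic tie rule matters
because count covariates tie often. Constant covariates cannot be
partitioned; they are flagged degenerate and excluded from mining rather
than silently becoming a single always-on item. Three bins are the default
for continuous covariates; sparse counts are better served by two
(`bins = c(rotifers = 2)`); the cut points are always reported so the
partition can be published alongside the rules. Missing covariate values
emit no item by default; `missing_as_item = TRUE` turns absence into an
explicit item for surveys where absence is informative.

Each sample then becomes a transaction of covariate items plus one
`Protein=Present/Absent` item per catalog protein. Frequent item-sets are
found by a level-wise Apriori with the downward-closure prune, written in
the package and verified against exhaustive bitmask enumeration on random
databases. Rules antecedent ⇒ consequent are scored by support (joint
frequency), confidence (support / antecedent support, exactly) and lift
(confidence / consequent support; 1 = independence). Consequents are
single items by default and can be filtered (e.g. to operon items), which
is the natural reading of presence/absence rule figures.

Default thresholds are `min_support = 0.1` and `min_confidence = 0.8`, with
rules ranked by lift then support. A practical note on the antecedent cap:
with ~60 items over 32 dense transactions, the frequent-set lattice up to
the default cap of 10 antecedent items is combinatorially enormous for any
Apriori-family miner. The cap is a function argument precisely so users can
bound the run; the package's own examples mine with `max_antecedent` of 1–2,
which is where single rules stay interpretable anyway.

## Spatial interpolation

Environmental fields over an irregular sampling layout are interpolated
linearly: Delaunay triangulation of the sites (via the `interp` package;
points are sorted lexicographically first so cocircular degeneracies are
broken reproducibly) followed by barycentric — piecewise-planar —
evaluation on a square-celled grid. This is the classic linear mode of
scattered-data interpolation for irregular layouts; the smooth bicubic
variant is deliberately out of scope. Consequences a user can rely on:

* the interpolant is exact at the sites (the barycentric weight of a
  queried vertex is exactly 1 in floating point, by construction of the
  weight formula);
* affine fields are reproduced to machine precision, and every value is
  bounded by its triangle's vertex values — no overshoot;
* grid nodes outside the convex hull are `NA`, as are nodes in triangles
  with a missing site value (a missing value poisons only its incident
  triangles);
* the default grid is ~200 cells along the longer bounding-box side with a
  2% margin; because triangulations of cocircular point sets are not
  unique, interpolants can differ between implementations exactly on shared
  edges, which is documented rather than hidden.

Fields export as ESRI ASCII grids and per-KO point layers (coordinates +
abundance/richness/variance) as CSV, consumable by any GIS front-end; the
package draws quick looks via `autoplot()` but leaves cartography to
dedicated tools.

## The synthetic survey generator

`generate_survey()` emulates the *structure* of the study inputs so the
whole pipeline can be exercised with no download: 32 samples by default,
per-KO GeneID counts from a negative binomial (dispersion 1.5) whose mean
is solved from a per-KO detection prevalence, Estimated Copy values from a
log-normal (meanlog 0.25, sdlog 0.6 — copies of a few units, occasionally
~5–10), clustered planar coordinates with a smooth habitat-quality bump,
and covariates on realistic marginals (pH ~8.6 ± 0.55 clipped to
[7.4, 9.7]; percent-scale log-normals for water and nutrient content;
integer counts for taxa). Default prevalences span the range such surveys
report — ubiquitous nitrate-reduction genes, patchy *nosZ*/*nifDKH*, rare
*hao*/*napB*, absent anammox genes — so every prevalence code path is
exercised.

Two kinds of structure are planted and recorded in a truth record:

* **Correlations** between a covariate and a KO's richness, via a Gaussian
  copula: the covariate's latent is `ρ·z + √(1−ρ²)·ε` where `z` is the
  KO's latent. Marginal transforms attenuate the realized Pearson
  correlation below the copula's ρ (monotone transforms always do), so the
  truth record stores the *realized* correlation alongside the target. At
  n = 32 the sign of every planted |ρ| ≥ 0.5 is recovered in ≈98% of
  seeds; when a rare KO happens to be all-zero in a draw the correlation is
  undefined and is counted as a failed recovery.
* **Rules**: in samples where the antecedent item holds (e.g. soil water
  above its 70th percentile), the consequent operon is forced complete with
  a stated obedience probability; at obedience 1 the miner recovers the
  rule with confidence exactly 1 and lift 1/P(consequent).

What the generator does *not* emulate: taxonomic composition, sequencing
depth artifacts, spatially autocorrelated noise beyond the single habitat
bump, or any attempt to match a real survey's joint distribution. Green
tests therefore demonstrate that the pipeline's logic is correct under a
known structure — not that any particular field dataset satisfies that
structure.

## Problem sizes and numerical tolerances

The test and acceptance workloads use: 200 random databases (≤ 12 items,
≤ 40 transactions) for miner-vs-enumeration equality (exact); 10,000 null
replicates at n = 32 for type-I calibration (asserted within ±0.01 of
0.05); 1,000 random record tables for metrics-vs-oracle equality (1e-12)
and conservation (1e-9 relative); 100 random layouts for affine
interpolation exactness (1e-10); 500 seeds for sign recovery (≥ 0.95).
Barycentric containment uses a −1e-12 weight slack so nodes on shared
edges belong to the first triangle tested; rule identities hold to 1e-12.

## Known limitations

* Presence/absence speaks to genetic potential only — not expression, nor
  the viability of the organisms carrying the genes.
* Raw-scale abundance comparisons across samples conflate biology with
  sequencing depth; users with depth estimates should normalize before
  correlation screening.
* The unadjusted p < 0.05 screen over many pairs implies a ~5% false-flag
  rate per pair by design; the BH option exists for users who need control
  over the family.
* Interpolated fields are only as good as the spatial coverage: everything
  outside the convex hull is honestly `NA`, and sparse regions inside it
  are long linear ramps between distant sites.
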