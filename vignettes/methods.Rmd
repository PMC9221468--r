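---
title: "Consensus co-expression modules and drug fingerprints: models and methods"
author: "coDrugNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus co-expression modules and drug fingerprints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coDrugNet mines a high-throughput drug screen against paired transcriptomes —
a handful of tumor-derived cell lines and a set of primary tumors — to
prioritize drugs and two-drug combinations whose in-vitro activity tracks
biology that is *conserved* between the culture model and the tumor. The
motivating setting is a rare nerve-sheath tumor (plexiform neurofibroma in
NF1 patients) with very few cell lines, a large mechanism-annotated compound
library, and a pressing need to rank candidates before scarce clinical-trial
slots are committed. This vignette describes each model in the pipeline, the
parameters that matter, the synthetic-data generator used for validation,
and the numerical choices made where the design was genuinely open.

## 1. From expression to a consensus network

**Gene filtering.** Genes are filtered by raw Mean Absolute Deviation
(`madFilter()`): the median of absolute deviations from the gene's median,
*without* the 1.4826 normal-consistency constant, compared strictly against
a threshold in expression units (default 1000, linear scale). The raw MAD is
deliberate — a threshold stated in expression units would silently select a
different survivor set if the consistency constant were applied. Whether the
threshold refers to linear or log units is data-dependent, so a `log2`
toggle is exposed rather than guessed. The filter is applied to the
cell-line matrix only; the tumor matrix is subset to the survivors, and both
are then standardized per gene within each dataset (`intersectAndMerge()`),
because correlation networks and eigengenes live on the standardized scale.

**Network.** The unsigned weighted adjacency is `|cor|^beta`
(`adjacencyFromExpr()`, default `beta = 8`). When chosen from data
(`pickSoftPower()`), the power is the smallest candidate whose signed
scale-free fit index (`-sign(slope) * R^2` of `log10 p(k)` on `log10 k`,
over 10 equal-width connectivity bins) reaches 0.8 in *both* datasets,
falling back to the default otherwise; degenerate inputs (too few genes to
bin, constant connectivity) report an undefined fit and fall back. The
topological overlap matrix (`tomSimilarity()`) augments each edge with
shared-neighbor weight; the two TOMs are put on a common scale by matching
their 95th-percentile off-diagonal entries (ratio scaling, capped at 1) and
combined by the elementwise minimum (`consensusTOM()`). The minimum is the
substantive choice: an edge survives only as strongly as *both* datasets
support it, which is what suppresses culture artifacts.

**Module detection.** `detectModules()` clusters `1 - TOM` by
average-linkage hierarchical clustering, cuts the tree at a fixed height
(default 0.995), greys out clusters below `minModuleSize` (default 30), and
then iteratively merges modules whose eigengenes correlate above
`1 - mergeCut` (default: r > 0.75), closest pair first. This static
cut-plus-merge is a fully specified, deterministic stand-in for hybrid
dynamic tree cutting; the module count on real data is parameter-sensitive
under either scheme, and no count is treated as a target. Modules are named
from a fixed colour sequence in descending size order, so names are
reproducible run to run (size ties break toward the earlier cluster id).

**Eigengenes.** A module eigengene (`moduleEigengenes()`) is the first
right singular vector of the module's standardized gene-by-sample block,
scaled to unit standard deviation and oriented so its mean correlation with
the module's genes is non-negative. The orientation is deterministic;
negating every module gene therefore negates the oriented eigengene — there
is no orientation rule that leaves it unchanged under data negation. A
single-gene module's eigengene is that gene's standardized profile.
Eigengene similarity is summarized as `(1 + cor)/2` (`eigengeneAdjacency()`).

## 2. Module preservation

`preservationZsummary()` asks whether a module defined on the reference
(cell-line) data stays coherent in the test (tumor) data. Two statistics are
observed per module: the **density** (mean off-diagonal intramodular
adjacency in the test set) and the **connectivity** pattern (correlation of
the intramodular connectivity vectors between reference and test). A
permutation null replaces the module with random gene sets of equal size
drawn from the shared gene universe; each statistic is standardized to a Z
score, `Zsummary` is their mean, and modules with `Zsummary > 5` are called
preserved — the conventional threshold, exposed as a parameter.

Two numerical choices deserve explanation:

- **The preservation adjacency uses `beta = 1`** (raw `|cor|`), not the
  network-construction power. Raising a noisy correlation estimate to the
  8th power amplifies its sampling error roughly eight-fold; with a few
  dozen samples this noise dominates the connectivity sums and collapses the
  permutation contrast. The Z normalization makes the statistics scale-free,
  so nothing is lost by scoring preservation on the gentler scale. The
  power is exposed for users who want the network's own scale.
- **Degenerate nulls return Z = 0, not 0/0.** If the test set equals the
  reference set, every permuted connectivity correlation is exactly 1 and
  the null has zero spread; when the observed value equals the degenerate
  null the Z is reported as 0 (no contrast), otherwise as missing.

A property of the latent-factor world worth knowing: the connectivity
statistic is only weakly informative there, because each gene's correlation
estimates share that gene's noise realization (the error in a connectivity
entry does not average out across module mates), while the permutation null
is itself structured by module composition. The density statistic carries
the classification; both are kept because together they form the standard
Z-summary skeleton.

## 3. Drug screen, fingerprints, and clustering

**Summary response.** Per drug and cell line, the response is the
trapezoidal area under the viability curve over `log10` concentration,
divided by the log-concentration span (`computeAUC()`). Normalizing by the
span keeps the "AUC" on the same 0–100 viability scale as the raw
readouts, which makes the pre-selection cutoff (median viability strictly
below 55 percent across lines, `viabilityPrefilter()`) dimensionally
coherent. If a deposited screen already carries a summary-response column it
is ingested verbatim and `computeAUC()` is the fallback. Annotation
filtering (`annotationFilter()`) keeps drugs with pChEMBL strictly above 6;
drugs without a curated pChEMBL are kept by default (screening libraries
contain tool compounds that never went through ChEMBL) and can be dropped.

**Fingerprints.** A drug's fingerprint (`drugModuleCorrelations()`) is the
vector of Pearson correlations between its per-line summary responses and
each *preserved* module's eigengene, computed on cell-line samples only —
drug responses exist nowhere else, so correlating against eigengenes from
the merged sample set would pair numbers from different universes.
Correlations over five cell lines are statistically fragile; the package
computes them for any `n >= 3` but the recovery analyses below use 10 lines
to separate implementation correctness from small-n noise. Zero variance on
either side yields a flagged missing value, never a silent zero, and
drugs with missing or flat fingerprints are dropped (not imputed) before
clustering.

**Consensus clustering.** `consensusClusterDrugs()` implements Monti-style
resampling consensus: subsample `itemFraction` of the drugs (default 0.8,
100 resamples), cluster each subsample by average-linkage hierarchical
clustering on `1 - Pearson r` between fingerprint rows (pattern similarity,
not magnitude), cut at each candidate `k`, and record the fraction of
co-samplings in which each pair co-clusters. Two `k`-selection diagnostics
are computed and reported for every candidate: the area under the consensus
CDF with its proportional increase (the classical delta-area elbow), and
the proportion of ambiguous clustering (PAC — consensus entries strictly
between 0.05 and 0.95). **PAC is the default rule** (minimum PAC, ties
toward the largest crisp `k`): when classes are crisply separated, the
frozen within-class micro-structure makes finer splits reproducible under
item subsampling, so the CDF area keeps growing and the elbow over-splits,
while PAC is exactly zero at the planted number of classes and positive
beyond it. The elbow rule remains selectable (`kRule = "deltaArea"`), and
`k` can be forced outright — on real data a fixed `k` chosen by inspection
of the per-`k` diagnostics is common practice.

**Candidate ranking.** `rankCandidates()` scores each drug by its most
negative fingerprint correlation across preserved modules (a negative
correlation means module genes go down where the drug bites), keeps
advanced-status drugs (FDA-approved, Phase III, Phase II) with strictly
negative scores, and emits the top 15 per cluster, ties broken by drug name.
The module attaining the score is kept explicit in the output rather than
collapsed away. `similarFingerprintDrugs()` makes "fingerprint look-alike"
quantitative: row correlation with the anchor at or above 0.8 by default.

## 4. Independent drug action combinations

Under independent drug action (IDA), each cell line responds to a
combination as if treated only by the drug most effective for it:
`V_combo(line) = min(V_A, V_B)` at the chosen concentrations. Averaged over
a panel of heterogeneous lines, the combination beats the best single agent
even without any molecular interaction — the population-level benefit of
non-overlapping sensitivity profiles.

The **IDAcombo score** of a pair is the maximum, over all concentration
pairs of the trimmed grid, of

> (best mean monotherapy viability) − (mean IDA combination viability),

in viability percentage points. The score formula is not restated in the
source literature; this operationalization was chosen because the
conventional reporting threshold of "score > 1" is meaningful for
percentage points and impossible for a 0–1 efficacy difference. It is
documented in every output and isolated behind `idaComboScore()` so an
alternative scoring hook can be swapped in. Because a mean of minima never
exceeds the minimum of means, the score is non-negative for every pair; the
attaining concentrations are always reported. The two extreme screening
concentrations (0.000780415 and 46.08294931 uM on the default 11-point
grid) are removed before prediction (`trimConcentrations()` — positional,
so an already-trimmed panel loses its own extremes). Shared cell lines are
intersected per pair, so drugs with partial panels remain comparable.

Two enumeration strategies (`enumerateCombinations()`): **vertical** pairs
within the anchor-like set (anchor plus advanced-status fingerprint
neighbours — same pathway axis, resistance-minded), **horizontal** pairs
the anchor with advanced-status members of a complementary cluster. When no
partner cluster is specified, `runPipeline()` picks the cluster whose mean
fingerprint is most anti-correlated with the anchor's.

## 5. The synthetic-data generator

`simConfig()` / `simulateExpression()` / `simulateDrugScreen()` generate a
full study with known ground truth. The generative choices:

- **Spiked-covariance modules.** Each planted module is a single latent
  factor: `gene = loading x factor + noiseSd x eps`, loadings uniform on
  \[0.7, 1\], `noiseSd = 0.5` by default. A one-factor module makes the
  module eigengene a well-defined recovery target. Module genes are scaled
  (default 3000) so they pass the raw-MAD-1000 filter while pure-noise
  background genes (scale 100) do not.
- **Preservation.** Preserved modules re-use their loadings with a fresh
  factor realization in the tumor set; non-preserved modules are
  *independent noise* there. A non-preserved module that kept its own
  (different) tumor factor would still be dense in the tumor network and no
  density-based statistic could distinguish it; incoherence in the test set
  is what "not preserved" means operationally. A consequence worth noting:
  non-preserved modules are invisible in the consensus network by
  construction, exactly as a cell-line-only artifact should be.
- **Drug coupling.** The per-line summary response is
  `clip(base + amplitude x sum_m c_dm E_m(line) + amplitude x drugNoiseSd x
  eps, 0, 100)` with `amplitude = 15` viability points per eigengene sd: a
  positive coupling means viability rises with the eigengene. Planted
  actives sit at base 40, inactives at 90 (default 95 percent active,
  mirroring a screen in which most library compounds show activity in at
  least one line). Dose-response curves are Hill curves (slope 2, top 100,
  bottom 0) whose EC50 is solved per drug and line so the log-concentration
  AUC reproduces the summary response — potency is monotone in response by
  construction, and `computeAUC()` round-trips the planted value to
  solver tolerance.
- **Sample sizes.** Defaults mirror the motivating study (5 cell lines, 13
  tumors, 11-point 3-fold dilution grid); recovery analyses use 20+20
  samples and 10 cell lines because correlations over n = 5 are
  statistically unstable — the tests are meant to detect implementation
  errors, not to certify small-n studies.
- **Planted drug classes** share prototype coupling vectors. Exact-recovery
  tests run them with all drugs at the active baseline: with an inactive
  (90-viability) baseline the coupling swing clips at the 100 percent
  ceiling and distorts fingerprints, which would conflate a boundary effect
  with clustering quality (clipping itself is tested separately).

What passing these tests does *not* show about real data: real expression
has correlated backgrounds, batch structure, and multi-factor modules; real
screens have plate effects, partial panels, and non-Hill curves; and five
cell lines remain five cell lines. The generator validates the machinery,
not the biology.

## 6. Orchestration, determinism, problem sizes

`runPipeline()` chains the stages from a single `pipelineConfig()`, writes
every artifact as plain text (TSV/CSV/JSON), and attaches a provenance
sidecar (stage, parameters, sub-seed, package version, input checksums —
deliberately no timestamps) so reruns with identical inputs are
byte-identical. The single global seed is fanned out to fixed per-stage
sub-seeds (`seed mod 1e6 x 1000 + stage index`), so stages can be rerun in
isolation. A stage failure halts with the stage name; artifacts already
written are kept.

The shipped validation uses desk-scale problem sizes chosen to exercise
every code path while keeping the whole suite interactive: 2000 genes / 8
modules / 20+20 samples for network recovery, 800 genes / 80 drugs for
fingerprint recovery, 600 genes / 40 drugs for the end-to-end bundle, 100
permutations for the preservation null, and 100 resamples for consensus
clustering. Whole-matrix computation is used throughout (no block-wise
decomposition), with the gene count controlled by the MAD filter; at these
scales the 2000x2000 TOM products are the dominant cost.

## 7. Known limitations

- Unsigned networks only: `|r|` conflates activation and repression within
  a module; a signed variant is out of scope.
- The Z-summary uses the two-statistic (density + connectivity) skeleton,
  not the full multi-statistic median-rank battery of larger preservation
  suites.
- The IDAcombo score definition is an explicit operationalization (see
  section 4) and is documented in output provenance rather than assumed
  canonical.
- Enrichment (`hypergeomEnrich()`) is a plain over-representation test
  against user-supplied gene sets with BH adjustment, with the MAD-filtered
  network gene space as the universe; no ontology-graph handling or term
  redundancy pruning.
- Correlations over very few cell lines are reported but should be read as
  descriptive, not inferential; no p-values are attached to fingerprints.
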