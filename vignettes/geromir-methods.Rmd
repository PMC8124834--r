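---
title: "Methods: geromiR differential expression, enrichment and target-network screening"
author: "geromir package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geromiR differential expression, enrichment and target-network screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geromir)
```

## The analysis this package implements

Colorectal-cancer cells that colonize the liver reprogram the surrounding
non-tumor cells — liver sinusoidal endothelial cells (E), hepatic
stellate/Ito cells (I) and Kupffer cells (K) — into a tumor
microenvironment (TME). One axis of that reprogramming is miRNA
dysregulation, and a particularly interesting subset of miRNAs are the
*geromiRs*: miRNAs implicated in the aging process and annotated to
hallmarks of aging (DNA methylation, histone modifications, inflammaging,
cellular senescence, and so on). This package implements, as reusable and
tested components, the analysis that detects coordinate geromiR
downregulation in TME cells from two-condition microarray data:

1. quantile normalization of log2 intensity matrices;
2. differential-expression calling between pooled control (C) and TME (T)
   samples of the three cell types;
3. curation of a literature-derived geromiR catalog and its restriction to
   the miRNAs measurable on the platform;
4. hypergeometric over-representation of geromiRs among the
   differentially expressed miRNAs (DEMs) and of aging hallmarks among
   the downregulated geromiRs;
5. a bipartite miRNA–target network over the downregulated geromiRs, with
   a screen for target genes whose expression moves the *opposite* way
   (upregulated), the signature expected when repression by their miRNAs
   is lost.

A synthetic-data generator with planted ground truth makes every stage
testable without any download.

## Differential-expression rule

For each feature the pipeline computes pooled group means on the log2
scale, $\bar{x}_C$ over all control samples of the selected cell types and
$\bar{x}_T$ over all TME samples, and selects a feature iff

$$ |\bar{x}_T - \bar{x}_C| \ge \log_2\theta
   \quad\text{and}\quad p < \alpha , $$

with defaults $\theta = 4$ (a four-fold selection threshold, compared in
log2 space where the boundary value is selected) and $\alpha = 0.001$ on
the raw p-value of a two-sided two-sample test. The defaults reproduce the
thresholds of the study design this package targets
($\theta_{DEM} = \theta_{DEG} = 4$, $\alpha = 0.001$); both are ordinary
parameters.

**Choice of test.** The statistical test behind the original analysis is
not restated in its methods, so the package makes it a parameter
(`dem_params(test = )`) with Welch's unequal-variance $t$-test as the
default: the replicate groups are small and unbalanced (three biological
replicates per group except two for the E-control and K-TME groups), which
is exactly the regime where the pooled-variance assumption is least safe.
Pooled-variance Student and a rank-sum Wilcoxon option are available. The
row-wise $t$ statistics are computed vectorized for matrix-scale
screening and are verified against `stats::t.test` in the unit tests.

**Multiple testing.** The selection rule deliberately applies a raw
$\alpha$ — the fold-change filter compounds the significance filter, and
the null simulations below show the combined rule's false-positive yield
is far below $\alpha N$. A Benjamini–Hochberg column is reported for
information only and never enters selection.

**Numerical details.** Zero (underflowed) p-values are floored at the
smallest positive double for $-\log_{10}p$ displays. Rows that are
constant in both groups get $p = 1$ when the group means agree and
$p = 0$ when they differ (a zero-variance separation is infinitely
significant in the $t$ limit). Duplicate probe identifiers are collapsed
to their per-sample median before analysis (robust and
order-independent); features with any missing value are dropped with a
message, because the thresholding rule has no missing-data contract.

## Quantile normalization

`quantile_normalize()` forces every sample column onto the common
distribution of across-sample rank means; ties receive the mean of the
reference values at their tied ranks. The implementation delegates to
`limma::normalizeQuantiles(ties = TRUE)`, the standard array
implementation of exactly this definition, and the tests assert the
definitional properties (exact value-multiset equality across columns,
idempotence) rather than trusting the delegation.

## The geromiR catalog

The catalog is compiled from three review compilations of aging-associated
miRNAs, packaged as a tab-separated fixture with one row per
(miRNA, hallmark, source) triple. Curation rules, chosen for fidelity to
the printed compilations:

* **Name harmonization** (`normalize_mirna_name()`): species prefixes
  (`mmu-`, `hsa-`, ...) and markup are stripped and the family stem is
  recapitalized to `miR-`/`let-`/`lin-`; numeric, letter and arm suffixes
  are preserved verbatim. The function is idempotent.
* **Distinct printed tokens are distinct miRNAs**: `miR-34` and
  `miR-34a` are *not* merged, and family names are not expanded into
  lettered members. Merging happens only through an explicit alias table,
  which is empty by default — under these rules the packaged tables yield
  exactly 115 unique geromiRs, of which 75 are represented on the arrays
  and 26 are flagged as significantly downregulated, so no aliasing was
  needed.
* **Apparent typos in the source reviews** (e.g. `miR-2016a`,
  `miR-E1108`, `miR-E1016`) are preserved verbatim: they are part of the
  printed compilation that produces the count of 115.
* **Hallmark vocabulary**: a closed list of fifteen hallmarks. The
  single-letter display labels used in figure legends reuse letters ("S"
  for both regulation of splicing and cellular senescence), so
  `aging_hallmarks()` carries unique internal codes alongside the display
  letters. A legend entry "changes in gene regulation" that has no
  corresponding catalog row is excluded from the vocabulary.

```{r catalog}
catalog_stats(geromir_catalog())
```

## Over-representation statistics

`set_enrichment()` computes the one-sided (upper-tail) hypergeometric
probability of observing at least $k$ category members among $n$ hits
drawn from a universe of $N$ containing $K$ category members. The tests
verify it against exhaustive subset enumeration for every instance with
$N \le 12$ and against a permutation oracle (`permutation_null()`, with
add-one smoothing) at $10^5$ draws.

**The choice of universe matters and is explicit.** Two tests use it:

* *GeromiRs among DEMs*: the natural universe is the number of distinct
  miRNAs actually tested on the platform after probe collapse — the
  `population_size` attribute of a `dem_table`.
* *Hallmarks among downregulated geromiRs*
  (`hallmark_enrichment()`): the default universe is the on-platform
  catalog itself ($N = 75$), but the pipeline passes the platform-wide
  universe. The distinction is not cosmetic: with $N = 75$ the small
  inflammaging category (both members downregulated) outranks DNA
  methylation, whereas against a platform-wide universe the ranking is
  histone modifications first and DNA methylation second — stably so for
  every universe size between roughly 140 and 2000 — which matches the
  reported biology (the downregulated geromiRs concentrate on the
  epigenetic hallmarks). Overlapping hallmark categories are tested
  independently, one test per hallmark, with Benjamini–Hochberg values
  reported alongside raw p.

**Calibration note.** The platform's total distinct-miRNA count is not
published. `calibrate_universe()` inverts the hypergeometric tail for a
reported statistic: for the reported geromiR-among-DEM enrichment
($p = 2.746\times10^{-6}$ at $k = 26$, $K = 75$, $n = 71$) the closest
universe is $N = 467$ (exact $p = 2.769\times10^{-6}$, within 1%). The
package documents this as a calibration estimate and uses it as a
plausible universe for desk-scale reproduction; it is not asserted as a
fact about the platform.

```{r hallmarks}
plat <- platform_catalog()
head(hallmark_enrichment(downregulated_geromirs(plat), plat,
                         population_size = 467), 3)
```

## The target network and the reverse-expression screen

Target interactions come from a local, versioned interaction table
(MirTarBase-export-like columns `mirna`, `gene`, `evidence`) rather than a
web service, for reproducibility and offline testing; users supply their
own export for real analyses. The packaged
`inst/extdata/mirtarbase_synthetic.tsv` is a *synthetic* stand-in
assembled for testing that encodes the curated neighborhoods of the
downregulated geromiRs (Cercam regulated by miR-10a/miR-26a/miR-26b;
Spsb4 by miR-15a/miR-16/miR-24) plus background edges. No evidence-level
filtering is applied by default; `read_interactions(evidence_pattern = )`
is the hook (applied before pair deduplication, so a filtered evidence
record survives a duplicated pair).

`build_network()` keeps exactly the interaction rows whose miRNA is in
the downregulated set; the graph is strictly bipartite (asserted on
construction and re-import) and exports to GraphML plus an edge-list TSV.
`reverse_expression_screen()` reuses the differential-expression rule —
the same $\theta$ and $\alpha$ by default, independently configurable —
on the gene matrix and reports the network's gene nodes selected as
upregulated, each with its linked miRNA regulators. Reusing the stated
thresholds is the only defensible default given that the target claim is
simply "upregulated in the TME"; gene symbols are matched
case-insensitively because mouse/human capitalization is mixed freely in
curated interaction sources.

## The synthetic-data generator

`simulate_dataset()` emulates the study design, not the platform's
physics: three cell types × two conditions, log2-scale intensities with
additive Gaussian noise (microarray intensities, not counts — hence no
negative-binomial layer), per-feature baselines drawn from
$\mathcal{N}(8, 2^2)$ log2 units, and a small per-cell-type offset
(SD 0.25, drawn once per cell type) so pooled testing is exercised under
realistic between-cell-type heterogeneity. Defaults are the study
conditions: 600 miRNAs with a 75-member on-platform geromiR catalog; 30
planted downregulated miRNAs, 10 of them geromiRs concentrated on a
designated hallmark (histone modifications); 10 planted upregulated
miRNAs (none geromiRs); 5 planted upregulated target genes wired to
planted downregulated miRNAs in the generated interaction table; a
planted shift of 3 log2 units against noise SD 0.5; three replicates per
miRNA group except two for E-control and K-TME, and four per gene group.
One seed drives a single documented stream of draws, so output is
bit-identical per seed and the generator restores the caller's RNG state.

What the generator does *not* emulate: probe-level structure, dye and
spatial artifacts, background correction, intensity-dependent variance,
and correlated miRNA families. Passing recovery tests therefore show that
the pipeline's inference machinery is correct under the declared noise
model — not that real arrays meet that model.

**Problem sizes used by the test suite and acceptance script** (chosen as
desk-scale study emulations): 100 simulated studies for the reference
recovery scenario (median precision/recall per direction, geromiR
enrichment, reverse-screen exactness) and 200 for the null scenario
(1000 features, no planted effect, three replicates throughout), where
the combined rule's mean selected-feature count stays below 1 per run.
On small matrices (tens of features) quantile normalization visibly
compresses planted shifts because the planted features are a large
fraction of the distribution; the recovery scenarios use 600+ features
where this effect is negligible.

## Pipeline and reproducibility

`run_pipeline()` chains the stages (normalize → DEM → catalog →
enrichment → network → screen → summary), writes every intermediate as
TSV plus a JSON summary, asserts the summary's internal count
consistency (downregulated geromiRs ≤ downregulated DEMs, on-platform ≤
catalog size), and labels any stage failure with the stage name. Reruns
on identical inputs and configuration are byte-identical. Configuration
is a single YAML file with strict key checking
(`read_run_config()`); `inst/cli/geromir.R` is a thin command-line
wrapper. A reader for GEO series-matrix files is included
(`read_geo_series_matrix()`) so the deposited study data (accession
GSE156431) can be fed to the same pipeline; sample-title parsing is a
configurable regular pattern because GEO titles are free text.

**Pooling choice.** Whether replicates should be averaged within cell
type before pooling across cell types is not determinable from the
analysis description; `group_means()` pools all samples directly by
default and exposes `average_within_cell_type = TRUE` as the documented
alternative. Direct pooling weights cell types by their replicate counts
and matches the "average the controls of the three cell types" reading
with the larger effective sample size.

## Known limitations

* With the deposited data, exact reproduction of the original DEM counts
  (71 down / 30 up) is not guaranteed: the original test statistic is
  delegated to earlier work and not restated, so this package's Welch
  default is a principled stand-in, not a forensic match.
* The hallmark-enrichment universe is a modeling choice the user must
  own; the package defaults are documented above.
* No moderated-variance (empirical-Bayes) testing, paired designs, or
  per-cell-type interaction models — the rule is a faithful
  reimplementation of a threshold-based screen, with its known
  conservatism.
* No target prediction: the network is only as good as the supplied
  interaction table.
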