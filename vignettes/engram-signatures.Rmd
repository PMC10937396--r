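---
title: "Identifying long-term memory engram signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying long-term memory engram signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engramtx)
```

# The experimental design the package models

Activity-dependent labelling (TRAP: a Fos-driven, tamoxifen-gated recombinase
switching on a permanent tdTomato reporter) marks the cells active during a
fear-memory recall session. Four behavioral conditions disentangle what the
label means:

* **FR** — fear training followed by recall: tdT+ cells are candidate engram
  cells;
* **NF** — context exposure without shock: tdT+ cells carry salience-driven,
  memory-unrelated activation;
* **NR** — training without recall: tdT+ cells carry residual
  training-period activity;
* **HC** — home cage: tdT+ cells reflect stochastic background labelling.

Because background labelling is never zero, *every* condition contains some
tdT+ cells, and a gene enriched in FR tdT+ cells may reflect fear memory, the
salient experience, basal activation, or training residue. The package's
central statistic — the remote-memory screen — is designed to strip the last
three away.

# Quality control and normalization

Cells are filtered before genes: cells need at least 2,000 detected genes
(raw count > 0), 50,000 total reads, at most 10% ERCC spike-in reads and at
most 20% mitochondrial reads (both fractions on the raw per-cell total);
genes must then be detected in at least 5 *retained* cells. ERCC genes are
used for the fraction computation and afterwards removed. These defaults
describe deep full-length (Smart-seq-class) libraries; for targeted panels or
simulated universes with fewer genes, the thresholds are parameters of
`qc_thresholds()` and should be scaled to the data (the packaged
`example_qc_table()` pairs the default cell rules with `min_cells_per_gene =
3`, because only three of its six cells survive — a gene cannot be detected
in five of three cells).

Normalization is CP10K-log1p: `log(1 + 10000 * count / cell_total)`, natural
log. "Detected" means raw count > 0 throughout the package — no detection
threshold beyond that is ever applied.

Two scale conventions matter downstream and are deliberate:

* **p values** come from rank statistics on the normalized (log) values and
  are therefore invariant to any strictly increasing transform of the scale.
* **fold changes** are ratios of group means on the *linear* (de-logged,
  CP10K) scale, with a pseudocount of 0.01 on both means:
  `log2_fold = log2((mean_a + 0.01) / (mean_b + 0.01))`. Means of log values
  would make a fixed biological fold shrink with baseline abundance (log
  compression), so an abundance-independent threshold such as "1.75-fold"
  is only meaningful on the linear scale.

# The rank-sum engine

All two-group comparisons use the two-sided Mann-Whitney-Wilcoxon test. When
both groups have at most `exact_max_n = 8` observations and the values are
tie-free, the exact null distribution is enumerated (`stats::pwilcox`);
otherwise the normal approximation with tie correction and continuity
correction is used — the same rules as `stats::wilcox.test`, against which
the implementation is verified in the test suite, together with a brute-force
enumeration oracle. p values are unadjusted unless a procedure explicitly
says otherwise; Benjamini-Hochberg adjustment (`bh_adjust()`, a wrapper
around `stats::p.adjust`) is used only where stated (marker discovery).

# The remote-memory screen

For one cell type, candidates are genes with p < 0.05 between FR tdT+ and
NF tdT+ cells. Three criteria follow:

1. **tdT- exclusion.** Genes also significant between FR tdT- and NF tdT-
   cells are removed, regardless of direction — label-independent activation
   is not an engram signature.
2. **NR/HC controls.** The gene must be significant against both the NR and
   the HC TRAPed populations, *with the same fold direction as the candidate
   effect*. Significance alone would admit sign flips; requiring the
   candidate's direction is the conservative reading. The controls are the
   tdT+ cells of NR and HC (TRAPed populations are contrasted throughout
   this design); `screen_config(nr_hc_cells = "all")` exposes the
   alternative of comparing against all cells of the type.
3. **Effect size.** Detected in at least 25% of cells in at least one of the
   two compared tdT+ groups (the design does not name a single denominator,
   so the more permissive "either group" is used), and at least a 1.75-fold
   change on the linear scale, boundary inclusive.

A cell type in which any required group has fewer than 3 cells is *skipped*
with a reason rather than screened — sparse TRAP labelling makes tiny groups
common, and a 2-cell rank test is meaningless.

Two statistical properties of this screen are worth knowing. First, the tdT-
exclusion removes true engram genes at roughly its own false-positive rate
(about 5% at large tdT- group sizes), so recall is bounded near 0.95 even
with strong planted signals. Second, a gene induced equally in FR and NR
TRAPed cells (training residue) passes the NR control at the rank test's
attained level — about 2% per gene at group sizes of 10 versus 6 — so a
screen over many such genes leaks a small, alpha-level number of them on
average. Both effects are visible in the synthetic-data tests and would be
equally present on real data.

# Marker discovery and panel assembly

`one_vs_all_markers()` implements targeted-panel marker selection: for every
population, a rank-sum test of each gene against all other cells, BH-adjusted
*within that population's test family* (the families are per-population; the
design leaves the family ambiguous and pooling across populations would
couple unrelated tests). A marker must be (1) detected in at least 30% of the
population (inclusive), (2) FDR < 0.001, (3) at least 4-fold above the
average linear expression of all cells outside the population (pseudocount
0.01), and (4) detected at a fraction at least twice that of *every* other
population individually (inclusive; a population with zero detection
elsewhere always satisfies it). Survivors are ranked by fold change, ties
broken by smaller q then lexicographic gene id (determinism), and the top 5
kept. `build_panel()` unions markers, curated literature genes and
remote-memory DEGs in that priority order; a size cap removes the
lowest-fold markers first and never removes literature/DEG entries. No cap is
applied by default — a realized panel size (for example 158 genes) is an
outcome, not a rule.

# Spatial neighborhoods

`find_peri_engram()` flags a cell as peri-engram iff it is not itself an
engram cell and its centroid lies within 30 µm (Euclidean, boundary
inclusive) of at least one engram cell — by default a tdT+ neuron — *in the
same tissue section*. Sections are physically separate slices, so
neighborhoods never cross them. The implementation scans engram-to-cell
distances per section (exact, no approximation) and the suite checks it
against a full O(n²) oracle; flags are invariant under rigid motions of a
section and monotone in the radius.

Panel counts for spatial DE are normalized per cell to the median panel
total and log1p-transformed — targeted panels have no stable "10K" scale, so
the median total is the natural anchor; this choice is configurable by
normalizing upstream if desired. Peri-engram DE (`peri_vs_other_de()`)
compares peri versus non-peri cells of one class with engram cells excluded
from both groups (whether the engram cells belong in the reference group is
ambiguous; excluding them keeps the contrast purely spatial).
`niche_condition_contrast()` tests one gene between conditions within the
niche; `engram_density_by_region()` counts tdT+ neurons per section and
region and compares conditions with a classic pooled-variance t test (per-mm²
normalization optional); `niche_composition()` reports the peri fraction per
subtype with a one-way ANOVA over per-section fractions.

# Cross-region co-direction and neuropeptide ratios

`cross_region_shared_degs()` runs the FR-vs-NF TRAPed contrast per matched
cell type in two regions over their common genes; a gene is shared when
p < 0.05 in both, and co-directional when its folds have the same nonzero
sign (a zero fold counts as not co-directional). `codirection_fraction()` is
a plain recount reported as a percentage to one decimal.
`neuropeptide_ratio()` computes per-cell `log2((up + 1) / (down + 1))` on
linear-scale normalized expression — with pseudocount 1, a cell expressing
neither gene has ratio exactly 0 — and compares groups by rank sum. Gene
pairs are parameters: Penk/Tac1 is the single-cell pairing, Penk/Tac2 the
usual targeted-panel pairing.

# The synthetic-data generators

`simulate_expression()` draws negative-binomial counts for a four-condition
experiment and plants six recoverable gene classes: *engram* (induced only in
FR tdT+ cells of the target types), *salience* (FR and NF tdT+),
*background* (all FR cells), *residual* (FR and NR tdT+), and a
neuropeptide pair (`Penk` ×4 up, `Tac1` ×6 down in the tdT+ FR cells of one
inhibitory type). Defaults: 2,000 genes; 300 cells per type per condition
for three types (two neuronal, one astrocytic); 40 genes per planted class
at fold 4; TRAP rates FR 3.2%, NF/NR 2%, HC 1%.

Choices that make the generator faithful to the data it emulates:

* **Trap labels are assigned by exact-fraction sampling** (`round(rate * n)`
  randomly chosen cells): the configured rates are design parameters and are
  realized exactly, and every screen group (including the 3 HC tdT+ cells at
  default sizes) exists deterministically.
* **Abundance regimes.** Null genes draw baseline means log-uniformly from
  100–1,000 counts (~0.7 million reads per cell over the 2,000-gene
  universe — the deep full-length regime), while planted inducible classes
  sit at 5–15 counts: activity-regulated genes are modestly expressed at
  baseline, and — critically — the induced program must be a negligible
  fraction of library mass, as it is in real data. If planted classes carry
  appreciable mass, per-cell normalization converts them into a global
  compositional shift that makes *every* gene differentially expressed in
  large-n contrasts, a genuine artifact of small gene universes. The
  neuropeptide genes sit at the abundant end (mean 1,000), as neuropeptide
  transcripts do in their expressing interneurons.
* **Dispersion.** A single NB size of 20 (variance `mu + mu²/20`) reflects
  the low technical noise of deep full-length libraries; rank-based
  statistics depend only on group separation, not on the exact noise law.

`simulate_tissue()` places cells by a uniform point process on independent
1 mm² sections (800 cells/mm²; 53.5% neurons, 20% astrocytes), flags engram
neurons per condition (FR 3.2%, NF 2%), computes planted peri-engram flags by
the same geometry as `find_peri_engram()`, and draws Poisson panel counts
(the low-mean regime of targeted panels) with an Igfbp2 fold of 3 on
peri-engram astrocytes in all conditions and a Fos fold of 2 in FR only.

What passing the synthetic tests does *not* show: the generators have no
batch structure, no doublets, no segmentation errors, no cell-type
misassignment, no dropout beyond NB/Poisson sampling, and no spatial
anisotropy. Recovery on this data validates the statistical machinery and its
bookkeeping, not robustness to those artifacts.

# Problem sizes and numerical choices

The test suite and the acceptance script run the screen recovery at the
default 2,000 × 3,600 configuration, the null calibration over 20 seeds, the
neighborhood oracle on ~2,000-cell sections, and the marker oracle on a
5-population × 60-gene toy — sizes chosen so the full suite completes in a
few minutes on one CPU while every planted effect is comfortably detectable.
Ties in marker ranking are broken deterministically; TSV output rounds
numerics to 6 significant digits so identical seeds give byte-identical
files; all pseudocounts (0.01 for folds, 1 for neuropeptide ratios) are
stated above and in the function documentation.

# Orchestration

`run_pipeline()` executes the configured stages (simulate or read → QC →
normalize → screen → panel → spatial) and writes every result as TSV next to
a `config_snapshot.yaml` carrying the validated configuration, seed and
package version; rerunning from the snapshot reproduces the outputs
byte-for-byte. Unknown configuration keys are rejected before any
computation. The package is driven from R (or `Rscript -e`); the repository's
`scripts/acceptance.R` is a worked example of scripting the full pipeline.

# Known limitations

* The screen's recall ceiling (~0.95) and residual alpha-leak (~2% per
  equally-induced gene) described above are properties of the design itself.
* DE is strictly two-group and rank-based: no covariates, no pseudobulk, no
  mixed models — animal-level pseudoreplication is not corrected.
* Type matching across regions is user-supplied; no batch integration is
  performed (out of scope by design).
* Spatial analysis is 2-D and per-section; 3-D reconstruction and
  registration to an atlas are out of scope.
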