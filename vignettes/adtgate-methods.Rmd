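---
title: "adtgate: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{adtgate: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adtgate` implements an analysis pipeline for targeted single-cell assays
that measure surface proteins through antibody-derived tags (ADTs) together
with a panel of a few hundred transcripts in the same PBMCs, pooled across
participants with per-sample hashtags. This vignette explains the models the
package assumes, the parameters that matter, what the synthetic-cohort
generator does and does not emulate, and the choices made where the design
was genuinely open. It states no empirical result that the test suite does
not itself compute.

## The data model

Three count matrices share one cell index:

* **ADT** — 40 antibodies; counts are surface-protein proxies with
  substantial non-specific background (incomplete Fc block, trapped
  antibody, titration error).
* **RNA** — a targeted panel (~485 genes); counts are small (tens to a few
  hundred UMIs per cell), not a whole transcriptome.
* **TAG** — 4 sample tags per loading plate; each pooled participant's
  cells carry one dominant tag.

## Quality control

QC runs in a fixed order, and cell counts are monotone non-increasing
through it:

1. **Tag demultiplexing.** A tag is positive when its count reaches its
   threshold; one positive tag → singlet, two or more → cross-sample
   doublet, none → undetermined. Per-tag thresholds are fitted with the
   same mixture machinery used for antibodies (on `log(count + 1)`,
   back-transformed), because the original vendor demultiplexer is
   unspecified; fixed constants would silently break on a different tag
   chemistry.
2. **Expression doublets.** A deliberately simple artificial-doublet
   detector: artificial doublets are sums of random cell pairs; real and
   artificial cells are embedded together by PCA on normalized features;
   each real cell is scored by the fraction of artificial cells among its
   `k = 25` nearest neighbours; the top `expected_rate` fraction (default
   7.5%) of cells is flagged. This is a *quota* contract — the stated rate
   is a formation rate, not a learned posterior — so exactly
   `floor(n * rate)` cells are flagged, ties broken by cell id. Homotypic
   doublets (two cells of the same type) are largely invisible to any
   expression-based detector; the recall tests therefore use cohorts where
   most doublets are heterotypic, which the random-pairing model produces.
3. **Antibody floor.** Cells with fewer than 128 (2^7) total antibody
   molecules are removed; a cell at exactly 128 is kept ("fewer than" is
   strict). Raw total ADT UMIs are used; whether the floor should count
   deduplicated molecules is unknowable from the outside, and raw totals
   are what the matrices contain.

**Normalization.** ADT counts are CLR-normalized per *marker across cells*
with pseudocount 1 and divided by `ln 2` (log2 units):
`y = (ln(x+1) − mean(ln(x+1))) / ln 2`. The margin and pseudocount are not
universal conventions; the per-marker margin is the standard ADT choice and
makes a constant marker exactly zero after centering. RNA counts are
divided by the cell total and scaled to 1,000 (a sensible library size for
a targeted panel); zero-total cells are excluded with a warning.

## Antibody thresholding

Every antibody shows background and signal; on the CLR scale these are two
overlapping approximately normal components. Per marker:

* **Mixture fit.** A 2-component Gaussian mixture by EM. Initialization
  splits the data at the median (component means = means of the halves);
  5 seeded random restarts (means drawn from the data) guard against
  label-degenerate optima; the best log-likelihood wins. Convergence when
  the log-likelihood improves by `< 1e-8`, cap 500 iterations; the
  log-likelihood is asserted non-decreasing at every iteration, so a
  numerical fault fails loudly rather than silently. A component variance
  collapsing below 1e-6 marks the start as degenerate.
* **Threshold.** The intersection of the two weighted component densities
  between the means: the point where a value becomes more likely signal
  than background. Equal variances give a closed form; unequal variances
  give a quadratic whose two roots both solve the equation, but only the
  root inside `[mu1, mu2]` separates background from signal, so that one is
  returned (the other lies in a tail where both densities are negligible).
  Under extreme weight imbalance no root may lie between the means; the
  midpoint is then returned with a warning rather than an error, because a
  usable threshold with a logged caveat beats an aborted run.
* **Fallbacks.** If EM does not converge (e.g. a marker with no positive
  population in the data at hand): a user-declared negative population
  gives a quantile threshold (default 0.99); otherwise a manual threshold
  is required. Which markers used which route in the emulating study is
  unknown; both routes are config.

Values strictly below the threshold are set to zero; a value exactly at the
threshold survives. After this step zero means "not expressed", which is
the contract the gates consume. One marker (CD197/CCR7 in the default
panel) has inherent chemokine-receptor background that thresholding does
not rescue; it is excluded from the analysis marker set, leaving 39 of 40.

## Gating

Major types are assigned by Boolean conjunctions over the thresholded
matrix, as in flow cytometry: `+` means nonzero, `−` means zero, and a gate
may have a parent whose predicates must also hold. The default scheme is
the classic 8-gate PBMC tree: B (CD19+CD3−), T (CD19−CD3+) with CD4+CD8−
and CD8+CD4− children, monocytes (CD19−CD3−CD56−) with classical
(CD14+CD16−), intermediate (CD14+CD16+) and nonclassical (CD14−CD16+CD56−)
children, and NK (CD4−CD56+CD14−CD20−CD123−CD206−). Two deliberate
fidelity choices: the nonclassical gate repeats CD56− although its parent
already requires it, and the NK gate lists CD20− and CD206− although CD19−
already removes most B cells — the printed scheme is kept verbatim rather
than minimized. Each cell gets the deepest terminal gate it satisfies;
cells satisfying none (e.g. CD3+CD4+CD8+ double positives, which both T
children reject) stay `"unassigned"` and are retained for audit rather than
dropped; ties between equal-depth terminal gates are resolved by an
explicit priority and counted.

## Clustering

Subclustering is **antibody-only**; the graph builder rejects a matrix
tagged as RNA, so transcripts cannot leak into cluster structure even by
accident. Per major type: markers genuinely detected in the type (nonzero
after thresholding in ≥ 5% of its cells — the operational reading of "all
non-negative antibodies") are kept, z-scaled per marker, a Euclidean
k-nearest-neighbour graph (`k = 20`) is re-weighted by shared-neighbour
Jaccard overlap (prune 1/15), and Louvain community detection runs at the
type's resolution (B 0.8, CD4 T 1.0, CD8 T 1.3, classical monocytes 0.5,
intermediate 0.4, nonclassical 0.4, NK 0.3). Labels are renumbered by
decreasing size and are deterministic given the seed.

Neither `k`, the metric, nor the scaling is dictated by the emulated
workflow; they are declared decisions. One behaviour worth knowing: a kNN
graph much sparser than its communities fragments at high resolution —
with 20 neighbours in a 10,000-cell compartment, resolution 1.3 yields a
dozen clusters even from smooth data. That is how these tools are used in
practice (the emulated analysis reports 13–14 clusters per T compartment);
the test fixtures that check *exact* blob recovery therefore size `k` to
the planted cluster size. An optional batch-correction hook can transform
the feature matrix before graph building (identity by default); the
original harmonization step is out of scope. Marker-based post-hoc splits
(`split_cluster`) partition a cluster into hi/lo sides on named markers,
record provenance, reject splits leaving a side empty, and are reversible.
The 2-D embedding is a PCA projection for diagnostics only.

## Statistics

* **Differential expression.** Wilcoxon rank-sum per gene — exact
  enumeration below 30 cells per side without ties, normal approximation
  with tie and continuity correction otherwise. Effects:
  `avg_log2FC = log2(mean(A)+1) − log2(mean(B)+1)` on normalized values
  (the pseudocount keeps all-zero genes finite; the emulated analysis
  reports log fold changes without printing its formula), plus detection
  fractions `pct.1`/`pct.2`. Bonferroni is applied per contrast over the
  genes tested in it, not across contrasts. The significance filter is
  `adj_p < 0.05` **and** `pct.1 > 0.2`. Group contrasts follow the staged
  disease ordering (consecutive pairs), cluster contrasts are
  one-vs-rest within the major type.
* **Proportions.** Per participant, a cluster's proportion of its parent
  major type; transformed by `ln(p'/(1−p'))` with
  `p' = (k + 0.5)/(n + 1)`. The emulating description says "log-odds ratio
  defined as p/(1−p)" — read literally that omits the log and explodes at
  p = 0, so the log and a continuity correction are applied; this is the
  transform the name denotes. One-way ANOVA then Tukey HSD over all six
  group pairs; summaries are reported on the percentage scale. No
  cross-cluster multiplicity adjustment is applied, matching the printed
  workflow.
* **Correlation screen.** Per cell type and mapped antibody–gene pair:
  cells below the antibody threshold or with zero gene counts are
  discarded; ≤ 10 surviving cells → insignificant (coefficient reported as
  0); otherwise Spearman rho with the t-approximation (tie-aware via
  ranks); p > 0.05 → reported as 0; antibodies/genes with at least one
  |reported rho| ≥ 0.25 are flagged selected. Exact small-sample p-values
  are moot: records that small are pre-filtered.
* **Random-forest importance.** 15 iterations; per iteration a balanced
  resample (1,000 cells per condition, with replacement when a condition
  is smaller, logged), a 500-tree CART forest (`mtry = sqrt(p)`, Gini
  splits, implemented in C++ in this package since no forest backend is
  available), per-gene importance scaled so each iteration's maximum is
  100, then the mean over iterations and its rank. **Importance measure:**
  Gini impurity decrease by default. Out-of-bag permutation importance is
  available (`importance = "permutation"`) but is *not* the default: its
  null expectation is zero, so after clamping and max-scaling, pure-noise
  panels produce unstable max/median ratios, violating the flatness
  property a noise panel should have; impurity importance has a positive
  per-gene baseline and behaves. Rankings of genuinely separating genes
  agree between the two modes in the test fixtures.

## The synthetic cohort: what it emulates, and what it does not

Defaults state the emulated study design once: 4 groups (HIV−, HIV+CVD−,
HIV+CVD+, HIV+CVD+ treated) × 8 participants × 1,300 cells; 8 plates of 4
participants, one per group (matched design); doublet rate 7.5%; 40
antibodies; 485 genes.

* **ADT**: `round(exp(Normal))` per marker — background `meanlog = ln 2`,
  signal `meanlog = ln 80`, both `sdlog = 0.45`. The choice is the simplest
  model that reproduces the heavy right tail and the CLR bimodality the
  thresholding stage assumes, with a signal/background separation (~5 log2
  units) comfortable enough that gating accuracy reflects the logic, not
  the noise floor. The emulating study publishes no ADT noise model; these
  are stand-ins, not estimates.
* **Type structure**: 7 major types at realistic PBMC fractions; each type
  has deterministic signature markers plus *sub-signature* markers positive
  in only a stated fraction of its cells (memory/activation subsets,
  monocyte CD163/CD152 states, CD16-bright NK), so subclustering has real
  structure to find.
* **RNA**: Poisson per (type, gene); signature-protein transcripts high in
  the matching type. Planted effects: three DE genes (log2 fold changes
  +2, +1.5, −2 in stated type × group cells) and a 2× proportion shift of
  intermediate monocytes in the untreated CVD group.
* **Tags**: dominant tag Poisson(60), ambient Poisson(1) — clean
  demultiplexing at defaults while still exercising the thresholds.
* **Doublets**: `Binomial(n_singlets, rate)` extra cells, each the sum of
  two freshly drawn constituents from the same plate (hashtag doublets
  arise within a loading plate). About a quarter are same-tag and only
  catchable by the expression detector, as in real pooling.
* **Seeding**: one master seed fans out to named substreams per stage
  (`substream_seed`), so regenerating one stage never shifts another.

Not emulated: sequencing error, UMI collapsing, ambient RNA, batch/plate
effects, per-cell ADT–RNA coupling (so the correlation screen finds little
in default cohorts — its tests use constructed fixtures), compositional
covariance between types, and transcriptome breadth beyond a targeted
panel. A green test on this world therefore establishes the *logic* of
each stage and its statistical calibration — not performance on real data,
where background is heavier-tailed, types are less separable and batch
effects are real.

## Numerical details worth knowing

* Degenerate inputs: zero-variance mixture input → `converged = FALSE` and
  an explicit error path; empty count matrices, missing thresholds,
  unknown markers and cyclic gate parents all fail with named messages.
* The Wilcoxon wrapper switches exact↔approximate at 30 per side or any
  tie, matching the behaviour pattern of the field's implementations.
* `count_matrix` validates integrality and non-negativity and names the
  offending cell/feature on failure.
* All tables carry the configuration hash and seed as attributes; the QC
  provenance table records cells in/out per stage.

## Known limitations

Single-threshold-per-marker (no per-type thresholds, k = 2 mixtures only);
cells are pooled across participants in DE (no participant-level random
effects); no compositional modelling of proportions; the doublet detector
is a contract-compatible simplification, not a reimplementation of the
cited tool; cluster counts at the stated resolutions are seed- and
implementation-dependent and are treated qualitatively.
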