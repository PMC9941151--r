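---
title: "Methods: 3D pseudospace-time trajectories from serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D pseudospace-time trajectories from serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Serial coronal sections of injured brain tissue, profiled with a
Visium-style spatial transcriptomics assay, capture how an expression
perturbation introduced at one anatomical site (here, blood in the lateral
ventricle) propagates through neighbouring structures over days. trajspace
turns a stack of such planar sections into **3D global pseudospace-time
trajectories**: ordered chains of anatomical regions along which per-spot
pseudotime increases, supported by multiple sections of the same time
point. Downstream, it ranks transition genes along each chain segment,
condenses them into time-point-specific cell-subtype marker profiles,
quantifies ligand-receptor (LR) communication density along each
trajectory, and compares that density across time points.

Region labels are an input (anatomical annotation is assumed done against a
reference atlas); images and alignment are out of scope.

## Planar pseudotime

Each section's counts are library-size normalised to 10,000 and
`log1p`-transformed. Pseudotime is classic diffusion pseudotime, computed
in-package:

1. PCA of the log-normalised matrix (default 30 components).
2. A k-nearest-neighbour graph over the PCA scores (default `k = 15`),
   symmetrised, with a self-tuning Gaussian kernel whose per-spot bandwidth
   is the distance to the k-th neighbour.
3. Eigendecomposition of the normalised transition operator
   `D^{-1/2} W D^{-1/2}`; diffusion coordinates are scaled by
   `lambda / (1 - lambda)` (default 10 components).
4. A spot's pseudotime is its Euclidean distance from the root reference in
   diffusion space, min-max rescaled to `[0, 1]`.

The root reference is the **medoid spot of the root region** (default
`"VL"`, the lateral ventricle) in PCA space — a single deterministic
anchor, robust to stray spots at the region boundary. Spots in graph
components unreachable from the root receive `NA` and are counted in an
`n_unreached` attribute; they are never silently assigned pseudotime 0. A
section with no usable expression variance (or a numerically constant
diffusion distance) is flagged `degenerate` and all spots report
pseudotime 0 so the caller can decide what to do.

## Region graphs and planar trajectories

Regions become nodes of a directed graph. An edge `A -> B` requires both

* spatial adjacency: at least `min_adjacent` (default 1) spot pairs within
  `adjacency_radius_um` (default 1.5 x the inferred grid spacing) across
  the A/B border, and
* a pseudotime gradient: `median_pt(B) - median_pt(A) >= min_delta`
  (default 0.05); equal medians give no edge.

Because the direction always follows the order of the two medians, the
graph is acyclic by construction; a defensive cycle-breaking pass (drop the
smallest-gradient edge) is retained but unreachable. Planar trajectories
are all simple paths from the root to a sink; an isolated root yields the
single-region trajectory.

## 3D reconstruction

Within one time point, planar chains from different sections are merged:

* `merge_mode = "exact"`: only identical chains merge.
* `merge_mode = "subsequence"` (default): a chain also supports any longer
  chain of which it is a prefix-preserving subsequence (same root, order
  preserved); the merged chain is the longer one.

In subsequence mode the reported trajectories are the *maximal* observed
chains, each credited with every section whose chain it contains. A short
chain consistent with two distinct maximal chains supports both — the
evidence does not distinguish them, and crediting both keeps the merge
invariant to input order and grouping (merging sections incrementally or
all at once gives the same result). Chains that are not
subsequence-related are never forced together. Trajectories with fewer
than `min_support` (default 2) distinct supporting sections are dropped;
results sort by support (descending) then chain string. Which mode matches
the original serial-section study is not decidable from published
information, so both are first-class; subsequence is the default because
sectioning artefacts commonly truncate a chain rather than reorder it.

Bundle labels summarise where a chain ends: bundle I ends in a hippocampal
region (`CA1`, `CA3`, `DG`) without passing an integrator; bundle II passes
a thalamic/hypothalamic integrator (`TH`, `HY`, `HYL`, `MB`) before a
hippocampal terminus; bundle III ends in a cortical region. The region
classes are plain configuration (`bundle_rules()`) and intentionally
user-editable; chains containing unknown regions are `unclassified` with a
warning. This terminal-region rule is a deliberate simplification — a
handful of historically published chains (e.g. one ending in a white-matter
tract) fall to `unclassified` under it.

## Transition genes and the signed union

For one subtrajectory (a consecutive region pair), each gene's Spearman
correlation with pseudotime is computed **over the spots of the two regions
only**, localising the transition to that border rather than diluting it
over the whole chain. Zero-variance genes are excluded; ties break by gene
ID. The top `K = 30` positive correlations are the up list, the top 30
negative the down list; at least `min_spots = 10` spots are required.

Per-section lists for the same subtrajectory and time point are unioned
into the 3D set. A gene seen with conflicting signs keeps the signed score
of **greatest absolute value**; an exact magnitude tie keeps the positive
score (an arbitrary but fixed convention — it can only trigger when two
sections disagree to the last floating-point digit). After merging, lists
are re-truncated to the top 30 per direction by `|rho|`, so the "3D top
30" is still a size-30 set per direction; truncating after (not before)
the union is the reading consistent with reporting a single top-30 3D set
per subtrajectory.

## Subtype profiles, similarity, matching

A trajectory's subtype profile at a time point is the union of its
subtrajectories' 3D up (+) and down (-) genes, with cross-subtrajectory
sign conflicts resolved by the same max-magnitude rule. Similarity between
two profiles is a **sign-aware Jaccard index**: the number of genes shared
with equal sign over the size of the union of the gene sets. It is
symmetric, lives in `[0, 1]`, equals 1 exactly for identical signed
profiles, and equals 0 exactly when the profiles share no (gene, sign)
pair. Alternatives (overlap coefficient, cosine on signed scores) were
considered; Jaccard was chosen because profile sizes are comparable by
construction (unions of fixed-size top lists), making the denominator
stable, and because it uses only set membership and sign — not the
correlation magnitudes, which are not comparable across time points.

Profiles are matched against a local marker database (a two-column
cell-type/gene TSV) by hypergeometric upper-tail enrichment of the
profile's genes (sign ignored) in each cell type's marker set, against the
union of database and profile genes as the default universe. Symbol
matching is case-insensitive (mouse symbols are cased differently from
human-centric databases). Ties break by p-value, then larger overlap, then
cell-type name. The top 5 types per profile are reported, with a
convenience union across time points. This local, deterministic stand-in
replaces remote probabilistic annotation services; it is a different
scoring model, so specific cell-type names from any given service are not
expected to reproduce.

Pathway sets are inputs (enrichment itself is out of scope). The mutual
pathway set is the intersection; similarity is the **overlap coefficient**
`|intersection| / min(|A|, |B|)`, chosen over Jaccard because the two sets
come from different enrichment runs whose sizes differ for uninteresting
reasons; it is defined as 0 when either set is empty.

## Communication density

For an LR pair, the raw per-spot intensity on log-normalised expression is

```
raw_i = 1/2 * ( L_i * mean(R over neighbours of i)
              + R_i * mean(L over neighbours of i) )
```

with neighbours inside 1.5 x the grid spacing (self excluded); a spot with
no neighbours uses a neighbour mean of 0, hence raw 0. The null
distribution permutes the spot labels of the ligand and receptor vectors
**independently** (destroying their spatial co-localisation, which is the
signal) `n_perm` times (default 200, minimum 100) and recomputes the raw
intensity, giving `Zscore_i = (raw_i - mean_null_i) / sd_null_i`. Spots
whose null standard deviation is numerically zero get z = 0 and a
degeneracy flag; the variance is accumulated as deviations from the
observed raw so that a permutation-invariant configuration yields an
exact zero.

Discretisation is binary by default: `ZT_i = 1` if `Zscore_i >= 1.96`
(the two-sided 5% normal point) else 0, so the density
`Density = ZT_Total / N` is the fraction of significant spots and lies in
`[0, 1]`. A binned mode (`ZT_i = trunc(Zscore_i / z*)`) is kept for
sensitivity analysis. Two invariants hold exactly: `ZT_Total` is the sum
of the per-spot `ZT_i`, and lowering the threshold never lowers the binary
density.

Per trajectory and time point, spots of the chain's regions are pooled
across all sections of that time point (one density per pair per time
point). Densities across time points are compared with the tie-corrected
Kruskal-Wallis test (`stats::kruskal.test`), treating LR pairs as
observations and time points as groups; when every value is identical the
convention H = 0, p = 1 applies. An exact permutation p-value is available
for small samples.

One property worth knowing: when LR pairs differ strongly in baseline
expression, a pair's density is correlated with itself across time points
(a block effect). The unpaired Kruskal-Wallis test is then conservative —
real designs share the same pairs across time points, so cross-time-point
p-values are, if anything, understated. The type-I calibration study below
therefore uses homogeneous baselines, where the per-pair densities within
a group are iid and the nominal level is the right yardstick.

## The synthetic generator

`synthetic_config()` / `generate_dataset()` emulate the *structure* of a
serial-section study, not its biology: spots on a square grid (default
20 x 20 at 100 um), regions as contiguous vertical bands in layout order
with the root at low x, and true pseudotime defined as the normalised arc
length of a spot's position along the planted chain — geometrically
checkable ground truth. Counts are negative binomial (default dispersion
0.3) with per-gene baseline log-means drawn from `N(0, 0.5)`. On top of
the baseline the generator plants, per time point:

* **gradient genes** (default 100 at log-slope 1.5 across the whole
  chain): the smooth expression manifold that makes diffusion pseudotime
  recoverable, as in real tissue where expression drifts continuously
  along a propagation path;
* **region markers** (default 15 per region, +1.5 log-units): anatomical
  identity;
* **transition genes** (default 10 up + 10 down per subtrajectory,
  log-slope `effect_size = 1`, ramping only within their region pair, and
  planted among well-expressed genes, +2 log-units baseline — a ramp in a
  barely-detected gene is not a usable marker); the `marker_shift`
  fractions swap planted genes for time-point-private ones so subtype
  profiles genuinely diverge across time points (default: sham 70%
  private, d3 0%, d7 10%);
* **LR hotspots** (default 6 pairs): one contiguous disc per pair covering
  15% of a region's spots where ligand and receptor means are multiplied
  by `exp(log(4) * timepoint_effect)`; the default time-point effects
  (sham 0, d3 1, d7 0) plant communication only at day 3, the
  rise-then-fall contrast.

What the generator does **not** emulate: real anatomical geometry, H&E
morphology, spot-level cell mixtures, mean-variance trends, batch effects
between sections, or any hemorrhage biology. Tests passing on this
generator demonstrate that the algorithms recover what they are defined to
recover under their stated assumptions — not that those assumptions hold
in any particular tissue.

## Numerical choices and degenerate inputs

* All gene-symbol matching for LR and marker lookups is by uppercased
  symbol; raw case is preserved in outputs.
* Gene universes across sections of a time point default to the
  intersection (a transition-gene union presumes genes measured in all
  merged sections); union is available, in which case a gene absent from a
  section is absent, not zero-correlated.
* Every stochastic step (generator, permutation nulls, exact tests) takes
  an explicit seed; per-section and per-pair streams are derived
  deterministically from the master seed, so full pipeline runs are
  byte-identical given config + seed.
* Library sizes of all-zero spots are treated as 1 during normalisation
  (the spot contributes zeros, not NaNs).
* Ranking ties anywhere (genes, cell types) break lexicographically, never
  by input order.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run, as the package's chosen
study conditions: chain recovery and transition-gene recovery on 3
sections x 400 spots x ~2000 genes; the union rule on 1000 random
instances of up to 50 genes and 3 sections against a brute-force merge;
similarity axioms exhaustively over all 3^4 - 1 signed profiles on a
4-gene universe; Kruskal-Wallis type-I error on 200 simulated null
datasets (1 section x 100 spots x 8 pairs x 3 time points each) with the
95% binomial band around 0.05 as the yardstick, and power on 200
two-group draws of n = 50 shifted by 2 SD; dynamics and determinism on the
default three-time-point configuration.

## Known limitations

* Planar pseudotime is a from-scratch diffusion pseudotime on expression
  only; morphology-aware smoothing (as in image-integrated toolkits) is
  deliberately out of scope, so pseudotime near region borders is noisier
  than an image-assisted estimate would be.
* The subsequence merge cannot distinguish a truncated observation of a
  long chain from a genuinely shorter trajectory; support counting treats
  it as the former.
* Subtype profiles are transition-gene unions; no additional
  differential-expression filter is applied.
* The Kruskal-Wallis comparison treats LR pairs as independent
  observations; with strong per-pair baseline heterogeneity it is
  conservative (see above), and a paired/blocked test would be the
  sharper instrument.
* Cell-type matching quality is bounded by the supplied marker database;
  hypergeometric enrichment ignores marker weights and signs.
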