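---
title: "Models and methods in spotcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spotcast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spotcast` integrates a labeled single-cell RNA-seq reference with
Visium-style spatial transcriptomics and propagates per-cell annotation —
type labels, individual identities and pseudotime — onto barcoded tissue
spots. This vignette explains the models, the tunable parameters and their
defaults, what the built-in simulator does and does not emulate, and the
design choices made where the method left room.

## Preprocessing

Quality control keeps a cell when it has **at least** 200 detected genes
**and at most** 20% mitochondrial transcripts. Both boundaries are
inclusive on the keeping side: the exclusion criteria are "fewer than 200"
and "more than 20 percent", so exactly-200 and exactly-20% survive.
`qc_config()` takes either a mitochondrial gene set or a name-prefix rule
(default `^MT-`); real annotations, e.g. chicken mitochondrial genes that
do not follow the prefix convention, should be passed as an explicit set.

Log-normalization is `ln(count / total * 1e6 + 1)` per observation; before
the log, each observation's scaled counts sum to the scale factor exactly,
which the tests assert on the inverted intermediate. Variable genes are
ranked by the *vst* standardized variance: a loess curve (degree 2, span
0.3) of log10 variance on log10 mean predicts each gene's expected
standard deviation from raw counts; counts are standardized by that
prediction, clipped above at sqrt(N), and genes are ranked by the variance
of the standardized values. PCA scales genes to unit variance (values
clipped at ±10) and embeds observations on the top 20 components, with a
deterministic sign convention (each component's largest-magnitude loading
is positive).

Clustering builds a kNN graph in PC space, re-weights edges by the Jaccard
overlap of the endpoints' neighborhoods (shared nearest neighbors, pruning
below 1/15), and optimizes modularity with Louvain. For spatial spots the
defaults are k = 30 and resolution = 0.5, the usual Visium settings. At the
cell level no single convention dominates; we default to k = 20 and
resolution = 0.8 (the reference single-cell toolkit's conventions) and
expose both.

Cluster annotation assigns each cluster the type whose marker panel has the
highest mean z-scored expression, ties going to the lexicographically
smallest type with a flag. One-vs-rest Wilcoxon rank-sum tests produce the
marker table; the null is exact (`pwilcox`) when both groups have at most
50 observations and there are no ties, otherwise a normal approximation
with tie and continuity corrections — the same switch-over rule as
`wilcox.test`. Log fold changes are `log2((mean(expm1 x_in)+1) /
(mean(expm1 x_out)+1))`, and the default multiplicity adjustment is
Bonferroni (configurable via `p.adjust` methods).

## Anchor-based integration

Cells and spots are co-embedded by canonical correlation analysis: both
matrices are restricted to their shared variable genes and
gene-standardized within dataset, and the top *d* = 20 singular vectors of
the cross-product XᵀY give paired embeddings whose rows are L2-normalized
(distances are then cosine-equivalent, which stabilizes mutual-nearest-
neighbor behavior). **Anchors** are cross-dataset mutual nearest neighbors
(k_anchor = 5), optionally filtered by requiring the cell among the spot's
k_filter = 200 nearest reference cells in gene space, and scored by the
overlap of the pair's k_score = 30 neighborhoods in the combined embedding,
min–max rescaled with 1st/90th-percentile capping. These parameter defaults
follow the anchor method's own published defaults.

**Label transfer** gives each spot Gaussian-kernel weights (bandwidth
sd = 1 in the unit-normalized embedding) over its k_weight = 50 nearest
anchors, multiplied by anchor scores and normalized; averaging the
anchors' one-hot type vectors yields prediction-score rows that sum to 1.
Row-normalization to 1 is deliberate: the downstream 5% heterogeneity rule
and "weighted mixture" reading of prediction scores presuppose it.
**Identity transfer** runs the same kernel with each reference cell as its
own label, producing the sparse spots × cells similarity map. Because both
use one weight matrix, collapsing similarity columns by type reproduces the
prediction scores exactly — the module's central consistency identity,
asserted to 1e-10 in the tests.

Two behaviors of this machinery are worth knowing. First, kernel smoothing
over k_weight anchors blends neighboring spots; at 400 spots the default
k_weight = 50 spans a few adjacent layers, which biases maximum-score
labels on spots without a strong dominant type. We therefore report
max-label accuracy on spots whose true dominant type holds at least half
the spot, where "the dominant type" is well defined. Second, rare but
transcriptionally distinct types anchor more crisply than continuum types
and are mildly over-represented in mixture spots — an intrinsic property of
mutual-nearest-neighbor matching, visible in the composition error tables.

## Spot statistics

*Heterogeneity* counts the types with prediction score **strictly** above
the threshold (default 5%). *Colocalization* takes each spot's top-4 types
by score (zero scores excluded; ties at the cutoff broken by score then
type name) and increments every unordered pair; the default counts
presence, and a score-weighted variant (increment = the smaller score of
the pair) sits behind a flag because the source description ("counting
pair abundances") is ambiguous between the two. Both the raw and the
row-normalized matrix are returned, since chord-diagram figures can be
drawn either way. *Regional markers* are one-vs-rest Wilcoxon tests per
gene with a significance flag at log2 fold change > 0.5 and raw
p < 1e-5 — raw, not adjusted, matching the volcano convention; the
adjusted p is reported alongside.

Region labels come from spot clustering plus a user-supplied cluster-to-
region mapping, or directly from simulator truth; assigning anatomy from
histology images is outside computational scope.

## Trajectories

The diffusion-potential embedding uses an adaptive-bandwidth α-decay
kernel: `K_ij = exp(-(d_ij / σ_i)^α)` with σ_i the distance to the knn-th
neighbor (knn = 15) and α = 10, symmetrized and row-normalized into a
diffusion operator. The operator is powered to time *t*; `t = "auto"`
chooses the knee of the von Neumann entropy of the spectrum over t = 1…60
by maximum second difference — fixed this way for determinism. Potentials
are `-log(max(P^t, ε))` with ε = 1e-7, embedded by classical
(Torgerson) MDS. This is a faithful but simplified implementation of the
potential-of-heat-diffusion family: the contract that matters downstream is
only that coordinate 1 orders cells by developmental state. Note the knee
heuristic favors small *t*; on noiseless, widely spread manifolds full
mixing needs an explicit larger *t* (the tests pass t = 40 for an exact
1-D ordering check).

Pseudotime is coordinate 1, sign-anchored so the earliest stage's mean
precedes the latest stage's (the analogue of rooting a tree at the branch
dominated by the earliest-stage cells), then min–max rescaled to [0, 1];
the raw coordinate is also returned for callers who prefer the unscaled
proxy. Spot pseudotime is the **unweighted** mean pseudotime of the
lineage cells with nonzero similarity to the spot — the literal reading of
the definition — with a similarity-weighted mean behind a flag; spots with
empty lineage support are NA, not dropped. The projection accepts any
per-cell ordering, so external pseudotime vectors can be plugged in
unchanged.

## The simulator

`simulate_reference()` draws negative-binomial counts (`size` =
`nb_dispersion`, default 2) with lognormal library-size factors
(meanlog = log 2500, sdlog = 0.3 across a 600-gene genome — per-gene depth
comparable to real data after feature-space reduction). Eight heart cell
types are the default: two epicardial, two myocardial and two endocardial
lineage segments plus two discrete types (immune, erythrocyte). Each type
elevates 25 marker genes by 2.0 on the natural-log scale; roughly a third
of the genome is type-informative across the eight panels, matching the
DE-gene fractions standard simulators plant per group — sparser marker sets
leave types unrecoverable by any method and would make every downstream
test vacuous.

Lineages are **continua**: the member types of a lineage are ordered
segments of a latent differentiation time in [0, 1] (type k of m centred
at (k−0.5)/m), and marker programs cross-fade as Gaussian bumps in latent
time (τ = 0.5/m) rather than stepping, so a cell near a segment boundary
genuinely expresses both programs. Labels are a discretization of the
continuum. Each lineage additionally carries a 60-gene maturity program
whose log-means shift linearly with latent time (slope 2.0). Four stages
are drawn independently with shifting type proportions (early types wane,
late types wax) and stage-specific latent windows.

`simulate_tissue()` lays spots on a square lattice (the hexagonal offset
of the real array is irrelevant to these statistics, none of which use
inter-spot geometry; pitch is recorded in µm for plotting). Lattice rows
are assigned to five anatomical layers in bands; each spot draws a uniform
10–20 constituent cells (the per-spot count distribution is unstated in
the source, so uniform is assumed) with type proportions from its layer's
composition row, and spot counts are exactly the sums of constituent-cell
counts, optionally binomially thinned at a stated capture rate. Cells are
sampled with a latent-time preference derived from their own segment: the
layers containing a type, outer to inner, prefer progressively later cells
within that type's window, emulating maturation with tissue depth (the
epicardial-to-myocardial transition gradient). Deliberate QC violators
(too few detected genes, inflated mitochondrial content) can be planted at
configurable fractions and are never sampled into spots.

What the simulator does **not** emulate: batch and section effects
(`batch_effect_sd` defaults to 0; batch correction proper belongs to
dedicated external tools and is out of scope here), doublets, ambient RNA,
segmentation errors, spatially smooth expression within a layer, and
histology images. Passing recovery tests on this generator therefore shows
the pipeline's statistical machinery is correct under the stated noise
model, not that it is robust to artifacts the generator omits.

## Problem sizes and determinism

The shipped tests run the full pipeline at 1,200 cells × 400 spots ×
600 genes and single-lineage trajectory recovery at 1,000 cells — sizes
chosen so the complete suite exercises every stage end-to-end in well
under a minute while leaving recovery statistics stable across seeds. All
randomness in simulation, clustering and permutation testing is seeded;
identical seeds give byte-identical simulations, and the acceptance script
derives every seed from its `--seed` argument.

## Known limitations

Prediction scores are anchor-kernel averages, not a deconvolution: they
recover composition with median per-spot correlation ≈ 0.9 under default
conditions but systematically smooth toward neighboring spots and slightly
inflate rare, distinct types. Pseudotime as a single embedding coordinate
assumes an essentially linear lineage; branches need the per-lineage
reclustering the pipeline applies upstream. The diffusion embedding is
dense (O(n²) memory) and intended for lineage subsets, not atlases.
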