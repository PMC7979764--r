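# spotcast

Anchor-based cell-type mapping and lineage projection for spatial
transcriptomics.

Barcoded spatial platforms such as 10x Visium measure whole transcriptomes
at 55 µm spots laid out at 110 µm pitch, but each spot pools the mRNA of
roughly 10–20 cells. In developing tissue — the motivating system is the
embryonic ventricular wall, with epicardial, myocardial and endocardial
lineages arranged in anatomical layers — the question is not just *what* is
expressed where, but *which cell types and differentiation states* occupy
each spot. `spotcast` answers this by integrating a single-cell RNA-seq
reference with the spatial data and propagating per-cell annotations onto
spots.

## The method

Given a reference of cells with curated type labels and a query of spatial
spots (both as raw count matrices):

1. **Preprocessing.** Cells with fewer than 200 detected genes or more than
   20% mitochondrial transcripts are removed. Counts are log-normalized
   (`ln(count / total × 10⁶ + 1)`), the top 2,000 highly variable genes are
   selected by standardized variance ("vst"), observations are embedded on
   20 principal components, and spots are clustered with a shared-nearest-
   neighbor graph and Louvain modularity (k = 30, resolution = 0.5).
2. **Anchors.** Cells and spots are co-embedded by canonical correlation
   analysis on their shared variable genes (top *d* singular vectors of
   XᵀY, rows L2-normalized). Mutual nearest neighbors across the two
   datasets form *anchors*, scored by the overlap of their neighborhoods
   and filtered for consistency in gene space.
3. **Label transfer.** Every spot takes Gaussian-kernel weights over its
   nearest anchors; averaging the anchors' one-hot type labels yields a
   **prediction-score matrix** (spots × types, rows summing to 1) — a proxy
   for per-spot cell-type composition. Transferring cell *identities*
   instead of type labels yields the sparse **cell–spot similarity map**.
   Collapsing the similarity map by cell type reproduces the prediction
   scores exactly; the package tests this identity to 1e-10.
4. **Spot statistics.** Max-score labels per spot; per-spot
   **heterogeneity** (number of types with prediction score strictly above
   5%); a symmetric **colocalization** matrix counting type pairs among
   each spot's top-4 predicted types; per-region mean composition; and
   one-vs-rest Wilcoxon rank-sum tests for regionally restricted genes
   (volcano thresholds log₂FC > 0.5, p < 10⁻⁵).
5. **Trajectories.** Lineage cells are embedded with a diffusion-potential
   method (adaptive-bandwidth α-decay kernel, row-stochastic diffusion
   operator powered to a von Neumann-entropy knee, −log potential, classical
   MDS); coordinate 1, sign-anchored so the earliest developmental stage
   precedes the latest, serves as **pseudotime**. A spot's pseudotime is the
   mean pseudotime of the lineage cells with nonzero similarity to it.

A layered-tissue simulator (`tissue_config()`, `simulate_reference()`,
`simulate_tissue()`) generates negative-binomial counts with planted
lineage continua, marker programs, anatomical layers and full ground truth,
so every stage of the pipeline has a parameter-recovery test.

## Worked example

```r
library(spotcast)

cfg <- tissue_config(seed = 1)          # 8 heart cell types, 20x20 spot grid
res <- run_pipeline(cfg)                # simulate + integrate + analyze

truth <- res$truth
comp_true <- truth$spot_composition
comp_pred <- res$scores$matrix[, colnames(comp_true)]
pear <- sapply(seq_len(nrow(comp_true)), function(i)
  cor(comp_pred[i, ], comp_true[i, ]))

cat(sprintf("spots: %d   cell types: %d   anchors: %d\n",
            nrow(comp_true), ncol(comp_true), nrow(res$anchors)))
cat(sprintf("median per-spot Pearson (predicted vs true composition): %.3f\n",
            median(pear)))
cat(sprintf("median heterogeneity (types > 5%% per spot): %d\n",
            median(res$heterogeneity)))
cm <- res$colocalization$counts
top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
cat(sprintf("most colocalized pair: %s - %s (%d spots)\n",
            rownames(cm)[top[1]], colnames(cm)[top[2]], max(cm)))
ok <- !is.na(res$spot_pt$value)
cat(sprintf("epicardial spot pseudotime defined on %d/%d spots\n",
            sum(ok), length(ok)))
print(head(label_spots_max(res$scores), 3))
```

prints

```
spots: 400   cell types: 8   anchors: 1363
median per-spot Pearson (predicted vs true composition): 0.925
median heterogeneity (types > 5% per spot): 3
most colocalized pair: trabecular_cardiomyocyte - compact_cardiomyocyte (212 spots)
epicardial spot pseudotime defined on 257/400 spots
          spot       label     score   tie
1 SPOT_000_000  epicardial 0.5491161 FALSE
2 SPOT_001_000  epicardial 0.6233686 FALSE
3 SPOT_002_000 erythrocyte 0.4670209 FALSE
```

The prediction-score rows track the true per-spot mixtures (median Pearson
0.93), a typical spot mixes three or four detectable cell types, and the
most frequent top-4 pairing is the trabecular–compact cardiomyocyte
interface, as the layered anatomy dictates. Spot pseudotime is defined
wherever epicardial-lineage cells have nonzero similarity support.

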