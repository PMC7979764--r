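#' Run the full integration pipeline on simulated tissue
#'
#' Convenience driver that chains every stage on one simulated dataset:
#' reference and tissue simulation, QC filtering, log-normalization, HVG
#' selection, reference clustering and marker-panel annotation (or truth
#' labels on request), CCA anchor finding, label and identity transfer,
#' spot statistics, and lineage pseudotime projected onto spots.
#'
#' @param config a [tissue_config()].
#' @param qc a [qc_config()].
#' @param n_hvg variable genes for embedding (default 2000, capped at the
#'   gene count).
#' @param cca_dims canonical dimensions (default 20).
#' @param k_anchor,k_filter,k_score anchor parameters, see [find_anchors()].
#' @param k_weight,sd_weight transfer kernel parameters, see
#'   [transfer_labels()].
#' @param label_source `"truth"` (default) uses the simulator's planted
#'   types as the reference labels, standing in for the curated cell-type
#'   annotation a real reference carries; `"annotation"` derives labels by
#'   SNN-Louvain clustering plus marker-panel annotation instead. Lineage
#'   types are segments of a continuum, so automated annotation is
#'   intrinsically ambiguous near segment boundaries.
#' @param cluster_k,cluster_resolution reference clustering parameters
#'   (defaults 20 and 0.8 for cells).
#' @param lineage lineage for the trajectory stage (default "epicardial");
#'   `NULL` skips it.
#' @param diffusion_knn kNN for the diffusion kernel (default 15).
#' @param seed seed for the clustering and any downstream randomness; the
#'   simulator uses `config$seed`.
#' @param verbose log progress messages.
#' @return list with the simulation (`reference`, `spots`, `truth`), the
#'   processed objects (`cells_filtered`, `cell_norm`, `spot_norm`, `hvg`,
#'   `ref_labels`), the integration results (`anchors`, `scores`, `sim`),
#'   the spot statistics (`max_labels`, `heterogeneity`, `colocalization`,
#'   `composition`), and the trajectory (`pseudotime`, `spot_pt`,
#'   `lineage_cells`).
#' @export
run_pipeline <- function(config = tissue_config(), qc = qc_config(),
                         n_hvg = 2000L, cca_dims = 20L,
                         k_anchor = 5L, k_filter = 200L, k_score = 30L,
                         k_weight = 50L, sd_weight = 1,
                         label_source = c("truth", "annotation"),
                         cluster_k = 20L, cluster_resolution = 0.8,
                         lineage = "epicardial", diffusion_knn = 15L,
                         seed = 42L, verbose = FALSE) {
  label_source <- match.arg(label_source)
  say <- function(...) if (verbose) message(...)

  say("simulating reference and tissue")
  ref <- simulate_reference(config)
  tis <- simulate_tissue(config, ref$cells, ref$truth)
  truth <- tis$truth

  say("QC filtering and normalization")
  cells_f <- filter_cells(ref$cells, qc, verbose = verbose)
  truth_idx <- match(cells_f$obs_ids, truth$cell_id)
  cell_norm <- lognormalize(cells_f)
  spot_norm <- lognormalize(tis$spots)

  hvg <- select_hvg(cells_f$counts, min(n_hvg, nrow(cells_f$counts)))

  if (label_source == "annotation") {
    say("clustering and annotating the reference")
    pca_ref <- run_pca(cell_norm, genes = hvg,
                       n_pcs = min(20L, length(hvg) - 1L))
    cl <- cluster_obs(pca_ref$embedding, k = cluster_k,
                      resolution = cluster_resolution, seed = seed)
    ann <- annotate_clusters(cell_norm, cl, truth$marker_panels,
                             markers = FALSE)
    map <- stats::setNames(ann$mapping$type, ann$mapping$cluster)
    ref_labels <- unname(map[as.character(cl)])
  } else {
    ref_labels <- truth$cell_type[truth_idx]
  }

  say("anchor finding and transfer")
  cca <- cca_embed(cell_norm, spot_norm, d = cca_dims, genes = hvg)
  anchors <- find_anchors(cca, k_anchor = k_anchor, k_filter = k_filter,
                          k_score = k_score)
  scores <- transfer_labels(anchors, ref_labels, k_weight = k_weight,
                            sd_weight = sd_weight)
  sim <- transfer_identity(anchors, k_weight = k_weight,
                           sd_weight = sd_weight)

  say("spot statistics")
  het <- heterogeneity(scores)
  coloc <- colocalization(scores)
  comp <- composition_by_region(scores, truth$spot_layer)
  max_labels <- label_spots_max(scores)

  pt <- spt <- lin_ids <- NULL
  if (!is.null(lineage)) {
    lin_ids <- cells_f$obs_ids[truth$lineage[truth_idx] == lineage]
    if (length(lin_ids) > diffusion_knn + 1) {
      say("trajectory for lineage ", lineage)
      lin_norm <- cell_norm[, lin_ids, drop = FALSE]
      pca_lin <- run_pca(lin_norm, genes = hvg,
                         n_pcs = min(20L, length(hvg) - 1L,
                                     length(lin_ids) - 2L))
      demb <- diffusion_embedding(pca_lin$embedding, knn = diffusion_knn)
      stages <- truth$cell_stage[truth_idx][match(lin_ids, cells_f$obs_ids)]
      pt <- extract_pseudotime(demb, stages)
      spt <- spot_pseudotime(sim, pt, lineage_cells = lin_ids)
    } else {
      warning("lineage '", lineage, "' has too few cells; trajectory skipped")
    }
  }

  list(config = config, reference = ref$cells, spots = tis$spots,
       truth = truth, cells_filtered = cells_f, cell_norm = cell_norm,
       spot_norm = spot_norm, hvg = hvg, ref_labels = ref_labels,
       cca = cca, anchors = anchors, scores = scores, sim = sim,
       max_labels = max_labels, heterogeneity = het,
       colocalization = coloc, composition = comp,
       pseudotime = pt, spot_pt = spt, lineage_cells = lin_ids)
}
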