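# Shared fixtures and small oracles for the suite. Everything is generated
# in code under fixed seeds; nothing is read from disk.

# a small, fast configuration for unit tests (not the acceptance conditions)
small_config <- function(...) {
  defaults <- list(seed = 1L, n_cells = 300L, n_genes = 300L,
                   grid_shape = c(8L, 8L), n_cell_types = 4L,
                   markers_per_type = 20L,
                   cell_type_names = paste0("type", 1:4),
                   type_lineages = c(type1 = "epicardial",
                                     type2 = "epicardial",
                                     type3 = "none", type4 = "none"))
  do.call(tissue_config, utils::modifyList(defaults, list(...)))
}

# a discrete-type configuration: no lineage continuum, so planted types are
# fully separated clusters (the setting the clustering claims are about)
discrete_config <- function(seed = 1L, n_cells = 600L, ...) {
  types <- tissue_config()$cell_type_names
  tissue_config(seed = seed, n_cells = n_cells,
                type_lineages = stats::setNames(rep("none", 8), types), ...)
}

# adjusted Rand index, computed from the contingency table
ari <- function(a, b) {
  tab <- table(a, b)
  x <- sum(choose(tab, 2))
  y <- sum(choose(rowSums(tab), 2))
  z <- sum(choose(colSums(tab), 2))
  e <- y * z / choose(sum(tab), 2)
  (x - e) / ((y + z) / 2 - e)
}

# build an AnchorSet by hand so transfer machinery can be tested against
# exact hand-computable weights
manual_anchors <- function(ref_emb, query_emb, ref_index, query_index,
                           score) {
  cca <- structure(list(ref = ref_emb, query = query_emb,
                        d = ncol(ref_emb)), class = "cca_embedding")
  structure(data.frame(ref_index = ref_index, query_index = query_index,
                       score = score),
            class = c("AnchorSet", "data.frame"), cca = cca)
}

# exact two-sided rank-sum p-value by enumerating every group assignment
exact_wilcox_p <- function(x, in_group) {
  n <- length(x)
  n1 <- sum(in_group)
  r <- rank(x)
  obs_u <- sum(r[in_group]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (length(x) - n1) / 2
  # two-sided: as-or-more-extreme in |U - mean|
  min(1, mean(abs(us - mu) >= abs(obs_u - mu) - 1e-12) *
        1)
}
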