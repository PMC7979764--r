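# Fixtures: normalized matrices for a reference/query pair come from the
# simulator; tiny dense fixtures exercise the linear algebra against oracles.

sim_pair <- function(seed = 41, n_cells = 400, grid = c(10, 10), ...) {
  cfg <- small_config(seed = seed, n_cells = n_cells, grid_shape = grid, ...)
  r <- simulate_reference(cfg)
  tis <- simulate_tissue(cfg, r$cells, r$truth)
  list(cfg = cfg, ref = r$cells, truth = tis$truth, spots = tis$spots,
       ref_norm = lognormalize(r$cells), spot_norm = lognormalize(tis$spots))
}

test_that("CCA singular values match a dense SVD oracle on a small fixture", {
  set.seed(1)
  X <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(paste0("g", 1:8),
                                                  paste0("c", 1:6)))
  Y <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(paste0("g", 1:8),
                                                  paste0("s", 1:5)))
  cca <- cca_embed(X, Y, d = 4)
  Xs <- t(scale(t(X))); Ys <- t(scale(t(Y)))
  oracle <- svd(crossprod(Xs, Ys))$d[1:4]
  expect_lt(max(abs(cca$singular_values - oracle)), 1e-10)
  expect_equal(dim(cca$ref), c(6L, 4L))
  expect_equal(dim(cca$query), c(5L, 4L))
  # embedding rows are unit length
  expect_equal(unname(rowSums(cca$ref^2)), rep(1, 6), tolerance = 1e-12)
})

test_that("self-alignment puts every observation next to its copy", {
  p <- sim_pair(seed = 42, n_cells = 150, grid = c(4, 4))
  cca <- cca_embed(p$ref_norm, p$ref_norm, d = 10)
  D <- as.matrix(dist(rbind(cca$ref, cca$query)))[1:150, 151:300]
  expect_true(all(apply(D, 1, which.min) == seq_len(150)))
  # canonical correlations of a dataset with itself are ~1:
  # cross-product singular values equal the gene-standardized total variance
  Xs <- t(scale(t(as.matrix(p$ref_norm))))
  expect_gt(cca$singular_values[1] / svd(crossprod(Xs))$d[1], 0.999)
})

test_that("anchors between identical datasets are the identity pairing", {
  p <- sim_pair(seed = 43, n_cells = 120, grid = c(4, 4))
  cca <- cca_embed(p$ref_norm, p$ref_norm, d = 10)
  anch <- find_anchors(cca, k_anchor = 3, k_filter = NULL, k_score = 20)
  self <- anch[anch$ref_index == anch$query_index, ]
  expect_equal(nrow(self), 120)
  expect_gt(mean(self$score), 0.9)
})

test_that("MNN anchor pairs are symmetric under role swap", {
  p <- sim_pair(seed = 44, n_cells = 120, grid = c(5, 5))
  cca_fwd <- cca_embed(p$ref_norm, p$spot_norm, d = 10)
  cca_rev <- cca_embed(p$spot_norm, p$ref_norm, d = 10)
  a_fwd <- find_anchors(cca_fwd, k_anchor = 5, k_filter = NULL, k_score = 20)
  a_rev <- find_anchors(cca_rev, k_anchor = 5, k_filter = NULL, k_score = 20)
  key_fwd <- sort(paste(a_fwd$ref_index, a_fwd$query_index))
  key_rev <- sort(paste(a_rev$query_index, a_rev$ref_index))
  expect_identical(key_fwd, key_rev)
})

test_that("query permutation permutes the embedding rows identically", {
  p <- sim_pair(seed = 45, n_cells = 100, grid = c(4, 4))
  cca <- cca_embed(p$ref_norm, p$spot_norm, d = 8)
  perm <- sample(ncol(p$spot_norm))
  cca_p <- cca_embed(p$ref_norm, p$spot_norm[, perm], d = 8)
  expect_equal(cca_p$query, cca$query[perm, ], tolerance = 1e-8)
})

test_that("anchors land only on the matching type for pure spots", {
  # two discrete types; outer layers hold pure type1 spots, inner layers
  # pure type2 spots (both pure, so anchors are type-checkable per spot)
  types <- c("type1", "type2")
  comp <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 1))
  cfg <- small_config(seed = 46, n_cells = 200, grid_shape = c(5, 5),
                      n_cell_types = 2, cell_type_names = types,
                      type_lineages = c(type1 = "none", type2 = "none"),
                      layer_composition = comp)
  r <- simulate_reference(cfg)
  tis <- simulate_tissue(cfg, r$cells, r$truth)
  cca <- cca_embed(lognormalize(r$cells), lognormalize(tis$spots), d = 10)
  anch <- find_anchors(cca, k_anchor = 5, k_filter = 25, k_score = 20)
  anchor_types <- r$truth$cell_type[anch$ref_index]
  # each anchor's reference cell type equals its spot's planted type
  planted <- ifelse(tis$truth$spot_layer[anch$query_index] %in%
                      c("epicardium", "compact_myocardium"),
                    "type1", "type2")
  expect_identical(anchor_types, planted)
})

test_that("transfer weights follow the stated Gaussian kernel exactly", {
  # two anchors on two spots: distances are measured from the scored spot
  # to each anchor's query-side position, hand-computable here
  ref_emb <- rbind(c(1, 0), c(0, 1))
  query_emb <- rbind(c(1, 0), c(0, 1))
  anch <- manual_anchors(ref_emb, query_emb,
                         ref_index = c(1L, 2L), query_index = c(1L, 2L),
                         score = c(1, 0.5))
  scores <- transfer_labels(anch, ref_labels = c("a", "b"), k_weight = 2,
                            sd_weight = 1)
  w1 <- c(exp(-0.5 * 0^2) * 1, exp(-0.5 * sqrt(2)^2) * 0.5)
  w1 <- w1 / sum(w1)
  expect_equal(unname(scores$matrix[1, c("a", "b")]), w1, tolerance = 1e-12)
  w2 <- c(exp(-0.5 * sqrt(2)^2) * 1, exp(-0.5 * 0^2) * 0.5)
  w2 <- w2 / sum(w2)
  expect_equal(unname(scores$matrix[2, c("a", "b")]), w2, tolerance = 1e-12)

  # a spot whose only usable anchor points at one cell: weight 1 support
  anch1 <- manual_anchors(ref_emb, query_emb, ref_index = 1L,
                          query_index = 1L, score = 1)
  sim <- transfer_identity(anch1, k_weight = 5)
  expect_equal(sim$support[[1]], 1L)
  expect_equal(sim$matrix[1, 1], 1)
})

test_that("single-type anchor neighborhoods give one-hot rows", {
  p <- sim_pair(seed = 47, n_cells = 150, grid = c(5, 5))
  cca <- cca_embed(p$ref_norm, p$spot_norm, d = 10)
  anch <- find_anchors(cca, k_anchor = 5, k_filter = NULL, k_score = 20)
  labels <- rep("only_type", nrow(cca$ref))
  scores <- transfer_labels(anch, labels)
  expect_true(all(abs(scores$matrix[, "only_type"] - 1) < 1e-12))
  expect_error(transfer_labels(anch, rep(NA, nrow(cca$ref))), "label")
})

test_that("prediction rows sum to one and similarity columns are sane", {
  p <- sim_pair(seed = 48)
  idx <- match(p$ref$obs_ids, p$truth$cell_id)
  cca <- cca_embed(p$ref_norm, p$spot_norm, d = 15)
  anch <- find_anchors(cca)
  scores <- transfer_labels(anch, p$truth$cell_type[idx])
  expect_true(all(abs(rowSums(scores$matrix) - 1) < 1e-9))
  sim <- transfer_identity(anch)
  expect_true(all(sim$matrix@x >= 0))
  colmarg <- Matrix::colSums(sim$matrix)
  expect_true(all(is.finite(colmarg)) && all(colmarg >= 0))
  # support matches the sparsity pattern
  expect_equal(unname(lengths(sim$support)),
               unname(as.integer(Matrix::rowSums(sim$matrix > 0))))
})

test_that("collapsing the similarity map by type reproduces label transfer", {
  p <- sim_pair(seed = 49)
  idx <- match(p$ref$obs_ids, p$truth$cell_id)
  labels <- p$truth$cell_type[idx]
  cca <- cca_embed(p$ref_norm, p$spot_norm, d = 15)
  anch <- find_anchors(cca)
  scores <- transfer_labels(anch, labels)
  collapsed <- collapse_similarity(transfer_identity(anch), labels)
  expect_lt(max(abs(scores$matrix - collapsed$matrix)), 1e-10)
  expect_identical(scores$max_label, collapsed$max_label)
})

test_that("self-transfer returns each cell its own label as the maximum", {
  # discrete, well-separated types: the premise of exact self-recovery
  p <- sim_pair(seed = 50, n_cells = 150, grid = c(4, 4),
                type_lineages = c(type1 = "none", type2 = "none",
                                  type3 = "none", type4 = "none"))
  idx <- match(p$ref$obs_ids, p$truth$cell_id)
  labels <- p$truth$cell_type[idx]
  cca <- cca_embed(p$ref_norm, p$ref_norm, d = 10)
  anch <- find_anchors(cca, k_anchor = 3, k_filter = NULL)
  scores <- transfer_labels(anch, labels, k_weight = 3)
  own <- scores$matrix[cbind(seq_along(labels), match(labels, scores$type_names))]
  expect_true(all(own >= scores$max_score - 1e-12))
})

test_that("similarity support shares the spot's dominant type", {
  # spots with a strong (80%) dominant type per layer: the support of a
  # spot should be predominantly cells of that type. (The support fraction
  # cannot exceed the spot's true dominant share, so the check needs spots
  # that actually have a clear majority.)
  comp <- matrix(0.2 / 3, 5, 4)
  comp[cbind(1:5, c(1, 2, 3, 4, 1))] <- 0.8
  comp[5, setdiff(1:4, 1)] <- 0.2 / 3
  p <- sim_pair(seed = 51, layer_composition = comp,
                type_lineages = c(type1 = "none", type2 = "none",
                                  type3 = "none", type4 = "none"))
  idx <- match(p$ref$obs_ids, p$truth$cell_id)
  cca <- cca_embed(p$ref_norm, p$spot_norm, d = 15)
  anch <- find_anchors(cca)
  sim <- transfer_identity(anch)
  truec <- p$truth$spot_composition
  dom <- colnames(truec)[max.col(truec, "first")]
  frac <- vapply(seq_len(nrow(truec)), function(s) {
    sup <- sim$support[[s]]
    if (!length(sup)) return(NA_real_)
    mean(p$truth$cell_type[idx][sup] == dom[s])
  }, numeric(1))
  expect_gte(mean(frac, na.rm = TRUE), 0.6)
})

test_that("degenerate anchor inputs raise informative errors", {
  p <- sim_pair(seed = 52, n_cells = 100, grid = c(4, 4))
  cca <- cca_embed(p$ref_norm, p$spot_norm, d = 8)
  expect_error(prediction_scores(matrix(c(0.4, 0.4), 1, 2,
                                        dimnames = list(NULL, c("a", "b")))),
               "sum to 1")
  expect_warning(cca_embed(p$ref_norm[1:5, ], p$spot_norm[1:5, ], d = 10),
                 "shared genes")
})
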