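make_em <- function(counts, mito_rows = integer(0)) {
  g <- sprintf("GENE%03d", seq_len(nrow(counts)))
  g[mito_rows] <- sprintf("MT-G%02d", seq_along(mito_rows))
  expression_matrix(counts, gene_ids = g, gene_names = g,
                    obs_ids = sprintf("C%03d", seq_len(ncol(counts))),
                    kind = "cells")
}

test_that("QC boundaries keep exactly-200 genes and exactly-20% mito", {
  set.seed(1)
  G <- 250
  base <- matrix(rpois(G * 4, 5) + 1L, G, 4)   # all genes detected
  # cell 1: exactly 199 detected; cell 2: exactly 200 detected
  base[200:G, 1] <- 0L
  base[201:G, 2] <- 0L
  # cell 3: mito fraction exactly 100/500 = 0.20; cell 4: 150/550 > 0.20
  base[, 3] <- 0L; base[2:201, 3] <- 2L; base[1, 3] <- 100L
  base[, 4] <- 0L; base[2:201, 4] <- 2L; base[1, 4] <- 150L
  m <- make_em(base, mito_rows = 1)
  kept <- suppressMessages(filter_cells(m, qc_config()))
  expect_setequal(kept$obs_ids, c("C002", "C003"))
  met <- attr(kept, "qc_metrics")
  expect_equal(met$detected_genes[1:2], c(199L, 200L))
  expect_equal(met$mito_frac[3], 0.20, tolerance = 1e-12)
})

test_that("QC filter is idempotent and an all-zero matrix keeps nothing", {
  cfg <- small_config(seed = 2, qc_low_gene_fraction = 0.1)
  r <- simulate_reference(cfg)
  once <- suppressMessages(filter_cells(r$cells))
  twice <- suppressMessages(filter_cells(once))
  expect_identical(once$obs_ids, twice$obs_ids)
  zero <- make_em(matrix(0L, 300, 5))
  expect_warning(out <- suppressMessages(filter_cells(zero)), "every")
  expect_equal(ncol(out$counts), 0)
})

test_that("log-normalization matches its closed form and a dense oracle", {
  # forced by the formula: ln(10 / 10000 * 1e6 + 1) = ln(1001)
  m <- make_em(rbind(c(10L), matrix(rep(c(555L), 18), ncol = 1),
                     c(9990L - 18L * 555L)))
  expect_equal(sum(m$counts[, 1]), 10000)
  norm <- lognormalize(m)
  expect_equal(norm[1, 1], log(1001), tolerance = 1e-12)

  set.seed(3)
  counts <- matrix(rpois(200 * 30, 2), 200, 30)
  em <- make_em(counts)
  norm <- lognormalize(em)
  dense <- log(t(t(counts) / colSums(counts)) * 1e6 + 1)
  expect_lt(max(abs(as.matrix(norm) - dense)), 1e-12)
  # zeros stay zero, sparsity preserved
  expect_equal(unname(as.matrix(norm)) == 0, counts == 0)
  # pre-log scaled counts per cell sum to the scale factor
  expect_equal(unname(colSums(expm1(as.matrix(norm)))),
               rep(1e6, 30), tolerance = 1e-6)
  expect_error(lognormalize(matrix(-1, 2, 2)), "negative")
})

test_that("vst ranks a planted high-variance gene first and ignores order", {
  set.seed(4)
  lambda <- runif(100, 1, 50)          # spread of means so the trend is real
  counts <- matrix(rpois(100 * 50, rep(lambda, 50)), 100, 50)
  # mean within the bulk but bimodal: large excess over the trend
  counts[7, ] <- sample(c(0L, 40L), 50, replace = TRUE)
  em <- make_em(counts)
  hv <- select_hvg(em, n_hvg = 10)
  expect_equal(hv[1], em$gene_names[7])

  perm <- sample(100)
  shuffled <- em$counts[perm, ]
  hv2 <- select_hvg(shuffled, n_hvg = 10)
  expect_setequal(hv, hv2)
})

test_that("vst standardized variance matches an independent dense oracle", {
  set.seed(5)
  counts <- matrix(rnbinom(150 * 40, size = 2, mu = 4), 150, 40)
  rownames(counts) <- sprintf("g%03d", 1:150)
  top <- select_hvg(counts, n_hvg = 25)

  # independent dense reimplementation of the ranking
  mu <- rowMeans(counts)
  v <- apply(counts, 1, var)
  ok <- v > 0 & mu > 0
  fit <- loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.3, degree = 2)
  esd <- sqrt(10^fitted(fit))
  clip <- sqrt(ncol(counts))
  sv <- rep(0, 150)
  okidx <- which(ok)
  sv[okidx] <- sapply(seq_along(okidx), function(j) {
    i <- okidx[j]
    z <- pmin((counts[i, ] - mu[i]) / esd[j], clip)
    sum(z^2) / (ncol(counts) - 1)
  })
  oracle <- rownames(counts)[order(-sv, rownames(counts))][1:25]
  expect_setequal(top, oracle)
})

test_that("PCA matches a dense eigendecomposition and orders variance", {
  set.seed(6)
  X <- matrix(rnorm(20 * 10), 20, 10)
  rownames(X) <- sprintf("g%02d", 1:20)
  colnames(X) <- sprintf("c%02d", 1:10)
  p <- run_pca(X, n_pcs = 5, clip = Inf)
  # oracle: eigendecomposition of the scaled-gene covariance
  Xs <- t(scale(t(X)))
  eg <- eigen(crossprod(Xs), symmetric = TRUE)
  for (j in 1:5) {
    # subspace agreement per component (sign-free)
    v <- p$embedding[, j] / sqrt(sum(p$embedding[, j]^2))
    w <- eg$vectors[, j]
    expect_lt(abs(abs(sum(v * w)) - 1), 1e-8)
  }
  expect_true(all(diff(p$var_explained) <= 1e-12))

  # a single shared axis across genes loads PC1 only
  s <- seq(-5, 5, length.out = 10)
  Y <- rbind(s + rnorm(10, sd = 0.01), s + rnorm(10, sd = 0.01),
             s + rnorm(10, sd = 0.01))
  rownames(Y) <- c("sig1", "sig2", "sig3")
  p2 <- run_pca(Y, n_pcs = 2, clip = Inf)
  expect_gt(p2$var_explained[1], 0.99)
  expect_gt(abs(cor(p2$embedding[, 1], s)), 0.99)
})

test_that("SNN-Louvain separates well-separated blobs deterministically", {
  set.seed(7)
  emb <- rbind(matrix(rnorm(100 * 5), 100), matrix(rnorm(100 * 5, 10), 100))
  rownames(emb) <- sprintf("o%03d", 1:200)
  cl <- cluster_obs(emb, k = 30, resolution = 0.5)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:100])), 1)
  expect_equal(length(unique(cl[101:200])), 1)
  cl2 <- cluster_obs(emb, k = 30, resolution = 0.5)
  expect_identical(cl, cl2)
  expect_error(cluster_obs(emb[1:10, ], k = 30), "at least")
})

test_that("returned partition beats the singleton partition on modularity", {
  set.seed(8)
  emb <- rbind(matrix(rnorm(60 * 3), 60), matrix(rnorm(60 * 3, 6), 60))
  cl <- cluster_obs(emb, k = 15, resolution = 0.5)
  # rebuild the same SNN graph independently to score both partitions
  d <- as.matrix(dist(emb))
  k <- 15
  nn <- t(apply(d, 1, function(r) order(r)[1:k]))
  A <- Matrix::sparseMatrix(i = rep(1:120, each = k), j = as.vector(t(nn)),
                            x = 1, dims = c(120, 120))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < 1 / 15] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, "undirected", weighted = TRUE)
  expect_gt(igraph::modularity(g, cl),
            igraph::modularity(g, seq_len(120)))
})

test_that("clustering recovers planted discrete types (ARI >= 0.9)", {
  cfg <- discrete_config(seed = 31, n_cells = 600)
  r <- simulate_reference(cfg)
  norm <- lognormalize(r$cells)
  hv <- select_hvg(r$cells$counts, n_hvg = 600)
  p <- run_pca(norm, genes = hv, n_pcs = 20)
  cl <- cluster_obs(p$embedding, k = 20, resolution = 0.8)
  expect_gte(ari(cl, r$truth$cell_type), 0.9)
})

test_that("marker-panel annotation recovers planted type identities", {
  cfg <- discrete_config(seed = 32, n_cells = 600)
  r <- simulate_reference(cfg)
  norm <- lognormalize(r$cells)
  p <- run_pca(norm, genes = select_hvg(r$cells$counts, 600), n_pcs = 20)
  cl <- cluster_obs(p$embedding, k = 20, resolution = 0.8)
  ann <- annotate_clusters(norm, cl, r$truth$marker_panels, markers = FALSE)
  map <- setNames(ann$mapping$type, ann$mapping$cluster)
  # every cluster maps to the type of its majority constituent
  for (cluster in ann$mapping$cluster) {
    truth_mode <- names(which.max(table(r$truth$cell_type[cl == cluster])))
    expect_equal(unname(map[as.character(cluster)]), truth_mode)
  }
  # a single cluster is assigned its best panel trivially
  one <- annotate_clusters(norm, rep(1L, ncol(norm)), r$truth$marker_panels,
                           markers = FALSE)
  expect_equal(nrow(one$mapping), 1)
  # absent panel genes are skipped with a warning
  panels <- c(r$truth$marker_panels, list(ghost = c("NOPE1", "NOPE2")))
  expect_warning(annotate_clusters(norm, cl, panels, markers = FALSE),
                 "absent")
})

test_that("one-vs-rest Wilcoxon markers find a planted DE gene", {
  set.seed(9)
  X <- matrix(rnorm(50 * 60), 50, 60)
  rownames(X) <- sprintf("g%02d", 1:50)
  labels <- rep(c(1L, 2L), each = 30)
  X[5, labels == 1] <- X[5, labels == 1] + 3
  mk <- find_markers(X, labels)
  top <- mk[mk$group == 1, ][1, ]
  expect_equal(top$gene, "g05")
  expect_gt(top$log2_fc, 0)
  expect_lt(top$p_adj, 0.01)
  # constant gene reports p = 1
  X[10, ] <- 7
  mk2 <- find_markers(X, labels)
  expect_equal(mk2$p[mk2$group == 1 & mk2$gene == "g10"], 1)
})

test_that("rank-sum p-values equal exact enumeration on a 6-vs-6 toy", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1, 7.3, 0.5, 6.6, 8.8, 2.9, 9.1, 4.8)
  grp <- rep(c(TRUE, FALSE), each = 6)
  ours <- spotcast:::rank_sum_test(x, grp)
  expect_equal(ours$p, exact_wilcox_p(x, grp), tolerance = 1e-12)
  expect_equal(ours$p,
               wilcox.test(x[grp], x[!grp], exact = TRUE)$p.value,
               tolerance = 1e-12)
  # large/tied samples agree with the normal-approximation reference
  set.seed(10)
  y <- round(rnorm(160), 1)
  g2 <- rep(c(TRUE, FALSE), 80)
  expect_equal(spotcast:::rank_sum_test(y, g2)$p,
               wilcox.test(y[g2], y[!g2], exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-10)
})
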