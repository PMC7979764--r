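# Anchor-based integration of a single-cell reference with spatial spots:
# a joint CCA embedding, mutual-nearest-neighbor anchors scored by
# neighborhood overlap, and kernel-weighted transfer of reference labels
# (prediction scores) or reference cell identities (similarity map).

standardize_genes <- function(X) {
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  sd[sd == 0] <- 1
  (X - mu) / sd
}

l2_normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  M / nrm
}

#' Joint canonical-correlation embedding of reference cells and query spots
#'
#' Both datasets are restricted to their shared genes and gene-standardized
#' within dataset; the top `d` singular vectors of the cross-product
#' \eqn{X^T Y} give paired low-dimensional embeddings in which correlated
#' structure between cells and spots is aligned. Embedding rows are
#' L2-normalized so distances are cosine-equivalent; signs are fixed so each
#' dimension's largest-magnitude reference coordinate is positive.
#'
#' @param ref normalized genes x cells matrix (gene row names required).
#' @param query normalized genes x spots matrix.
#' @param d number of canonical dimensions (default 20); reduced with a
#'   warning when more than the shared gene count allows.
#' @param genes optional gene subset (e.g. shared HVGs) used for the
#'   embedding.
#' @return list of class `cca_embedding`: `ref` (cells x d), `query`
#'   (spots x d), `d`, `singular_values`, `genes` (shared genes used), and
#'   the standardized matrices `ref_std`/`query_std` used downstream for
#'   high-dimensional anchor filtering.
#' @export
cca_embed <- function(ref, query, d = 20L, genes = NULL) {
  shared <- intersect(rownames(ref), rownames(query))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (!length(shared)) stop("no shared genes between reference and query")
  if (length(shared) < d) {
    warning("only ", length(shared), " shared genes; reducing d from ", d)
    d <- length(shared)
  }
  X <- standardize_genes(as.matrix(ref[shared, , drop = FALSE]))
  Y <- standardize_genes(as.matrix(query[shared, , drop = FALSE]))
  M <- crossprod(X, Y)                       # cells x spots
  d <- min(d, dim(M))
  sv <- svd(M, nu = d, nv = d)
  U <- sv$u; V <- sv$v
  for (j in seq_len(d)) {
    if (U[which.max(abs(U[, j])), j] < 0) {
      U[, j] <- -U[, j]; V[, j] <- -V[, j]
    }
  }
  U <- l2_normalize_rows(U); V <- l2_normalize_rows(V)
  rownames(U) <- colnames(ref); rownames(V) <- colnames(query)
  colnames(U) <- colnames(V) <- paste0("CC", seq_len(d))
  structure(list(ref = U, query = V, d = d,
                 singular_values = sv$d[seq_len(d)],
                 genes = shared, ref_std = X, query_std = Y),
            class = "cca_embedding")
}

cross_dist <- function(A, B) {
  # Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

knn_sets <- function(D, k) {
  # row-wise indices of the k smallest entries
  idx <- apply(D, 1, function(r) order(r)[seq_len(k)])
  if (k == 1) matrix(idx, ncol = 1) else t(idx)
}

#' Find mutual-nearest-neighbor anchors in the joint CCA space
#'
#' An anchor is a (reference cell, query spot) pair that are within each
#' other's `k_anchor` nearest cross-dataset neighbors in the joint
#' embedding. Anchors are optionally filtered for consistency in the
#' high-dimensional shared-gene space (the cell must lie among the spot's
#' `k_filter` nearest reference cells there), then scored by the overlap of
#' the two endpoints' `k_score` neighborhoods in the combined embedding,
#' min-max rescaled to [0, 1] with capping at the 1st and 90th percentiles.
#'
#' @param cca a [cca_embed()] result.
#' @param k_anchor cross-dataset neighbors defining mutuality (default 5).
#' @param k_filter neighbors for the gene-space consistency filter (default
#'   200, capped at the number of reference cells; `NULL` disables).
#' @param k_score neighborhood size for anchor scoring (default 30).
#' @return data.frame of class `AnchorSet` with columns `ref_index`,
#'   `query_index`, `score`; the embedding is carried in attribute `"cca"`.
#' @export
find_anchors <- function(cca, k_anchor = 5L, k_filter = 200L,
                         k_score = 30L) {
  stopifnot(inherits(cca, "cca_embedding"))
  n_ref <- nrow(cca$ref); n_query <- nrow(cca$query)
  k_anchor <- min(k_anchor, n_ref, n_query)
  D <- cross_dist(cca$ref, cca$query)        # cells x spots
  nn_rq <- knn_sets(D, k_anchor)             # per cell: nearest spots
  nn_qr <- knn_sets(t(D), k_anchor)          # per spot: nearest cells

  hits_cell <- rep(seq_len(n_ref), each = k_anchor)
  hits_spot <- as.vector(t(nn_rq))
  mutual <- vapply(seq_along(hits_cell), function(i) {
    hits_cell[i] %in% nn_qr[hits_spot[i], ]
  }, logical(1))
  pairs <- unique(data.frame(ref_index = hits_cell[mutual],
                             query_index = hits_spot[mutual]))
  if (!nrow(pairs))
    stop("no anchors found; try a larger k_anchor")

  if (!is.null(k_filter) && k_filter < n_ref) {
    Dg <- cross_dist(t(cca$query_std), t(cca$ref_std))  # spots x cells
    nn_gene <- knn_sets(Dg, k_filter)
    ok <- vapply(seq_len(nrow(pairs)), function(i) {
      pairs$ref_index[i] %in% nn_gene[pairs$query_index[i], ]
    }, logical(1))
    pairs <- pairs[ok, , drop = FALSE]
    if (!nrow(pairs))
      stop("all anchors removed by the gene-space filter; ",
           "try a larger k_filter")
  }

  E <- rbind(cca$ref, cca$query)
  k_score <- min(k_score, nrow(E) - 1L)
  DE <- as.matrix(stats::dist(E))
  diag(DE) <- Inf
  nbr <- knn_sets(DE, k_score)
  raw <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- nbr[pairs$ref_index[i], ]
    b <- nbr[n_ref + pairs$query_index[i], ]
    length(intersect(a, b))
  }, numeric(1))
  q <- stats::quantile(raw, c(0.01, 0.90), names = FALSE)
  score <- if (q[2] > q[1]) (raw - q[1]) / (q[2] - q[1]) else rep(1, length(raw))
  pairs$score <- pmin(1, pmax(0, score))
  rownames(pairs) <- NULL
  structure(pairs, class = c("AnchorSet", "data.frame"), cca = cca)
}

# Per-spot kernel weights over the k_weight nearest anchors.
# Distance is measured in the CCA embedding between the spot and each
# anchor's query-side position; weights are Gaussian (scale sd_weight),
# multiplied by anchor scores, and normalized to sum 1 per spot.
# Returns a sparse spots x anchors matrix.
anchor_weights <- function(anchors, k_weight = 50L, sd_weight = 1) {
  cca <- attr(anchors, "cca")
  n_query <- nrow(cca$query)
  n_anchor <- nrow(anchors)
  k <- min(k_weight, n_anchor)
  Aq <- cca$query[anchors$query_index, , drop = FALSE]
  D <- cross_dist(cca$query, Aq)             # spots x anchors
  ii <- jj <- integer(n_query * k); xx <- numeric(n_query * k)
  pos <- 0L
  for (s in seq_len(n_query)) {
    near <- order(D[s, ])[seq_len(k)]
    w <- exp(-0.5 * (D[s, near] / sd_weight)^2) * anchors$score[near]
    if (sum(w) == 0) w <- rep(1, k)
    w <- w / sum(w)
    idx <- pos + seq_len(k)
    ii[idx] <- s; jj[idx] <- near; xx[idx] <- w
    pos <- pos + k
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_query, n_anchor))
}

#' Construct a PredictionScores object
#'
#' @param mat spots x types non-negative matrix whose rows sum to 1.
#' @return list of class `PredictionScores` with `matrix`, `type_names`,
#'   `max_label`, `max_score` and a logical `tie` flag (exact argmax ties go
#'   to the lexicographically smallest type).
#' @export
prediction_scores <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  if (length(mat) && min(mat) < -1e-12) stop("scores must be non-negative")
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-9))
    stop("prediction score rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  types <- colnames(mat)
  M <- mat[, order(types), drop = FALSE]
  max_label <- character(nrow(mat)); max_score <- numeric(nrow(mat))
  tie <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    r <- as.numeric(M[i, ])
    mx <- max(r)
    cand <- colnames(M)[r == mx]
    max_label[i] <- cand[1]
    max_score[i] <- mx
    tie[i] <- length(cand) > 1
  }
  structure(list(matrix = mat, type_names = types,
                 max_label = max_label, max_score = max_score, tie = tie),
            class = "PredictionScores")
}

#' @export
print.PredictionScores <- function(x, ...) {
  cat(sprintf("PredictionScores: %d spots x %d types\n",
              nrow(x$matrix), length(x$type_names)))
  invisible(x)
}

#' Transfer reference cell-type labels to spots
#'
#' Each spot's prediction-score row is the kernel-weighted average of the
#' one-hot type vectors of its nearest anchors' reference cells: Gaussian
#' weights over the `k_weight` nearest anchors in CCA space (scale
#' `sd_weight`), multiplied by anchor scores and normalized, so every row
#' sums to 1.
#'
#' @param anchors an [find_anchors()] result.
#' @param ref_labels per-reference-cell type labels (character or factor,
#'   length = number of reference cells).
#' @param k_weight anchors averaged per spot (default 50, capped at the
#'   anchor count).
#' @param sd_weight Gaussian bandwidth in the unit-normalized CCA space
#'   (default 1).
#' @return a [prediction_scores()] object.
#' @export
transfer_labels <- function(anchors, ref_labels, k_weight = 50L,
                            sd_weight = 1) {
  cca <- attr(anchors, "cca")
  if (length(ref_labels) != nrow(cca$ref))
    stop("ref_labels length != number of reference cells")
  if (anyNA(ref_labels)) stop("unknown (NA) label in ref_labels")
  f <- factor(ref_labels)
  W <- anchor_weights(anchors, k_weight, sd_weight)
  onehot <- Matrix::sparseMatrix(i = seq_len(nrow(anchors)),
                                 j = as.integer(f)[anchors$ref_index],
                                 x = 1,
                                 dims = c(nrow(anchors), nlevels(f)))
  scores <- as.matrix(W %*% onehot)
  dimnames(scores) <- list(rownames(cca$query), levels(f))
  prediction_scores(scores)
}

#' Transfer individual cell identities to spots (similarity map)
#'
#' The same kernel machinery as [transfer_labels()], with each reference
#' cell as its own one-hot label: the result is a sparse spots x cells
#' weight matrix whose nonzero support identifies, for every spot, the
#' reference cells it resembles. Collapsing columns by cell type reproduces
#' [transfer_labels()] exactly.
#'
#' @inheritParams transfer_labels
#' @return list of class `SimilarityMap`: `matrix` (sparse spots x cells,
#'   rows sum to 1) and `support` (per-spot integer vector of cells with
#'   nonzero weight).
#' @export
transfer_identity <- function(anchors, k_weight = 50L, sd_weight = 1) {
  cca <- attr(anchors, "cca")
  n_ref <- nrow(cca$ref)
  W <- anchor_weights(anchors, k_weight, sd_weight)
  incidence <- Matrix::sparseMatrix(i = seq_len(nrow(anchors)),
                                    j = anchors$ref_index, x = 1,
                                    dims = c(nrow(anchors), n_ref))
  sim <- Matrix::drop0(methods::as(W %*% incidence, "CsparseMatrix"))
  dimnames(sim) <- list(rownames(cca$query), rownames(cca$ref))
  tm <- methods::as(sim, "TsparseMatrix")
  support <- split(tm@j + 1L, factor(tm@i + 1L, levels = seq_len(nrow(sim))))
  structure(list(matrix = sim, support = support), class = "SimilarityMap")
}

#' Collapse a similarity map to prediction scores by cell type
#'
#' @param sim a [transfer_identity()] result.
#' @param ref_labels per-cell type labels in reference cell order.
#' @return a [prediction_scores()] object.
#' @export
collapse_similarity <- function(sim, ref_labels) {
  stopifnot(inherits(sim, "SimilarityMap"))
  f <- factor(ref_labels)
  group <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                                dims = c(length(f), nlevels(f)))
  scores <- as.matrix(sim$matrix %*% group)
  dimnames(scores) <- list(rownames(sim$matrix), levels(f))
  prediction_scores(scores)
}
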