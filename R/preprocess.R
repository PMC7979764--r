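#' Quality-control configuration
#'
#' Cells are kept when they have at least `min_genes` detected genes AND at
#' most `max_mito_frac` mitochondrial transcript fraction. The conventional
#' thresholds exclude cells with *less than* 200 unique genes or *more than*
#' 20 percent mitochondrial transcripts, so both boundaries are kept:
#' exactly 200 genes or exactly 20% mito survives.
#'
#' @param min_genes minimum detected genes (default 200).
#' @param max_mito_frac maximum mitochondrial fraction (default 0.20).
#' @param mito_genes either a character vector of mitochondrial gene names or
#'   a regular expression applied to gene names (default the "MT-" prefix
#'   convention). Real annotations (e.g. chicken mitochondrial genes) can be
#'   supplied as an explicit set.
#' @return list of class `QCConfig`.
#' @export
qc_config <- function(min_genes = 200L, max_mito_frac = 0.20,
                      mito_genes = "^MT-") {
  stopifnot(min_genes >= 0, max_mito_frac >= 0, max_mito_frac <= 1)
  structure(list(min_genes = as.integer(min_genes),
                 max_mito_frac = max_mito_frac,
                 mito_genes = mito_genes), class = "QCConfig")
}

qc_metrics <- function(m, qc) {
  counts <- m$counts
  mito <- if (length(qc$mito_genes) == 1 && grepl("^\\^", qc$mito_genes[1])) {
    grepl(qc$mito_genes, m$gene_names)
  } else m$gene_names %in% qc$mito_genes
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito_counts <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else rep(0, ncol(counts))
  mito_frac <- ifelse(total > 0, mito_counts / total, 0)
  data.frame(obs_id = m$obs_ids, detected_genes = as.integer(detected),
             total_counts = as.numeric(total), mito_frac = mito_frac)
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' @param m an [expression_matrix()].
#' @param qc a [qc_config()].
#' @param verbose log per-stage kept counts (default TRUE).
#' @return the filtered ExpressionMatrix; the per-observation QC table is
#'   attached as attribute `"qc_metrics"` with a logical `kept` column.
#'   Idempotent: filtering a filtered matrix changes nothing.
#' @export
filter_cells <- function(m, qc = qc_config(), verbose = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  met <- qc_metrics(m, qc)
  keep <- met$detected_genes >= qc$min_genes &
    met$mito_frac <= qc$max_mito_frac
  met$kept <- keep
  if (!any(keep)) warning("QC filter removed every observation")
  if (verbose) {
    if ("stage" %in% colnames(m$obs_meta)) {
      tab <- table(m$obs_meta$stage[keep])
      message("QC kept ", sum(keep), "/", length(keep), " (",
              paste(names(tab), tab, sep = "=", collapse = ", "), ")")
    } else {
      message("QC kept ", sum(keep), "/", length(keep))
    }
  }
  out <- subset_obs(m, which(keep))
  attr(out, "qc_metrics") <- met
  out
}

#' Log-normalize counts
#'
#' Each observation's counts are divided by its total, multiplied by
#' `scale_factor` (default 1e6) and natural-log transformed with a
#' pseudocount of one: `ln(count / total * scale_factor + 1)`. Zero counts
#' stay zero, so the sparsity pattern is preserved.
#'
#' @param m an [expression_matrix()] or a sparse genes x observations count
#'   matrix.
#' @param scale_factor positive scale factor (default 1e6).
#' @return a dgCMatrix of normalized values with the input's dimnames.
#' @export
lognormalize <- function(m, scale_factor = 1e6) {
  stopifnot(scale_factor > 0)
  counts <- if (inherits(m, "ExpressionMatrix")) m$counts else {
    if (!inherits(m, "Matrix")) m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
    methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  }
  if (length(counts@x) && min(counts@x) < 0)
    stop("negative counts are not allowed")
  total <- Matrix::colSums(counts)
  if (any(total == 0))
    warning(sum(total == 0), " observation(s) with zero total counts; ",
            "their normalized values are 0")
  out <- counts
  percol <- diff(counts@p)
  denom <- rep(pmax(total, 1), percol)
  out@x <- log(counts@x / denom * scale_factor + 1)
  out
}

#' Select highly variable genes by standardized variance ("vst")
#'
#' The variance-stabilizing ranking: per-gene mean and variance of raw
#' counts are computed; a loess curve (degree 2, span 0.3) of log10 variance
#' on log10 mean predicts each gene's expected standard deviation; counts are
#' standardized by that sd and clipped above at sqrt(N); genes are ranked by
#' the variance of the standardized values.
#'
#' @param counts raw count matrix (genes x observations) or ExpressionMatrix.
#' @param n_hvg number of genes to keep (default 2000).
#' @param span loess span for the mean-variance trend.
#' @return character vector of selected gene names, highest standardized
#'   variance first; the full ranking table is attached as attribute
#'   `"hvg_table"`. If fewer genes have nonzero variance than `n_hvg`, all of
#'   them are returned with a warning.
#' @export
select_hvg <- function(counts, n_hvg = 2000L, span = 0.3) {
  if (inherits(counts, "ExpressionMatrix")) counts <- counts$counts
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  G <- nrow(counts); N <- ncol(counts)
  gene_names <- rownames(counts)
  if (is.null(gene_names)) gene_names <- as.character(seq_len(G))
  mu <- Matrix::rowSums(counts) / N
  ex2 <- Matrix::rowSums(counts^2) / N
  v <- (ex2 - mu^2) * N / (N - 1)
  ok <- v > 0 & mu > 0
  if (sum(ok) < n_hvg)
    warning("only ", sum(ok), " genes with nonzero variance; returning all")

  fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = span, degree = 2)
  exp_sd <- rep(NA_real_, G)
  exp_sd[ok] <- sqrt(10^stats::fitted(fit))

  clip <- sqrt(N)
  std_var <- rep(0, G)
  tm <- methods::as(counts, "TsparseMatrix")
  gi <- tm@i + 1L
  use <- ok[gi]
  z <- (tm@x[use] - mu[gi[use]]) / exp_sd[gi[use]]
  z <- pmin(z, clip)
  nz_ss <- rep(0, G); nz_n <- rep(0, G)
  agg <- rowsum(cbind(z^2, 1), gi[use])
  at <- as.integer(rownames(agg))
  nz_ss[at] <- agg[, 1]; nz_n[at] <- agg[, 2]
  z0 <- ifelse(ok, -mu / exp_sd, 0)      # standardized value of a zero count
  std_var <- (nz_ss + (N - nz_n) * z0^2) / (N - 1)
  std_var[!ok] <- 0

  ord <- order(-std_var, gene_names)
  take <- head(ord[ok[ord]], min(n_hvg, sum(ok)))
  res <- gene_names[take]
  attr(res, "hvg_table") <- data.frame(
    gene = gene_names, mean = mu, variance = v,
    expected_sd = exp_sd, std_variance = std_var)[ord, ]
  res
}

#' Principal component analysis of normalized expression
#'
#' Genes are centred and scaled to unit variance (values clipped at +/-
#' `clip`), then observations are embedded on the top `n_pcs` components via
#' SVD. Components are ordered by decreasing explained variance; signs are
#' fixed so each component's largest-magnitude gene loading is positive.
#'
#' @param norm normalized genes x observations matrix (dense or sparse).
#' @param genes optional gene subset (names or indices), typically the HVGs.
#' @param n_pcs number of components (default 20); truncated with a warning
#'   when it exceeds the matrix rank.
#' @param clip clipping bound for scaled values (default 10).
#' @return list with `embedding` (observations x n_pcs score matrix),
#'   `loadings` (genes x n_pcs), `sdev` and `var_explained`.
#' @export
run_pca <- function(norm, genes = NULL, n_pcs = 20L, clip = 10) {
  X <- as.matrix(norm)
  if (!is.null(genes)) X <- X[genes, , drop = FALSE]
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  keep <- sd > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance gene(s) dropped before PCA")
    X <- X[keep, , drop = FALSE]; mu <- mu[keep]; sd <- sd[keep]
  }
  Xs <- (X - mu) / sd
  Xs[Xs > clip] <- clip
  Xs[Xs < -clip] <- -clip

  r <- min(dim(Xs)) - 1L
  if (n_pcs > r) {
    warning("n_pcs reduced from ", n_pcs, " to rank ", r)
    n_pcs <- r
  }
  sv <- svd(Xs, nu = n_pcs, nv = n_pcs)
  U <- sv$u; V <- sv$v; d <- sv$d[seq_len(n_pcs)]
  for (j in seq_len(n_pcs)) {
    if (U[which.max(abs(U[, j])), j] < 0) {
      U[, j] <- -U[, j]; V[, j] <- -V[, j]
    }
  }
  emb <- V %*% diag(d, n_pcs)
  rownames(emb) <- colnames(norm)
  colnames(emb) <- paste0("PC", seq_len(n_pcs))
  rownames(U) <- rownames(X)
  colnames(U) <- colnames(emb)
  list(embedding = emb, loadings = U,
       sdev = d / sqrt(ncol(Xs) - 1),
       var_explained = sv$d[seq_len(n_pcs)]^2 / sum(sv$d^2))
}

#' Graph clustering of observations in PC space
#'
#' Builds a k-nearest-neighbor graph (Euclidean distances in the embedding),
#' re-weights edges by the Jaccard overlap of the two endpoints'
#' neighborhoods (shared nearest neighbors, pruning weak edges), and
#' optimizes modularity with the Louvain algorithm at the given resolution.
#' Labels are contiguous integers ordered by decreasing cluster size.
#'
#' @param embedding observations x dims matrix.
#' @param k neighbors for the kNN graph (default 30, the conventional spot
#'   setting).
#' @param resolution Louvain resolution (default 0.5, the conventional spot
#'   setting).
#' @param prune SNN edges with Jaccard below this are dropped (default 1/15).
#' @param seed RNG seed for the community search.
#' @return integer vector of cluster labels (1-based), named by observation.
#' @export
cluster_obs <- function(embedding, k = 30L, resolution = 0.5,
                        prune = 1 / 15, seed = 42L) {
  n <- nrow(embedding)
  if (n < k + 1) stop("need at least k+1 = ", k + 1, " observations")
  d <- as.matrix(stats::dist(embedding))
  # neighborhoods include the observation itself, as is conventional for SNN
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(comm)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relabel[as.character(raw)])
  names(labels) <- rownames(embedding)
  labels
}

#' Annotate clusters with cell types from marker panels
#'
#' Each cluster receives the type whose marker panel has the highest mean
#' scaled (per-gene z-scored) expression in that cluster. Ties go to the
#' lexicographically smallest type name and are flagged. A one-vs-rest
#' Wilcoxon marker table is returned alongside the mapping.
#'
#' @param norm normalized genes x observations matrix with gene row names.
#' @param labels cluster labels from [cluster_obs()].
#' @param marker_panels named list: type -> character vector of marker genes.
#' @param markers compute the Wilcoxon marker table (default TRUE).
#' @return list with `mapping` (data.frame cluster, type, score, tie),
#'   `panel_scores` (clusters x types matrix) and `markers` (see
#'   [find_markers()]).
#' @export
annotate_clusters <- function(norm, labels, marker_panels, markers = TRUE) {
  stopifnot(length(labels) == ncol(norm), length(marker_panels) > 0)
  gene_names <- rownames(norm)
  panels <- lapply(marker_panels, function(gs) {
    absent <- setdiff(gs, gene_names)
    if (length(absent))
      warning("panel gene(s) absent, skipped: ",
              paste(absent, collapse = ", "))
    intersect(gs, gene_names)
  })
  if (all(lengths(panels) == 0)) stop("no panel gene found in the matrix")

  X <- as.matrix(norm)
  mu <- rowMeans(X); sd <- apply(X, 1, stats::sd)
  sd[sd == 0] <- 1
  Z <- (X - mu) / sd
  cl <- sort(unique(labels))
  score <- matrix(NA_real_, length(cl), length(panels),
                  dimnames = list(as.character(cl), names(panels)))
  for (ci in seq_along(cl)) {
    in_cl <- labels == cl[ci]
    for (ty in names(panels)) {
      gs <- panels[[ty]]
      if (length(gs))
        score[ci, ty] <- mean(Z[gs, in_cl, drop = FALSE])
    }
  }
  types <- sort(names(panels))
  pick <- apply(score, 1, function(r) {
    best <- max(r, na.rm = TRUE)
    cand <- sort(names(r)[!is.na(r) & r == best])
    c(cand[1], as.character(length(cand) > 1))
  })
  mapping <- data.frame(cluster = cl, type = pick[1, ],
                        score = score[cbind(seq_along(cl), pick[1, ])],
                        tie = as.logical(pick[2, ]))
  mk <- if (markers) find_markers(norm, labels) else NULL
  list(mapping = mapping, panel_scores = score, markers = mk)
}
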