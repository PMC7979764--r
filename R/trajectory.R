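# Diffusion-potential trajectory embedding. An adaptive-bandwidth
# alpha-decay kernel over kNN distances is symmetrized and row-normalized
# into a diffusion operator; the operator is powered (diffusion time chosen
# at the knee of the von Neumann entropy), log-transformed into potentials,
# and embedded by classical MDS. The first coordinate serves as a proxy for
# developmental time, sign-anchored by stage.

#' Diffusion-potential embedding of cells
#'
#' @param embedding cells x dims matrix (typically PCA scores).
#' @param knn neighbors for the adaptive bandwidth (default 15).
#' @param n_components output dimensions (default 2).
#' @param t diffusion time: `"auto"` picks the knee (maximum second
#'   difference) of the von Neumann entropy over `1:t_max`, or an explicit
#'   positive integer.
#' @param alpha decay exponent of the kernel (default 10).
#' @param eps floor applied before the -log potential transform
#'   (default 1e-7).
#' @param t_max largest diffusion time scanned when `t = "auto"`.
#' @return list of class `diffusion_embedding`: `coords` (cells x
#'   n_components, signs fixed so each component's largest-magnitude entry
#'   is positive), `t`, `P` (the diffusion operator), `P_t` (the powered
#'   operator), `entropy` (von Neumann entropy per scanned t when auto).
#' @export
diffusion_embedding <- function(embedding, knn = 15L, n_components = 2L,
                                t = "auto", alpha = 10, eps = 1e-7,
                                t_max = 60L) {
  n <- nrow(embedding)
  if (knn >= n) stop("knn must be smaller than the number of cells")
  D <- as.matrix(stats::dist(embedding))
  sigma <- apply(D, 1, function(r) sort(r)[knn + 1L])  # k-th neighbor, self excluded
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-12)
  K <- exp(-(sweep(D, 1, sigma, "/"))^alpha)
  K <- (K + t(K)) / 2
  deg <- rowSums(K)
  P <- K / deg

  # symmetric conjugate shares P's eigenvalues; P^t via its eigenvectors
  s <- 1 / sqrt(deg)
  A <- K * outer(s, s)
  eg <- eigen(A, symmetric = TRUE)
  lam <- pmin(eg$values, 1)
  V <- eg$vectors

  entropy <- NULL
  if (identical(t, "auto")) {
    al <- abs(lam)
    entropy <- vapply(seq_len(t_max), function(tt) {
      p <- al^tt
      p <- p / sum(p)
      p <- p[p > 0]
      -sum(p * log(p))
    }, numeric(1))
    if (t_max >= 3) {
      d2 <- diff(diff(entropy))
      t <- which.max(d2) + 1L
    } else t <- 1L
  }
  t <- as.integer(t)
  if (t < 1) stop("t must be a positive integer")

  # P = D^{-1/2} A D^{1/2}, so P^t = D^{-1/2} (V lam^t V') D^{1/2}
  Pt <- sweep(V, 2, lam^t, "*") %*% t(V)
  Pt <- Pt * outer(s, 1 / s)

  pot <- -log(pmax(Pt, eps))
  pd <- stats::dist(pot)
  coords <- stats::cmdscale(pd, k = n_components)
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0)
      coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(embedding)
  colnames(coords) <- paste0("DP", seq_len(ncol(coords)))
  structure(list(coords = coords, t = t, P = P, P_t = Pt,
                 eigenvalues = lam, entropy = entropy),
            class = "diffusion_embedding")
}

#' Extract pseudotime from the first diffusion-potential coordinate
#'
#' Pseudotime is the first embedding coordinate, sign-anchored so the
#' earliest stage's mean precedes the latest stage's mean (mirroring rooting
#' a trajectory at the earliest developmental stage), then min-max rescaled
#' to [0, 1].
#'
#' @param coords embedding matrix (first column used) or a
#'   `diffusion_embedding`.
#' @param stage_labels per-cell stage labels; stage order is the factor
#'   level order when a factor, otherwise the sorted unique values.
#' @return list of class `Pseudotime`: `values` (rescaled, named by cell),
#'   `raw` (the anchored but unscaled coordinate), `flipped`, `stages`
#'   (the stage order used). With a single stage the sign is left as-is
#'   with a warning.
#' @export
extract_pseudotime <- function(coords, stage_labels) {
  if (inherits(coords, "diffusion_embedding")) coords <- coords$coords
  v <- coords[, 1]
  stages <- if (is.factor(stage_labels)) levels(stage_labels) else
    sort(unique(as.character(stage_labels)))
  stages <- stages[stages %in% as.character(stage_labels)]
  flipped <- FALSE
  if (length(stages) < 2) {
    warning("single stage: pseudotime orientation is arbitrary")
  } else {
    first <- as.character(stage_labels) == stages[1]
    last <- as.character(stage_labels) == stages[length(stages)]
    if (mean(v[first]) > mean(v[last])) {
      v <- -v
      flipped <- TRUE
    }
  }
  rng <- range(v)
  values <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0, length(v))
  names(values) <- rownames(coords)
  structure(list(values = values, raw = v, flipped = flipped,
                 stages = stages), class = "Pseudotime")
}

#' Project pseudotime onto tissue spots through the similarity map
#'
#' A spot's pseudotime for a lineage is the unweighted arithmetic mean of
#' the pseudotime of the lineage cells that have nonzero similarity weight
#' with that spot. Spots with no supporting lineage cell are undefined (NA).
#' A similarity-weighted mean is available behind `weighted`.
#'
#' @param sim a [transfer_identity()] similarity map.
#' @param pt a [extract_pseudotime()] result, or a named numeric vector of
#'   per-cell pseudotime (any external ordering can be plugged in).
#' @param lineage_cells cells defining the lineage (names or indices into
#'   the similarity map's columns); default all cells with a pseudotime.
#' @param weighted use similarity weights instead of the plain mean.
#' @return data.frame of class `SpotPseudotime`: `spot`, `value`,
#'   `n_support_cells` (`value` is NA iff `n_support_cells` is 0).
#' @export
spot_pseudotime <- function(sim, pt, lineage_cells = NULL,
                            weighted = FALSE) {
  stopifnot(inherits(sim, "SimilarityMap"))
  values <- if (inherits(pt, "Pseudotime")) pt$values else pt
  M <- sim$matrix
  cells <- colnames(M)
  if (is.null(lineage_cells)) lineage_cells <- names(values)
  if (is.numeric(lineage_cells)) lineage_cells <- cells[lineage_cells]
  lineage_cells <- intersect(lineage_cells, cells)
  lineage_cells <- intersect(lineage_cells, names(values))
  Ml <- M[, lineage_cells, drop = FALSE]
  pv <- values[lineage_cells]

  n_support <- as.integer(Matrix::rowSums(Ml > 0))
  if (all(n_support == 0))
    warning("lineage cells are disjoint from the similarity support: ",
            "all spots undefined")
  out <- numeric(nrow(Ml))
  if (weighted) {
    wsum <- Matrix::rowSums(Ml)
    out <- as.numeric(Ml %*% pv) / ifelse(wsum > 0, wsum, 1)
  } else {
    ind <- Ml
    ind@x <- rep(1, length(ind@x))
    out <- as.numeric(ind %*% pv) / ifelse(n_support > 0, n_support, 1)
  }
  out[n_support == 0] <- NA_real_
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))
  structure(data.frame(spot = ids, value = out,
                       n_support_cells = n_support),
            class = c("SpotPseudotime", "data.frame"))
}

#' Genes trending with pseudotime
#'
#' Spearman correlation of each gene's normalized expression with
#' pseudotime, with permutation p-values (pseudotime permuted `n_perm`
#' times under a fixed seed) and Benjamini-Hochberg q-values. Constant
#' genes are reported with correlation 0 and flagged.
#'
#' @param norm normalized genes x cells matrix with gene row names.
#' @param pt a `Pseudotime` or numeric vector aligned with the columns.
#' @param n_perm permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @return data.frame with `gene`, `rho`, `p`, `q`, `constant`, sorted by p.
#' @export
pseudotime_gene_trends <- function(norm, pt, n_perm = 200L, seed = 1L) {
  values <- if (inherits(pt, "Pseudotime")) pt$values else pt
  X <- as.matrix(norm)
  if (ncol(X) < 10) stop("need at least 10 cells")
  stopifnot(ncol(X) == length(values))
  n <- ncol(X)

  R <- t(apply(X, 1, rank))
  constant <- apply(X, 1, function(x) max(x) == min(x))
  Z <- R - rowMeans(R)
  zs <- sqrt(rowSums(Z^2))
  zs[zs == 0] <- 1
  Z <- Z / zs
  rp <- rank(values)
  zp <- (rp - mean(rp)) / sqrt(sum((rp - mean(rp))^2))
  rho <- as.numeric(Z %*% zp)
  rho[constant] <- 0

  set.seed(seed)
  exceed <- numeric(nrow(X))
  for (b in seq_len(n_perm)) {
    zb <- zp[sample.int(n)]
    rb <- abs(as.numeric(Z %*% zb))
    exceed <- exceed + (rb >= abs(rho) - 1e-12)
  }
  p <- (1 + exceed) / (n_perm + 1)
  p[constant] <- 1
  res <- data.frame(gene = rownames(X), rho = rho, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    constant = constant)
  res[order(res$p), ]
}
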