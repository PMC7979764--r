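# Spot-level statistics over prediction scores: maximum-label maps,
# per-spot cell-type heterogeneity, pairwise colocalization, per-region
# composition and regional differential expression.

#' Label each spot by its maximum prediction score
#'
#' @param scores a [prediction_scores()] object.
#' @return data.frame with `spot` (row name or index), `label`, `score`,
#'   `tie` (exact ties resolved to the lexicographically smallest type and
#'   flagged).
#' @export
label_spots_max <- function(scores) {
  stopifnot(inherits(scores, "PredictionScores"))
  ids <- rownames(scores$matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(scores$matrix)))
  data.frame(spot = ids, label = scores$max_label,
             score = scores$max_score, tie = scores$tie)
}

#' Per-spot cell-type heterogeneity
#'
#' The number of distinct cell types whose prediction score is strictly
#' greater than `threshold` (default 5%) in each spot.
#'
#' @param scores a [prediction_scores()] object.
#' @param threshold proportion in [0, 1); strictly-greater comparison.
#' @return integer vector, one count per spot.
#' @export
heterogeneity <- function(scores, threshold = 0.05) {
  stopifnot(inherits(scores, "PredictionScores"))
  if (threshold >= 1) stop("threshold must be < 1")
  if (threshold < 0) stop("threshold must be >= 0")
  counts <- as.integer(rowSums(scores$matrix > threshold))
  names(counts) <- rownames(scores$matrix)
  counts
}

#' Cell-type colocalization matrix
#'
#' For each spot, the `top_k` cell types by prediction score (zero scores
#' excluded; ties at the cutoff broken by score then type name) contribute
#' one increment to every unordered pair among them; increments accumulate
#' into a symmetric types x types matrix with zero diagonal. A score-weighted
#' variant (increment = the smaller of the pair's two scores) is available
#' behind `weighted`.
#'
#' @param scores a [prediction_scores()] object.
#' @param top_k types considered per spot (default 4; must be >= 2).
#' @param weighted use min-score increments instead of presence counts.
#' @return list of class `ColocalizationMatrix`: `counts` (symmetric
#'   matrix), `normalized` (rows divided by their sums, 0-sum rows left 0),
#'   `n_spots_used` (spots contributing at least one pair), `top_k`.
#' @export
colocalization <- function(scores, top_k = 4L, weighted = FALSE) {
  stopifnot(inherits(scores, "PredictionScores"))
  if (top_k < 2) stop("top_k must be >= 2")
  types <- sort(scores$type_names)
  K <- length(types)
  counts <- matrix(0, K, K, dimnames = list(types, types))
  used <- 0L
  M <- scores$matrix[, types, drop = FALSE]
  for (s in seq_len(nrow(M))) {
    r <- M[s, ]
    nz <- which(r > 0)
    if (length(nz) < 2) next
    ord <- nz[order(-r[nz], types[nz])]
    top <- ord[seq_len(min(top_k, length(ord)))]
    used <- used + 1L
    for (a in seq_len(length(top) - 1)) for (b in (a + 1):length(top)) {
      inc <- if (weighted) min(r[top[a]], r[top[b]]) else 1
      counts[top[a], top[b]] <- counts[top[a], top[b]] + inc
      counts[top[b], top[a]] <- counts[top[b], top[a]] + inc
    }
  }
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs > 0, rs, 1)
  structure(list(counts = counts, normalized = normalized,
                 n_spots_used = used, top_k = as.integer(top_k),
                 weighted = weighted),
            class = "ColocalizationMatrix")
}

#' Mean cell-type composition per anatomical region
#'
#' @param scores a [prediction_scores()] object.
#' @param region_labels per-spot region labels (length = number of spots).
#' @return region x type matrix of mean prediction scores; every row sums
#'   to 1. Empty regions are dropped with a warning.
#' @export
composition_by_region <- function(scores, region_labels) {
  stopifnot(inherits(scores, "PredictionScores"),
            length(region_labels) == nrow(scores$matrix))
  f <- if (is.factor(region_labels)) region_labels else factor(region_labels)
  empty <- setdiff(levels(f), unique(as.character(f)))
  if (length(empty)) {
    warning("empty region(s) dropped: ", paste(empty, collapse = ", "))
    f <- droplevels(f)
  }
  agg <- rowsum(scores$matrix, f) / as.vector(table(f))
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Differential-expression configuration for regional markers
#'
#' @param lfc_threshold minimum log2 fold change for significance
#'   (default 0.5).
#' @param p_threshold maximum raw p-value for significance (default 1e-5,
#'   the conventional volcano threshold).
#' @param adjust multiplicity adjustment method (reported alongside raw p;
#'   default "bonferroni").
#' @return list of class `DEConfig`.
#' @export
de_config <- function(lfc_threshold = 0.5, p_threshold = 1e-5,
                      adjust = "bonferroni") {
  stopifnot(lfc_threshold > 0, p_threshold > 0)
  structure(list(lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                 adjust = adjust), class = "DEConfig")
}

#' Regionally restricted marker genes
#'
#' One-vs-rest two-sided Wilcoxon rank-sum tests per gene for each region of
#' the tissue, with log2 fold changes of mean de-logged expression and a
#' significance flag at the configured thresholds.
#'
#' @param norm normalized genes x spots matrix with gene row names.
#' @param region_labels per-spot region labels; at least two regions with at
#'   least three spots each.
#' @param de a [de_config()].
#' @return data.frame from [find_markers()] plus a logical `significant`
#'   column (`log2_fc > lfc_threshold & p < p_threshold`).
#' @export
regional_markers <- function(norm, region_labels, de = de_config()) {
  stopifnot(inherits(de, "DEConfig"))
  tab <- table(region_labels)
  if (sum(tab >= 3) < 2)
    stop("need at least two regions with at least three spots each")
  res <- find_markers(norm, region_labels, adjust = de$adjust)
  res$significant <- res$log2_fc > de$lfc_threshold & res$p < de$p_threshold
  res
}
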