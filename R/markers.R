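# Wilcoxon rank-sum machinery shared by cluster markers and regional DE.

# Two-sided rank-sum test of x[in_group] vs x[!in_group].
# Exact null (pwilcox) when both groups are <= `exact_max` and there are no
# ties, otherwise normal approximation with tie correction and continuity
# correction -- the same switch-over convention as stats::wilcox.test.
rank_sum_test <- function(x, in_group, exact_max = 50L) {
  n1 <- sum(in_group); n2 <- sum(!in_group)
  r <- rank(x)
  U <- sum(r[in_group]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
    p <- if (U > n1 * n2 / 2) {
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n1, n2)
    }
  } else {
    z <- U - n1 * n2 / 2
    n <- n1 + n2
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = U, p = 1))
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  }
  list(statistic = U, p = min(1, p))
}

# log2 fold change of mean de-logged normalized expression, Seurat-style:
# log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))
log2_fc <- function(x, in_group) {
  log2((mean(expm1(x[in_group])) + 1) / (mean(expm1(x[!in_group])) + 1))
}

#' One-vs-rest Wilcoxon marker genes per cluster
#'
#' For every cluster (or region) and gene, a two-sided Wilcoxon rank-sum
#' test of that group's normalized expression against all other
#' observations, with a log2 fold change of mean de-logged expression and a
#' multiplicity-adjusted p-value.
#'
#' @param norm normalized genes x observations matrix with gene row names.
#' @param labels per-observation group labels.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default "bonferroni", adjusting within each group over genes).
#' @param min_group_size groups smaller than this are skipped with a
#'   warning.
#' @return data.frame with columns `group`, `gene`, `statistic`, `p`,
#'   `log2_fc`, `p_adj`, sorted by group then p. Constant genes get `p = 1`.
#' @export
find_markers <- function(norm, labels, adjust = "bonferroni",
                         min_group_size = 3L) {
  X <- as.matrix(norm)
  gene_names <- rownames(X)
  if (is.null(gene_names)) gene_names <- as.character(seq_len(nrow(X)))
  groups <- sort(unique(labels))
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    in_g <- labels == g
    if (sum(in_g) < min_group_size || sum(!in_g) < min_group_size) {
      warning("group ", g, " skipped: fewer than ", min_group_size,
              " observations on one side")
      next
    }
    stat <- p <- lfc <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      x <- X[i, ]
      if (max(x) == min(x)) {             # constant gene: no evidence
        stat[i] <- sum(in_g) * sum(!in_g) / 2
        p[i] <- 1
        lfc[i] <- 0
        next
      }
      t <- rank_sum_test(x, in_g)
      stat[i] <- t$statistic; p[i] <- t$p
      lfc[i] <- log2_fc(x, in_g)
    }
    out[[gi]] <- data.frame(group = g, gene = gene_names,
                            statistic = stat, p = p, log2_fc = lfc,
                            p_adj = stats::p.adjust(p, method = adjust))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(group = character(0), gene = character(0),
                      statistic = numeric(0), p = numeric(0),
                      log2_fc = numeric(0), p_adj = numeric(0)))
  res[order(res$group, res$p), ]
}
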