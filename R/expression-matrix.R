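#' Construct an ExpressionMatrix
#'
#' The package's core container: a sparse genes x observations matrix of raw
#' non-negative integer counts plus gene and observation annotation. The same
#' container holds dissociated cells (`kind = "cells"`) and barcoded tissue
#' spots (`kind = "spots"`); observations are always columns.
#'
#' @param counts sparse (or coercible) genes x observations matrix of
#'   non-negative counts.
#' @param gene_ids character vector of stable gene identifiers (rows).
#' @param gene_names character vector of display gene symbols; defaults to
#'   `gene_ids`.
#' @param obs_ids character vector of observation barcodes (columns); must be
#'   unique.
#' @param obs_meta data.frame of per-observation annotation (stage, section,
#'   array coordinates for spots); zero-column default.
#' @param kind `"cells"` or `"spots"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `counts` (dgCMatrix), `gene_ids`, `gene_names`, `obs_ids`, `obs_meta`,
#'   `kind`.
#' @export
expression_matrix <- function(counts, gene_ids, gene_names = gene_ids,
                              obs_ids, obs_meta = NULL,
                              kind = c("cells", "spots")) {
  kind <- match.arg(kind)
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length (", length(gene_ids), ") != nrow(counts) (",
         nrow(counts), ")")
  if (length(obs_ids) != ncol(counts))
    stop("obs_ids length (", length(obs_ids), ") != ncol(counts) (",
         ncol(counts), ")")
  if (anyDuplicated(obs_ids))
    stop("duplicate obs_ids are not allowed")
  if (length(counts@x) && min(counts@x) < 0)
    stop("counts must be non-negative")
  if (is.null(obs_meta))
    obs_meta <- data.frame(row.names = obs_ids)
  rownames(counts) <- gene_names   # symbols are the working row names
  colnames(counts) <- obs_ids
  structure(list(counts = counts,
                 gene_ids = as.character(gene_ids),
                 gene_names = as.character(gene_names),
                 obs_ids = as.character(obs_ids),
                 obs_meta = obs_meta,
                 kind = kind),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d genes x %d %s, %d nonzero\n",
              x$kind, nrow(x$counts), ncol(x$counts), x$kind,
              length(x$counts@x)))
  if (ncol(x$obs_meta))
    cat("  obs_meta:", paste(colnames(x$obs_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Subset an ExpressionMatrix by observation
#'
#' @param m ExpressionMatrix.
#' @param keep logical, integer or character index over observations.
#' @return ExpressionMatrix restricted to the selected observations.
#' @export
subset_obs <- function(m, keep) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.character(keep)) keep <- match(keep, m$obs_ids)
  expression_matrix(m$counts[, keep, drop = FALSE],
                    gene_ids = m$gene_ids, gene_names = m$gene_names,
                    obs_ids = m$obs_ids[keep],
                    obs_meta = m$obs_meta[keep, , drop = FALSE],
                    kind = m$kind)
}
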