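# Consensus reference profiles, high-variance gene selection, gene
# restriction.

#' Build consensus cell-type reference profiles
#'
#' The column for a level node is the arithmetic mean of the
#' depth-normalized (counts-per-10k) profiles of all cells whose leaf label
#' descends from that node. Depth normalization makes the consensus
#' scale-free: multiplying all library sizes by a constant leaves it
#' unchanged, and every column sums to 10,000.
#'
#' @param cells a [CellData-class].
#' @param tree a [CellTree-class].
#' @param level character vector of node names (a valid level or any set of
#'   tree nodes), or the name of a declared level of `tree`.
#' @return numeric matrix, genes x level nodes (columns in level order).
#' @export
buildReference <- function(cells, tree, level) {
  if (is.character(level) && length(level) == 1 &&
      level %in% names(treeLevels(tree))) {
    level <- treeLevels(tree)[[level]]
  }
  counts <- cellCounts(cells)
  labels <- cellLabels(cells)
  depths <- colSums(counts)
  if (any(depths == 0)) {
    stop(sprintf("%d cell(s) with zero total counts", sum(depths == 0)),
         call. = FALSE)
  }
  norm <- sweep(counts, 2, depths / 1e4, "/")
  ref <- matrix(0, nrow(counts), length(level),
                dimnames = list(rownames(counts), level))
  for (v in level) {
    idx <- labels %in% descendantLeaves(tree, v)
    if (!any(idx)) {
      stop(sprintf("no cells for node '%s'", v), call. = FALSE)
    }
    ref[, v] <- rowMeans(norm[, idx, drop = FALSE])
  }
  ref
}

#' Select the highest-variance genes of a reference matrix
#'
#' Ranks genes by their variance across the reference columns (cell types),
#' descending, ties broken by input order, and returns the top `k` gene
#' ids. Default `k` keeps 5000 genes.
#'
#' @param ref genes x cell-types matrix with gene rownames.
#' @param k number of genes to keep; `k >= nrow(ref)` returns all genes.
#' @return character vector of gene ids, ordered by decreasing variance.
#' @export
selectTopVarianceGenes <- function(ref, k = 5000) {
  stopifnot(k >= 1)
  m <- rowMeans(ref)
  v <- rowSums((ref - m)^2) / (ncol(ref) - 1)
  ord <- order(-v)  # radix sort: stable, ties keep input order
  rownames(ref)[ord[seq_len(min(k, nrow(ref)))]]
}

#' Restrict a matrix to a gene index
#'
#' Subsets and reorders the rows of a reference or bulk matrix to the given
#' gene index, so that all matrices entering a fit share one gene space.
#'
#' @param m genes x anything matrix with gene rownames.
#' @param genes character vector of gene ids, all present in `m`.
#' @return the row-subset matrix, rows in `genes` order.
#' @export
restrictGenes <- function(m, genes) {
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    stop(sprintf("gene(s) absent from matrix: %s%s",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""), call. = FALSE)
  }
  m[genes, , drop = FALSE]
}
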