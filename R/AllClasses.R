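#' @import methods
NULL

#' Cell-type hierarchy
#'
#' A rooted forest of cell types together with an ordered list of declared
#' resolution levels. Leaves are the finest cell types; internal nodes are
#' coarser populations. A *level* is an antichain of nodes that covers every
#' leaf exactly once (a node without a subdivision at some level simply
#' stands for itself there, so the same node may appear in several levels).
#'
#' @slot nodes character vector of all node names (unique across the tree),
#'   in document order.
#' @slot parent named character vector mapping each node to its parent;
#'   `NA` for roots.
#' @slot children named list mapping each node to the character vector of
#'   its children (in document order); empty vector for leaves.
#' @slot levels named list of character vectors, ordered from coarsest to
#'   finest; each entry is a valid level (antichain covering all leaves).
#'
#' @seealso [readCellTree()], [cellTree()], [aggregateProportions()]
#' @export
setClass("CellTree",
  representation(
    nodes = "character",
    parent = "character",
    children = "list",
    levels = "list"
  )
)

#' Annotated single-cell expression data
#'
#' A genes x cells matrix of non-negative integer counts plus one leaf-level
#' cell-type label per cell. Stands in for an annotated single-cell
#' compendium: the simulator produces objects of this class, and the
#' reference builder and pseudo-bulk generator consume them.
#'
#' @slot counts numeric matrix, genes x cells, non-negative; rownames are
#'   gene ids, colnames are cell ids.
#' @slot labels character vector, one leaf cell-type name per cell.
#'
#' @seealso [simulateCells()], [buildReference()], [makePseudoBulks()]
#' @export
setClass("CellData",
  representation(
    counts = "matrix",
    labels = "character"
  )
)

#' Trained hierarchical deconvolution model
#'
#' Holds everything needed to deconvolve new bulks: the tree and its levels,
#' the shared gene index, per-level consensus reference matrices, and per
#' node the learned gene weights plus the per-child affine rescaling
#' parameters (slope theta, intercept delta) fitted on the training
#' mixtures.
#'
#' @slot tree a [CellTree-class].
#' @slot levels named list of character vectors (coarse to fine) actually
#'   used for fitting.
#' @slot genes character vector, the shared (variance-filtered) gene index.
#' @slot references named list of genes x types matrices, one per level.
#' @slot rootModel list with elements `types`, `weights`, `rescale`.
#' @slot nodeModels named list (one entry per fitted internal node) with
#'   elements `node`, `level` (index of the parent level), `children`,
#'   `weights`, `rescale`.
#' @slot config list of fitting options recorded for reproducibility.
#'
#' @seealso [hideFit()], [hidePredict()], [saveHideModel()]
#' @export
setClass("HideModel",
  representation(
    tree = "CellTree",
    levels = "list",
    genes = "character",
    references = "list",
    rootModel = "list",
    nodeModels = "list",
    config = "list"
  )
)

setValidity("CellTree", function(object) {
  msg <- character()
  n <- object@nodes
  if (length(n) == 0) msg <- c(msg, "tree has no nodes")
  if (anyDuplicated(n)) {
    msg <- c(msg, sprintf("duplicate node name(s): %s",
                          paste(unique(n[duplicated(n)]), collapse = ", ")))
  }
  if (!identical(sort(names(object@parent)), sort(n)) ||
      !identical(sort(names(object@children)), sort(n))) {
    msg <- c(msg, "parent/children maps must cover exactly the node set")
  } else {
    p <- object@parent
    bad <- p[!is.na(p) & !(p %in% n)]
    if (length(bad)) {
      msg <- c(msg, sprintf("unknown parent(s): %s", paste(bad, collapse = ", ")))
    }
    # acyclicity: walk up from every node, bounded by node count
    for (v in n) {
      seen <- character()
      cur <- v
      while (!is.na(p[[cur]])) {
        if (cur %in% seen) {
          msg <- c(msg, sprintf("cycle detected at node '%s'", v))
          break
        }
        seen <- c(seen, cur)
        cur <- p[[cur]]
        if (length(seen) > length(n)) break
      }
    }
    if (length(treeLeaves(object)) == 0) msg <- c(msg, "tree has no leaves")
    for (lv in names(object@levels)) {
      err <- .checkLevel(object, object@levels[[lv]])
      if (!is.null(err)) msg <- c(msg, sprintf("level '%s': %s", lv, err))
    }
  }
  if (length(msg)) msg else TRUE
})

setValidity("CellData", function(object) {
  msg <- character()
  if (ncol(object@counts) != length(object@labels)) {
    msg <- c(msg, "one label per cell required")
  }
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (is.null(rownames(object@counts))) msg <- c(msg, "counts need gene rownames")
  if (length(msg)) msg else TRUE
})
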