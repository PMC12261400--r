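# Cell-type tree: construction, queries, level handling, aggregation.

#' Construct a cell-type tree from nested lists
#'
#' @param roots a list of nodes, each a list with a `name` (string) and an
#'   optional `children` list of nodes of the same shape.
#' @param levels optional named list of character vectors declaring the
#'   resolution levels, ordered coarsest to finest. When omitted, levels are
#'   derived from tree depth ([defaultLevels()]).
#' @return a [CellTree-class] object.
#' @examples
#' tr <- cellTree(list(
#'   list(name = "Immune", children = list(list(name = "T"), list(name = "B"))),
#'   list(name = "Stromal")))
#' treeLeaves(tr)
#' @export
cellTree <- function(roots, levels = NULL) {
  nodes <- character()
  parent <- character()
  children <- list()
  add <- function(node, par) {
    nm <- node$name
    if (is.null(nm) || !nzchar(nm)) stop("tree node without a name", call. = FALSE)
    if (nm %in% nodes) stop(sprintf("duplicate node name '%s'", nm), call. = FALSE)
    nodes <<- c(nodes, nm)
    parent[nm] <<- if (is.null(par)) NA_character_ else par
    kids <- node$children
    children[[nm]] <<- character()
    if (!is.null(kids) && length(kids)) {
      for (k in kids) add(k, nm)
      children[[nm]] <<- vapply(kids, function(x) x$name, character(1))
    }
  }
  if (length(roots) == 0) stop("empty tree", call. = FALSE)
  for (r in roots) add(r, NULL)
  tr <- new("CellTree", nodes = nodes, parent = parent,
            children = children, levels = list())
  lv <- if (is.null(levels)) defaultLevels(tr) else levels
  if (is.null(names(lv)) || any(!nzchar(names(lv)))) {
    names(lv) <- paste0("level", seq_along(lv))
  }
  tr@levels <- lapply(lv, as.character)
  validObject(tr)
  tr
}

#' Read a cell-type tree from a JSON document
#'
#' The document holds the nodes under `"roots"` (each node an object with
#' `"name"` and optional `"children"`) and, optionally, declared resolution
#' levels under `"levels"` as an ordered array of `{"name":..., "nodes":
#' [...]}` objects. Declared levels let a node stand for itself at a finer
#' level when it has no subdivision there, without inserting phantom nodes.
#'
#' @param path path to a JSON file (UTF-8).
#' @return a [CellTree-class].
#' @seealso [breastCellTree()] for the packaged breast-tissue hierarchy.
#' @export
readCellTree <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  roots <- doc$roots
  if (is.null(roots)) stop("tree document has no 'roots' entry", call. = FALSE)
  levels <- NULL
  if (!is.null(doc$levels)) {
    levels <- lapply(doc$levels, function(l) unlist(l$nodes, use.names = FALSE))
    names(levels) <- vapply(doc$levels, function(l) l$name, character(1))
  }
  cellTree(roots, levels)
}

#' Write a cell-type tree to JSON
#'
#' Inverse of [readCellTree()]: emits the nested `roots` representation and
#' the declared levels.
#'
#' @param tree a [CellTree-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCellTree <- function(tree, path) {
  asNode <- function(v) {
    kids <- tree@children[[v]]
    if (length(kids) == 0) list(name = v)
    else list(name = v, children = lapply(kids, asNode))
  }
  doc <- list(
    roots = lapply(treeRoots(tree), asNode),
    levels = lapply(names(tree@levels), function(nm) {
      list(name = nm, nodes = as.list(tree@levels[[nm]]))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The packaged breast-tissue cell-type hierarchy
#'
#' Three declared levels (major, minor, sub_minor) with 9, 13 and 34 cell
#' types; transcribed from the annotation hierarchy of a public breast
#' single-cell compendium. Two major types subdivide at the minor level and
#' 11 of the 13 minor types subdivide further.
#'
#' @return a [CellTree-class].
#' @export
breastCellTree <- function() {
  readCellTree(system.file("extdata", "breast_cell_tree.json",
                           package = "hideconv", mustWork = TRUE))
}

#' The packaged synthetic benchmark hierarchy
#'
#' A three-level tree (4 major, 7 minor, 10 leaf types) used by the
#' simulation benchmark; entirely synthetic, with types named for the
#' tissue roles they mimic.
#'
#' @return a [CellTree-class].
#' @export
syntheticBenchmarkTree <- function() {
  readCellTree(system.file("extdata", "synthetic_benchmark_tree.json",
                           package = "hideconv", mustWork = TRUE))
}

# ---- queries ---------------------------------------------------------------

#' Tree accessors
#'
#' `treeNodes`, `treeRoots` and `treeLeaves` return node name vectors;
#' `treeChildren` and `treeParent` query one node; `treeLevels` returns the
#' named list of declared levels; `descendantLeaves` returns the leaves at
#' or below a node.
#'
#' @param tree a [CellTree-class].
#' @param node a node name.
#' @return character vector(s) of node names; `treeParent` returns `NA` for
#'   a root; `treeLevels` a named list.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
treeNodes <- function(tree) tree@nodes

#' @rdname tree-accessors
#' @export
treeRoots <- function(tree) tree@nodes[is.na(tree@parent[tree@nodes])]

#' @rdname tree-accessors
#' @export
treeLeaves <- function(tree) {
  tree@nodes[vapply(tree@children[tree@nodes], length, integer(1)) == 0]
}

#' @rdname tree-accessors
#' @export
treeChildren <- function(tree, node) {
  .checkNode(tree, node)
  tree@children[[node]]
}

#' @rdname tree-accessors
#' @export
treeParent <- function(tree, node) {
  .checkNode(tree, node)
  unname(tree@parent[[node]])
}

#' @rdname tree-accessors
#' @export
treeLevels <- function(tree) tree@levels

#' @rdname tree-accessors
#' @export
descendantLeaves <- function(tree, node) {
  .checkNode(tree, node)
  kids <- tree@children[[node]]
  if (length(kids) == 0) return(node)
  unlist(lapply(kids, descendantLeaves, tree = tree), use.names = FALSE)
}

.checkNode <- function(tree, node) {
  if (!(node %in% tree@nodes)) {
    stop(sprintf("unknown tree node '%s'", node), call. = FALSE)
  }
}

# ancestors of v including v itself, leaf-to-root order
.selfAndAncestors <- function(tree, v) {
  out <- v
  while (!is.na(tree@parent[[v]])) {
    v <- tree@parent[[v]]
    out <- c(out, v)
  }
  out
}

# NULL when `level` is a valid antichain covering all leaves, else message
.checkLevel <- function(tree, level) {
  if (!all(level %in% tree@nodes)) {
    return(sprintf("unknown node(s): %s",
                   paste(setdiff(level, tree@nodes), collapse = ", ")))
  }
  for (leaf in treeLeaves(tree)) {
    hits <- intersect(.selfAndAncestors(tree, leaf), level)
    if (length(hits) != 1) {
      return(sprintf("leaf '%s' is covered by %d level node(s), need exactly 1",
                     leaf, length(hits)))
    }
  }
  NULL
}

#' Derive resolution levels from tree depth
#'
#' Level d contains every node at depth d plus every leaf shallower than d
#' (a leaf keeps standing for itself at all finer levels). Produces as many
#' levels as the tree is deep.
#'
#' @param tree a [CellTree-class].
#' @return named list of character vectors, coarse to fine.
#' @export
defaultLevels <- function(tree) {
  depth <- vapply(tree@nodes, function(v) length(.selfAndAncestors(tree, v)),
                  integer(1))
  names(depth) <- tree@nodes
  leaves <- treeLeaves(tree)
  maxd <- max(depth)
  lv <- lapply(seq_len(maxd), function(d) {
    tree@nodes[depth == d | (tree@nodes %in% leaves & depth < d)]
  })
  names(lv) <- paste0("level", seq_len(maxd))
  lv
}

# For node k standing at level l, the nodes of the next (finer) level that
# descend from (or are) k. Passthrough => the node itself.
.standsBelow <- function(tree, k, nextLevel) {
  if (k %in% nextLevel) return(k)
  nextLevel[vapply(nextLevel, function(v) k %in% .selfAndAncestors(tree, v),
                   logical(1))]
}

# map each node of `level` to its unique node in coarser `upper`
.levelParentMap <- function(tree, level, upper) {
  vapply(level, function(v) {
    hit <- intersect(.selfAndAncestors(tree, v), upper)
    if (length(hit) != 1) {
      stop(sprintf("levels are not nested at node '%s'", v), call. = FALSE)
    }
    hit
  }, character(1))
}

# ---- aggregation -----------------------------------------------------------

#' Aggregate leaf proportions to a coarser level
#'
#' Each level node's row is the sum of the rows of its descendant leaves
#' (or its own row if it is itself a leaf). Column totals are preserved
#' exactly, so proportions that sum to one stay summing to one.
#'
#' @param C numeric matrix, leaves x samples, rownames = leaf names.
#' @param tree a [CellTree-class].
#' @param level character vector of node names forming a valid level, or the
#'   name of a declared level of `tree`.
#' @return numeric matrix, level nodes x samples.
#' @examples
#' tr <- cellTree(list(
#'   list(name = "P", children = list(list(name = "a"), list(name = "b"))),
#'   list(name = "c")))
#' C <- matrix(c(0.2, 0.3, 0.5), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
#' aggregateProportions(C, tr, c("P", "c"))
#' @export
aggregateProportions <- function(C, tree, level) {
  if (is.character(level) && length(level) == 1 && level %in% names(tree@levels)) {
    level <- tree@levels[[level]]
  }
  err <- .checkLevel(tree, level)
  if (!is.null(err)) stop(err, call. = FALSE)
  leaves <- rownames(C)
  if (is.null(leaves)) stop("proportion matrix needs leaf rownames", call. = FALSE)
  missing <- setdiff(leaves, treeLeaves(tree))
  if (length(missing)) {
    stop(sprintf("row(s) not leaves of the tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- matrix(0, nrow = length(level), ncol = ncol(C),
                dimnames = list(level, colnames(C)))
  for (v in level) {
    dl <- intersect(descendantLeaves(tree, v), leaves)
    if (length(dl) == 1) out[v, ] <- C[dl, ]
    else if (length(dl) > 1) out[v, ] <- colSums(C[dl, , drop = FALSE])
  }
  out
}

#' @describeIn CellTree-class compact display of node and level counts.
#' @param object a `CellTree`.
#' @export
setMethod("show", "CellTree", function(object) {
  cat(sprintf("CellTree: %d nodes, %d roots, %d leaves\n",
              length(object@nodes), length(treeRoots(object)),
              length(treeLeaves(object))))
  for (nm in names(object@levels)) {
    cat(sprintf("  level '%s': %d types\n", nm, length(object@levels[[nm]])))
  }
})

#' @describeIn CellData-class dimensions and label summary.
#' @param object a `CellData`.
#' @export
setMethod("show", "CellData", function(object) {
  cat(sprintf("CellData: %d genes x %d cells, %d cell types\n",
              nrow(object@counts), ncol(object@counts),
              length(unique(object@labels))))
})

#' CellData accessors
#'
#' @param x a [CellData-class].
#' @return `cellCounts` the genes x cells count matrix; `cellLabels` the
#'   per-cell leaf labels.
#' @export
cellCounts <- function(x) x@counts

#' @rdname cellCounts
#' @export
cellLabels <- function(x) x@labels
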