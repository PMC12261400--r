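# Synthetic hierarchical single-cell data and pseudo-bulk mixtures with
# known ground-truth composition. Emulates an annotated single-cell
# compendium: expression means are structured along the cell-type tree
# (children perturb a random marker subset of their parent's mean in log
# space), counts are negative binomial, and pseudo-bulks are sums of cells
# drawn uniformly from the pool.

# derive independent sub-seeds from one user seed (kept below 2^31)
.deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.paramAtDepth <- function(x, depth) x[min(depth, length(x))]

#' Simulate annotated single-cell counts along a cell-type tree
#'
#' Every tree node perturbs a random marker subset of its parent's mean
#' profile by `effectSize` (natural-log fold change) in log space, so
#' sibling types share most of their profile and types deep in the tree are
#' harder to tell apart than major populations -- the structure real
#' lineage-annotated data shows. Counts are negative binomial around the
#' leaf profile scaled to a per-cell library size.
#'
#' `markerFraction` and `effectSize` may be vectors indexed by node depth
#' (root = 1; the last value is recycled for deeper nodes), so separation
#' can decay down the tree.
#'
#' @param tree a [CellTree-class].
#' @param nGenes number of genes.
#' @param cellsPerLeaf cells simulated per leaf type.
#' @param markerFraction fraction of genes perturbed per node, by depth.
#' @param effectSize natural-log fold change applied to markers, by depth.
#' @param dispersion negative-binomial dispersion (NB size = 1/dispersion).
#' @param depthMean mean per-cell library size (counts).
#' @param seed integer seed; output is fully reproducible.
#' @return a [CellData-class].
#' @export
simulateCells <- function(tree, nGenes = 1000, cellsPerLeaf = 200,
                          markerFraction = c(0.20, 0.05, 0.02),
                          effectSize = c(1.5, 1.0, 0.8),
                          dispersion = 0.5, depthMean = 2000, seed = 1L) {
  stopifnot(nGenes >= 1, cellsPerLeaf >= 1, all(markerFraction >= 0),
            all(markerFraction <= 1), all(effectSize >= 0),
            dispersion > 0, depthMean > 0)
  seeds <- .deriveSeeds(seed, 2)
  genes <- sprintf("g%05d", seq_len(nGenes))

  set.seed(seeds[1])
  baseLog <- stats::rnorm(nGenes, mean = 0, sd = 1.5)
  logProf <- list()
  walk <- function(node, parentLog, depth) {
    mf <- .paramAtDepth(markerFraction, depth)
    es <- .paramAtDepth(effectSize, depth)
    nMark <- round(mf * nGenes)
    lp <- parentLog
    if (nMark > 0 && es > 0) {
      idx <- sample.int(nGenes, nMark)
      lp[idx] <- lp[idx] + sample(c(-es, es), nMark, replace = TRUE)
    }
    kids <- treeChildren(tree, node)
    if (length(kids) == 0) logProf[[node]] <<- lp
    else for (k in kids) walk(k, lp, depth + 1)
  }
  for (r in treeRoots(tree)) walk(r, baseLog, 1)

  leaves <- treeLeaves(tree)
  nCells <- cellsPerLeaf * length(leaves)
  labels <- rep(leaves, each = cellsPerLeaf)

  set.seed(seeds[2])
  libSizes <- stats::rgamma(nCells, shape = 10, rate = 10 / depthMean)
  counts <- matrix(0L, nGenes, nCells,
                   dimnames = list(genes, sprintf("cell%06d", seq_len(nCells))))
  size <- 1 / dispersion
  for (li in seq_along(leaves)) {
    prof <- exp(logProf[[leaves[li]]])
    prof <- prof / sum(prof)
    cols <- seq.int((li - 1) * cellsPerLeaf + 1, li * cellsPerLeaf)
    mu <- prof %o% libSizes[cols]
    counts[, cols] <- stats::rnbinom(length(mu), mu = mu, size = size)
  }
  new("CellData", counts = counts, labels = labels)
}

#' Split annotated cells into equal training and testing halves
#'
#' Stratified per leaf type: each type contributes half of its cells to
#' each side, so the two halves are equally sized and equally distributed.
#' Odd counts assign the extra cell to one side by a seeded draw.
#'
#' @param cells a [CellData-class]; every type needs at least 2 cells.
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both [CellData-class];
#'   disjoint, union = input.
#' @export
splitTrainTest <- function(cells, seed = 1L) {
  labels <- cellLabels(cells)
  set.seed(as.integer(seed))
  trainIdx <- integer()
  for (type in unique(labels)) {
    idx <- which(labels == type)
    if (length(idx) < 2) {
      stop(sprintf("cell type '%s' has only %d cell(s); need at least 2",
                   type, length(idx)), call. = FALSE)
    }
    idx <- sample(idx)
    k <- length(idx) %/% 2
    if (length(idx) %% 2 == 1 && stats::runif(1) < 0.5) k <- k + 1
    trainIdx <- c(trainIdx, idx[seq_len(k)])
  }
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_along(labels), trainIdx)
  list(
    train = new("CellData", counts = cellCounts(cells)[, trainIdx, drop = FALSE],
                labels = labels[trainIdx]),
    test = new("CellData", counts = cellCounts(cells)[, testIdx, drop = FALSE],
               labels = labels[testIdx])
  )
}

#' Build pseudo-bulk mixtures with known composition
#'
#' Each bulk draws `cellsPerBulk` cells uniformly at random from the whole
#' pool (without replacement within a bulk, with replacement across bulks)
#' and sums their count vectors. The ground-truth proportion of a leaf type
#' in a bulk is the number of its cells drawn divided by `cellsPerBulk`, so
#' truth columns sum to one exactly.
#'
#' @param cells a [CellData-class].
#' @param nBulks number of mixtures.
#' @param cellsPerBulk cells per mixture (default 100).
#' @param seed integer seed.
#' @return list with `bulks` (genes x bulks matrix) and `proportions`
#'   (leaf types x bulks matrix, columns summing to 1).
#' @export
makePseudoBulks <- function(cells, nBulks, cellsPerBulk = 100, seed = 1L) {
  if (nBulks < 1 || cellsPerBulk < 1) {
    stop("nBulks and cellsPerBulk must be >= 1", call. = FALSE)
  }
  counts <- cellCounts(cells)
  labels <- cellLabels(cells)
  nCells <- ncol(counts)
  if (cellsPerBulk > nCells) {
    stop("cellsPerBulk exceeds the number of available cells", call. = FALSE)
  }
  set.seed(as.integer(seed))
  draws <- replicate(nBulks, sample.int(nCells, cellsPerBulk), simplify = FALSE)
  ind <- Matrix::sparseMatrix(
    i = unlist(draws), j = rep(seq_len(nBulks), each = cellsPerBulk), x = 1,
    dims = c(nCells, nBulks))
  bulkIds <- sprintf("bulk%05d", seq_len(nBulks))
  bulks <- as.matrix(counts %*% ind)
  colnames(bulks) <- bulkIds
  types <- sort(unique(labels))
  prop <- vapply(draws, function(d) {
    tabulate(factor(labels[d], levels = types), nbins = length(types))
  }, numeric(length(types))) / cellsPerBulk
  dimnames(prop) <- list(types, bulkIds)
  list(bulks = bulks, proportions = prop)
}

#' Simulate a full training/validation dataset
#'
#' One call that emulates the whole data design: simulate annotated cells,
#' split them 50/50 into training and testing cohorts, build training
#' mixtures from the training half and test batches from the testing half.
#' One global seed drives cell simulation, split, and all bulk sampling via
#' independent derived streams.
#'
#' @param tree a [CellTree-class].
#' @param nTrainBulks training mixtures (default 20000).
#' @param nTestBulks mixtures per test batch (default 1000).
#' @param testBatches number of test batches (default 10).
#' @param cellsPerBulk cells per mixture (default 100).
#' @param seed integer seed.
#' @param ... further arguments passed to [simulateCells()].
#' @return list with `cellsTrain`, `cellsTest` ([CellData-class]), `train`
#'   (list of `bulks`, `proportions`) and `test` (list of such lists, one
#'   per batch).
#' @export
simulateHideDataset <- function(tree, nTrainBulks = 20000, nTestBulks = 1000,
                                testBatches = 10, cellsPerBulk = 100,
                                seed = 1L, ...) {
  seeds <- .deriveSeeds(seed, 3 + testBatches)
  cells <- simulateCells(tree, seed = seeds[1], ...)
  halves <- splitTrainTest(cells, seed = seeds[2])
  train <- makePseudoBulks(halves$train, nTrainBulks, cellsPerBulk,
                           seed = seeds[3])
  test <- lapply(seq_len(testBatches), function(b) {
    makePseudoBulks(halves$test, nTestBulks, cellsPerBulk, seed = seeds[3 + b])
  })
  list(cellsTrain = halves$train, cellsTest = halves$test,
       train = train, test = test)
}
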