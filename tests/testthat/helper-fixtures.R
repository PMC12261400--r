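# Shared fixtures. The heavier simulated-benchmark objects are built once
# per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# small 3-level tree: 3 majors, nested subdivisions, one flat root
smallTree <- function() {
  cellTree(list(
    list(name = "A", children = list(
      list(name = "A1", children = list(list(name = "A1a"),
                                        list(name = "A1b"))),
      list(name = "A2"))),
    list(name = "B", children = list(list(name = "B1"), list(name = "B2"))),
    list(name = "C")
  ), levels = list(
    major = c("A", "B", "C"),
    minor = c("A1", "A2", "B", "C"),
    leaf  = c("A1a", "A1b", "A2", "B1", "B2", "C")
  ))
}

# tree with a single-child node (A1 -> only A1a)
singleChildTree <- function() {
  cellTree(list(
    list(name = "A", children = list(
      list(name = "A1", children = list(list(name = "A1a"))),
      list(name = "A2"))),
    list(name = "B")
  ), levels = list(
    major = c("A", "B"),
    minor = c("A1", "A2", "B"),
    leaf  = c("A1a", "A2", "B")
  ))
}

# simulation benchmark at the default (realistic) generator conditions:
# hierarchy-structured means, NB noise, 100-cell mixtures
benchmarkFixture <- function() {
  if (!is.null(.fixtures$bm)) return(.fixtures$bm)
  tree <- syntheticBenchmarkTree()
  ds <- simulateHideDataset(tree, nTrainBulks = 2000, nTestBulks = 200,
                            testBatches = 2, cellsPerBulk = 100,
                            seed = 20240901, nGenes = 1000, cellsPerLeaf = 300)
  opts <- trainOptions(maxIters = 300)
  model <- suppressMessages(suppressWarnings(
    hideFit(ds$cellsTrain, tree, ds$train$bulks, ds$train$proportions,
            topK = 600, opts = opts)))
  preds <- lapply(ds$test, function(b) hidePredict(model, b$bulks))
  .fixtures$bm <- list(tree = tree, ds = ds, opts = opts, model = model,
                       preds = preds)
  .fixtures$bm
}

# same data, ablated fits
ablationFixture <- function() {
  if (!is.null(.fixtures$ab)) return(.fixtures$ab)
  bm <- benchmarkFixture()
  .fixtures$ab <- lapply(c(flat = "flat", no_residual = "no_residual"),
    function(v) {
      ab <- suppressMessages(suppressWarnings(
        hideAblation(v, bm$ds$cellsTrain, bm$tree, bm$ds$train$bulks,
                     bm$ds$train$proportions, topK = 600, opts = bm$opts)))
      list(fit = ab, preds = lapply(bm$ds$test,
                                    function(b) ab$testPredict(b$bulks)))
    })
  .fixtures$ab
}

# well-separated regime (strong markers, low dispersion): the conditions
# under which parameter recovery is checked
recoveryFixture <- function() {
  if (!is.null(.fixtures$rec)) return(.fixtures$rec)
  tree <- syntheticBenchmarkTree()
  ds <- simulateHideDataset(tree, nTrainBulks = 2000, nTestBulks = 200,
                            testBatches = 1, cellsPerBulk = 100, seed = 11,
                            nGenes = 800, cellsPerLeaf = 300,
                            markerFraction = c(0.35, 0.2, 0.15),
                            effectSize = c(3, 2.5, 2.5), dispersion = 0.05,
                            depthMean = 4000)
  model <- suppressMessages(suppressWarnings(
    hideFit(ds$cellsTrain, tree, ds$train$bulks, ds$train$proportions,
            topK = 500, opts = trainOptions(maxIters = 300))))
  .fixtures$rec <- list(tree = tree, ds = ds, model = model)
  .fixtures$rec
}

# quick deterministic cell pool on a given tree
tinyCells <- function(tree, seed = 3, nGenes = 120, cellsPerLeaf = 40) {
  simulateCells(tree, nGenes = nGenes, cellsPerLeaf = cellsPerLeaf,
                seed = seed)
}

# independent brute-force oracle: grid search over the non-negative
# quadrant for a 2-type weighted least-squares problem
gridNnls <- function(X, y, g, lo = 0, hi = 4, step = 1e-3) {
  obj <- function(c1, c2) {
    r <- y - X[, 1] * c1 - X[, 2] * c2
    sum((g * r)^2)
  }
  refine <- function(lo1, hi1, lo2, hi2, by) {
    c1s <- seq(lo1, hi1, by = by)
    c2s <- seq(lo2, hi2, by = by)
    vals <- outer(c1s, c2s, Vectorize(obj))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    c(c1s[ij[1]], c2s[ij[2]])
  }
  best <- refine(lo, hi, lo, hi, 0.01)
  refine(max(lo, best[1] - 0.02), min(hi, best[1] + 0.02),
         max(lo, best[2] - 0.02), min(hi, best[2] + 0.02), step)
}

# random non-negative expression-like matrix with dimnames
randMatrix <- function(p, n, seed = 1, prefixRow = "g", prefixCol = "s") {
  set.seed(seed)
  matrix(rexp(p * n), p, n,
         dimnames = list(sprintf("%s%03d", prefixRow, seq_len(p)),
                         sprintf("%s%03d", prefixCol, seq_len(n))))
}
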