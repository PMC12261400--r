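test_that("simulated cells have the configured size and labels", {
  tr <- cellTree(list(
    list(name = "R1", children = list(list(name = "r1a"), list(name = "r1b"))),
    list(name = "R2", children = list(list(name = "r2a"), list(name = "r2b"))),
    list(name = "R3", children = list(list(name = "r3a"), list(name = "r3b")))))
  cd <- simulateCells(tr, nGenes = 100, cellsPerLeaf = 50, seed = 5)
  expect_equal(ncol(cellCounts(cd)), 300)
  expect_setequal(unique(cellLabels(cd)), treeLeaves(tr))
  expect_true(all(cellCounts(cd) >= 0))
  expect_true(all(cellCounts(cd) == round(cellCounts(cd))))
})

test_that("simulation is bit-identical under the same seed", {
  tr <- smallTree()
  a <- simulateCells(tr, nGenes = 80, cellsPerLeaf = 20, seed = 9)
  b <- simulateCells(tr, nGenes = 80, cellsPerLeaf = 20, seed = 9)
  expect_identical(cellCounts(a), cellCounts(b))
  c <- simulateCells(tr, nGenes = 80, cellsPerLeaf = 20, seed = 10)
  expect_false(identical(cellCounts(a), cellCounts(c)))
})

test_that("zero effect size makes sibling types indistinguishable", {
  tr <- cellTree(list(list(name = "P", children = list(
    list(name = "s1"), list(name = "s2")))))
  cd <- simulateCells(tr, nGenes = 200, cellsPerLeaf = 120,
                      effectSize = 0, seed = 21)
  counts <- cellCounts(cd)
  lab <- cellLabels(cd)
  # per-gene two-sample t-tests between the siblings, Bonferroni at 0.01
  pvals <- vapply(seq_len(nrow(counts)), function(g) {
    x <- counts[g, lab == "s1"]; y <- counts[g, lab == "s2"]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
    stats::t.test(x, y)$p.value
  }, numeric(1))
  expect_equal(sum(pvals < 0.01 / length(pvals)), 0)
})

test_that("large effects and low dispersion separate the leaf consensus", {
  tr <- smallTree()
  cd <- simulateCells(tr, nGenes = 800, cellsPerLeaf = 100,
                      markerFraction = c(0.35, 0.2, 0.15),
                      effectSize = c(3, 2.5, 2.5), dispersion = 0.05, seed = 2)
  ref <- buildReference(cd, tr, treeLeaves(tr))
  cc <- stats::cor(ref)
  expect_lt(max(cc[upper.tri(cc)]), 1 - 0.1)
})

test_that("train/test split is stratified, disjoint and seeded", {
  tr <- cellTree(list(list(name = "x"), list(name = "y")))
  cd <- simulateCells(tr, nGenes = 50, cellsPerLeaf = 10, seed = 4)
  sp <- splitTrainTest(cd, seed = 1)
  expect_equal(table(cellLabels(sp$train)), table(cellLabels(sp$test)))
  expect_equal(sum(table(cellLabels(sp$train))), 10)
  ids <- c(colnames(cellCounts(sp$train)), colnames(cellCounts(sp$test)))
  expect_setequal(ids, colnames(cellCounts(cd)))
  expect_equal(anyDuplicated(ids), 0)
  sp2 <- splitTrainTest(cd, seed = 1)
  expect_identical(colnames(cellCounts(sp2$train)),
                   colnames(cellCounts(sp$train)))
})

test_that("odd per-type counts split 6/5 with the extra cell seeded", {
  tr <- cellTree(list(list(name = "x")))
  cd <- new("CellData",
            counts = randMatrix(20, 11, prefixCol = "c"),
            labels = rep("x", 11))
  sp <- splitTrainTest(cd, seed = 2)
  sizes <- sort(c(ncol(cellCounts(sp$train)), ncol(cellCounts(sp$test))))
  expect_equal(sizes, c(5, 6))
  one <- new("CellData", counts = randMatrix(20, 1, prefixCol = "c"),
             labels = "x")
  expect_error(splitTrainTest(one), "at least 2")
})

test_that("pseudo-bulk truths count drawn cells and columns sum to one", {
  tr <- smallTree()
  cd <- tinyCells(tr)
  pb <- makePseudoBulks(cd, nBulks = 30, cellsPerBulk = 100, seed = 8)
  expect_equal(colSums(pb$proportions), rep(1, 30), ignore_attr = TRUE)
  # multiples of 1/cells_per_bulk
  expect_true(all(abs(pb$proportions * 100 -
                        round(pb$proportions * 100)) < 1e-12))
  # with every cell drawn, the bulk is the pool total and the truth the
  # pool's label frequencies
  all_ <- makePseudoBulks(cd, nBulks = 2, cellsPerBulk = ncol(cellCounts(cd)),
                          seed = 1)
  expect_equal(all_$bulks[, 1], rowSums(cellCounts(cd)), ignore_attr = TRUE)
  freq <- table(cellLabels(cd)) / ncol(cellCounts(cd))
  expect_equal(all_$proportions[, 1],
               c(freq)[rownames(all_$proportions)])
  expect_error(makePseudoBulks(cd, 0, 10), ">= 1")
  expect_error(makePseudoBulks(cd, 2, 1e6), "exceeds")
  pb2 <- makePseudoBulks(cd, nBulks = 30, cellsPerBulk = 100, seed = 8)
  expect_identical(pb2$bulks, pb$bulks)
})

test_that("aggregated ground truth still sums to one at every level", {
  tr <- smallTree()
  cd <- tinyCells(tr)
  pb <- makePseudoBulks(cd, nBulks = 10, cellsPerBulk = 50, seed = 3)
  for (lv in treeLevels(tr)) {
    up <- aggregateProportions(pb$proportions, tr, lv)
    expect_equal(colSums(up), rep(1, 10), ignore_attr = TRUE)
  }
})

test_that("the full dataset wrapper wires seeds through all parts", {
  tr <- smallTree()
  d1 <- simulateHideDataset(tr, nTrainBulks = 20, nTestBulks = 10,
                            testBatches = 2, cellsPerBulk = 30, seed = 6,
                            nGenes = 60, cellsPerLeaf = 20)
  d2 <- simulateHideDataset(tr, nTrainBulks = 20, nTestBulks = 10,
                            testBatches = 2, cellsPerBulk = 30, seed = 6,
                            nGenes = 60, cellsPerLeaf = 20)
  expect_identical(d1$train$bulks, d2$train$bulks)
  expect_identical(d1$test[[2]]$proportions, d2$test[[2]]$proportions)
  expect_equal(length(d1$test), 2)
  expect_false(identical(d1$test[[1]]$bulks, d1$test[[2]]$bulks))
})
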