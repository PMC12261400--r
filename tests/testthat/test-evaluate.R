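mkProp <- function(vals, types, samples = NULL) {
  n <- length(vals) / length(types)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  matrix(vals, length(types), n, dimnames = list(types, samples))
}

test_that("per-type Pearson is 1 under affine maps and NA when degenerate", {
  C <- mkProp(c(0.1, 0.9, 0.2, 0.8, 0.3, 0.7), c("a", "b"))
  expect_equal(pearsonPerType(C, C), c(a = 1, b = 1))
  expect_equal(pearsonPerType(C, 2 * C + 0.05), c(a = 1, b = 1))
  anti <- C; anti["a", ] <- rev(C["a", ])
  expect_equal(unname(pearsonPerType(C, anti)["a"]), -1)
  Cdeg <- C; Cdeg["b", ] <- 0.5
  expect_true(is.na(pearsonPerType(Cdeg, C)["b"]))
  expect_error(pearsonPerType(C, C[, 1:2]), "do not match")
  expect_error(pearsonPerType(C[, 1:2], C[, 1:2]), "at least 3")
})

test_that("NMAE normalizes the MAE by the mean (or range) of the truth", {
  Ct <- mkProp(c(0.1, 0.3), "a", c("s1", "s2"))
  Ce <- mkProp(c(0.2, 0.4), "a", c("s1", "s2"))
  expect_equal(unname(nmaePerType(Ct, Ce)), 0.5)  # MAE 0.1 / mean 0.2
  expect_equal(nmaePerType(Ct, Ct), c(a = 0))
  # scale invariance of the mean normalizer
  expect_equal(nmaePerType(2 * Ct, 2 * Ce), nmaePerType(Ct, Ce))
  # range normalizer: MAE 0.1 / range 0.2
  expect_equal(unname(nmaePerType(Ct, Ce, normalizer = "range")), 0.5)
  zero <- mkProp(c(0, 0), "a", c("s1", "s2"))
  expect_true(is.na(nmaePerType(zero, Ce)["a"]))
})

test_that("metrics are invariant to joint sample permutations", {
  set.seed(31)
  Ct <- mkProp(runif(20), c("a", "b"))
  Ce <- Ct + mkProp(rnorm(20, sd = 0.05), c("a", "b"))
  perm <- sample(ncol(Ct))
  expect_equal(pearsonPerType(Ct[, perm], Ce[, perm]),
               pearsonPerType(Ct, Ce))
  expect_equal(nmaePerType(Ct[, perm], Ce[, perm]), nmaePerType(Ct, Ce))
})

test_that("consistency correlation separates tied from independent routes", {
  set.seed(32)
  direct <- mkProp(runif(1000), c("a", "b"))
  expect_equal(consistencyCorrelation(direct, direct), c(a = 1, b = 1))
  other <- mkProp(runif(1000), c("a", "b"))
  cc <- consistencyCorrelation(direct, other)
  # independent routes: correlations scattered around 0
  expect_true(all(abs(cc) < 3 / sqrt(500)))
})

test_that("benchmark report aggregates batches and levels correctly", {
  tr <- smallTree()
  lv <- treeLevels(tr)
  set.seed(33)
  mkBatch <- function() {
    C <- matrix(rexp(6 * 12), 6, 12, dimnames = list(lv$leaf, paste0("s", 1:12)))
    sweep(C, 2, colSums(C), "/")
  }
  truth <- list(mkBatch(), mkBatch())
  noise <- function(C) {
    E <- pmax(C + matrix(rnorm(length(C), sd = 0.03), nrow(C)), 0)
    sweep(E, 2, colSums(E), "/")
  }
  preds <- lapply(truth, function(tb) {
    leafEst <- noise(tb)
    lapply(lv, function(l) aggregateProportions(leafEst, tr, l))
  })
  rep2 <- benchmarkReport(preds, truth, tr, lv)
  # level mean equals the mean over exactly that level's types
  majRows <- rep2$perType[rep2$perType$level == "major", ]
  batchMeans <- sapply(1:2, function(b) {
    tl <- aggregateProportions(truth[[b]], tr, lv$major)
    mean(pearsonPerType(tl, preds[[b]]$major))
  })
  expect_equal(rep2$levelMeans$pearson[rep2$levelMeans$level == "major"],
               mean(batchMeans))
  expect_equal(nrow(rep2$perType), length(lv$major) + length(lv$minor) +
                 length(lv$leaf))
  # identical batches give zero spread; a single batch has no spread column
  repSame <- benchmarkReport(preds[c(1, 1)], truth[c(1, 1)], tr, lv)
  expect_equal(max(repSame$perType$pearson_sd, na.rm = TRUE), 0)
  repOne <- benchmarkReport(preds[1], truth[1], tr, lv)
  expect_true(all(is.na(repOne$perType$pearson_sd)))
})

test_that("conservation error detects broken hierarchies", {
  bm <- benchmarkFixture()
  lv <- treeLevels(bm$tree)
  expect_lt(conservationError(bm$preds[[1]], bm$tree, lv), 1e-10)
  broken <- bm$preds[[1]]
  broken$leaf[1, 1] <- broken$leaf[1, 1] + 0.05
  expect_gt(conservationError(broken, bm$tree, lv), 0.04)
})
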