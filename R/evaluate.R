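# Scoring predictions against ground truth: per-type Pearson correlation,
# normalized mean absolute error, cross-level consistency, and the
# multi-batch benchmark report.

.alignMatrices <- function(Ctrue, Cest) {
  if (is.null(rownames(Ctrue)) || is.null(rownames(Cest))) {
    stop("both matrices need cell-type rownames", call. = FALSE)
  }
  if (!setequal(rownames(Ctrue), rownames(Cest)) ||
      ncol(Ctrue) != ncol(Cest)) {
    stop("truth and estimate shapes/types do not match", call. = FALSE)
  }
  Cest[rownames(Ctrue), colnames(Ctrue), drop = FALSE]
}

#' Per-cell-type Pearson correlation
#'
#' Sample Pearson correlation between true and estimated proportions,
#' computed per cell type across samples. Types whose truth or estimate is
#' constant get `NA` (the correlation is undefined) and are excluded from
#' level means downstream.
#'
#' @param Ctrue,Cest cell-types x samples matrices with matching dimnames.
#' @return named numeric vector, one value per cell type.
#' @export
pearsonPerType <- function(Ctrue, Cest) {
  Cest <- .alignMatrices(Ctrue, Cest)
  if (ncol(Ctrue) < 3) stop("need at least 3 samples", call. = FALSE)
  vapply(rownames(Ctrue), function(j) {
    x <- Ctrue[j, ]; y <- Cest[j, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }, numeric(1))
}

#' Per-cell-type normalized mean absolute error
#'
#' Mean absolute error between estimated and true proportions, normalized
#' per cell type. The default normalizer is the mean true proportion of
#' the type (scale-invariant: doubling truth and estimate together leaves
#' the value unchanged); `"range"` divides by the truth's range instead.
#' Types with a zero normalizer get `NA`.
#'
#' @inheritParams pearsonPerType
#' @param normalizer `"mean"` (default) or `"range"`.
#' @return named numeric vector, one value per cell type.
#' @export
nmaePerType <- function(Ctrue, Cest, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  Cest <- .alignMatrices(Ctrue, Cest)
  mae <- rowMeans(abs(Cest - Ctrue))
  denom <- switch(normalizer,
                  mean = rowMeans(Ctrue),
                  range = apply(Ctrue, 1, function(x) diff(range(x))))
  out <- mae / denom
  out[denom == 0] <- NA_real_
  out
}

#' Consistency between direct and summed level predictions
#'
#' Per-type Pearson correlation between proportions predicted directly at
#' a level and proportions obtained by summing the same method's
#' child-level predictions. A hierarchy-preserving method gives exactly 1
#' for every type; methods that treat levels independently generally do
#' not.
#'
#' @param direct level-types x samples matrix predicted at the level.
#' @param summed same shape, aggregated from finer predictions.
#' @return named numeric vector of correlations.
#' @export
consistencyCorrelation <- function(direct, summed) {
  pearsonPerType(direct, summed)
}

#' Benchmark a set of per-level predictions over test batches
#'
#' Scores every batch at every level (truth aggregated from the leaf-level
#' ground truth) and summarizes per type and per level as mean and
#' standard deviation across batches (sd is `NA` with a single batch).
#' Degenerate types (undefined correlation or NMAE) are excluded from
#' level means and counted per level.
#'
#' @param predictions list over batches; each element a named list of
#'   per-level cell-types x samples matrices (as returned by
#'   [hidePredict()]).
#' @param truthLeaf list over batches of leaf-types x samples ground-truth
#'   matrices.
#' @param tree a [CellTree-class].
#' @param levels named list of levels matching the prediction tables.
#' @param normalizer NMAE normalizer, see [nmaePerType()].
#' @return list with data frames `perType` (level, cellType, mean/sd of
#'   Pearson and NMAE) and `levelMeans` (per-level means across types,
#'   mean/sd across batches, and the count of excluded degenerate types).
#' @export
benchmarkReport <- function(predictions, truthLeaf, tree, levels,
                            normalizer = "mean") {
  stopifnot(length(predictions) >= 1,
            length(predictions) == length(truthLeaf))
  nb <- length(predictions)
  perBatch <- lapply(seq_len(nb), function(b) {
    lapply(names(levels), function(lv) {
      tl <- aggregateProportions(truthLeaf[[b]], tree, levels[[lv]])
      est <- predictions[[b]][[lv]]
      list(pearson = pearsonPerType(tl, est),
           nmae = nmaePerType(tl, est, normalizer))
    })
  })
  sdOrNA <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  perType <- do.call(rbind, lapply(seq_along(levels), function(li) {
    types <- levels[[li]]
    do.call(rbind, lapply(types, function(tp) {
      pe <- vapply(perBatch, function(pb) pb[[li]]$pearson[tp], numeric(1))
      nm <- vapply(perBatch, function(pb) pb[[li]]$nmae[tp], numeric(1))
      data.frame(level = names(levels)[li], cellType = tp,
                 pearson = mean(pe), pearson_sd = sdOrNA(pe),
                 nmae = mean(nm), nmae_sd = sdOrNA(nm))
    }))
  }))
  levelMeans <- do.call(rbind, lapply(seq_along(levels), function(li) {
    pe <- vapply(perBatch, function(pb) mean(pb[[li]]$pearson, na.rm = TRUE),
                 numeric(1))
    nm <- vapply(perBatch, function(pb) mean(pb[[li]]$nmae, na.rm = TRUE),
                 numeric(1))
    excl <- max(vapply(perBatch, function(pb) {
      sum(is.na(pb[[li]]$pearson) | is.na(pb[[li]]$nmae))
    }, numeric(1)))
    data.frame(level = names(levels)[li],
               pearson = mean(pe), pearson_sd = sdOrNA(pe),
               nmae = mean(nm), nmae_sd = sdOrNA(nm),
               excluded = excl)
  }))
  rownames(perType) <- NULL
  rownames(levelMeans) <- NULL
  list(perType = perType, levelMeans = levelMeans)
}

#' Check hierarchy conservation of per-level predictions
#'
#' Verifies that the finest level sums to its parent level's values at
#' every depth and every sample (and hence that all levels carry the same
#' per-sample totals). Returns the largest absolute violation.
#'
#' @param estimates named list of per-level matrices (coarse to fine).
#' @param tree a [CellTree-class].
#' @param levels named list of levels matching `estimates`.
#' @return largest absolute parent-minus-children discrepancy.
#' @export
conservationError <- function(estimates, tree, levels) {
  worst <- 0
  for (l in seq_along(levels)[-1]) {
    pm <- .levelParentMap(tree, levels[[l]], levels[[l - 1]])
    for (v in levels[[l - 1]]) {
      rows <- levels[[l]][pm == v]
      if (length(rows) == 0) next
      s <- colSums(estimates[[l]][rows, , drop = FALSE])
      worst <- max(worst, max(abs(s - estimates[[l - 1]][v, ])))
    }
  }
  worst
}
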