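# The hierarchical deconvolution pipeline: a top-level fit over the root
# cell types, then per internal node (1) residual bulks, (2) child gene
# weighting, (3) per-child affine rescaling and xi normalization tying the
# children's total exactly to their parent's estimate. Upper-level results
# are finalized before any deeper level is touched, so refining the tree
# never changes coarser estimates.

# scale every bulk column to a fixed total so bulks live in the same unit
# as the counts-per-10k consensus references; proportion-scale estimates
# are then directly subtractable in the residual step
.BULK_TOTAL <- 1e4

.normalizeBulkColumns <- function(Y) {
  tot <- colSums(Y)
  bad <- tot <= 0
  if (any(bad)) {
    stop(sprintf("%d bulk column(s) with non-positive total", sum(bad)),
         call. = FALSE)
  }
  sweep(Y, 2, tot / .BULK_TOTAL, "/")
}

# columns normalized to sum 1; all-zero columns fall back to equal shares
.normalizeProportions <- function(C) {
  s <- colSums(C)
  zero <- s == 0
  if (any(zero)) C[, zero] <- 1 / nrow(C)
  s[zero] <- 1
  sweep(C, 2, s, "/")
}

#' Affine rescaling of an estimated proportion row
#'
#' `fitRescale` regresses the true proportions of one cell type on its raw
#' estimates across the training mixtures, giving a slope `theta` and
#' intercept `delta` that map solver output onto the proportion scale; the
#' parameters are fitted on training data once and stay fixed afterwards.
#' A degenerate (constant) estimate row falls back to `theta = 1, delta =
#' 0`. `applyRescaleRow` applies the map and clips negatives to zero.
#'
#' @param chatRow raw estimates across mixtures.
#' @param cRow matching ground-truth proportions.
#' @return `fitRescale`: list with `theta` and `delta`.
#' @export
fitRescale <- function(chatRow, cRow) {
  v <- stats::var(chatRow)
  if (!is.finite(v) || v == 0) return(list(theta = 1, delta = 0))
  theta <- stats::cov(cRow, chatRow) / v
  list(theta = theta, delta = mean(cRow) - theta * mean(chatRow))
}

#' @rdname fitRescale
#' @param theta slope.
#' @param delta intercept.
#' @return `applyRescaleRow`: the rescaled, zero-clipped row.
#' @export
applyRescaleRow <- function(chatRow, theta, delta) {
  pmax(theta * chatRow + delta, 0)
}

#' Residual bulks for one parent cell type
#'
#' Subtracts from the bulks the reconstructed contribution of every
#' parent-level type except the type of interest `k`, then clips negative
#' entries to zero. What remains is, ideally, the expression contributed by
#' `k` alone -- the input for deconvolving `k`'s children.
#'
#' @param Y genes x samples bulks (reference-scale columns).
#' @param Xlevel genes x parent-level-types reference matrix.
#' @param Clevel parent-level-types x samples estimated proportions.
#' @param k the parent type of interest (kept, not subtracted).
#' @return genes x samples residual matrix, non-negative.
#' @export
residualBulks <- function(Y, Xlevel, Clevel, k) {
  if (!(k %in% rownames(Clevel)) || !(k %in% colnames(Xlevel))) {
    stop(sprintf("'%s' is not a parent-level cell type", k), call. = FALSE)
  }
  others <- setdiff(colnames(Xlevel), k)
  if (length(others) == 0) return(Y)
  R <- Y - Xlevel[, others, drop = FALSE] %*% Clevel[others, , drop = FALSE]
  R[R < 0] <- 0
  R
}

#' Normalize child estimates to their parent's estimate
#'
#' Per sample, scales the children's (non-negative) estimates by
#' `xi = parent / sum(children)` so that they sum exactly to the parent's
#' value; when the children's raw sum is zero, `xi = 0` (the children stay
#' zero, and division by zero is avoided). A zero parent forces zero
#' children, so absent populations stay absent at every finer level.
#'
#' @param Cchildren children x samples matrix, non-negative.
#' @param parentRow the parent's finalized estimates per sample.
#' @return rescaled children x samples matrix.
#' @export
applyXi <- function(Cchildren, parentRow) {
  if (any(Cchildren < 0)) {
    stop("negative child estimates; clip before normalizing", call. = FALSE)
  }
  s <- colSums(Cchildren)
  xi <- ifelse(s == 0, 0, parentRow / s)
  sweep(Cchildren, 2, xi, "*")
}

# fit weights + rescale for one set of sibling types against truth
.fitNodeCore <- function(X, Y, truth, opts, label) {
  lw <- learnGeneWeights(X, Y, truth, opts)
  Craw <- solveWeightedNnls(X, Y, lw$weights, opts$ridge)
  types <- rownames(truth)
  theta <- stats::setNames(numeric(length(types)), types)
  delta <- theta
  for (j in types) {
    if (stats::sd(truth[j, ]) == 0 && all(truth[j, ] == 0)) {
      warning(sprintf("%s: '%s' absent from all training mixtures; rescale kept at identity",
                      label, j))
      theta[j] <- 1; delta[j] <- 0
    } else {
      rs <- fitRescale(Craw[j, ], truth[j, ])
      theta[j] <- rs$theta; delta[j] <- rs$delta
    }
  }
  Cresc <- Craw
  for (j in types) Cresc[j, ] <- applyRescaleRow(Craw[j, ], theta[j], delta[j])
  list(weights = lw$weights, trace = lw$trace,
       rescale = list(theta = theta, delta = delta),
       Craw = Craw, Cresc = Cresc)
}

.checkNestedLevels <- function(tree, levels) {
  for (l in seq_along(levels)) {
    err <- .checkLevel(tree, levels[[l]])
    if (!is.null(err)) {
      stop(sprintf("level %d: %s", l, err), call. = FALSE)
    }
    if (l > 1) .levelParentMap(tree, levels[[l]], levels[[l - 1]])
  }
  invisible(levels)
}

#' Fit a hierarchical deconvolution model
#'
#' Trains the full top-down model on mixtures of known leaf composition:
#'
#' 1. Consensus references are built from the annotated cells for every
#'    level, and the gene space is restricted to the `topK`
#'    highest-variance genes of the leaf-level reference.
#' 2. Root level: gene weights are learned against the truth aggregated to
#'    the root types; root predictions are raw constrained estimates,
#'    affinely rescaled per type, clipped at zero and normalized to sum one
#'    per mixture.
#' 3. Walking the levels coarse to fine, each parent type with two or more
#'    children gets its own model: residual bulks (its siblings'
#'    reconstructed content subtracted), child gene weights learned on
#'    them, per-child rescaling fitted -- and child estimates are tied to
#'    the parent's finalized estimate by xi normalization.
#'
#' Residual bulks are built from the model's *own* training estimates, not
#' from the ground truth, matching what is available at deployment.
#' Single-child nodes bypass fitting; the child inherits the parent row.
#'
#' @param cells training [CellData-class] (used for the references).
#' @param tree a [CellTree-class].
#' @param bulks genes x mixtures training bulk matrix.
#' @param truth leaf-types x mixtures ground-truth proportions (columns
#'   summing to 1).
#' @param levels named list of levels, coarse to fine; defaults to the
#'   tree's declared levels.
#' @param topK high-variance gene count to retain (default 5000).
#' @param opts optimizer options from [trainOptions()].
#' @return a [HideModel-class]. The per-level training estimates are
#'   attached as attribute `"trainingEstimates"`.
#' @seealso [hidePredict()], [hideAblation()]
#' @export
hideFit <- function(cells, tree, bulks, truth, levels = treeLevels(tree),
                    topK = 5000, opts = trainOptions()) {
  if (length(levels) == 0) stop("no levels declared", call. = FALSE)
  .checkNestedLevels(tree, levels)
  refLeafFull <- buildReference(cells, tree, treeLeaves(tree))
  genes <- selectTopVarianceGenes(refLeafFull, topK)
  refs <- lapply(levels, function(lv) {
    restrictGenes(buildReference(cells, tree, lv), genes)
  })
  Y <- .normalizeBulkColumns(restrictGenes(bulks, genes))
  truthLevels <- lapply(levels, function(lv) aggregateProportions(truth, tree, lv))
  n <- ncol(Y)

  L1 <- levels[[1]]
  if (length(L1) < 2) {
    rootModel <- list(types = L1,
                      weights = stats::setNames(rep(1 / sqrt(length(genes)),
                                                    length(genes)), genes),
                      rescale = list(theta = stats::setNames(1, L1),
                                     delta = stats::setNames(0, L1)))
    Cfin <- matrix(1, 1, n, dimnames = list(L1, colnames(Y)))
  } else {
    message(sprintf("fitting root level (%d types, %d genes, %d mixtures)",
                    length(L1), length(genes), n))
    fc <- .fitNodeCore(refs[[1]], Y, truthLevels[[1]], opts, "root")
    rootModel <- list(types = L1, weights = fc$weights, rescale = fc$rescale)
    Cfin <- .normalizeProportions(fc$Cresc)
  }
  finals <- list(Cfin)
  nodeModels <- list()

  for (l in seq_along(levels)[-1]) {
    parentLevel <- levels[[l - 1]]
    childLevel <- levels[[l]]
    Cl <- matrix(0, length(childLevel), n,
                 dimnames = list(childLevel, colnames(Y)))
    for (k in parentLevel) {
      kids <- .standsBelow(tree, k, childLevel)
      if (length(kids) == 0) next
      if (length(kids) == 1) {
        Cl[kids, ] <- finals[[l - 1]][k, ]
        next
      }
      message(sprintf("fitting node '%s' (%d children)", k, length(kids)))
      Yk <- residualBulks(Y, refs[[l - 1]], finals[[l - 1]], k)
      Xk <- refs[[l]][, kids, drop = FALSE]
      fc <- tryCatch(
        .fitNodeCore(Xk, Yk, truthLevels[[l]][kids, , drop = FALSE], opts, k),
        error = function(e) {
          stop(sprintf("training failed at node '%s': %s", k, conditionMessage(e)),
               call. = FALSE)
        })
      Cl[kids, ] <- applyXi(fc$Cresc, finals[[l - 1]][k, ])
      nodeModels[[k]] <- list(node = k, level = l - 1L, children = kids,
                              weights = fc$weights, rescale = fc$rescale)
    }
    finals[[l]] <- Cl
  }
  names(finals) <- names(levels)

  model <- new("HideModel", tree = tree, levels = levels, genes = genes,
               references = refs, rootModel = rootModel,
               nodeModels = nodeModels,
               config = list(topK = topK, maxIters = opts$maxIters,
                             tol = opts$tol, ridge = opts$ridge,
                             constrainedGradient = opts$constrainedGradient,
                             seed = opts$seed))
  attr(model, "trainingEstimates") <- finals
  model
}

#' Deconvolve bulk profiles with a trained model
#'
#' Applies the fixed, trained parameters top-down: root solve, per-type
#' rescale, clip, normalize to one; then per node residual bulks, child
#' solve, rescale, clip, and xi normalization to the finalized parent row.
#' Root columns sum to one and every deeper level reproduces its parent
#' totals exactly, so all levels sum to one per sample.
#'
#' @param model a [HideModel-class].
#' @param bulks genes x samples matrix; gene ids are matched to the model's
#'   gene index (order-free).
#' @param maxMissing maximum tolerated fraction of model genes absent from
#'   `bulks` (default 0.05); missing genes are dropped from the solve.
#' @return named list of cell-types x samples proportion matrices, one per
#'   model level.
#' @export
hidePredict <- function(model, bulks, maxMissing = 0.05) {
  genes <- model@genes
  present <- intersect(genes, rownames(bulks))
  missFrac <- 1 - length(present) / length(genes)
  if (missFrac > maxMissing) {
    stop(sprintf("%.1f%% of model genes missing from input (max %.1f%%)",
                 100 * missFrac, 100 * maxMissing), call. = FALSE)
  }
  Y <- .normalizeBulkColumns(bulks[present, , drop = FALSE])
  refs <- lapply(model@references, function(r) r[present, , drop = FALSE])
  levels <- model@levels
  n <- ncol(Y)
  rm0 <- model@rootModel
  w0 <- rm0$weights[present]
  L1 <- levels[[1]]
  if (length(L1) < 2) {
    Cfin <- matrix(1, 1, n, dimnames = list(L1, colnames(Y)))
  } else {
    Craw <- solveWeightedNnls(refs[[1]], Y, w0, model@config$ridge)
    for (j in L1) {
      Craw[j, ] <- applyRescaleRow(Craw[j, ], rm0$rescale$theta[j],
                                   rm0$rescale$delta[j])
    }
    Cfin <- .normalizeProportions(Craw)
  }
  finals <- list(Cfin)
  for (l in seq_along(levels)[-1]) {
    parentLevel <- levels[[l - 1]]
    childLevel <- levels[[l]]
    Cl <- matrix(0, length(childLevel), n,
                 dimnames = list(childLevel, colnames(Y)))
    for (k in parentLevel) {
      kids <- .standsBelow(model@tree, k, childLevel)
      if (length(kids) == 0) next
      if (length(kids) == 1) {
        Cl[kids, ] <- finals[[l - 1]][k, ]
        next
      }
      nm <- model@nodeModels[[k]]
      if (is.null(nm)) {
        stop(sprintf("no trained model for node '%s'", k), call. = FALSE)
      }
      Yk <- residualBulks(Y, refs[[l - 1]], finals[[l - 1]], k)
      Xk <- refs[[l]][, kids, drop = FALSE]
      Ck <- solveWeightedNnls(Xk, Yk, nm$weights[present], model@config$ridge)
      for (j in kids) {
        Ck[j, ] <- applyRescaleRow(Ck[j, ], nm$rescale$theta[j],
                                   nm$rescale$delta[j])
      }
      Cl[kids, ] <- applyXi(Ck, finals[[l - 1]][k, ])
    }
    finals[[l]] <- Cl
  }
  names(finals) <- names(levels)
  finals
}

#' Ablated variants of the hierarchical fit
#'
#' Two reduced models for quantifying what the hierarchical machinery
#' contributes:
#'
#' * `"flat"`: one gene-weight learning run directly on the finest level
#'   (no residuals, no per-node models); finest estimates are rescaled,
#'   clipped and normalized to one, and coarser levels are obtained by
#'   summing the finest predictions.
#' * `"no_residual"`: the root model plus per-node gene weighting exactly
#'   as in the full fit, but the children are solved on the *original*
#'   bulks and reported raw -- no residual subtraction, no rescaling, no
#'   xi normalization. Coarser levels again by summation of the finest
#'   table.
#'
#' @inheritParams hideFit
#' @param variant `"flat"` or `"no_residual"`.
#' @return list with `variant`, and `estimates`/`testPredict`: `estimates`
#'   is the named per-level list of training-set proportion tables;
#'   `testPredict` is a function `(bulks) -> per-level list` applying the
#'   frozen variant to new bulks.
#' @export
hideAblation <- function(variant = c("flat", "no_residual"), cells, tree,
                         bulks, truth, levels = treeLevels(tree),
                         topK = 5000, opts = trainOptions()) {
  variant <- match.arg(variant)
  .checkNestedLevels(tree, levels)
  refLeafFull <- buildReference(cells, tree, treeLeaves(tree))
  genes <- selectTopVarianceGenes(refLeafFull, topK)
  refs <- lapply(levels, function(lv) {
    restrictGenes(buildReference(cells, tree, lv), genes)
  })
  Y <- .normalizeBulkColumns(restrictGenes(bulks, genes))
  truthLevels <- lapply(levels, function(lv) aggregateProportions(truth, tree, lv))
  nl <- length(levels)
  fine <- levels[[nl]]

  sumUp <- function(Cfine) {
    out <- vector("list", nl)
    out[[nl]] <- Cfine
    for (l in seq_len(nl - 1)) {
      pm <- .levelParentMap(tree, fine, levels[[l]])
      M <- matrix(0, length(levels[[l]]), ncol(Cfine),
                  dimnames = list(levels[[l]], colnames(Cfine)))
      for (v in levels[[l]]) {
        rows <- fine[pm == v]
        M[v, ] <- colSums(Cfine[rows, , drop = FALSE])
      }
      out[[l]] <- M
    }
    names(out) <- names(levels)
    out
  }

  if (variant == "flat") {
    fc <- .fitNodeCore(refs[[nl]], Y, truthLevels[[nl]], opts, "flat")
    Cfine <- .normalizeProportions(fc$Cresc)
    predict <- function(newBulks) {
      Yn <- .normalizeBulkColumns(restrictGenes(newBulks, genes))
      Craw <- solveWeightedNnls(refs[[nl]], Yn, fc$weights, opts$ridge)
      for (j in fine) {
        Craw[j, ] <- applyRescaleRow(Craw[j, ], fc$rescale$theta[j],
                                     fc$rescale$delta[j])
      }
      sumUp(.normalizeProportions(Craw))
    }
    return(list(variant = variant, estimates = sumUp(Cfine),
                testPredict = predict))
  }

  # no_residual: root model (step 0) + per-node weights on original bulks
  fcRoot <- .fitNodeCore(refs[[1]], Y, truthLevels[[1]], opts, "root")
  CfinRoot <- .normalizeProportions(fcRoot$Cresc)
  nodeFits <- list()
  assemble <- function(Yin, rootFin, rawSolve) {
    finals <- list(rootFin)
    for (l in seq_along(levels)[-1]) {
      Cl <- matrix(0, length(levels[[l]]), ncol(Yin),
                   dimnames = list(levels[[l]], colnames(Yin)))
      for (k in levels[[l - 1]]) {
        kids <- .standsBelow(tree, k, levels[[l]])
        if (length(kids) == 0) next
        if (length(kids) == 1) { Cl[kids, ] <- finals[[l - 1]][k, ]; next }
        Cl[kids, ] <- rawSolve(k, l, kids, Yin)
      }
      finals[[l]] <- Cl
    }
    finals[[nl]]
  }
  for (l in seq_along(levels)[-1]) {
    for (k in levels[[l - 1]]) {
      kids <- .standsBelow(tree, k, levels[[l]])
      if (length(kids) >= 2) {
        Xk <- refs[[l]][, kids, drop = FALSE]
        lw <- learnGeneWeights(Xk, Y, truthLevels[[l]][kids, , drop = FALSE],
                               opts)
        nodeFits[[k]] <- lw$weights
      }
    }
  }
  rawSolve <- function(k, l, kids, Yin) {
    solveWeightedNnls(refs[[l]][, kids, drop = FALSE], Yin, nodeFits[[k]],
                      opts$ridge)
  }
  Cfine <- assemble(Y, CfinRoot, rawSolve)
  predict <- function(newBulks) {
    Yn <- .normalizeBulkColumns(restrictGenes(newBulks, genes))
    Craw <- solveWeightedNnls(refs[[1]], Yn, fcRoot$weights, opts$ridge)
    for (j in levels[[1]]) {
      Craw[j, ] <- applyRescaleRow(Craw[j, ], fcRoot$rescale$theta[j],
                                   fcRoot$rescale$delta[j])
    }
    sumUp(assemble(Yn, .normalizeProportions(Craw), rawSolve))
  }
  list(variant = variant, estimates = sumUp(Cfine), testPredict = predict)
}

#' @describeIn HideModel-class summary of tree size, gene index and fitted
#'   nodes.
#' @param object a `HideModel`.
#' @export
setMethod("show", "HideModel", function(object) {
  cat(sprintf("HideModel: %d levels (%s), %d genes, %d fitted node model(s)\n",
              length(object@levels),
              paste(names(object@levels), collapse = " > "),
              length(object@genes), length(object@nodeModels)))
})

#' HideModel accessors
#'
#' @param x a [HideModel-class].
#' @param node internal node name (for `nodeWeights`); omit for the root.
#' @return `modelGenes`: the shared gene index; `nodeWeights`: the learned
#'   unit-norm gene weights of one node.
#' @export
modelGenes <- function(x) x@genes

#' @rdname modelGenes
#' @export
nodeWeights <- function(x, node = NULL) {
  if (is.null(node)) return(x@rootModel$weights)
  nm <- x@nodeModels[[node]]
  if (is.null(nm)) stop(sprintf("no fitted model for node '%s'", node),
                        call. = FALSE)
  nm$weights
}
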