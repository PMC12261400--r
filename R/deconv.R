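# Weighted (non-negative) least-squares deconvolution and loss-function
# learning of per-gene weights. This is the inner machinery reused at every
# node of the cell-type tree.
#
# Model: a bulk profile y is a non-negative linear combination of reference
# columns, y ~ X c, fitted under per-gene weights g:
#     c-hat = argmin_{c >= 0} || diag(g) (y - X c) ||^2 .
# The weights are learned by minimizing the negative sum of per-type
# Pearson correlations between known and estimated proportions on training
# mixtures, under ||g||_2 = 1. Effective weights enter as g^2, so the sign
# of g is immaterial and the unit norm is a pure normalization: with the
# ridge term scaled by trace(X' G X)/q the estimate is exactly invariant to
# positive rescaling of g.

#' Optimizer settings for gene-weight learning
#'
#' @param maxIters iteration budget of the gradient descent.
#' @param tol stop when the relative loss improvement falls below this.
#' @param stepSize initial step size of the backtracking line search.
#' @param ridge relative ridge jitter; the absolute jitter is
#'   `ridge * trace(X' diag(g^2) X) / q`.
#' @param constrainedGradient train against the cone-constrained solver
#'   with numerical gradients (small gene counts only) instead of the
#'   differentiable closed form.
#' @param seed integer seed recorded with the run.
#' @return named list of options.
#' @export
trainOptions <- function(maxIters = 1000, tol = 1e-6, stepSize = 1,
                         ridge = 1e-8, constrainedGradient = FALSE,
                         seed = 1L) {
  stopifnot(maxIters >= 1, tol > 0, stepSize > 0, ridge > 0)
  list(maxIters = as.integer(maxIters), tol = tol, stepSize = stepSize,
       ridge = ridge, constrainedGradient = isTRUE(constrainedGradient),
       seed = as.integer(seed))
}

.checkDeconvDims <- function(X, Y, g) {
  if (nrow(X) != nrow(Y)) {
    stop(sprintf("gene dimension mismatch: X has %d rows, Y has %d",
                 nrow(X), nrow(Y)), call. = FALSE)
  }
  if (length(g) != nrow(X)) {
    stop(sprintf("weight vector length %d does not match %d genes",
                 length(g), nrow(X)), call. = FALSE)
  }
}

# weighted Gram matrix and cross-products; shared by both solvers
.weightedNormalEqs <- function(X, Y, g) {
  Xg <- X * g
  A <- crossprod(Xg)
  B <- crossprod(Xg, Y * g)
  list(A = A, B = B)
}

#' Weighted non-negative least squares, per bulk
#'
#' Solves `argmin_{c >= 0} ||diag(g) (y - X c)||^2` for every column of
#' `Y`. The p-dimensional problem is reduced to q dimensions through the
#' Cholesky factor of the weighted Gram matrix and solved with the
#' Lawson-Hanson active-set algorithm. A rank-deficient weighted design is
#' regularized with a small ridge jitter (with a warning).
#'
#' @param X genes x cell-types reference matrix.
#' @param Y genes x samples bulk matrix (same gene order as `X`).
#' @param g per-gene weights (effective weights are `g^2`); defaults to
#'   uniform.
#' @param ridge relative ridge jitter used only if the weighted Gram matrix
#'   is not positive definite.
#' @return cell-types x samples matrix of non-negative estimates.
#' @export
solveWeightedNnls <- function(X, Y, g = NULL, ridge = 1e-8) {
  Y <- as.matrix(Y)
  if (is.null(g)) g <- rep(1 / sqrt(nrow(X)), nrow(X))
  .checkDeconvDims(X, Y, g)
  q <- ncol(X)
  ne <- .weightedNormalEqs(X, Y, g)
  A <- ne$A
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    warning("weighted design is rank deficient; adding ridge jitter")
    A <- A + diag(ridge * max(sum(diag(A)), 1) / q, q)
    R <- chol(A)
  }
  # ||diag(g)(y - Xc)||^2 = ||R c - z||^2 + const,  z = R^{-T} X' diag(g^2) y
  Z <- forwardsolve(t(R), ne$B)
  C <- matrix(0, q, ncol(Y), dimnames = list(colnames(X), colnames(Y)))
  for (i in seq_len(ncol(Y))) {
    C[, i] <- pracma::lsqnonneg(R, Z[, i])$x
  }
  C
}

#' Weighted least squares without the non-negativity cone
#'
#' Closed form `(X' G X + eps I)^{-1} X' G Y` with `G = diag(g^2)` and
#' `eps = ridge * trace(X' G X) / q`. This is the differentiable estimator
#' used inside gene-weight learning; the cone-constrained solver is used at
#' inference.
#'
#' @inheritParams solveWeightedNnls
#' @param ridge relative ridge jitter (always applied).
#' @return cell-types x samples matrix (may contain negative values).
#' @export
solveWeightedLs <- function(X, Y, g = NULL, ridge = 1e-8) {
  Y <- as.matrix(Y)
  if (is.null(g)) g <- rep(1 / sqrt(nrow(X)), nrow(X))
  .checkDeconvDims(X, Y, g)
  q <- ncol(X)
  ne <- .weightedNormalEqs(X, Y, g)
  eps <- ridge * sum(diag(ne$A)) / q
  C <- solve(ne$A + diag(eps, q), ne$B)
  dimnames(C) <- list(colnames(X), colnames(Y))
  C
}

# per-row Pearson pieces used by loss and gradient; degenerate rows
# (zero variance in truth or estimate) contribute 0 to loss and gradient
.corRows <- function(C, Chat) {
  q <- nrow(C)
  n <- ncol(C)
  cc <- C - rowMeans(C)
  hh <- Chat - rowMeans(Chat)
  sc <- sqrt(rowSums(cc^2))
  sh <- sqrt(rowSums(hh^2))
  ok <- sc > 0 & sh > 0
  rho <- rep(NA_real_, q)
  G <- matrix(0, q, n)
  if (any(ok)) {
    rho[ok] <- rowSums(cc[ok, , drop = FALSE] * hh[ok, , drop = FALSE]) /
      (sc[ok] * sh[ok])
    G[ok, ] <- -(cc[ok, , drop = FALSE] / (sc[ok] * sh[ok]) -
                   (rho[ok] / sh[ok]^2) * hh[ok, , drop = FALSE])
  }
  list(rho = rho, grad = G, ok = ok)
}

# loss and analytic gradient through the closed-form estimator
.lossAndGrad <- function(g, X, Y, C, ridge) {
  q <- ncol(X)
  ne <- .weightedNormalEqs(X, Y, g)
  eps <- ridge * sum(diag(ne$A)) / q
  Areg <- ne$A + diag(eps, q)
  S <- chol2inv(chol(Areg))
  Chat <- S %*% ne$B
  cr <- .corRows(C, Chat)
  loss <- -sum(cr$rho[cr$ok])
  G <- cr$grad
  SG <- S %*% G
  term <- rowSums((Y - X %*% Chat) * (X %*% SG))
  grad <- 2 * g * term
  # the jitter eps = ridge/q * sum_k g_k^2 ||x_k||^2 also depends on g
  tGSC <- sum(G * (S %*% Chat))
  grad <- grad - tGSC * (2 * ridge / q) * g * rowSums(X^2)
  list(loss = loss, grad = grad, nUsed = sum(cr$ok))
}

#' Correlation loss of a gene weighting
#'
#' The negative sum, over cell types with non-degenerate ground truth, of
#' the Pearson correlation between true and estimated proportions across
#' the training mixtures. Perfect estimates of q types give `-q`. Rows
#' whose truth or estimate is constant across mixtures are excluded (the
#' correlation is undefined there).
#'
#' @param g per-gene weights.
#' @param X genes x cell-types reference matrix.
#' @param Y genes x mixtures training bulks.
#' @param C cell-types x mixtures ground-truth proportions (rows matching
#'   the columns of `X`).
#' @param estimator `"unconstrained"` (closed form, the training default)
#'   or `"constrained"` (non-negative solver).
#' @param ridge relative ridge jitter.
#' @return scalar loss.
#' @export
correlationLoss <- function(g, X, Y, C,
                            estimator = c("unconstrained", "constrained"),
                            ridge = 1e-8) {
  estimator <- match.arg(estimator)
  if (ncol(Y) < 3) stop("need at least 3 mixtures", call. = FALSE)
  if (nrow(C) != ncol(X)) {
    stop("truth rows must match reference columns", call. = FALSE)
  }
  Chat <- if (estimator == "unconstrained") solveWeightedLs(X, Y, g, ridge)
          else solveWeightedNnls(X, Y, g, ridge)
  cr <- .corRows(C, Chat)
  if (!any(cr$ok)) stop("all cell-type rows are degenerate", call. = FALSE)
  -sum(cr$rho[cr$ok])
}

#' Learn per-gene weights by loss-function learning
#'
#' Minimizes [correlationLoss()] with respect to the gene weights under
#' `||g||_2 = 1`, starting from uniform weights `1/sqrt(p)`. Gradient
#' descent with backtracking line search; `g` is renormalized to unit norm
#' after every accepted step (the loss is invariant to positive rescaling
#' of `g`, so the constraint is a normalization, not a restriction). The
#' accepted-loss sequence is non-increasing by construction, so the learned
#' weights are never worse than the uniform start.
#'
#' @inheritParams correlationLoss
#' @param opts options from [trainOptions()].
#' @return list with `weights` (unit-norm, named by gene), `trace` (loss
#'   after each accepted step, starting with the uniform-weight loss),
#'   `iterations`, and `converged`.
#' @export
learnGeneWeights <- function(X, Y, C, opts = trainOptions()) {
  p <- nrow(X)
  if (ncol(Y) < 3) stop("need at least 3 training mixtures", call. = FALSE)
  if (nrow(C) != ncol(X)) {
    stop("truth rows must match reference columns", call. = FALSE)
  }
  varying <- apply(C, 1, stats::sd) > 0
  if (sum(varying) < 1) {
    stop("no cell type with varying ground truth", call. = FALSE)
  }
  if (!all(varying)) {
    message(sprintf("excluding %d truth-constant cell type(s) from the loss: %s",
                    sum(!varying),
                    paste(rownames(C)[!varying], collapse = ", ")))
  }
  g <- rep(1 / sqrt(p), p)
  evalLoss <- function(gg) {
    if (opts$constrainedGradient) {
      correlationLoss(gg, X, Y, C, "constrained", opts$ridge)
    } else {
      correlationLoss(gg, X, Y, C, "unconstrained", opts$ridge)
    }
  }
  evalGrad <- function(gg) {
    if (opts$constrainedGradient) {
      h <- 1e-6
      vapply(seq_len(p), function(k) {
        e <- numeric(p); e[k] <- h
        (evalLoss(gg + e) - evalLoss(gg - e)) / (2 * h)
      }, numeric(1))
    } else {
      .lossAndGrad(gg, X, Y, C, opts$ridge)$grad
    }
  }
  loss <- evalLoss(g)
  if (!is.finite(loss)) {
    stop("non-finite loss at uniform weights; degenerate training data",
         call. = FALSE)
  }
  trace <- loss
  step <- opts$stepSize
  converged <- FALSE
  iter <- 0
  while (iter < opts$maxIters) {
    iter <- iter + 1
    grad <- evalGrad(g)
    gnorm2 <- sum(grad^2)
    if (!is.finite(gnorm2) || gnorm2 == 0) { converged <- TRUE; break }
    accepted <- FALSE
    s <- step
    for (bt in 1:40) {
      cand <- g - s * grad
      cand <- cand / sqrt(sum(cand^2))
      lc <- evalLoss(cand)
      if (is.finite(lc) && lc < loss) {
        g <- cand
        relImp <- (loss - lc) / max(abs(loss), 1e-12)
        loss <- lc
        trace <- c(trace, loss)
        step <- s * 2  # warm-start the next line search
        accepted <- TRUE
        if (relImp < opts$tol) converged <- TRUE
        break
      }
      s <- s / 2
    }
    if (!accepted || converged) { converged <- TRUE; break }
  }
  names(g) <- rownames(X)
  list(weights = g, trace = trace, iterations = iter, converged = converged)
}
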