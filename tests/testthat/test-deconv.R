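test_that("constrained solver reproduces closed-form toy solutions", {
  X <- diag(2)
  dimnames(X) <- list(c("g1", "g2"), c("t1", "t2"))
  y <- matrix(c(3, 1), 2, 1, dimnames = list(c("g1", "g2"), "s"))
  expect_equal(solveWeightedNnls(X, y)[, 1], c(t1 = 3, t2 = 1))

  # optimum on the boundary
  X1 <- matrix(c(1, 0), 2, 1, dimnames = list(c("g1", "g2"), "t1"))
  y1 <- matrix(c(0, 5), 2, 1, dimnames = list(c("g1", "g2"), "s"))
  expect_equal(unname(solveWeightedNnls(X1, y1)[1, 1]), 0)

  # interior optimum, certified by the brute-force grid oracle
  X2 <- cbind(t1 = c(1, 0, 1), t2 = c(0, 1, 1))
  rownames(X2) <- paste0("g", 1:3)
  y2 <- matrix(c(2, 1, 3), 3, 1, dimnames = list(rownames(X2), "s"))
  g <- rep(1, 3)
  est <- solveWeightedNnls(X2, y2, g)
  oracle <- gridNnls(X2, y2[, 1], g)
  expect_equal(unname(est[, 1]), c(2, 1), tolerance = 1e-8)
  expect_equal(unname(est[, 1]), oracle, tolerance = 2e-3)
})

test_that("noise-free mixtures are identified to 1e-8 for any positive weights", {
  for (seed in 1:4) {
    set.seed(seed)
    p <- 120; q <- 5; n <- 15
    X <- matrix(rexp(p * q), p, q,
                dimnames = list(paste0("g", 1:p), paste0("t", 1:q)))
    C <- matrix(runif(q * n), q, n,
                dimnames = list(colnames(X), paste0("s", 1:n)))
    g <- runif(p, 0.2, 3)
    est <- solveWeightedNnls(X, X %*% C, g)
    expect_lt(max(abs(est - C)), 1e-8)
  }
})

test_that("unconstrained closed form matches the cone solver on interior optima", {
  set.seed(3)
  p <- 60; q <- 4; n <- 10
  X <- matrix(rexp(p * q), p, q,
              dimnames = list(paste0("g", 1:p), paste0("t", 1:q)))
  C <- matrix(runif(q * n, 0.3, 1), q, n)
  Y <- X %*% C + abs(matrix(rnorm(p * n, sd = 0.01), p, n))
  g <- runif(p, 0.5, 2)
  cone <- solveWeightedNnls(X, Y, g)
  free <- solveWeightedLs(X, Y, g, ridge = 1e-12)
  expect_true(all(cone > 0))  # interior
  expect_equal(unname(free), unname(cone), tolerance = 1e-6)
  # identity design: estimate equals the data as ridge vanishes
  I2 <- diag(2); dimnames(I2) <- list(c("a", "b"), c("ta", "tb"))
  Y2 <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(solveWeightedLs(I2, Y2, c(1, 1), ridge = 1e-14)),
               unname(Y2), tolerance = 1e-10)
})

test_that("a zero weight removes that gene from the normal equations", {
  set.seed(8)
  X <- matrix(rexp(10 * 2), 10, 2,
              dimnames = list(paste0("g", 1:10), c("t1", "t2")))
  Y <- matrix(rexp(10 * 4), 10, 4, dimnames = list(rownames(X), NULL))
  g <- runif(10, 0.5, 1); g[4] <- 0
  full <- solveWeightedLs(X, Y, g)
  drop4 <- solveWeightedLs(X[-4, ], Y[-4, ], g[-4])
  expect_equal(full, drop4, tolerance = 1e-10)
})

test_that("correlation loss is -q at perfection and drops degenerate rows", {
  set.seed(4)
  p <- 40; q <- 3; n <- 25
  X <- matrix(rexp(p * q), p, q,
              dimnames = list(paste0("g", 1:p), paste0("t", 1:q)))
  C <- matrix(runif(q * n), q, n, dimnames = list(colnames(X), NULL))
  Y <- X %*% C
  expect_equal(correlationLoss(rep(1, p), X, Y, C), -q, tolerance = 1e-6)
  # constant truth row contributes nothing
  C2 <- C; C2[2, ] <- 0.5
  l2 <- correlationLoss(rep(1, p), X, Y, C2)
  expect_equal(l2, -2, tolerance = 1e-6)
  # all rows degenerate is an error
  C3 <- C; C3[] <- 1 / 3
  expect_error(correlationLoss(rep(1, p), X, Y, C3), "degenerate")
  expect_error(correlationLoss(rep(1, p), X, Y[, 1:2], C[, 1:2]),
               "at least 3")
})

test_that("the loss is exactly invariant to positive rescaling of g", {
  set.seed(5)
  p <- 30; q <- 3; n <- 20
  X <- matrix(rexp(p * q), p, q)
  C <- matrix(runif(q * n), q, n)
  Y <- X %*% C + matrix(rnorm(p * n, sd = 0.2), p, n)
  g <- runif(p, 0.5, 1.5)
  for (a in c(0.1, 1, 7.3)) {
    expect_equal(correlationLoss(a * g, X, Y, C),
                 correlationLoss(g, X, Y, C), tolerance = 1e-12)
  }
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(1)
  p <- 6; q <- 3; n <- 40
  X <- matrix(rexp(p * q), p, q)
  C <- matrix(runif(q * n), q, n)
  Y <- X %*% C + matrix(rnorm(p * n, sd = 0.3), p, n)
  g0 <- runif(p, 0.5, 1.5)
  lg <- hideconv:::.lossAndGrad(g0, X, Y, C, 1e-8)
  num <- vapply(seq_len(p), function(k) {
    h <- 1e-6; e <- numeric(p); e[k] <- h
    (hideconv:::.lossAndGrad(g0 + e, X, Y, C, 1e-8)$loss -
       hideconv:::.lossAndGrad(g0 - e, X, Y, C, 1e-8)$loss) / (2 * h)
  }, numeric(1))
  expect_equal(lg$grad, num, tolerance = 1e-6)
})

test_that("weight learning finds the exhaustive-search optimum on a 2-gene toy", {
  # one cell type observed through two genes with different noise levels:
  # the optimal weighting is inverse-variance, an interior point on the
  # unit circle
  set.seed(42)
  n <- 400
  X <- matrix(c(1, 1), 2, 1, dimnames = list(c("g1", "g2"), "typeA"))
  C <- matrix(runif(n, 0.2, 1), 1, n, dimnames = list("typeA", NULL))
  Y <- rbind(C[1, ] + rnorm(n, sd = 0.1),
             C[1, ] + rnorm(n, sd = 0.4))
  rownames(Y) <- rownames(X)

  # independent 1-D oracle: plain normal equations at 0.1 degree resolution
  angles <- seq(0.05, 89.95, by = 0.1)
  lossAt <- function(deg) {
    g <- c(cos(deg * pi / 180), sin(deg * pi / 180))
    A <- t(X) %*% diag(g^2) %*% X
    Chat <- solve(A + 1e-8 * sum(diag(A)), t(X) %*% diag(g^2) %*% Y)
    -stats::cor(C[1, ], Chat[1, ])
  }
  best <- angles[which.min(vapply(angles, lossAt, numeric(1)))]

  fit <- learnGeneWeights(X, Y, C, trainOptions(maxIters = 5000, tol = 1e-12))
  g <- abs(fit$weights)
  learned <- atan2(g[["g2"]], g[["g1"]]) * 180 / pi
  expect_lt(abs(learned - best), 1)
  # the less noisy gene carries more weight
  expect_gt(g[["g1"]], g[["g2"]])
  expect_equal(sum(fit$weights^2), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$trace) <= 0))
  expect_lte(fit$trace[length(fit$trace)], fit$trace[1])
})

test_that("learning improves on uniform weights for a noisy-gene mixture", {
  set.seed(6)
  p <- 40; q <- 3; n <- 150
  X <- matrix(rexp(p * q), p, q,
              dimnames = list(paste0("g", 1:p), paste0("t", 1:q)))
  C <- matrix(runif(q * n), q, n, dimnames = list(colnames(X), NULL))
  Y <- X %*% C
  noisy <- 1:15
  Y[noisy, ] <- Y[noisy, ] + matrix(rnorm(length(noisy) * n, sd = 6),
                                    length(noisy), n)
  fit <- learnGeneWeights(X, Y, C, trainOptions(maxIters = 300))
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])
  expect_true(all(diff(fit$trace) <= 0))
  # noisy genes end up down-weighted on average
  expect_lt(mean(abs(fit$weights[noisy])), mean(abs(fit$weights[-noisy])))
  expect_error(learnGeneWeights(X, Y, C * 0 + 0.5, trainOptions()),
               "varying")
})
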