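test_that("observation restriction keeps known entries and zeroes the rest", {
  H <- matrix(c(1, 3, 2, 4), 2)                 # [[1,2],[3,4]] row-wise
  all_known <- matrix(TRUE, 2, 2)
  expect_equal(project_observed(H, all_known), H)
  expect_equal(project_observed(H, !all_known), matrix(0, 2, 2))
  expect_equal(project_observed(H, diag(2) == 1),
               matrix(c(1, 0, 0, 4), 2))
  # idempotence
  set.seed(1)
  X <- matrix(rnorm(12), 3)
  m <- random_mask(3, 4, 5, 1)
  expect_equal(project_observed(project_observed(X, m), m),
               project_observed(X, m))
  expect_error(project_observed(X, matrix(TRUE, 2, 2)), "shape")
})

test_that("spectral clipping solves the norm-constrained nearest-matrix problem", {
  set.seed(3)
  H <- matrix(rnorm(20), 4)
  expect_equal(clip_spectral(H, svd(H)$d[1] + 1), H, tolerance = 1e-12)
  expect_equal(clip_spectral(H, 0), matrix(0, 4, 5))
  expect_equal(clip_spectral(diag(c(3, 1)), 2), diag(c(2, 1)))
  # projection: applying twice equals once; norm bounded
  once <- clip_spectral(H, 1.5)
  expect_equal(clip_spectral(once, 1.5), once, tolerance = 1e-12)
  expect_lte(svd(once)$d[1], 1.5 + 1e-12)
})

test_that("nuclear-ball projection is a projection with the exact radius", {
  set.seed(4)
  H <- matrix(rnorm(30), 5)
  expect_equal(project_nuclear(H, sum(svd(H)$d) + 1), H)
  lam <- 0.6 * sum(svd(H)$d)
  P <- project_nuclear(H, lam)
  expect_equal(sum(svd(P)$d), lam, tolerance = 1e-9)
  expect_equal(project_nuclear(P, lam), P, tolerance = 1e-9)
  expect_equal(project_nuclear(H, 0), matrix(0, 5, 6))
})

test_that("the restoration step overwrites exactly the known entries", {
  H <- matrix(1:6, 2)
  X <- matrix(0, 2, 3)
  all_known <- matrix(TRUE, 2, 3)
  expect_equal(izma_update(X, all_known, H), H)
  expect_equal(izma_update(X, !all_known, H), X)
  m <- matrix(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), 2)
  out <- izma_update(X, m, H)
  expect_equal(out[m], H[m])
  expect_equal(out[!m], X[!m])
})

test_that("the fixed-point iteration honours its limit cases", {
  set.seed(5)
  H <- matrix(rnorm(12), 3)
  all_known <- matrix(TRUE, 3, 4)
  r <- izma_iterate(H, all_known, sum(svd(H)$d) + 1)
  expect_equal(r$X, H, tolerance = 1e-12)
  expect_lt(r$epsilon, 1e-12)

  m <- random_mask(3, 4, 4, 2)
  r0 <- izma_iterate(H, m, 0)
  expect_equal(r0$X, matrix(0, 3, 4))
  expect_equal(r0$epsilon, sqrt(sum((H * m)^2)))
})

test_that("the known-entry residual is nonincreasing across inner iterations", {
  for (seed in 1:5) {
    M <- make_lowrank(12, 15, 2, seed)
    m <- random_mask(12, 15, 50, seed)
    lam <- 0.8 * sum(svd(M * m)$d)
    r <- izma_iterate(M, m, lam)
    expect_true(all(diff(r$epsilon_history) <= 1e-12))
  }
})

test_that("completion recovers a duplicated-row rank-1 structure", {
  row <- c(2, 5, 1, 4, 3)
  S <- rbind(row, row, row, 2 * row)
  m <- matrix(TRUE, 4, 5)
  m[1, 3] <- FALSE
  fit <- complete_matrix(S, m)
  expect_true(fit$converged)
  expect_lt(abs(fit$X[1, 3] - 1) / 1, 1e-2)
  # known entries conserved to sqrt(e_tol)
  expect_lte(sqrt(sum(((fit$X - S) * m)^2)), sqrt(1e-8))
})

test_that("completion matches a brute-force nuclear-norm oracle on 3x3 problems", {
  worst <- 0
  for (seed in 1:20) {
    set.seed(100 + seed)
    M <- matrix(rnorm(9), 3)
    hid <- sample(9, 1)
    m <- matrix(TRUE, 3, 3)
    m[hid] <- FALSE
    # oracle: line search over the hidden value, minimising the nuclear norm
    f <- function(x) { A <- M; A[hid] <- x; sum(svd(A)$d) }
    oracle <- stats::optimize(f, c(-10, 10), tol = 1e-10)$minimum
    est <- complete_matrix(M, m)$X[hid]
    worst <- max(worst, abs(est - oracle) / max(abs(oracle), 1e-9))
  }
  expect_lt(worst, 0.05)
})

test_that("completion agrees with the minimum-nuclear-norm completion of a rank-1 pattern", {
  H <- c(1, 2, 3) %*% t(c(1, 1, 2, 2))
  m <- matrix(TRUE, 3, 4)
  m[cbind(1:3, 2:4)] <- FALSE
  # independent oracle: BFGS over the three hidden values
  f <- function(x) { A <- H; A[!m] <- x; sum(svd(A)$d) }
  o <- stats::optim(c(0, 0, 0), f, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 5000))
  fit <- complete_matrix(H, m)
  expect_lt(max(abs(fit$X[!m] - o$par)), 0.05 * max(abs(o$par)))
})

test_that("a well-observed rank-1 matrix is completed exactly", {
  H <- c(1, 2, 3) %*% t(c(1, 1, 2, 2))
  m <- matrix(TRUE, 3, 4)
  m[2, 3] <- FALSE
  fit <- complete_matrix(H, m)
  expect_lt(abs(fit$X[2, 3] - H[2, 3]) / H[2, 3], 1e-2)
})

test_that("bisection respects the interval-halving iteration bound", {
  for (seed in 1:5) {
    M <- make_lowrank(15, 20, 2, seed)
    m <- random_mask(15, 20, 90, seed)
    cfg <- completion_config()
    fit <- complete_matrix(M, m, cfg)
    nuc <- sum(svd(M * m)$d)
    ltol <- min(cfg$lambda_tol, cfg$lambda_rtol * nuc)
    expect_lte(fit$outer_iterations, ceiling(log2(nuc / ltol)) + 1)
  }
})

test_that("completion configuration defaults follow the reference settings", {
  cfg <- completion_config()
  expect_equal(cfg$e_tol, 1e-8)
  expect_equal(cfg$lambda_tol, 10)
  expect_error(completion_config(e_tol = -1), "positive")
})

test_that("random rank-2 matrices are recovered from 70% of their entries", {
  ok <- 0
  for (seed in 1:8) {
    M <- make_lowrank(30, 40, 2, seed)
    m <- random_mask(30, 40, 360, seed)
    fit <- complete_matrix(M, m)
    if (rel_frob(fit$X[!m], M[!m]) <= 1e-2) ok <- ok + 1
  }
  expect_gte(ok, 7)
})

test_that("SVT baseline completes rank-1 data and respects constraints", {
  M <- make_lowrank(20, 20, 1, 31)
  m <- random_mask(20, 20, 200, 31)
  fit <- svt_complete(M, m)
  expect_lt(rel_frob(fit$X[!m], M[!m]), 1e-2)

  all_known <- matrix(TRUE, 20, 20)
  fit2 <- svt_complete(M, all_known, tol = 1e-3)
  expect_lt(rel_frob(fit2$X[all_known], M[all_known]), 1e-3)

  z <- svt_complete(matrix(0, 5, 5), random_mask(5, 5, 10, 1))
  expect_equal(z$X, matrix(0, 5, 5))
})
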