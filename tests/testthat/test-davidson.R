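test_that("diagonal operators converge immediately to the lowest eigenvalue", {
  d <- c(1, 2, 3)
  op <- function(x) d * x
  res <- davidson(op, guess = c(0.2, 1, 0.4), diag_preconditioner = d)
  expect_equal(res$value, 1, tolerance = 1e-10)
  expect_true(res$converged)
  expect_equal(abs(res$vector[1]), 1, tolerance = 1e-8)
})

test_that("random hermitian matrices match full diagonalization", {
  for (seed in 1:4) {
    set.seed(seed)
    A <- matrix(rnorm(2500), 50, 50)
    A <- (A + t(A)) / 2
    res <- davidson(function(x) A %*% x, guess = rnorm(50), tol = 1e-11,
                    diag_preconditioner = diag(A), max_iter = 200)
    expect_true(res$converged)
    expect_equal(res$value, min(eigen(A, symmetric = TRUE)$values),
                 tolerance = 1e-9)
  }
})

test_that("an exact eigenvector guess converges within two iterations", {
  set.seed(1)
  A <- matrix(rnorm(400), 20, 20); A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  res <- davidson(function(x) A %*% x, guess = es$vectors[, 20],
                  diag_preconditioner = diag(A))
  expect_true(res$converged)
  expect_lte(res$iterations, 2L)
})

test_that("subspace restarts keep convergence on hard spectra", {
  set.seed(2)
  # diagonally dominant operator (like a DMRG effective Hamiltonian) with a
  # small subspace cap so the search passes through several restarts
  d0 <- c(1, 1.05, 1.1, seq(2, 60, length.out = 97))
  P <- matrix(rnorm(100^2, sd = 0.05), 100); P <- (P + t(P)) / 2
  A <- diag(d0) + P
  ref <- min(eigen(A, symmetric = TRUE)$values)
  res <- davidson(function(x) A %*% x, guess = rnorm(100), tol = 1e-9,
                  diag_preconditioner = diag(A), max_iter = 500,
                  max_subspace = 8)
  expect_true(res$converged)
  expect_gt(res$iterations, 8)    # at least one restart happened
  expect_equal(res$value, ref, tolerance = 1e-8)
})
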