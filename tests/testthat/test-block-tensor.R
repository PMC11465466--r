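random_axes <- function() {
  list(bt_axis(1L, c(0, 1), c(0, 1), c(2, 3)),
       bt_axis(1L, c(0, 1, 1, 2), c(0, 1, -1, 0), c(1, 1, 1, 1)),
       bt_axis(-1L, c(0, 1, 2), c(0, 1, 0), c(2, 3, 2)))
}

test_that("conservation law is enforced at construction", {
  ax <- random_axes()
  # a key whose direction-weighted quantum numbers do not cancel
  bad_key <- c(qcdmrg:::qn_encode(0L, 0L), qcdmrg:::qn_encode(1L, 1L),
               qcdmrg:::qn_encode(0L, 0L))
  expect_error(block_tensor(ax, list(bad_key), list(array(1, c(2, 1, 2)))),
               "conservation")
  # wrong block shape
  good_key <- c(qcdmrg:::qn_encode(0L, 0L), qcdmrg:::qn_encode(1L, 1L),
                qcdmrg:::qn_encode(1L, 1L))
  expect_error(block_tensor(ax, list(good_key), list(array(1, c(2, 1, 1)))),
               "shape")
  expect_silent(block_tensor(ax, list(good_key), list(array(1, c(2, 1, 3)))))
})

test_that("block contraction matches the dense oracle and counts 2mnk flops", {
  # single dense sector: ledger increments by exactly 2*m*n*k
  axm <- bt_axis(1L, 1, 1, 2)
  a <- block_tensor(list(axm, bt_axis(-1L, 1, 1, 2)),
                    list(c(qcdmrg:::qn_encode(1L, 1L), qcdmrg:::qn_encode(1L, 1L))),
                    list(matrix(1:4, 2, 2)))
  led <- flop_ledger()
  bt_contract(a, a, 2, 1, led, "p")
  expect_identical(ledger_total(led), 16)

  # random multi-sector tensors against scatter-to-dense contraction
  for (seed in 1:5) {
    set.seed(seed)
    ax <- random_axes()
    A <- qcdmrg:::bt_random(ax)
    B <- qcdmrg:::bt_random(list(bt_axis(1L, c(0, 1, 2), c(0, 1, 0), c(2, 3, 2)),
                                 bt_axis(-1L, c(0, 1), c(0, -1), c(2, 2))))
    led <- flop_ledger()
    C <- bt_contract(A, B, 3, 1, led, "p")
    DA <- bt_to_dense(A); DB <- bt_to_dense(B); DC <- bt_to_dense(C)
    ref <- matrix(DA, prod(dim(DA)[1:2]), dim(DA)[3]) %*% DB
    expect_lt(max(abs(array(ref, dim(DC)) - DC)), 1e-12)
    expect_true(ledger_total(led) %% 1 == 0)
    # rerun gives identical counts
    led2 <- flop_ledger()
    bt_contract(A, B, 3, 1, led2, "p")
    expect_identical(ledger_total(led), ledger_total(led2))
  }

  # direction mismatch is a structural error naming the axis pair
  A <- qcdmrg:::bt_random(random_axes())
  expect_error(bt_contract(A, A, 1, 1), "opposite directions")
})

test_that("svd_split factorizes exactly and truncates by global weight", {
  set.seed(11)
  A <- qcdmrg:::bt_random(random_axes())
  # keeping all states reconstructs the input
  sp <- bt_svd_split(A, c(1, 2))
  rec <- bt_contract(sp$left, sp$right, 3, 1)
  expect_lt(max(abs(bt_to_dense(rec) - bt_to_dense(A))) / max(abs(bt_to_dense(A))),
            1e-12)
  expect_equal(sp$discarded_weight, 0)

  # discarded weight matches the dense singular spectrum, for every cap
  DA <- bt_to_dense(A)
  M <- matrix(DA, prod(dim(DA)[1:2]), dim(DA)[3])
  sv <- svd(M)$d
  total <- sum(sv^2)
  prev <- Inf
  for (d in 1:6) {
    spd <- bt_svd_split(A, c(1, 2), d_max = d)
    expected <- sum(sort(sv, decreasing = TRUE)[-seq_len(min(d, length(sv)))]^2) / total
    expect_equal(spd$discarded_weight, expected, tolerance = 1e-10)
    expect_lte(spd$discarded_weight, prev + 1e-12)  # monotone in the cap
    prev <- spd$discarded_weight
  }

  # a rank-1 (product) tensor has zero discarded weight at any cap >= 1
  u <- rnorm(6); v <- rnorm(7)
  P <- outer(u, v)
  axr <- bt_axis(1L, c(0, 1), c(0, 1), c(3, 3))
  axc <- bt_axis(-1L, c(0, 1), c(0, 1), c(3, 4))
  # restrict to a single sector pair so the dense array is conserving
  P1 <- matrix(0, 6, 7); P1[1:3, 1:3] <- P[1:3, 1:3]
  A1 <- qcdmrg:::bt_from_dense(array(P1, c(6, 7)), list(axr, axc))
  sp1 <- bt_svd_split(A1, 1, d_max = 1)
  expect_lt(sp1$discarded_weight, 1e-24)
})

test_that("dense scatter/gather round-trips and rejects non-conserving arrays", {
  set.seed(3)
  A <- qcdmrg:::bt_random(random_axes())
  D <- bt_to_dense(A)
  B <- qcdmrg:::bt_from_dense(D, A$axes)
  expect_equal(bt_to_dense(B), D)
  D[1, 4, 1] <- 1  # outside any conserving block
  expect_error(qcdmrg:::bt_from_dense(D, A$axes), "outside")
})

test_that("SU(2)-mode truncation keeps whole degenerate multiplets", {
  # two exactly degenerate values across Sz = +-1 form one doublet; a cap of
  # one multiplet must keep both or neither
  vals <- c(0.8, 0.8, 0.5)
  n <- c(1L, 1L, 0L); s <- c(1L, -1L, 0L)
  keep <- qcdmrg:::select_kept_states(vals, n, s, d_max = 1, mode = "su2")
  expect_setequal(keep, c(1L, 2L))
  keep2 <- qcdmrg:::select_kept_states(vals, n, s, d_max = 2, mode = "su2")
  expect_setequal(keep2, 1:3)
  # u1 mode counts states, not multiplets
  keep_u1 <- qcdmrg:::select_kept_states(vals, n, s, d_max = 1, mode = "u1")
  expect_length(keep_u1, 1)
})
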