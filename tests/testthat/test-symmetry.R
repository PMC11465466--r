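test_that("sector fusion follows particle-number addition and the Clebsch-Gordan series", {
  # U(1): projections add
  f <- fuse(sector(1, 1, "u1"), sector(1, -1, "u1"), "u1")
  expect_length(f, 1)
  expect_equal(c(f[[1]]$n, f[[1]]$spin_label), c(2L, 0L))

  # SU(2): two doublets give singlet and triplet
  f <- fuse(sector(1, 1, "su2"), sector(1, 1, "su2"), "su2")
  expect_equal(vapply(f, function(s) s$spin_label, 0L), c(0L, 2L))
  expect_true(all(vapply(f, function(s) s$n, 0L) == 2L))

  # identity fusion
  f <- fuse(sector(0, 0, "su2"), sector(3, 1, "su2"), "su2")
  expect_length(f, 1)
  expect_equal(c(f[[1]]$n, f[[1]]$spin_label), c(3L, 1L))

  # combined U(1) dimension of the series is (2Sa+1)(2Sb+1)
  for (sa in 0:3) for (sb in 0:3) {
    f <- fuse(sector(sa, sa, "su2"), sector(sb, sb, "su2"), "su2")
    expect_equal(sum(vapply(f, function(s) s$spin_label + 1L, 0L)),
                 (sa + 1L) * (sb + 1L))
  }

  # invalid sectors are rejected
  expect_error(sector(1, -1, "su2"), "2S")
  expect_error(sector(2, 1, "su2"), "parity")
})

test_that("local single-orbital basis has dimension 4 in both accounting modes", {
  u1 <- local_basis("u1")
  expect_equal(nrow(u1), 4L)
  expect_equal(sum(u1$dim), 4L)
  su2 <- local_basis("su2")
  expect_equal(nrow(su2), 3L)            # two singlets and one doublet
  expect_equal(sum(su2$dim), 4L)         # U(1)-equivalent dimension
  # parity of the spin label matches the parity of n everywhere
  expect_true(all((su2$spin_label - su2$n) %% 2 == 0))
  expect_true(all((u1$spin_label - u1$n) %% 2 == 0))
})

test_that("u1_dimension implements the multiplet accounting rule", {
  expect_equal(u1_dimension(multiplet_spectrum(1, 3)), 6L)
  expect_equal(u1_dimension(multiplet_spectrum(c(0, 1, 2), c(2, 3, 1))), 11L)
  expect_equal(u1_dimension(multiplet_spectrum()), 0L)

  # additivity under concatenation and the multiplet-count lower bound
  set.seed(42)
  for (rep in 1:20) {
    s1 <- sample(0:4, 3, replace = TRUE); m1 <- sample(1:5, 3, replace = TRUE)
    s2 <- sample(0:4, 2, replace = TRUE); m2 <- sample(1:5, 2, replace = TRUE)
    a <- multiplet_spectrum(s1, m1); b <- multiplet_spectrum(s2, m2)
    ab <- multiplet_spectrum(c(s1, s2), c(m1, m2))
    expect_equal(u1_dimension(ab), u1_dimension(a) + u1_dimension(b))
    expect_gte(u1_dimension(a), multiplet_count(a))
    if (all(s1 == 0)) expect_equal(u1_dimension(a), multiplet_count(a))
  }
})

test_that("character peeling recovers multiplet content from Sz-resolved counts", {
  set.seed(7)
  for (rep in 1:25) {
    two_s <- sample(0:5, sample(1:4, 1), replace = TRUE)
    mult <- sample(1:4, length(two_s), replace = TRUE)
    truth <- multiplet_spectrum(two_s, mult)
    # build the Sz-resolved counts of these multiplets
    cnt <- new.env(parent = emptyenv())
    for (i in seq_along(two_s)) {
      for (sz in seq.int(-two_s[i], two_s[i], by = 2)) {
        key <- as.character(sz)
        cnt[[key]] <- (if (is.null(cnt[[key]])) 0L else cnt[[key]]) + mult[i]
      }
    }
    szs <- as.integer(ls(cnt))
    peeled <- qcdmrg:::peel_multiplets(szs, vapply(as.character(szs),
                                                  function(k) cnt[[k]], 0L))
    got <- multiplet_spectrum(peeled$two_s, peeled$multiplicity)
    expect_equal(as.data.frame(got), as.data.frame(truth))
  }
  # inconsistent counts (broken multiplet) are flagged
  expect_null(qcdmrg:::peel_multiplets(c(-1L, 1L), c(1L, 2L)))
})
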