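test_that("FCIDUMP write/read round-trips tables exactly", {
  for (tb in list(hubbard_chain(3, 0.7, 2.5),
                  random_cas(3, 4, seed = 9, scale = 0.8))) {
    tb$core_energy <- 0.125
    f <- withr::local_tempfile()
    write_fcidump(tb, f)
    back <- read_fcidump(f)
    expect_equal(back$n_orb, tb$n_orb)
    expect_equal(back$n_elec, tb$n_elec)
    expect_equal(back$two_s_target, tb$two_s_target)
    expect_equal(back$core_energy, tb$core_energy)
    expect_equal(back$one_body, tb$one_body, tolerance = 1e-14)
    expect_equal(back$two_body, tb$two_body, tolerance = 1e-14)
  }
})

test_that("FCIDUMP parsing fills symmetry partners and handles minimal files", {
  f <- withr::local_tempfile()
  writeLines(c("&FCI NORB=1,NELEC=2,MS2=0,", " ORBSYM=1,", " ISYM=1,", "/",
               " 0.5 1 1 1 1"), f)
  tb <- read_fcidump(f)
  expect_equal(tb$two_body[1, 1, 1, 1], 0.5)
  expect_true(all(tb$one_body == 0))

  # a single listed h[1,2] populates h[2,1]
  f2 <- withr::local_tempfile()
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "/", " -1.0 1 2 0 0"), f2)
  tb2 <- read_fcidump(f2)
  expect_equal(tb2$one_body[2, 1], -1)
  expect_equal(tb2$one_body[1, 2], -1)

  # one listed (21|11)-class integral populates its full 8-fold orbit
  f3 <- withr::local_tempfile()
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "/", " 0.25 2 1 1 1"), f3)
  g <- read_fcidump(f3)$two_body
  for (idx in list(c(2, 1, 1, 1), c(1, 2, 1, 1), c(1, 1, 2, 1), c(1, 1, 1, 2)))
    expect_equal(g[idx[1], idx[2], idx[3], idx[4]], 0.25)

  # core-energy-only table writes exactly one value record
  f4 <- withr::local_tempfile()
  write_fcidump(integral_table(1, 0, 0, core_energy = 1.25), f4)
  recs <- grep("^\\s*[-0-9]", readLines(f4), value = TRUE)
  expect_length(recs, 1)
  expect_match(recs, "1\\.25.*0\\s+0\\s+0\\s+0")
})

test_that("malformed headers and symmetry violations are rejected with context", {
  f <- withr::local_tempfile()
  writeLines(c("&FCI NELEC=2,MS2=0,", "/", " 1.0 1 1 1 1"), f)
  expect_error(read_fcidump(f), "NORB")
  writeLines(c("not a header", "/"), f)
  expect_error(read_fcidump(f), "line 1")

  tb <- hubbard_chain(2, 1, 1)
  tb$two_body[1, 2, 1, 1] <- 0.3   # break the 8-fold symmetry
  expect_error(validate_integral_table(tb), "symmetry")
  expect_error(write_fcidump(tb, withr::local_tempfile()), "symmetry")
})

test_that("model generators satisfy their defining algebra exactly", {
  tb <- hubbard_chain(2, 1, 4)
  expect_equal(tb$one_body, matrix(c(0, -1, -1, 0), 2, 2))
  expect_equal(tb$two_body[1, 1, 1, 1], 4)
  expect_equal(tb$two_body[2, 2, 2, 2], 4)
  expect_equal(sum(tb$two_body != 0), 2)

  # single site, U = 0, doubly occupied: E = 2 h[1,1] = 0
  tb1 <- hubbard_chain(1, 1, 0, n_elec = 2, two_s_target = 0)
  expect_equal(fci_ground_state(tb1, 2, 0)$energy, 0)

  # random tables: deterministic, exactly symmetric, caller RNG untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  a <- random_cas(4, 4, seed = 7)
  b <- random_cas(4, 4, seed = 7)
  expect_identical(a, b)
  expect_equal(rnorm(1), before)
  g <- a$two_body
  for (perm in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2)))
    expect_identical(g, aperm(g, perm))
  expect_identical(a$one_body, t(a$one_body))
  expect_silent(validate_integral_table(a))
  expect_false(identical(a$two_body, random_cas(4, 4, seed = 8)$two_body))
})

test_that("state energies are invariant under symmetry-orbit averaging of g", {
  # replacing g by its 8-fold orbit average must leave every matrix element
  # of H unchanged (the spin-summed Hamiltonian only sees the average)
  set.seed(5)
  tb <- random_cas(3, 3, seed = 5)
  g2 <- qcdmrg:::symmetrize_two_body(tb$two_body)
  expect_equal(g2, tb$two_body, tolerance = 1e-14)
  e1 <- fci_ground_state(tb, 3, 1)$energy
  tb2 <- tb; tb2$two_body <- g2
  expect_equal(fci_ground_state(tb2, 3, 1)$energy, e1, tolerance = 1e-12)
})
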