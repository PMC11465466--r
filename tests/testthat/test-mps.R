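test_that("random states are normalized, right-canonical and seed-deterministic", {
  psi <- random_mps(4, c(4, 0), d = 8, seed = 5)
  expect_equal(mps_norm(psi), 1, tolerance = 1e-12)
  expect_equal(psi$center, 1L)
  expect_lt(mps_isometry_error(psi), 1e-12)
  psi2 <- random_mps(4, c(4, 0), d = 8, seed = 5)
  expect_equal(mps_overlap(psi, psi2), 1, tolerance = 1e-12)
  psi3 <- random_mps(4, c(4, 0), d = 8, seed = 6)
  expect_lt(abs(mps_overlap(psi, psi3)), 1 - 1e-6)

  # target sector constraints
  expect_silent(random_mps(2, c(2, 0), d = 4, seed = 1))
  expect_error(random_mps(2, c(5, 1), d = 4, seed = 1), "unreachable")
})

test_that("canonicalization is exact, idempotent and gauge-invariant", {
  tb <- random_cas(4, 4, seed = 2)
  mpo <- build_mpo(tb)
  psi <- random_mps(4, c(4, 0), d = 10, seed = 3)
  e0 <- mps_expectation(psi, mpo)
  for (ctr in c(3L, 1L, 4L, 2L)) {
    psi <- canonicalize(psi, ctr)
    expect_equal(psi$center, ctr)
    expect_lt(mps_isometry_error(psi), 1e-11)
    expect_equal(mps_norm(psi), 1, tolerance = 1e-11)
    expect_equal(mps_expectation(psi, mpo), e0, tolerance = 1e-10)
  }
  # double application changes nothing measurable
  psi_a <- canonicalize(psi, 2L)
  psi_b <- canonicalize(psi_a, 2L)
  expect_equal(mps_overlap(psi_a, psi_b), 1, tolerance = 1e-12)
})

test_that("bond truncation reports the global discarded weight and renormalizes", {
  psi <- random_mps(4, c(4, 0), d = 12, seed = 9)
  # cap above the current dimension: nothing happens
  tr <- truncate_bond(psi, 2, d_max = Inf)
  expect_equal(tr$discarded_weight, 0)
  expect_equal(abs(mps_overlap(tr$state, psi)), 1, tolerance = 1e-11)

  # discarded weight is non-increasing in the cap and the state stays normalized
  prev <- Inf
  for (d in c(1, 2, 4, 8)) {
    tr <- truncate_bond(psi, 2, d_max = d)
    expect_lte(tr$discarded_weight, prev + 1e-14)
    expect_equal(mps_norm(tr$state), 1, tolerance = 1e-11)
    prev <- tr$discarded_weight
  }

  # a product state (every bond already rank 1) truncates without loss
  prod <- random_mps(3, c(3, 1), d = 4, seed = 4)
  for (b in 1:2) prod <- truncate_bond(prod, b, d_max = 1)$state
  tr <- truncate_bond(prod, 1, d_max = 1)
  expect_lt(tr$discarded_weight, 1e-24)
  tr2 <- truncate_bond(prod, 2, d_max = 5)
  expect_lt(tr2$discarded_weight, 1e-24)
})

test_that("Schmidt spectra are consistent with the state norm", {
  psi <- random_mps(5, c(5, 1), d = 10, seed = 11)
  spectra <- mps_schmidt_spectra(psi)
  expect_length(spectra, 4)
  for (sp in spectra)
    expect_equal(sum(sp$value^2), 1, tolerance = 1e-11)
})

test_that("multiplet decomposition of singlet-state bonds accounts for all states", {
  # a converged singlet ground state has multiplet-complete bond bases
  tb <- hubbard_chain(4, 1, 4)
  res <- run_dmrg(tb, c(4, 0), full_d_schedule(), seed = 2, mode = "su2")
  for (i in seq_along(res$multiplet_spectra)) {
    spec <- res$multiplet_spectra[[i]]
    expect_equal(u1_dimension(spec),
                 sum(vapply(res$bond_spectra[[i]]$value, function(v) 1L, 1L)))
    expect_gte(u1_dimension(spec), multiplet_count(spec))
  }
})
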