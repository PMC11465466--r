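test_that("the Hamiltonian MPO reproduces analytic single-site expectations", {
  tb <- integral_table(1, 2, 0, one_body = matrix(-1, 1, 1),
                       two_body = array(0.5, rep(1, 4)))
  mpo <- build_mpo(tb)
  H <- qcdmrg:::mpo_to_dense(mpo)
  # doubly occupied state is the 4th local basis state
  expect_equal(H[4, 4], -1.5)
})

test_that("MPO action equals the dense second-quantized Hamiltonian", {
  for (cfg in list(hubbard_chain(2, 1, 4),
                   hubbard_chain(3, 0.8, 1.5),
                   random_cas(2, 2, seed = 3),
                   random_cas(3, 4, seed = 7, scale = 0.7))) {
    mpo <- build_mpo(cfg)
    expect_lt(max(abs(qcdmrg:::mpo_to_dense(mpo) - dense_fock_hamiltonian(cfg))),
              1e-11)
  }
})

test_that("Hubbard dimer MPO expectations on product states follow the model", {
  tb <- hubbard_chain(2, 1, 4)
  H <- qcdmrg:::mpo_to_dense(build_mpo(tb))
  # product basis index (site 1 slowest): |up, dn> -> (2-1)*4 + 3 = 7
  expect_equal(H[7, 7], 0)     # no double occupancy, no diagonal energy
  # |updn, 0> -> (4-1)*4 + 1 = 13
  expect_equal(H[13, 13], 4)   # one doubly occupied site costs U
})

test_that("MPO expectation on matrix product states matches the dense oracle", {
  tb <- random_cas(3, 4, seed = 21, scale = 0.5)
  mpo <- build_mpo(tb)
  Hd <- dense_fock_hamiltonian(tb)
  for (seed in 1:6) {
    psi <- random_mps(3, c(4, 0), d = 6, seed = seed)
    e_mps <- mps_expectation(psi, mpo)
    # scatter the MPS to a dense Fock-space vector
    v <- mps_to_dense_vector(psi)
    expect_equal(e_mps, as.numeric(t(v) %*% Hd %*% v), tolerance = 1e-10)
  }
})

test_that("zero and constant operators behave as scalars", {
  tb0 <- integral_table(2, 2, 0)           # all integrals zero
  psi <- random_mps(2, c(2, 0), d = 4, seed = 1)
  expect_equal(mps_expectation(psi, build_mpo(tb0)), 0)
  tb1 <- integral_table(2, 2, 0, core_energy = 1)
  expect_equal(mps_expectation(psi, build_mpo(tb1)), 1, tolerance = 1e-12)
})

test_that("the total-spin MPO has integer spin spectrum and respects the ancilla", {
  s2 <- qcdmrg:::mpo_to_dense(build_s2_mpo(2))
  ev <- sort(unique(round(eigen(s2, symmetric = TRUE)$values, 8)))
  expect_equal(ev, c(0, 0.75, 2))
  s2a <- qcdmrg:::mpo_to_dense(build_s2_mpo(1, ancilla_two_s = 2L))
  ev <- sort(unique(round(eigen(s2a, symmetric = TRUE)$values, 8)))
  # spin-1 ancilla coupled to one orbital: S in {1/2, 3/2} union {0,1,2} sectors
  expect_true(all(ev %in% c(0, 0.75, 2, 3.75, 6)))
})

test_that("operator-bond dimension stays quadratic in orbital count", {
  dims <- vapply(3:6, function(n)
    max(build_mpo(hubbard_chain(n, 1, 2))$bond_dims), 0L)
  # nearest-neighbor model: constant small bond dimension
  expect_true(all(dims <= 8))
  d6 <- max(build_mpo(random_cas(6, 6, seed = 2))$bond_dims)
  # dense two-body table: complementary-operator scale, far below the
  # O(n^4) term count
  expect_lt(d6, 6^2 * 5)
})
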