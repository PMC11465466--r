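test_that("single-determinant limits reproduce analytic energies", {
  # one orbital, two electrons: E = 2 h11 + (11|11)
  tb <- integral_table(1, 2, 0, one_body = matrix(-1, 1, 1),
                       two_body = array(0.5, rep(1, 4)))
  expect_equal(fci_ground_state(tb, 2, 0)$energy, -1.5)

  # core energy enters additively
  tb$core_energy <- 0.25
  expect_equal(fci_ground_state(tb, 2, 0)$energy, -1.25)
})

test_that("Hubbard dimer ground state matches the closed form and is a singlet", {
  for (par in list(c(1, 4), c(0.5, 2), c(2, 1))) {
    tb <- hubbard_chain(2, par[1], par[2])
    res <- fci_ground_state(tb, 2, 0)
    expect_equal(res$energy, hubbard_dimer_energy(par[1], par[2]),
                 tolerance = 1e-12)
    expect_lt(abs(s_squared(res$vector, res$basis)), 1e-10)
  }
})

test_that("s_squared labels determinants and multiplets correctly", {
  b <- determinant_basis(2, 2, 2)          # |up, up>
  expect_length(b$dets, 1)
  expect_equal(s_squared(1, b), 2)          # S = 1

  b0 <- determinant_basis(1, 2, 0)          # closed shell |updn>
  expect_equal(s_squared(1, b0), 0)

  # triplet energy is independent of Sz within the multiplet
  tb <- hubbard_chain(2, 1, 4)
  e_szmax <- fci_ground_state(tb, 2, 2)$energy
  res0 <- fci_ground_state(tb, 2, 0)
  # lowest S=1 state in the Sz=0 sector via spin-resolved search
  t0 <- fci_lowest_with_spin(tb, two_s = 2)
  expect_equal(t0$energy, e_szmax, tolerance = 1e-10)
  expect_equal(t0$s_squared, 2, tolerance = 1e-8)
})

test_that("iterative and dense diagonalization agree", {
  tb <- random_cas(4, 4, seed = 3)
  b <- determinant_basis(4, 4, 0)
  H <- qcdmrg:::build_fci_hamiltonian(tb, b)
  dense <- eigen(as.matrix(H), symmetric = TRUE)$values
  lan <- qcdmrg:::lanczos_lowest(function(x) as.numeric(H %*% x),
                                 Matrix::diag(H), length(b$dets))
  expect_equal(lan$value, min(dense), tolerance = 1e-9)
})

test_that("determinant basis counting and caps are enforced", {
  b <- determinant_basis(4, 4, 0)
  expect_equal(length(b$dets), choose(4, 2)^2)
  expect_error(determinant_basis(4, 5, 0), "parity")
  expect_error(determinant_basis(2, 5, 1), "empty")
})

test_that("Slater-Condon matrix elements equal the materialized MPO elementwise", {
  # sign-convention lock between the determinant oracle and the MPO route,
  # checked on all pairs of a 3-orbital system
  tb <- random_cas(3, 4, seed = 13, scale = 0.6)
  Hf <- dense_fock_hamiltonian(tb)
  Hm <- qcdmrg:::mpo_to_dense(build_mpo(tb))
  expect_lt(max(abs(Hf - Hm)), 1e-11)
})
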