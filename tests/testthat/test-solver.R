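test_that("the two-site effective Hamiltonian materializes the sector Hamiltonian", {
  # on a 2-orbital system the two-site window spans the whole chain, so
  # H_eff columns must reproduce the dense Hamiltonian in the target sector
  tb <- random_cas(2, 2, seed = 6)
  mpo <- qcdmrg:::mpo_prepare(build_mpo(tb))
  psi <- random_mps(2, c(2, 0), d = 4, seed = 1)
  envs <- qcdmrg:::init_environments(psi, mpo)
  heff <- heff_operator(mpo, envs$L[[1]], envs$R[[3]], 1,
                        psi$tensors[[1]]$axes[[1]], psi$tensors[[2]]$axes[[3]])
  n <- heff$total
  Hmat <- vapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- 1
    apply_heff(heff, e)
  }, numeric(n))
  expect_equal(Hmat, t(Hmat), tolerance = 1e-11)
  # eigenvalues equal the (N=2, Sz=0) sector spectrum
  ref <- eigen(as.matrix(qcdmrg:::build_fci_hamiltonian(tb, determinant_basis(2, 2, 0))),
               symmetric = TRUE)$values
  expect_equal(sort(eigen(Hmat, symmetric = TRUE)$values), sort(ref),
               tolerance = 1e-9)

  # linearity of the matvec closure
  set.seed(4)
  x <- rnorm(n); y <- rnorm(n)
  expect_equal(apply_heff(heff, 2 * x - 3 * y),
               2 * apply_heff(heff, x) - 3 * apply_heff(heff, y),
               tolerance = 1e-10)
  # hermiticity through inner products
  expect_equal(sum(x * apply_heff(heff, y)), sum(y * apply_heff(heff, x)),
               tolerance = 1e-9)
})

test_that("a zero Hamiltonian leaves the state unchanged at zero energy", {
  tb0 <- integral_table(3, 3, 1)
  sch <- sweep_schedule(d_max = 8, n_sweeps = 2, max_sweeps = 4, energy_tol = 1e-9)
  res <- run_dmrg(tb0, c(3, 1), sch, seed = 2, mode = "u1")
  expect_equal(res$energy, 0, tolerance = 1e-12)
  expect_equal(abs(res$records$energy), rep(0, nrow(res$records)), tolerance = 1e-12)
})

test_that("the Hubbard dimer converges to the closed form within two sweep pairs", {
  tb <- hubbard_chain(2, 1, 4)
  sch <- sweep_schedule(d_max = 4, n_sweeps = 2, max_sweeps = 2, energy_tol = 1e-10)
  res <- run_dmrg(tb, c(2, 0), sch, seed = 1, mode = "u1")
  expect_equal(res$energy, hubbard_dimer_energy(1, 4), tolerance = 1e-8)
})

test_that("sweep energies decrease monotonically and bound the FCI energy", {
  tb <- random_cas(4, 4, seed = 31)
  e_fci <- fci_ground_state(tb, 4, 0)$energy
  sch <- sweep_schedule(d_max = c(8, 16, 64), n_sweeps = 2, max_sweeps = 10,
                        energy_tol = 1e-10)
  res <- run_dmrg(tb, c(4, 0), sch, seed = 3, mode = "u1")
  e <- res$records$energy
  expect_true(all(diff(e) <= 1e-9))
  expect_true(all(e >= e_fci - 1e-9))
  expect_equal(res$energy, e_fci, tolerance = 1e-8)
})

test_that("ground-state energies match full CI in both symmetry modes", {
  cases <- list(
    list(tb = hubbard_chain(3, 1, 2, n_elec = 3), tgt = c(3, 1)),
    list(tb = random_cas(3, 4, seed = 17), tgt = c(4, 0)),
    list(tb = random_cas(4, 4, seed = 23), tgt = c(4, 0)))
  for (cs in cases) {
    res_u1 <- run_dmrg(cs$tb, cs$tgt, full_d_schedule(), seed = 1, mode = "u1")
    e_fci <- fci_ground_state(cs$tb, cs$tgt[1], cs$tgt[2])$energy
    expect_equal(res_u1$energy, e_fci, tolerance = 1e-8)

    res_su2 <- run_dmrg(cs$tb, cs$tgt, full_d_schedule(), seed = 1, mode = "su2")
    spin_ref <- fci_lowest_with_spin(cs$tb, two_s = cs$tgt[2], n_elec = cs$tgt[1])
    expect_equal(res_su2$energy, spin_ref$energy, tolerance = 1e-8)
    expect_equal(res_su2$s_squared, 0, tolerance = 1e-7)  # embedded singlet
  }
})

test_that("identical configuration and seed reproduce runs exactly", {
  tb <- random_cas(4, 4, seed = 41)
  sch <- sweep_schedule(d_max = c(8, 24), n_sweeps = 2, max_sweeps = 6,
                        energy_tol = 1e-10)
  a <- run_dmrg(tb, c(4, 0), sch, seed = 7, mode = "u1")
  b <- run_dmrg(tb, c(4, 0), sch, seed = 7, mode = "u1")
  expect_equal(a$records$energy, b$records$energy, tolerance = 1e-12)
  expect_identical(ledger_phases(a$ledger), ledger_phases(b$ledger))
  expect_true(all(ledger_phases(a$ledger) %% 1 == 0))
})

test_that("schedules validate their stage structure", {
  expect_error(sweep_schedule(d_max = c(16, 8)), "non-decreasing")
  expect_error(sweep_schedule(d_max = 8, davidson_tol = -1))
  sch <- sweep_schedule(d_max = c(8, 16), n_sweeps = c(2, 3))
  expect_equal(sch$stages$n_sweeps, c(2L, 3L))
  expect_equal(qcdmrg:::stage_for_sweep(sch, 1), 1L)
  expect_equal(qcdmrg:::stage_for_sweep(sch, 5), 2L)
  expect_equal(qcdmrg:::stage_for_sweep(sch, 99), 2L)
})
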