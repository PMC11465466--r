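# Shared fixtures and oracle helpers for the test suite.  Everything is
# generated in code; no stored data.

# closed-form Hubbard dimer singlet ground energy at half filling
hubbard_dimer_energy <- function(t, u) (u - sqrt(u^2 + 16 * t^2)) / 2

# scatter the sector-wise FCI Hamiltonians into the full Fock-space matrix
# (product-basis index convention: site 1 slowest, matching mpo_to_dense)
dense_fock_hamiltonian <- function(tb) {
  n <- tb$n_orb
  D <- 4^n
  H <- matrix(0, D, D)
  for (ne in 0:(2 * n)) for (tsz in seq(-ne, ne, by = 2)) {
    nu <- (ne + tsz) / 2; nd <- (ne - tsz) / 2
    if (nu < 0 || nd < 0 || nu > n || nd > n) next
    b <- determinant_basis(n, ne, tsz)
    Hs <- as.matrix(qcdmrg:::build_fci_hamiltonian(tb, b))
    ids <- vapply(b$dets, embed_det, 0, n = n)
    H[ids, ids] <- H[ids, ids] + Hs
  }
  H
}

# Fock-space index of a determinant bitmask (site-major spin orbitals)
embed_det <- function(det, n) {
  idx <- 0
  for (i in seq_len(n)) {
    up <- bitwAnd(det, bitwShiftL(1L, 2L * (i - 1L))) != 0L
    dn <- bitwAnd(det, bitwShiftL(1L, 2L * (i - 1L) + 1L)) != 0L
    idx <- idx + (up + 2 * dn) * 4^(n - i)
  }
  idx + 1
}

# quick schedule for exact (full bond dimension) runs on tiny systems
full_d_schedule <- function(max_sweeps = 14, energy_tol = 1e-11) {
  sweep_schedule(d_max = c(64, 4096), n_sweeps = 2, max_sweeps = max_sweeps,
                 energy_tol = energy_tol)
}

# scatter an MPS into the dense Fock-space vector (site 1 slowest, local
# states in the |0>, |up>, |dn>, |updn> order used by mpo_to_dense)
mps_to_dense_vector <- function(state) {
  M <- matrix(1, 1, 1)
  for (i in seq_len(state$n_sites)) {
    t <- state$tensors[[i]]
    T <- bt_to_dense(t)
    d <- dim(T)
    # reorder the physical axis from sector-sorted order to matrix order
    codes_matrix <- qcdmrg:::qn_encode(qcdmrg:::fermion_sectors()$n,
                                       qcdmrg:::fermion_sectors()$s)
    perm <- match(codes_matrix, t$axes[[2]]$qn)
    T <- T[, perm, , drop = FALSE]
    A <- M %*% matrix(T, d[1], d[2] * d[3])
    arr <- aperm(array(A, c(nrow(M), d[2], d[3])), c(2, 1, 3))
    M <- matrix(arr, d[2] * nrow(M), d[3])
  }
  as.numeric(M[, 1])
}

# check the left/right isometry conditions of a canonical MPS
mps_isometry_error <- function(state) {
  err <- 0
  if (is.na(state$center)) return(NA_real_)
  for (i in seq_len(state$n_sites)) {
    T <- bt_to_dense(state$tensors[[i]])
    d <- dim(T)
    if (i < state$center) {
      M <- matrix(T, d[1] * d[2], d[3])
      err <- max(err, max(abs(crossprod(M) - diag(d[3]))))
    } else if (i > state$center) {
      M <- matrix(T, d[1], d[2] * d[3])
      err <- max(err, max(abs(tcrossprod(M) - diag(d[1]))))
    }
  }
  err
}
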