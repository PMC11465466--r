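# Brute-force full-CI reference for small active spaces.
#
# Determinants are occupation bitstrings over 2*n_orb spin orbitals in
# site-major order (site 1 up, site 1 down, site 2 up, ...), i.e. the same
# Jordan-Wigner ordering and sign convention used by the MPO module, so
# matrix elements can be compared between the two routes directly.

pkg_cache <- new.env(parent = emptyenv())

popcount16 <- function() {
  if (is.null(pkg_cache$pop16)) {
    v <- integer(65536)
    v1 <- c(0L, 1L)
    for (b in 1:15) v1 <- c(v1, v1 + 1L)
    pkg_cache$pop16 <- v1
  }
  pkg_cache$pop16
}

popcount <- function(x) {
  p <- popcount16()
  p[bitwAnd(x, 65535L) + 1L] + p[bitwAnd(bitwShiftR(x, 16L), 65535L) + 1L]
}

#' Determinant basis of a fixed (N, Sz) sector
#'
#' All Slater determinants with `n_elec` electrons and spin projection
#' `two_sz/2` over `n_orb` spatial orbitals, as occupation bitmasks over
#' `2*n_orb` spin orbitals (site-major, up before down within a site).
#'
#' @param n_orb spatial orbital count.
#' @param n_elec electron count.
#' @param two_sz twice the Sz projection.
#' @return object of class `determinant_basis` with the sorted bitmask
#'   vector `dets` and bookkeeping fields.
#' @export
determinant_basis <- function(n_orb, n_elec, two_sz) {
  n_orb <- as.integer(n_orb); n_elec <- as.integer(n_elec); two_sz <- as.integer(two_sz)
  if ((n_elec + two_sz) %% 2L != 0L)
    stop("determinant_basis: n_elec and two_sz have incompatible parity")
  n_up <- (n_elec + two_sz) %/% 2L
  n_dn <- (n_elec - two_sz) %/% 2L
  if (n_up < 0 || n_dn < 0 || n_up > n_orb || n_dn > n_orb)
    stop("determinant_basis: sector is empty for this orbital count")
  count <- choose(n_orb, n_up) * choose(n_orb, n_dn)
  if (count > 1e5) stop("determinant_basis: determinant count exceeds the 1e5 cap")
  pick <- function(k) {
    if (k == 0) return(0L)
    combos <- utils::combn(n_orb, k)
    apply(combos, 2, function(ix) sum(bitwShiftL(1L, ix - 1L)))
  }
  ups <- pick(n_up)    # masks over spatial positions
  dns <- pick(n_dn)
  # spin-orbital bitmask: up of site i -> bit 2i-2, down -> bit 2i-1
  spread <- function(mask, off) {
    out <- 0L
    for (i in seq_len(n_orb)) {
      if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L)
        out <- out + bitwShiftL(1L, 2L * (i - 1L) + off)
    }
    out
  }
  upm <- vapply(ups, spread, 0L, off = 0L)
  dnm <- vapply(dns, spread, 0L, off = 1L)
  dets <- sort(as.integer(outer(upm, dnm, `+`)))
  structure(list(n_orb = n_orb, n_elec = n_elec, two_sz = two_sz,
                 n_up = n_up, n_dn = n_dn, dets = dets),
            class = "determinant_basis")
}

#' @export
print.determinant_basis <- function(x, ...) {
  cat(sprintf("<determinant_basis> %d orbitals, %d electrons, 2Sz = %d: %d determinants\n",
              x$n_orb, x$n_elec, x$two_sz, length(x$dets)))
  invisible(x)
}

# sparse matrix of a+_k a_l (spin-orbital indices 1..2n, site-major) mapping
# basis_from -> basis_to (may be the same object).  Jordan-Wigner sign:
# (-1)^(number of occupied spin orbitals below the one acted on).
single_excitation_op <- function(k, l, basis_to, basis_from) {
  dets <- basis_from$dets
  bit_k <- bitwShiftL(1L, k - 1L)
  bit_l <- bitwShiftL(1L, l - 1L)
  below_k <- bit_k - 1L
  below_l <- bit_l - 1L
  occ_l <- bitwAnd(dets, bit_l) != 0L
  if (k == l) {
    i <- which(occ_l)
    return(Matrix::sparseMatrix(i = i, j = i, x = rep(1, length(i)),
                                dims = c(length(basis_to$dets), length(dets))))
  }
  sel <- which(occ_l & bitwAnd(dets, bit_k) == 0L)
  if (!length(sel)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(basis_to$dets), length(dets))))
  }
  d <- dets[sel]
  sign_l <- 1 - 2 * (popcount(bitwAnd(d, below_l)) %% 2L)
  d1 <- d - bit_l
  sign_k <- 1 - 2 * (popcount(bitwAnd(d1, below_k)) %% 2L)
  d2 <- d1 + bit_k
  i <- match(d2, basis_to$dets)
  if (anyNA(i)) stop("single_excitation_op: excitation leaves the target sector")
  Matrix::sparseMatrix(i = i, j = sel, x = sign_l * sign_k,
                       dims = c(length(basis_to$dets), length(dets)))
}

# spin-summed one-body operator E_pq = sum_sigma a+_{p sigma} a_{q sigma}
# within one sector basis
e_pq_op <- function(p, q, basis) {
  up <- single_excitation_op(2L * p - 1L, 2L * q - 1L, basis, basis)
  dn <- single_excitation_op(2L * p, 2L * q, basis, basis)
  up + dn
}

# sparse Hamiltonian of the table in the sector of `basis`
build_fci_hamiltonian <- function(table, basis) {
  n <- table$n_orb
  K <- length(basis$dets)
  E <- vector("list", n * n)
  for (p in seq_len(n)) for (q in seq_len(n))
    E[[(p - 1L) * n + q]] <- e_pq_op(p, q, basis)
  H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(K, K))
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (table$one_body[p, q] != 0)
      H <- H + table$one_body[p, q] * E[[(p - 1L) * n + q]]
  }
  g <- table$two_body
  for (r in seq_len(n)) for (s in seq_len(n)) {
    W <- NULL
    for (p in seq_len(n)) for (q in seq_len(n)) {
      if (g[p, q, r, s] != 0) {
        term <- g[p, q, r, s] * E[[(p - 1L) * n + q]]
        W <- if (is.null(W)) term else W + term
      }
    }
    if (!is.null(W)) H <- H + 0.5 * (W %*% E[[(r - 1L) * n + s]])
  }
  # exchange correction: -1/2 sum_ps (sum_q g[p,q,q,s]) E_ps
  for (p in seq_len(n)) for (s in seq_len(n)) {
    c_ps <- sum(vapply(seq_len(n), function(q) g[p, q, q, s], 0))
    if (c_ps != 0) H <- H - 0.5 * c_ps * E[[(p - 1L) * n + s]]
  }
  H <- (H + Matrix::t(H)) / 2  # symmetrize away round-off
  H + Matrix::Diagonal(K, table$core_energy)
}

# deterministic Lanczos (full reorthogonalization) for the lowest eigenpair
# of a symmetric operator given as a matvec closure
lanczos_lowest <- function(matvec, diag_hint, K, tol = 1e-11, max_outer = 60,
                           m = 80) {
  v <- numeric(K)
  v[which.min(diag_hint)] <- 1
  lambda <- NA_real_
  for (outer in seq_len(max_outer)) {
    V <- matrix(0, K, 0)
    alpha <- numeric(0); beta <- numeric(0)
    w <- v / sqrt(sum(v^2))
    for (j in seq_len(min(m, K))) {
      V <- cbind(V, w)
      hw <- matvec(w)
      a <- sum(w * hw)
      alpha <- c(alpha, a)
      hw <- hw - V %*% crossprod(V, hw)  # full reorthogonalization
      hw <- hw - V %*% crossprod(V, hw)
      b <- sqrt(sum(hw^2))
      if (j == K || b < 1e-13) break
      beta <- c(beta, b)
      w <- as.numeric(hw / b)
    }
    k <- length(alpha)
    Tm <- diag(alpha, k)
    if (k > 1) for (j in seq_len(k - 1)) { Tm[j, j + 1] <- beta[j]; Tm[j + 1, j] <- beta[j] }
    es <- eigen(Tm, symmetric = TRUE)
    lambda <- es$values[k]
    v <- as.numeric(V %*% es$vectors[, k])
    v <- v / sqrt(sum(v^2))
    res <- sqrt(sum((matvec(v) - lambda * v)^2))
    if (res < tol) break
  }
  list(value = lambda, vector = v)
}

#' Full-CI ground state of an (N, Sz) sector
#'
#' Lowest eigenpair of the active-space Hamiltonian in the fixed
#' particle-number / spin-projection sector, via dense diagonalization for
#' small determinant counts and deterministic Lanczos iteration above 2000
#' determinants.  The determinant count is capped at 1e5.
#'
#' @param table an [integral_table()].
#' @param n_elec electron count (default from the table).
#' @param two_sz twice the Sz projection (default `table$two_s_target`).
#' @return list with `energy` (Hartree), `vector` (coefficients over
#'   `basis$dets`), and `basis`.
#' @export
fci_ground_state <- function(table, n_elec = table$n_elec,
                             two_sz = table$two_s_target) {
  basis <- determinant_basis(table$n_orb, n_elec, two_sz)
  H <- build_fci_hamiltonian(table, basis)
  K <- length(basis$dets)
  if (K <= 2000) {
    Hd <- as.matrix(H)
    es <- eigen(Hd, symmetric = TRUE)
    v <- es$vectors[, K]
    return(list(energy = es$values[K], vector = v, basis = basis))
  }
  out <- lanczos_lowest(function(x) as.numeric(H %*% x), Matrix::diag(H), K)
  list(energy = out$value, vector = out$vector, basis = basis)
}

# S+ operator from sector (n_elec, two_sz) to (n_elec, two_sz + 2)
s_plus_op <- function(basis) {
  n <- basis$n_orb
  if (basis$n_up >= n || basis$n_dn <= 0) return(NULL)
  basis_up <- determinant_basis(n, basis$n_elec, basis$two_sz + 2L)
  Sp <- NULL
  for (p in seq_len(n)) {
    term <- single_excitation_op(2L * p - 1L, 2L * p, basis_up, basis)
    Sp <- if (is.null(Sp)) term else Sp + term
  }
  Sp
}

#' Total-spin expectation of a CI vector
#'
#' Computes `<S^2>` of a normalized vector over a determinant basis using
#' `S^2 = S_- S_+ + Sz (Sz + 1)`.
#'
#' @param vector numeric coefficients over `basis$dets` (normalized).
#' @param basis a [determinant_basis()].
#' @return numeric `<S^2>` (equals `S*(S+1)` for a spin-pure state).
#' @export
s_squared <- function(vector, basis) {
  stopifnot(length(vector) == length(basis$dets))
  sz <- basis$two_sz / 2
  Sp <- s_plus_op(basis)
  raise <- if (is.null(Sp)) 0 else sum(as.numeric(Sp %*% vector)^2)
  raise + sz * (sz + 1)
}

#' Lowest full-CI state with a given total spin
#'
#' Diagonalizes the sector `Sz = S` and returns the lowest eigenstate whose
#' `<S^2>` equals `S(S+1)`.  For determinant counts above the dense limit a
#' spin-penalized Lanczos iteration is used.
#'
#' @param table an [integral_table()].
#' @param two_s twice the target total spin.
#' @param n_elec electron count (default from the table).
#' @param penalty spin-penalty strength for the iterative path (Hartree).
#' @return list with `energy`, `vector`, `basis`, `s_squared`.
#' @export
fci_lowest_with_spin <- function(table, two_s = table$two_s_target,
                                 n_elec = table$n_elec, penalty = 2) {
  basis <- determinant_basis(table$n_orb, n_elec, two_s)
  H <- build_fci_hamiltonian(table, basis)
  K <- length(basis$dets)
  target <- (two_s / 2) * (two_s / 2 + 1)
  if (K <= 2000) {
    es <- eigen(as.matrix(H), symmetric = TRUE)
    for (j in rev(seq_len(K))) {
      v <- es$vectors[, j]
      s2 <- s_squared(v, basis)
      if (abs(s2 - target) < 1e-6)
        return(list(energy = es$values[j], vector = v, basis = basis, s_squared = s2))
    }
    stop("fci_lowest_with_spin: no state with the requested spin found")
  }
  Sp <- s_plus_op(basis)
  sz <- basis$two_sz / 2
  matvec <- function(x) {
    hx <- as.numeric(H %*% x)
    s2x <- sz * (sz + 1) * x
    if (!is.null(Sp)) s2x <- s2x + as.numeric(Matrix::t(Sp) %*% (Sp %*% x))
    hx + penalty * (s2x - target * x)
  }
  out <- lanczos_lowest(matvec, Matrix::diag(H), K)
  v <- out$vector
  s2 <- s_squared(v, basis)
  if (abs(s2 - target) > 1e-5)
    stop("fci_lowest_with_spin: penalized iteration did not land on the requested spin")
  energy <- sum(v * as.numeric(H %*% v))
  list(energy = energy, vector = v, basis = basis, s_squared = s2)
}
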