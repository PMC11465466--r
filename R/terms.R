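# Local operator algebra and symbolic second-quantized term lists.
#
# Fermionic orbitals use the local basis |0>, |up>, |dn>, |updn> with
# |updn> = c+_up c+_dn |0>.  Jordan-Wigner strings run along the site-major
# spin-orbital order (site 1 up, site 1 down, site 2 up, ...), realized as
# parity operators P = diag(1,-1,-1,1) on every site left of the acted-on
# orbital.  An optional non-interacting spin-S "ancilla" site (singlet
# embedding) carries local dimension 2S+1 and plain spin operators.

fermion_ops <- function() {
  if (!is.null(pkg_cache$fops)) return(pkg_cache$fops)
  I4 <- diag(4)
  cu <- matrix(0, 4, 4); cu[1, 2] <- 1; cu[3, 4] <- 1      # annihilate up
  cd <- matrix(0, 4, 4); cd[1, 3] <- 1; cd[2, 4] <- -1     # annihilate down
  P <- diag(c(1, -1, -1, 1))
  sz <- diag(c(0, 0.5, -0.5, 0))
  sp <- matrix(0, 4, 4); sp[2, 3] <- 1                     # S+ = c+_up c_dn
  ops <- list(I = I4, P = P, cu = cu, cd = cd, cdu = t(cu), cdd = t(cd),
              sz = sz, sp = sp, sm = t(sp),
              s2loc = diag(c(0, 0.75, 0.75, 0)))
  pkg_cache$fops <- ops
  ops
}

# local (n, 2sz) labels of the fermionic basis states, matrix order
fermion_sectors <- function() {
  data.frame(n = c(0L, 1L, 1L, 2L), s = c(0L, 1L, -1L, 0L))
}

# spin-S ancilla: states ordered by descending Sz (2sz = two_s, two_s-2, ...)
ancilla_sectors <- function(two_s) {
  data.frame(n = rep(0L, two_s + 1L), s = seq.int(two_s, -two_s, by = -2L))
}

ancilla_ops <- function(two_s) {
  d <- two_s + 1L
  s <- two_s / 2
  m <- seq(s, -s, by = -1)
  sz <- diag(m, d)
  sp <- matrix(0, d, d)
  if (d > 1) for (i in 2:d) sp[i - 1, i] <- sqrt(s * (s + 1) - m[i] * (m[i] + 1))
  list(I = diag(d), sz = sz, sp = sp, sm = t(sp), s2loc = s * (s + 1) * diag(d))
}

# A chain layout: fermionic orbital sites plus an optional trailing ancilla.
chain_layout <- function(n_orb, ancilla_two_s = 0L) {
  n_sites <- n_orb + (ancilla_two_s > 0L)
  dims <- rep(4L, n_orb)
  sectors <- rep(list(fermion_sectors()), n_orb)
  if (ancilla_two_s > 0L) {
    dims <- c(dims, ancilla_two_s + 1L)
    sectors <- c(sectors, list(ancilla_sectors(ancilla_two_s)))
  }
  list(n_orb = n_orb, n_sites = n_sites, dims = dims, sectors = sectors,
       ancilla_two_s = as.integer(ancilla_two_s))
}

# Build the per-site matrix string of an ordered product of ladder operators.
# factors: list of c(site, spin, dagger) with spin 1 = up, 2 = down,
# dagger 1/0.  Returns list of 4x4 matrices (NULL = identity).
jw_product <- function(factors, n_orb) {
  f <- fermion_ops()
  mats <- vector("list", n_orb)
  mul <- function(a, b) if (is.null(a)) b else a %*% b
  for (fc in factors) {
    site <- fc[1]; spin <- fc[2]; dag <- fc[3]
    # the local matrices already carry the intra-site anticommutation signs,
    # so only inter-site parity strings are needed
    loc <- if (dag) { if (spin == 1) f$cdu else f$cdd } else { if (spin == 1) f$cu else f$cd }
    for (j in seq_len(site - 1)) mats[[j]] <- mul(mats[[j]], f$P)
    mats[[site]] <- mul(mats[[site]], loc)
  }
  mats
}

is_zero_mat <- function(m) !is.null(m) && all(m == 0)
is_identity_mat <- function(m) is.null(m) || (nrow(m) == ncol(m) && all(m == diag(nrow(m))))

# term: list(coeff, sites (ascending int), ops (list of matrices))
make_term <- function(coeff, mats) {
  support <- which(!vapply(mats, is_identity_mat, TRUE))
  for (m in mats) if (is_zero_mat(m)) return(NULL)
  if (!length(support)) return(list(coeff = coeff, sites = 1L, ops = list(NULL)))
  list(coeff = coeff, sites = support, ops = mats[support])
}

# collect and merge terms by their operator-string signature
term_accumulator <- function() {
  env <- new.env(parent = emptyenv())
  env$terms <- list()
  env$index <- new.env(parent = emptyenv())
  env
}

op_signature <- function(m) {
  if (is.null(m)) return("I")
  paste(signif(m, 13), collapse = ",")
}

acc_add <- function(acc, term) {
  if (is.null(term) || term$coeff == 0) return(invisible(NULL))
  key <- paste(term$sites, vapply(term$ops, op_signature, ""), sep = ":", collapse = ";")
  i <- acc$index[[key]]
  if (is.null(i)) {
    acc$terms[[length(acc$terms) + 1L]] <- term
    acc$index[[key]] <- length(acc$terms)
  } else {
    acc$terms[[i]]$coeff <- acc$terms[[i]]$coeff + term$coeff
  }
  invisible(NULL)
}

acc_finish <- function(acc) {
  Filter(function(t) abs(t$coeff) > 1e-14, acc$terms)
}

# Second-quantized term list of the active-space Hamiltonian
hamiltonian_terms <- function(table) {
  n <- table$n_orb
  acc <- term_accumulator()
  if (table$core_energy != 0)
    acc_add(acc, list(coeff = table$core_energy, sites = 1L, ops = list(NULL)))
  h <- table$one_body
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (h[p, q] == 0) next
    for (sp in 1:2) {
      mats <- jw_product(list(c(p, sp, 1L), c(q, sp, 0L)), n)
      acc_add(acc, make_term(h[p, q], mats))
    }
  }
  g <- table$two_body
  for (p in seq_len(n)) for (q in seq_len(n)) for (r in seq_len(n)) for (s in seq_len(n)) {
    v <- g[p, q, r, s]
    if (v == 0) next
    for (sg in 1:2) for (tu in 1:2) {
      mats <- jw_product(list(c(p, sg, 1L), c(r, tu, 1L), c(s, tu, 0L), c(q, sg, 0L)), n)
      acc_add(acc, make_term(0.5 * v, mats))
    }
  }
  acc_finish(acc)
}

# Total-S^2 term list over a chain layout (fermion sites + optional ancilla).
# S^2 = sum_i S_i^2 + 2 sum_{i<j} [Sz_i Sz_j + (S+_i S-_j + S-_i S+_j)/2]
s_squared_terms <- function(layout) {
  f <- fermion_ops()
  n <- layout$n_sites
  site_op <- function(i, name) {
    if (i <= layout$n_orb) f[[name]] else ancilla_ops(layout$ancilla_two_s)[[name]]
  }
  terms <- list()
  add <- function(coeff, sites, ops) {
    terms[[length(terms) + 1L]] <<- list(coeff = coeff, sites = sites, ops = ops)
  }
  for (i in seq_len(n)) add(1, i, list(site_op(i, "s2loc")))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1L, n)) {
    add(2, c(i, j), list(site_op(i, "sz"), site_op(j, "sz")))
    add(1, c(i, j), list(site_op(i, "sp"), site_op(j, "sm")))
    add(1, c(i, j), list(site_op(i, "sm"), site_op(j, "sp")))
  }
  terms
}
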