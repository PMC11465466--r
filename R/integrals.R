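# Active-space Hamiltonians as one-/two-electron integral tables.
#
# H = E_core + sum_pq h[p,q] sum_sigma a+_{p sigma} a_{q sigma}
#   + 1/2 sum_pqrs (pq|rs) sum_{sigma tau} a+_{p sigma} a+_{r tau} a_{s tau} a_{q sigma}
#
# with (pq|rs) in chemists' notation and the 8-fold index symmetry of real
# orbitals.  Indices are 0-free here: everything is 1-based in R, and the
# FCIDUMP file convention is also 1-based, so no conversion is needed at the
# file boundary.

#' Construct an active-space integral table
#'
#' @param n_orb number of spatial orbitals.
#' @param n_elec electron count of the target state.
#' @param two_s_target twice the target total spin (integer >= 0).
#' @param core_energy scalar core energy in Hartree.
#' @param one_body `n_orb x n_orb` symmetric matrix `h[p,q]` (Hartree).
#' @param two_body `n_orb^4` array `g[p,q,r,s] = (pq|rs)` in chemists'
#'   notation (Hartree), with the 8-fold symmetry of real orbitals.
#' @param orbital_labels optional character identifiers.
#' @param validate check invariants (default TRUE).
#' @return object of class `integral_table`.
#' @export
integral_table <- function(n_orb, n_elec, two_s_target = n_elec %% 2,
                           core_energy = 0,
                           one_body = matrix(0, n_orb, n_orb),
                           two_body = array(0, rep(n_orb, 4)),
                           orbital_labels = NULL, validate = TRUE) {
  t <- structure(list(n_orb = as.integer(n_orb), n_elec = as.integer(n_elec),
                      two_s_target = as.integer(two_s_target),
                      core_energy = as.numeric(core_energy),
                      one_body = one_body, two_body = two_body,
                      orbital_labels = orbital_labels),
                 class = "integral_table")
  if (validate) validate_integral_table(t)
  t
}

#' Validate integral-table invariants
#'
#' Checks hermiticity of `h`, the 8-fold symmetry of `g`, electron count and
#' spin-parity constraints, and finiteness.
#'
#' @param table an [integral_table()].
#' @param tol symmetry tolerance in Hartree; violations beyond it raise an
#'   error naming the worst offending quadruple.
#' @return the table, invisibly.
#' @export
validate_integral_table <- function(table, tol = 1e-10) {
  stopifnot(inherits(table, "integral_table"))
  n <- table$n_orb
  if (n < 1) stop("integral_table: n_orb must be >= 1")
  if (table$n_elec < 0 || table$n_elec > 2 * n)
    stop("integral_table: need 0 <= n_elec <= 2*n_orb")
  if (table$two_s_target < 0)
    stop("integral_table: two_s_target must be >= 0")
  if ((table$n_elec - table$two_s_target) %% 2 != 0 ||
      table$n_elec - table$two_s_target < 0)
    stop("integral_table: n_elec - two_s_target must be even and >= 0")
  if (!all(is.finite(table$one_body)) || !all(is.finite(table$two_body)) ||
      !is.finite(table$core_energy))
    stop("integral_table: non-finite entries")
  if (!identical(dim(table$one_body), c(n, n)))
    stop("integral_table: one_body must be n_orb x n_orb")
  if (!identical(dim(table$two_body), rep(n, 4L)))
    stop("integral_table: two_body must be n_orb^4")
  dh <- abs(table$one_body - t(table$one_body))
  if (max(dh) > tol) {
    w <- which(dh == max(dh), arr.ind = TRUE)[1, ]
    stop(sprintf("integral_table: h[%d,%d] != h[%d,%d] (|diff| = %.3e)",
                 w[1], w[2], w[2], w[1], max(dh)))
  }
  g <- table$two_body
  worst <- 0; worst_idx <- NULL
  for (perm in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2))) {
    d <- abs(g - aperm(g, perm))
    m <- max(d)
    if (m > worst) {
      worst <- m
      worst_idx <- which(d == m, arr.ind = TRUE)[1, ]
    }
  }
  if (worst > tol)
    stop(sprintf("integral_table: two_body symmetry violated at (%d,%d|%d,%d), |diff| = %.3e",
                 worst_idx[1], worst_idx[2], worst_idx[3], worst_idx[4], worst))
  invisible(table)
}

#' @export
print.integral_table <- function(x, ...) {
  cat(sprintf("<integral_table> CAS(%d, %d), 2S = %d, core = %.8f Ha\n",
              x$n_elec, x$n_orb, x$two_s_target, x$core_energy))
  invisible(x)
}

# symmetrize an arbitrary 4-index array onto the 8-fold symmetric subspace.
# One average is computed per symmetry orbit and written to every member, so
# the result is exactly (bitwise) symmetric, not merely to round-off.
symmetrize_two_body <- function(g) {
  n <- dim(g)[1]
  out <- array(0, dim(g))
  for (p in seq_len(n)) for (q in seq_len(p)) for (r in seq_len(p)) {
    smax <- if (r == p) q else r
    for (s in seq_len(smax)) {
      orbit <- unique(list(c(p, q, r, s), c(q, p, r, s), c(p, q, s, r),
                           c(q, p, s, r), c(r, s, p, q), c(s, r, p, q),
                           c(r, s, q, p), c(s, r, q, p)))
      v <- mean(vapply(orbit, function(i) g[i[1], i[2], i[3], i[4]], 0))
      for (i in orbit) out[i[1], i[2], i[3], i[4]] <- v
    }
  }
  out
}

#' Hubbard chain model Hamiltonian
#'
#' Open-boundary Hubbard chain as an integral table: hopping
#' `h[i,i+1] = h[i+1,i] = -t` and on-site repulsion `g[i,i,i,i] = u`, chosen
#' in chemists' convention so the spin-summed Hamiltonian gives
#' `U * n_up * n_down` on each site.  Half filling (`n_elec = n_sites`) by
#' default.
#'
#' @param n_sites chain length (>= 1).
#' @param t hopping amplitude (Hartree).
#' @param u on-site interaction (Hartree).
#' @param n_elec electron count (default `n_sites`).
#' @param two_s_target twice the target spin (default `n_elec %% 2`).
#' @return an [integral_table()].
#' @examples
#' hubbard_chain(2, 1, 4)
#' @export
hubbard_chain <- function(n_sites, t = 1, u = 0, n_elec = n_sites,
                          two_s_target = n_elec %% 2) {
  stopifnot(n_sites >= 1)
  h <- matrix(0, n_sites, n_sites)
  if (n_sites > 1) {
    for (i in seq_len(n_sites - 1)) {
      h[i, i + 1] <- -t
      h[i + 1, i] <- -t
    }
  }
  g <- array(0, rep(n_sites, 4L))
  for (i in seq_len(n_sites)) g[i, i, i, i] <- u
  integral_table(n_sites, n_elec, two_s_target, 0, h, g)
}

#' Randomized symmetric integral table
#'
#' Draws `h` and `g` from a seeded pseudorandom stream and projects them
#' exactly onto the hermitian / 8-fold-symmetric subspace.  Deterministic for
#' a fixed seed; the caller's RNG state is left untouched.
#'
#' @param n_orb number of spatial orbitals (small test scale intended).
#' @param n_elec electron count (default `n_orb`, half filling).
#' @param seed integer seed.
#' @param scale overall magnitude in Hartree.
#' @param two_s_target twice the target spin (default `n_elec %% 2`).
#' @return an [integral_table()].
#' @export
random_cas <- function(n_orb, n_elec = n_orb, seed = 1, scale = 1,
                       two_s_target = n_elec %% 2) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  h0 <- matrix(stats::rnorm(n_orb^2, sd = scale), n_orb, n_orb)
  h <- (h0 + t(h0)) / 2
  g <- symmetrize_two_body(array(stats::rnorm(n_orb^4, sd = scale), rep(n_orb, 4L)))
  integral_table(n_orb, n_elec, two_s_target, 0, h, g)
}

#' Write an integral table in FCIDUMP format
#'
#' Molpro-dialect FCIDUMP: `&FCI` namelist header with `NORB`, `NELEC`,
#' `MS2`, `ORBSYM`, `ISYM`, then one record per unique nonzero integral:
#' `value p q r s` for two-body `(pq|rs)`, `value p q 0 0` for one-body,
#' `value 0 0 0 0` for the core energy.  Only one representative per 8-fold
#' symmetry orbit is written; zeros are omitted.
#'
#' @param table a valid [integral_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(table, path) {
  validate_integral_table(table)
  n <- table$n_orb
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, table$n_elec, table$two_s_target),
    sprintf(" ORBSYM=%s", paste(rep("1,", n), collapse = "")),
    " ISYM=1,",
    "/"), con)
  fmt <- function(v, p, q, r, s) sprintf("%22.16E %3d %3d %3d %3d", v, p, q, r, s)
  lines <- character(0)
  for (p in seq_len(n)) for (q in seq_len(p)) {
    for (r in seq_len(p)) {
      smax <- if (r == p) q else r
      for (s in seq_len(smax)) {
        v <- table$two_body[p, q, r, s]
        if (v != 0) lines <- c(lines, fmt(v, p, q, r, s))
      }
    }
  }
  for (p in seq_len(n)) for (q in seq_len(p)) {
    v <- table$one_body[p, q]
    if (v != 0) lines <- c(lines, fmt(v, p, q, 0L, 0L))
  }
  if (table$core_energy != 0)
    lines <- c(lines, fmt(table$core_energy, 0L, 0L, 0L, 0L))
  writeLines(lines, con)
  invisible(path)
}

#' Read an FCIDUMP file
#'
#' Parses the Molpro-dialect namelist header (`NORB`, `NELEC`, `MS2`;
#' `ORBSYM`/`ISYM` are accepted and ignored) and the integral records, fills
#' all symmetry-equivalent entries from each stored representative, and
#' validates the result.  Unlisted integrals are zero.
#'
#' @param path path to an FCIDUMP file.
#' @return an [integral_table()].
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_fcidump: no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("read_fcidump: empty file")
  # header: from &FCI up to a line containing '/' or '&END'
  hdr_end <- NULL
  for (i in seq_along(lines)) {
    if (grepl("/|&END", lines[i], ignore.case = TRUE)) { hdr_end <- i; break }
  }
  if (is.null(hdr_end) || !grepl("^\\s*&FCI", lines[1], ignore.case = TRUE))
    stop(sprintf("read_fcidump: malformed header at line 1: '%s'", lines[1]))
  hdr <- paste(lines[1:hdr_end], collapse = " ")
  hdr <- sub("^\\s*&FCI", "", hdr, ignore.case = TRUE)
  hdr <- sub("/.*$", "", hdr)
  get_field <- function(name) {
    m <- regmatches(hdr, regexec(paste0(name, "\\s*=\\s*(-?[0-9]+)"), hdr,
                                 ignore.case = TRUE))[[1]]
    if (length(m) < 2)
      stop(sprintf("read_fcidump: header is missing %s (line 1)", name))
    as.integer(m[2])
  }
  n <- get_field("NORB")
  n_elec <- get_field("NELEC")
  ms2 <- get_field("MS2")
  if (n < 1) stop("read_fcidump: NORB must be >= 1")

  h <- matrix(0, n, n)
  g <- array(0, rep(n, 4L))
  core <- 0
  body <- lines[seq.int(hdr_end + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  for (li in seq_along(body)) {
    toks <- strsplit(trimws(body[li]), "\\s+")[[1]]
    if (length(toks) != 5)
      stop(sprintf("read_fcidump: malformed record at line %d: '%s'",
                   hdr_end + li, body[li]))
    v <- suppressWarnings(as.numeric(sub("[dD]", "E", toks[1])))
    idx <- suppressWarnings(as.integer(toks[2:5]))
    if (is.na(v) || any(is.na(idx)))
      stop(sprintf("read_fcidump: malformed record at line %d: '%s'",
                   hdr_end + li, body[li]))
    if (any(idx > n))
      stop(sprintf("read_fcidump: orbital index out of range at line %d", hdr_end + li))
    p <- idx[1]; q <- idx[2]; r <- idx[3]; s <- idx[4]
    if (all(idx == 0)) {
      core <- v
    } else if (r == 0 && s == 0) {
      if (p == 0 || q == 0)
        stop(sprintf("read_fcidump: malformed one-body record at line %d", hdr_end + li))
      h[p, q] <- v; h[q, p] <- v
    } else if (all(idx > 0)) {
      for (pq in list(c(p, q), c(q, p))) for (rs in list(c(r, s), c(s, r))) {
        g[pq[1], pq[2], rs[1], rs[2]] <- v
        g[rs[1], rs[2], pq[1], pq[2]] <- v
      }
    } else {
      stop(sprintf("read_fcidump: malformed record at line %d: '%s'",
                   hdr_end + li, body[li]))
    }
  }
  integral_table(n, n_elec, ms2, core, h, g)
}
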