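# Quantum-number algebra for particle number and spin.
#
# Internally every symmetry sector is a pair of integers (n, s):
#   * U(1) mode:  s = 2*Sz (twice the spin projection, may be negative);
#   * SU(2) mode: s = 2*S  (twice the total spin, >= 0).
# Half-integer spins are therefore handled with exact integer arithmetic.
# Sectors are encoded as single integers for fast keying; the encoding is an
# implementation detail and never leaves the package.

QN_SHIFT <- 2048L
QN_BASE <- 4096L

qn_encode <- function(n, s) as.integer(n) * QN_BASE + (as.integer(s) + QN_SHIFT)

qn_decode <- function(code) {
  code <- as.integer(code)
  s <- (code %% QN_BASE) - QN_SHIFT
  n <- (code - (s + QN_SHIFT)) %/% QN_BASE
  cbind(n = n, s = s)
}

#' Construct a symmetry sector
#'
#' A sector labels a symmetry block by particle number `n` and a spin label:
#' twice the Sz projection in `"u1"` mode (any sign) or twice the total spin S
#' in `"su2"` mode (non-negative, with the parity of the spin label matching
#' the parity of `n`).
#'
#' @param n particle count (non-negative integer).
#' @param spin_label integer; `2*Sz` (u1) or `2*S` (su2).
#' @param mode `"u1"` or `"su2"`.
#' @return an object of class `sector`.
#' @examples
#' sector(1, 1, "su2")  # one electron, spin-1/2 doublet
#' @export
sector <- function(n, spin_label, mode = c("u1", "su2")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  spin_label <- as.integer(spin_label)
  if (n < 0) stop("sector: particle count must be >= 0")
  if (mode == "su2") {
    if (spin_label < 0) stop("sector: SU(2) spin label 2S must be >= 0")
    if ((spin_label - n) %% 2L != 0L)
      stop("sector: parity of the spin label must equal the parity of n")
  }
  structure(list(n = n, spin_label = spin_label, mode = mode), class = "sector")
}

#' @export
print.sector <- function(x, ...) {
  lbl <- if (x$mode == "su2") "2S" else "2Sz"
  cat(sprintf("<sector %s: n=%d, %s=%d>\n", x$mode, x$n, lbl, x$spin_label))
  invisible(x)
}

#' Fuse two symmetry sectors
#'
#' Combines the quantum numbers of two blocks.  In U(1) mode particle number
#' and Sz projection add, giving a single sector.  In SU(2) mode particle
#' numbers add and the spins couple through the Clebsch-Gordan series
#' `|S_a - S_b| ... S_a + S_b`, giving one sector per total spin.
#'
#' @param a,b sectors (see [sector()]); both must be in the same mode.
#' @param mode `"u1"` or `"su2"`; must match the sectors' mode.
#' @return list of `sector` objects.
#' @examples
#' fuse(sector(1, 1, "su2"), sector(1, 1, "su2"))  # singlet and triplet
#' @export
fuse <- function(a, b, mode = c("u1", "su2")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "sector"), inherits(b, "sector"))
  if (a$mode != mode || b$mode != mode)
    stop("fuse: sector mode does not match the requested mode")
  n <- a$n + b$n
  if (mode == "u1") {
    return(list(sector(n, a$spin_label + b$spin_label, "u1")))
  }
  two_s <- seq.int(abs(a$spin_label - b$spin_label), a$spin_label + b$spin_label, by = 2L)
  lapply(two_s, function(s) sector(n, s, "su2"))
}

#' Local single-orbital basis
#'
#' The four states of a spinful spatial orbital (empty, up, down, doubly
#' occupied).  In U(1) mode these are four one-dimensional Sz-resolved
#' sectors; in SU(2) mode they form three multiplets (two singlets and one
#' spin-1/2 doublet of U(1) dimension 2), for a total local dimension of 4 in
#' both modes.
#'
#' @param mode `"u1"` or `"su2"`.
#' @return data frame with columns `n`, `spin_label`, `dim` (multiplet count
#'   is `nrow`; `dim` is the U(1)-equivalent dimension of each entry).
#' @export
local_basis <- function(mode = c("u1", "su2")) {
  mode <- match.arg(mode)
  if (mode == "u1") {
    data.frame(n = c(0L, 1L, 1L, 2L), spin_label = c(0L, 1L, -1L, 0L),
               dim = c(1L, 1L, 1L, 1L))
  } else {
    data.frame(n = c(0L, 1L, 2L), spin_label = c(0L, 1L, 0L),
               dim = c(1L, 2L, 1L))
  }
}

#' Multiplet spectrum of a retained bond basis
#'
#' Describes an SU(2)-resolved bond basis as a list of (2S, multiplicity)
#' entries.  Duplicate spin labels are merged; entries are sorted by 2S.
#'
#' @param two_s integer vector of spin labels (2S, each >= 0).
#' @param multiplicity integer vector of multiplet counts (each >= 1).
#' @return object of class `multiplet_spectrum`: data frame with columns
#'   `two_s` and `multiplicity`.
#' @examples
#' multiplet_spectrum(c(0, 1), c(2, 3))
#' @export
multiplet_spectrum <- function(two_s = integer(0), multiplicity = integer(0)) {
  stopifnot(length(two_s) == length(multiplicity))
  two_s <- as.integer(two_s)
  multiplicity <- as.integer(multiplicity)
  if (any(two_s < 0)) stop("multiplet_spectrum: 2S labels must be >= 0")
  if (any(multiplicity < 1)) stop("multiplet_spectrum: multiplicities must be >= 1")
  if (length(two_s)) {
    agg <- rowsum(multiplicity, group = two_s)
    two_s <- as.integer(rownames(agg))
    multiplicity <- as.integer(agg[, 1])
    o <- order(two_s)
    two_s <- two_s[o]
    multiplicity <- multiplicity[o]
  }
  structure(data.frame(two_s = two_s, multiplicity = multiplicity),
            class = c("multiplet_spectrum", "data.frame"))
}

#' U(1)-equivalent dimension of a multiplet spectrum
#'
#' The accounting rule relating an SU(2) multiplet count D to the
#' corresponding number of Sz-resolved U(1) states: each spin-S multiplet
#' contributes 2S+1 states, so the result is
#' `sum(multiplicity * (two_s + 1))`.
#'
#' @param spec a [multiplet_spectrum()].
#' @return integer count.
#' @examples
#' u1_dimension(multiplet_spectrum(1, 3))  # three doublets -> 6
#' @export
u1_dimension <- function(spec) {
  stopifnot(inherits(spec, "multiplet_spectrum"))
  if (!nrow(spec)) return(0L)
  as.integer(sum(spec$multiplicity * (spec$two_s + 1L)))
}

#' Total multiplet count of a spectrum
#' @param spec a [multiplet_spectrum()].
#' @return integer number of multiplets.
#' @export
multiplet_count <- function(spec) {
  stopifnot(inherits(spec, "multiplet_spectrum"))
  as.integer(sum(spec$multiplicity))
}

# Decompose Sz-resolved state counts into SU(2) multiplets by character
# peeling: counts is a named table mapping 2Sz -> number of states (within a
# fixed particle-number sector of a spin-symmetric basis).  Repeatedly peel
# the multiplet with the largest |2Sz| present.  Returns data.frame(two_s,
# multiplicity) or NULL if the counts are not consistent with complete
# multiplets.
peel_multiplets <- function(two_sz, counts) {
  stopifnot(length(two_sz) == length(counts))
  cnt <- as.integer(counts)
  names(cnt) <- as.character(as.integer(two_sz))
  out_s <- integer(0)
  out_m <- integer(0)
  while (any(cnt > 0L)) {
    present <- as.integer(names(cnt))[cnt > 0L]
    smax <- max(abs(present))
    members <- as.character(seq.int(-smax, smax, by = 2L))
    if (!all(members %in% names(cnt))) return(NULL)
    # multiplicity of spin-(smax/2) multiplets is fixed by the extremal
    # projection; both extremes must agree and every member must support it
    m <- cnt[[as.character(smax)]]
    if (m < 1L || cnt[[as.character(-smax)]] != m) return(NULL)
    if (any(cnt[members] < m)) return(NULL)
    cnt[members] <- cnt[members] - m
    out_s <- c(out_s, smax)
    out_m <- c(out_m, m)
  }
  if (!length(out_s)) return(data.frame(two_s = integer(0), multiplicity = integer(0)))
  agg <- rowsum(out_m, group = out_s)
  data.frame(two_s = as.integer(rownames(agg)), multiplicity = as.integer(agg[, 1]))
}
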