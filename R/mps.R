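# Matrix product states over spinful orbital chains.
#
# A state is a chain of order-3 block tensors A[l, p, r] with axis
# directions (+1, +1, -1): the right-bond sector is the cumulative quantum
# number from the left vacuum, so q_r = q_l + q_p for every stored block.
# The first bond holds the vacuum sector, the last bond the target sector
# (N_elec, 2Sz).  The canonical center gauges all tensors left of it to left
# isometries and all tensors right of it to right isometries.

mps_local_axis <- function(sectors) {
  bt_axis(1L, sectors$n, sectors$s, rep(1L, nrow(sectors)))
}

#' Random normalized matrix product state
#'
#' Draws a right-canonical random state in the given symmetry sector.  Bond
#' sector content is the intersection of forward-reachable (from the vacuum)
#' and backward-reachable (from the target) quantum numbers, with per-sector
#' dimensions capped so that no bond exceeds `d` states in total.
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param n_orb number of orbitals (fermionic sites).
#' @param target length-2 integer vector `(n_elec, 2Sz_total)`.
#' @param d bond-dimension cap in U(1) states (`Inf` for the full reachable
#'   basis).
#' @param seed integer seed.
#' @param mode bookkeeping tag.
#' @param ancilla_two_s twice the spin of a trailing ancilla site (singlet
#'   embedding; 0 for none).
#' @return object of class `mps`.
#' @export
random_mps <- function(n_orb, target, d = 16, seed = 1, mode = "u1",
                       ancilla_two_s = 0L) {
  layout <- chain_layout(n_orb, ancilla_two_s)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  mps_random_impl(layout, target, d, mode)
}

# bond sector tables: list over bonds 0..N of data.frame(code, dim)
mps_bond_structure <- function(layout, target, d) {
  n <- layout$n_sites
  tgt <- qn_encode(target[1], target[2])
  fwd <- vector("list", n + 1L)
  fwd[[1]] <- c(`0` = 1)
  names(fwd[[1]]) <- as.character(qn_encode(0L, 0L))
  for (i in seq_len(n)) {
    sec <- layout$sectors[[i]]
    acc <- new.env(parent = emptyenv())
    for (code in names(fwd[[i]])) {
      q <- qn_decode(as.integer(code))
      for (j in seq_len(nrow(sec))) {
        nc <- as.character(qn_encode(q[1, "n"] + sec$n[j], q[1, "s"] + sec$s[j]))
        acc[[nc]] <- (if (is.null(acc[[nc]])) 0 else acc[[nc]]) + fwd[[i]][[code]]
      }
    }
    fwd[[i + 1L]] <- unlist(as.list(acc))
  }
  bwd <- vector("list", n + 1L)
  bwd[[n + 1L]] <- c(1); names(bwd[[n + 1L]]) <- as.character(tgt)
  for (i in seq.int(n, 1L)) {
    sec <- layout$sectors[[i]]
    acc <- new.env(parent = emptyenv())
    for (code in names(bwd[[i + 1L]])) {
      q <- qn_decode(as.integer(code))
      for (j in seq_len(nrow(sec))) {
        nn <- q[1, "n"] - sec$n[j]; ss <- q[1, "s"] - sec$s[j]
        if (nn < 0) next
        nc <- as.character(qn_encode(nn, ss))
        acc[[nc]] <- (if (is.null(acc[[nc]])) 0 else acc[[nc]]) + bwd[[i + 1L]][[code]]
      }
    }
    bwd[[i]] <- unlist(as.list(acc))
  }
  bonds <- vector("list", n + 1L)
  for (i in seq_len(n + 1L)) {
    codes <- intersect(names(fwd[[i]]), names(bwd[[i]]))
    if (!length(codes))
      stop("random_mps: target sector is unreachable on this chain")
    full <- pmin(fwd[[i]][codes], bwd[[i]][codes])
    dim <- pmin(full, ceiling(d * full / sum(full)))
    dim <- pmax(dim, 1)
    o <- order(as.integer(codes))
    bonds[[i]] <- data.frame(code = as.integer(codes)[o], dim = as.integer(dim)[o])
  }
  bonds
}

mps_random_impl <- function(layout, target, d, mode) {
  n <- layout$n_sites
  bonds <- mps_bond_structure(layout, target, d)
  tensors <- vector("list", n)
  for (i in seq_len(n)) {
    sec <- layout$sectors[[i]]
    bl <- bonds[[i]]; br <- bonds[[i + 1L]]
    axL <- bt_axis(1L, qn_decode(bl$code)[, "n"], qn_decode(bl$code)[, "s"], bl$dim)
    axP <- mps_local_axis(sec)
    axR <- bt_axis(-1L, qn_decode(br$code)[, "n"], qn_decode(br$code)[, "s"], br$dim)
    keys <- list(); blocks <- list()
    for (li in seq_len(nrow(bl))) for (pj in seq_len(nrow(sec))) {
      ql <- qn_decode(bl$code[li])
      rc <- qn_encode(ql[1, "n"] + sec$n[pj], ql[1, "s"] + sec$s[pj])
      ri <- match(rc, br$code)
      if (is.na(ri)) next
      keys[[length(keys) + 1L]] <- c(bl$code[li], qn_encode(sec$n[pj], sec$s[pj]), rc)
      blocks[[length(blocks) + 1L]] <-
        array(stats::rnorm(bl$dim[li] * br$dim[ri]), dim = c(bl$dim[li], 1L, br$dim[ri]))
    }
    tensors[[i]] <- block_tensor(list(axL, axP, axR), keys, blocks, mode = mode)
  }
  state <- structure(list(n_sites = n, layout = layout, tensors = tensors,
                          center = NA_integer_, target = as.integer(target),
                          mode = mode, bond_spectra = NULL),
                     class = "mps")
  state <- canonicalize(state, 1L)
  # normalize the center tensor
  nrm <- bt_norm(state$tensors[[1]])
  state$tensors[[1]] <- bt_scale(state$tensors[[1]], 1 / nrm)
  state
}

#' @export
print.mps <- function(x, ...) {
  cat(sprintf("<mps> %d sites, target (n=%d, 2Sz=%d), center %s, D = %s\n",
              x$n_sites, x$target[1], x$target[2],
              ifelse(is.na(x$center), "none", x$center),
              paste(mps_bond_dims(x), collapse = " ")))
  invisible(x)
}

#' Realized bond dimensions of a state
#' @param state an [random_mps()] object.
#' @return integer vector of U(1) state counts per interior bond.
#' @export
mps_bond_dims <- function(state) {
  vapply(state$tensors, function(t) sum(t$axes[[3]]$dim), 0L)
}

# divide (or multiply) the blocks of `t` along axis `ax` by per-sector
# vectors `vals` (named list code -> numeric vector)
axis_rescale <- function(t, ax, vals, inverse = FALSE) {
  for (b in seq_len(nrow(t$keys))) {
    code <- as.character(t$keys[b, ax])
    v <- vals[[code]]
    if (is.null(v)) next
    if (inverse) v <- 1 / v
    arr <- t$blocks[[b]]
    d <- dim(arr)
    perm <- c(ax, setdiff(seq_along(d), ax))
    m <- matrix(aperm(arr, perm), d[ax])
    m <- m * v
    t$blocks[[b]] <- aperm(array(m, d[perm]), order(perm))
  }
  t
}

spectrum_by_sector <- function(spectrum) {
  sp <- split(spectrum$value, qn_encode(spectrum$n, spectrum$s))
  names(sp) <- as.character(names(sp))
  sp
}

# split center site i to the right: A_i becomes a left isometry, the
# singular-value carrier is absorbed into A_{i+1}
move_center_right <- function(state, i, d_max = Inf, weight_threshold = 0,
                              ledger = NULL) {
  sp <- bt_svd_split(state$tensors[[i]], c(1L, 2L), d_max = d_max,
                     weight_threshold = weight_threshold, ledger = ledger)
  state$tensors[[i]] <- sp$left
  carrier <- sp$right  # S V^T with axes (bond, R)
  state$tensors[[i + 1L]] <- bt_contract(carrier, state$tensors[[i + 1L]],
                                         2L, 1L, ledger, "canon")
  state$center <- i + 1L
  attr(state, "last_split") <- list(spectrum = sp$spectrum,
                                    discarded_weight = sp$discarded_weight)
  state
}

# split center site i to the left: A_i becomes a right isometry (V^T), the
# U S carrier is absorbed into A_{i-1}
move_center_left <- function(state, i, d_max = Inf, weight_threshold = 0,
                             ledger = NULL) {
  sp <- bt_svd_split(state$tensors[[i]], 1L, d_max = d_max,
                     weight_threshold = weight_threshold, ledger = ledger)
  vals <- spectrum_by_sector(sp$spectrum)
  vt <- axis_rescale(sp$right, 1L, vals, inverse = TRUE)   # V^T
  us <- axis_rescale(sp$left, 2L, vals, inverse = FALSE)   # U S
  state$tensors[[i]] <- vt
  state$tensors[[i - 1L]] <- bt_contract(state$tensors[[i - 1L]], us,
                                         3L, 1L, ledger, "canon")
  state$center <- i - 1L
  attr(state, "last_split") <- list(spectrum = sp$spectrum,
                                    discarded_weight = sp$discarded_weight)
  state
}

#' Move the canonical center of a state
#'
#' Gauges the state so that every tensor left of `center` satisfies the left
#' isometry condition and every tensor right of it the right isometry
#' condition.  The physical state is unchanged (no truncation).
#'
#' @param state an `mps`.
#' @param center target site index.
#' @param ledger optional [flop_ledger()].
#' @return the re-gauged `mps`.
#' @export
canonicalize <- function(state, center, ledger = NULL) {
  stopifnot(center >= 1, center <= state$n_sites)
  lo <- if (is.na(state$center)) 1L else min(state$center, center)
  hi <- if (is.na(state$center)) state$n_sites else max(state$center, center)
  for (i in seq.int(lo, length.out = max(0L, center - lo)))
    state <- move_center_right(state, i, ledger = ledger)
  for (i in seq.int(hi, by = -1L, length.out = max(0L, hi - center)))
    state <- move_center_left(state, i, ledger = ledger)
  state$center <- as.integer(center)
  state
}

#' Overlap of two matrix product states
#'
#' @param a,b states over the same chain and target sector.
#' @param ledger optional [flop_ledger()].
#' @return numeric `<a|b>`.
#' @export
mps_overlap <- function(a, b, ledger = NULL) {
  stopifnot(a$n_sites == b$n_sites)
  E <- list(`0` = matrix(1, 1, 1))
  names(E) <- as.character(qn_encode(0L, 0L))
  for (i in seq_len(a$n_sites)) {
    A <- a$tensors[[i]]; B <- b$tensors[[i]]
    En <- new.env(parent = emptyenv())
    for (ba in seq_len(nrow(A$keys))) {
      lc <- as.character(A$keys[ba, 1])
      if (is.null(E[[lc]])) next
      # matching ket blocks: same l and p sectors
      for (bb in seq_len(nrow(B$keys))) {
        if (B$keys[bb, 1] != A$keys[ba, 1] || B$keys[bb, 2] != A$keys[ba, 2]) next
        da <- dim(A$blocks[[ba]]); db <- dim(B$blocks[[bb]])
        Am <- matrix(A$blocks[[ba]], da[1], da[3])
        Bm <- matrix(B$blocks[[bb]], db[1], db[3])
        contrib <- crossprod(Am, E[[lc]] %*% Bm)
        ledger_add(ledger, "overlap", 2 * (da[1] * db[1] * db[3] + da[3] * da[1] * db[3]))
        rc <- as.character(A$keys[ba, 3])
        En[[rc]] <- if (is.null(En[[rc]])) contrib else En[[rc]] + contrib
      }
    }
    E <- as.list(En)
  }
  tgt <- as.character(qn_encode(a$target[1], a$target[2]))
  if (is.null(E[[tgt]])) 0 else as.numeric(E[[tgt]])
}

#' Norm of a matrix product state
#' @param state an `mps`.
#' @return numeric norm.
#' @export
mps_norm <- function(state) sqrt(max(0, mps_overlap(state, state)))

#' Truncate one bond of a state
#'
#' Caps the Schmidt spectrum across the given bond (between sites `bond` and
#' `bond + 1`), restores the norm, and reports the discarded weight.  The
#' retained set follows the global truncation rule: top `d_max` states in
#' U(1) mode, top `d_max` whole multiplets in SU(2) mode.
#'
#' @param state an `mps`.
#' @param bond interior bond index (1 .. n_sites-1).
#' @param d_max state / multiplet cap (`Inf` keeps everything).
#' @param weight_threshold maximum allowed discarded weight (alternative).
#' @param ledger optional [flop_ledger()].
#' @return list with `state` and `discarded_weight`.
#' @export
truncate_bond <- function(state, bond, d_max = Inf, weight_threshold = 0,
                          ledger = NULL) {
  stopifnot(bond >= 1, bond < state$n_sites)
  state <- canonicalize(state, bond, ledger = ledger)
  state <- move_center_right(state, bond, d_max = d_max,
                             weight_threshold = weight_threshold, ledger = ledger)
  info <- attr(state, "last_split")
  nrm <- bt_norm(state$tensors[[state$center]])
  state$tensors[[state$center]] <- bt_scale(state$tensors[[state$center]], 1 / nrm)
  list(state = state, discarded_weight = info$discarded_weight)
}

#' Schmidt spectra of every interior bond
#'
#' Sweeps the canonical center across the chain and collects the exact
#' Schmidt values (with sector labels) of each bond of the current state.
#'
#' @param state an `mps`.
#' @return list (one entry per interior bond) of data frames
#'   `value`, `n`, `s`.
#' @export
mps_schmidt_spectra <- function(state) {
  st <- canonicalize(state, 1L)
  out <- vector("list", st$n_sites - 1L)
  for (i in seq_len(st$n_sites - 1L)) {
    st <- move_center_right(st, i)
    out[[i]] <- attr(st, "last_split")$spectrum
  }
  out
}

#' SU(2) multiplet content of the bond spectra
#'
#' Decomposes the Sz-resolved Schmidt spectrum of each bond into SU(2)
#' multiplets by character peeling of the per-(N, Sz) state counts.  Under
#' singlet embedding the bond bases consist of complete multiplets and the
#' decomposition is exact; the U(1) dimension of each returned spectrum then
#' equals the bond's state count.
#'
#' @param state an `mps`.
#' @param n_bonds number of leading bonds to analyze (default: all interior
#'   bonds of the physical chain, excluding an ancilla bond).
#' @return list of [multiplet_spectrum()] objects.
#' @export
mps_multiplet_spectra <- function(state, n_bonds = NULL) {
  spectra <- mps_schmidt_spectra(state)
  n_phys <- state$layout$n_orb
  if (is.null(n_bonds)) n_bonds <- min(length(spectra), n_phys - 1L)
  out <- vector("list", n_bonds)
  for (i in seq_len(n_bonds)) {
    sp <- spectra[[i]]
    entries_s <- integer(0); entries_m <- integer(0)
    for (nn in unique(sp$n)) {
      tab <- table(sp$s[sp$n == nn])
      peel <- peel_multiplets(as.integer(names(tab)), as.integer(tab))
      if (is.null(peel)) {
        # not multiplet-complete: report each state as its own entry
        entries_s <- c(entries_s, abs(sp$s[sp$n == nn]))
        entries_m <- c(entries_m, rep(1L, sum(sp$n == nn)))
      } else {
        entries_s <- c(entries_s, peel$two_s)
        entries_m <- c(entries_m, peel$multiplicity)
      }
    }
    out[[i]] <- multiplet_spectrum(entries_s, entries_m)
  }
  out
}
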