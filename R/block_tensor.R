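# Symmetry-conserving block-sparse tensors.
#
# A block tensor carries an ordered list of axes, each with a direction
# (incoming +1 / outgoing -1) and a sector -> dimension map, and a set of
# dense blocks keyed by one sector per axis.  Every stored block satisfies
# the conservation law: the direction-weighted sum of its sector quantum
# numbers equals the tensor charge.  Quantum numbers are (n, s) integer
# pairs encoded as in symmetry.R.

#' Construct a tensor axis
#'
#' @param dir +1 (incoming) or -1 (outgoing).
#' @param n,spin_label integer vectors of sector labels.
#' @param dim integer vector of sector dimensions.
#' @return an axis object (list with `dir`, `qn` codes, `dim`).
#' @export
bt_axis <- function(dir, n, spin_label, dim) {
  stopifnot(dir %in% c(1L, -1L), length(n) == length(spin_label),
            length(n) == length(dim), all(dim >= 1))
  qn <- qn_encode(n, spin_label)
  if (anyDuplicated(qn)) stop("bt_axis: duplicate sectors on one axis")
  o <- order(qn)
  structure(list(dir = as.integer(dir), qn = qn[o], dim = as.integer(dim[o])),
            class = "bt_axis")
}

axis_dim_of <- function(axis, code) {
  i <- match(code, axis$qn)
  if (is.na(i)) NA_integer_ else axis$dim[i]
}

axis_offsets <- function(axis) {
  off <- cumsum(axis$dim) - axis$dim
  names(off) <- as.character(axis$qn)
  off
}

#' Construct a block-sparse symmetric tensor
#'
#' @param axes list of [bt_axis()] objects.
#' @param keys integer matrix (one row per block) of encoded sector codes, or
#'   a list of integer vectors; use [qn_encode_public()] to build codes from
#'   `(n, spin_label)` pairs, or the higher-level helpers.
#' @param blocks list of numeric arrays, one per row of `keys`, with
#'   dimensions matching the axis sector dimensions.
#' @param charge length-2 integer vector `(n, spin_label)` carried by the
#'   tensor (0 for ordinary states/operators that conserve the quantum
#'   numbers).
#' @param mode `"u1"` or `"su2"` bookkeeping tag.
#' @return object of class `block_tensor`.
#' @export
block_tensor <- function(axes, keys = NULL, blocks = list(), charge = c(0L, 0L),
                         mode = "u1") {
  if (is.null(keys)) keys <- matrix(integer(0), nrow = 0, ncol = length(axes))
  if (is.list(keys)) keys <- do.call(rbind, keys)
  storage.mode(keys) <- "integer"
  t <- structure(list(axes = axes, keys = keys, blocks = blocks,
                      charge = as.integer(charge), mode = mode),
                 class = "block_tensor")
  bt_validate(t)
  t
}

#' Encode sector labels to internal codes
#' @param n,spin_label integer vectors.
#' @return integer codes usable in block keys.
#' @export
qn_encode_public <- function(n, spin_label) qn_encode(n, spin_label)

bt_validate <- function(t) {
  na <- length(t$axes)
  if (nrow(t$keys) != length(t$blocks))
    stop("block_tensor: keys/blocks length mismatch")
  if (na > 0 && ncol(t$keys) != na)
    stop("block_tensor: key width does not match axis count")
  if (nrow(t$keys) && anyDuplicated(apply(t$keys, 1, paste, collapse = ",")))
    stop("block_tensor: duplicate sector keys")
  for (b in seq_len(nrow(t$keys))) {
    key <- t$keys[b, ]
    tot <- c(0L, 0L)
    dims <- integer(na)
    for (ax in seq_len(na)) {
      axis <- t$axes[[ax]]
      d <- axis_dim_of(axis, key[ax])
      if (is.na(d))
        stop(sprintf("block_tensor: block %d uses a sector absent from axis %d", b, ax))
      dims[ax] <- d
      q <- qn_decode(key[ax])
      tot <- tot + axis$dir * c(q[1, "n"], q[1, "s"])
    }
    if (!all(tot == t$charge))
      stop(sprintf("block_tensor: block %d violates the conservation law", b))
    bd <- dim(t$blocks[[b]])
    if (is.null(bd)) bd <- length(t$blocks[[b]])
    if (na > 0 && !identical(as.integer(bd), dims))
      stop(sprintf("block_tensor: block %d shape does not match axis dimensions", b))
    if (!all(is.finite(t$blocks[[b]])))
      stop(sprintf("block_tensor: block %d has non-finite entries", b))
  }
  invisible(t)
}

#' Number of stored blocks
#' @param t a [block_tensor()].
#' @return integer.
#' @export
bt_n_blocks <- function(t) length(t$blocks)

#' Frobenius norm of a block tensor
#' @param t a [block_tensor()].
#' @return numeric.
#' @export
bt_norm <- function(t) sqrt(sum(vapply(t$blocks, function(b) sum(b^2), 0)))

#' Scale a block tensor
#' @param t a [block_tensor()].
#' @param alpha scalar.
#' @return scaled tensor.
#' @export
bt_scale <- function(t, alpha) {
  t$blocks <- lapply(t$blocks, function(b) b * alpha)
  t
}

#' Add two structurally compatible block tensors
#' @param a,b block tensors over the same axes and charge.
#' @return their sum.
#' @export
bt_add <- function(a, b) {
  stopifnot(length(a$axes) == length(b$axes), all(a$charge == b$charge))
  keys_a <- apply(a$keys, 1, paste, collapse = ",")
  keys_b <- apply(b$keys, 1, paste, collapse = ",")
  out <- a
  for (i in seq_along(keys_b)) {
    j <- match(keys_b[i], keys_a)
    if (is.na(j)) {
      out$keys <- rbind(out$keys, b$keys[i, , drop = FALSE])
      out$blocks[[length(out$blocks) + 1L]] <- b$blocks[[i]]
    } else {
      out$blocks[[j]] <- out$blocks[[j]] + b$blocks[[i]]
    }
  }
  out
}

#' Scatter a block tensor into a dense array
#'
#' Test and oracle helper: embeds every block at its sector offsets in the
#' full dense array of the tensor.
#'
#' @param t a [block_tensor()].
#' @return dense array with one dimension per axis.
#' @export
bt_to_dense <- function(t) {
  na <- length(t$axes)
  full <- vapply(t$axes, function(a) sum(a$dim), 0L)
  arr <- array(0, dim = full)
  offs <- lapply(t$axes, axis_offsets)
  for (b in seq_len(nrow(t$keys))) {
    idx <- vector("list", na)
    for (ax in seq_len(na)) {
      o <- offs[[ax]][[as.character(t$keys[b, ax])]]
      d <- axis_dim_of(t$axes[[ax]], t$keys[b, ax])
      idx[[ax]] <- seq.int(o + 1L, o + d)
    }
    arr <- do.call(`[<-`, c(list(arr), idx, list(value = t$blocks[[b]])))
  }
  arr
}

#' Gather a dense array into a block tensor
#'
#' Inverse of [bt_to_dense()]: extracts the symmetry-allowed blocks of a
#' dense array.  Entries outside allowed blocks must be (numerically) zero.
#'
#' @param arr dense array.
#' @param axes list of [bt_axis()] objects matching `dim(arr)`.
#' @param charge tensor charge `(n, spin_label)`.
#' @param mode bookkeeping tag.
#' @param tol entries larger than `tol` outside allowed blocks raise an error.
#' @return a [block_tensor()].
#' @export
bt_from_dense <- function(arr, axes, charge = c(0L, 0L), mode = "u1", tol = 1e-12) {
  na <- length(axes)
  stopifnot(identical(as.integer(dim(arr)), vapply(axes, function(a) sum(a$dim), 0L)))
  offs <- lapply(axes, axis_offsets)
  combos <- expand.grid(lapply(axes, function(a) seq_along(a$qn)), KEEP.OUT.ATTRS = FALSE)
  keys <- list(); blocks <- list()
  captured <- 0
  for (r in seq_len(nrow(combos))) {
    key <- integer(na); ok <- TRUE
    tot <- c(0L, 0L)
    idx <- vector("list", na)
    for (ax in seq_len(na)) {
      i <- combos[r, ax]
      key[ax] <- axes[[ax]]$qn[i]
      q <- qn_decode(key[ax])
      tot <- tot + axes[[ax]]$dir * c(q[1, "n"], q[1, "s"])
      o <- offs[[ax]][[as.character(key[ax])]]
      idx[[ax]] <- seq.int(o + 1L, o + axes[[ax]]$dim[i])
    }
    if (!all(tot == as.integer(charge))) next
    blk <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    captured <- captured + sum(blk^2)
    if (sum(blk^2) == 0) next
    keys[[length(keys) + 1L]] <- key
    blocks[[length(blocks) + 1L]] <- array(blk, dim = vapply(idx, length, 0L))
  }
  if (sum(arr^2) - captured > tol^2 * max(1, sum(arr^2)))
    stop("bt_from_dense: array has weight outside symmetry-allowed blocks")
  block_tensor(axes, keys, blocks, charge = charge, mode = mode)
}

#' Random conserving block tensor
#'
#' Fills every symmetry-allowed block with standard normal entries drawn from
#' the current RNG stream.
#'
#' @param axes list of [bt_axis()].
#' @param charge tensor charge.
#' @param mode bookkeeping tag.
#' @return a [block_tensor()].
#' @export
bt_random <- function(axes, charge = c(0L, 0L), mode = "u1") {
  na <- length(axes)
  combos <- expand.grid(lapply(axes, function(a) seq_along(a$qn)), KEEP.OUT.ATTRS = FALSE)
  keys <- list(); blocks <- list()
  for (r in seq_len(nrow(combos))) {
    key <- integer(na); tot <- c(0L, 0L); dims <- integer(na)
    for (ax in seq_len(na)) {
      i <- combos[r, ax]
      key[ax] <- axes[[ax]]$qn[i]
      q <- qn_decode(key[ax])
      tot <- tot + axes[[ax]]$dir * c(q[1, "n"], q[1, "s"])
      dims[ax] <- axes[[ax]]$dim[i]
    }
    if (!all(tot == as.integer(charge))) next
    keys[[length(keys) + 1L]] <- key
    blocks[[length(blocks) + 1L]] <- array(stats::rnorm(prod(dims)), dim = dims)
  }
  block_tensor(axes, keys, blocks, charge = charge, mode = mode)
}

#' Contract two block tensors
#'
#' Sector-wise tensor contraction over paired axes.  Paired axes must have
#' opposite directions; sectors present on both sides are contracted,
#' sectors present on one side only contribute zero.  Every dense block
#' multiply adds `2*m*n*k` operations to the ledger.
#'
#' @param a,b block tensors.
#' @param axes_a,axes_b integer vectors of axis positions to contract
#'   (pairwise: `axes_a[i]` with `axes_b[i]`).
#' @param ledger optional [flop_ledger()].
#' @param phase ledger phase name.
#' @return a [block_tensor()] whose axes are the free axes of `a` followed by
#'   the free axes of `b`; if no free axes remain, a numeric scalar.
#' @export
bt_contract <- function(a, b, axes_a, axes_b, ledger = NULL, phase = "contract") {
  axes_a <- as.integer(axes_a); axes_b <- as.integer(axes_b)
  stopifnot(length(axes_a) == length(axes_b))
  for (i in seq_along(axes_a)) {
    axa <- a$axes[[axes_a[i]]]; axb <- b$axes[[axes_b[i]]]
    if (axa$dir != -axb$dir)
      stop(sprintf("bt_contract: axes %d/%d do not have opposite directions", axes_a[i], axes_b[i]))
    common <- intersect(axa$qn, axb$qn)
    if (length(common)) {
      da <- axa$dim[match(common, axa$qn)]
      db <- axb$dim[match(common, axb$qn)]
      if (!all(da == db))
        stop(sprintf("bt_contract: dimension map mismatch on contracted axis pair %d", i))
    }
  }
  free_a <- setdiff(seq_along(a$axes), axes_a)
  free_b <- setdiff(seq_along(b$axes), axes_b)

  # a-blocks as matrices (free x contracted), grouped by contracted key
  mat_a <- vector("list", nrow(a$keys)); cka <- character(nrow(a$keys))
  fka <- vector("list", nrow(a$keys))
  for (i in seq_len(nrow(a$keys))) {
    arr <- a$blocks[[i]]
    d <- dim(arr); if (is.null(d)) d <- length(arr)
    perm <- c(free_a, axes_a)
    arr <- aperm(array(arr, dim = d), perm)
    m <- prod(d[free_a]); k <- prod(d[axes_a])
    mat_a[[i]] <- matrix(arr, nrow = max(m, 1L), ncol = max(k, 1L))
    cka[i] <- paste(a$keys[i, axes_a], collapse = ",")
    fka[[i]] <- a$keys[i, free_a]
  }
  mat_b <- vector("list", nrow(b$keys)); ckb <- character(nrow(b$keys))
  fkb <- vector("list", nrow(b$keys))
  for (i in seq_len(nrow(b$keys))) {
    arr <- b$blocks[[i]]
    d <- dim(arr); if (is.null(d)) d <- length(arr)
    perm <- c(axes_b, free_b)
    arr <- aperm(array(arr, dim = d), perm)
    k <- prod(d[axes_b]); nn <- prod(d[free_b])
    mat_b[[i]] <- matrix(arr, nrow = max(k, 1L), ncol = max(nn, 1L))
    ckb[i] <- paste(b$keys[i, axes_b], collapse = ",")
    fkb[[i]] <- b$keys[i, free_b]
  }

  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(a$keys))) {
    js <- which(ckb == cka[i])
    for (j in js) {
      mm <- nrow(mat_a[[i]]); kk <- ncol(mat_a[[i]]); nn <- ncol(mat_b[[j]])
      prod_mat <- mat_a[[i]] %*% mat_b[[j]]
      ledger_add(ledger, phase, 2 * mm * nn * kk)
      okey <- paste(c(fka[[i]], fkb[[j]]), collapse = ",")
      if (is.null(acc[[okey]])) {
        acc[[okey]] <- list(key = c(fka[[i]], fkb[[j]]), mat = prod_mat,
                            dims = c(dim_of_key(a, fka[[i]], free_a),
                                     dim_of_key(b, fkb[[j]], free_b)))
      } else {
        acc[[okey]]$mat <- acc[[okey]]$mat + prod_mat
      }
    }
  }

  out_axes <- c(a$axes[free_a], b$axes[free_b])
  charge <- a$charge + b$charge
  if (length(out_axes) == 0L) {
    tot <- 0
    for (nm in ls(acc)) tot <- tot + as.numeric(acc[[nm]]$mat)
    return(tot)
  }
  keys <- list(); blocks <- list()
  for (nm in ls(acc)) {
    e <- acc[[nm]]
    keys[[length(keys) + 1L]] <- e$key
    blocks[[length(blocks) + 1L]] <- array(e$mat, dim = e$dims)
  }
  block_tensor(out_axes, keys, blocks, charge = charge, mode = a$mode)
}

dim_of_key <- function(t, key, axes_idx) {
  if (!length(axes_idx)) return(integer(0))
  vapply(seq_along(axes_idx), function(i)
    axis_dim_of(t$axes[[axes_idx[i]]], key[i]), 0L)
}

# Global truncation rule shared by all split points.
# values: singular values (all sectors), sec_n/sec_s: sector labels per value.
# Returns indices to keep.  In SU(2) mode d_max caps the number of whole
# multiplets; degenerate groups (exact multiplet partners under singlet
# embedding) are never split.
select_kept_states <- function(values, sec_n, sec_s, d_max = Inf,
                               weight_threshold = 0, mode = "u1",
                               degeneracy_tol = 1e-8) {
  stopifnot(length(values) == length(sec_n), length(values) == length(sec_s))
  if (!length(values)) return(integer(0))
  total <- sum(values^2)
  vmax <- max(values)
  keepable <- which(values > vmax * 1e-14)
  if (!length(keepable)) keepable <- which.max(values)
  o <- keepable[order(-values[keepable], sec_n[keepable], sec_s[keepable])]
  if (mode != "su2") {
    n_keep <- length(o)
    if (weight_threshold > 0) {
      w <- rev(cumsum(rev(values[o]^2)))  # weight from i to end
      # smallest prefix whose discarded tail weight is below threshold
      disc <- c(w[-1], 0) / total
      n_keep <- min(which(disc <= weight_threshold))
    }
    n_keep <- min(n_keep, d_max)
    return(sort(o[seq_len(n_keep)]))
  }
  # SU(2): walk degeneracy groups, never split one, cap multiplet count
  vals <- values[o]
  grp <- cumsum(c(TRUE, diff(vals) < -degeneracy_tol * vmax))
  kept <- integer(0)
  kept_mult <- 0L
  for (g in seq_len(max(grp))) {
    cand <- o[grp == g]
    trial <- c(kept, cand)
    mult <- su2_multiplet_count(sec_n[trial], sec_s[trial])
    if (mult > d_max) break
    kept <- trial
    kept_mult <- mult
    if (weight_threshold > 0) {
      disc <- (total - sum(values[kept]^2)) / total
      if (disc <= weight_threshold && !is.finite(d_max)) break
    }
  }
  if (!length(kept)) kept <- o[grp == 1]
  sort(kept)
}

# multiplet count of a set of Sz-resolved states by character peeling;
# falls back to the state count if the set is not multiplet-complete
# (possible mid-optimization before the state is spin pure).
su2_multiplet_count <- function(sec_n, sec_s) {
  tot <- 0L
  for (n in unique(sec_n)) {
    sel <- sec_n == n
    tab <- table(sec_s[sel])
    peel <- peel_multiplets(as.integer(names(tab)), as.integer(tab))
    tot <- tot + if (is.null(peel)) as.integer(sum(tab)) else sum(peel$multiplicity)
  }
  tot
}

#' Split a block tensor by singular value decomposition
#'
#' Factorizes the tensor across a bipartition of its axes, sector by sector,
#' and truncates the shared bond.  The retained basis is chosen by globally
#' sorting squared singular values across sectors: in U(1) mode the top
#' `d_max` states are kept; in SU(2) mode whole multiplets (identified as
#' exactly degenerate groups) are kept up to `d_max` multiplets.  The
#' discarded weight is the sum of discarded squared singular values divided
#' by the total.
#'
#' @param t a [block_tensor()].
#' @param row_axes integer positions of the axes forming the left factor.
#' @param d_max state cap (U(1)) or multiplet cap (SU(2)); `Inf` keeps all
#'   numerically nonzero states.
#' @param weight_threshold maximum allowed discarded weight (alternative to
#'   `d_max`; 0 disables).
#' @param ledger optional [flop_ledger()] (factorizations count 0 operations
#'   by convention; retained state counts are reported instead).
#' @return list with `left` (isometry, bond axis last, outgoing),
#'   `spectrum` (data frame of singular values with sector labels),
#'   `right` (bond axis first, incoming), and `discarded_weight`.
#' @export
bt_svd_split <- function(t, row_axes, d_max = Inf, weight_threshold = 0,
                         ledger = NULL) {
  na <- length(t$axes)
  row_axes <- as.integer(row_axes)
  col_axes <- setdiff(seq_len(na), row_axes)
  if (!length(row_axes) || !length(col_axes))
    stop("bt_svd_split: bipartition must leave both groups non-empty")
  if (!length(t$blocks)) stop("bt_svd_split: empty tensor")

  # fused row sector of each block: direction-weighted qn sum over row axes
  fused_of <- function(key, axes_idx) {
    tot <- c(0L, 0L)
    for (i in seq_along(axes_idx)) {
      q <- qn_decode(key[axes_idx[i]])
      tot <- tot + t$axes[[axes_idx[i]]]$dir * c(q[1, "n"], q[1, "s"])
    }
    tot
  }
  nb <- nrow(t$keys)
  rowq <- matrix(0L, nb, 2)
  for (b in seq_len(nb)) rowq[b, ] <- fused_of(t$keys[b, ], row_axes)
  rcode <- qn_encode(rowq[, 1], rowq[, 2])

  sectors <- sort(unique(rcode))
  left_keys <- list(); left_blocks <- list()
  right_keys <- list(); right_blocks <- list()
  spec_vals <- numeric(0); spec_n <- integer(0); spec_s <- integer(0)
  per_sector <- list()

  for (sc in sectors) {
    bl <- which(rcode == sc)
    # row / col layout within this fused sector
    rkeys <- unique(lapply(bl, function(b) t$keys[b, row_axes]))
    ckeys <- unique(lapply(bl, function(b) t$keys[b, col_axes]))
    rdims <- vapply(rkeys, function(k) prod(dim_of_key(t, k, row_axes)), 0)
    cdims <- vapply(ckeys, function(k) prod(dim_of_key(t, k, col_axes)), 0)
    roff <- cumsum(rdims) - rdims
    coff <- cumsum(cdims) - cdims
    M <- matrix(0, sum(rdims), sum(cdims))
    rid <- vapply(rkeys, paste, "", collapse = ",")
    cid <- vapply(ckeys, paste, "", collapse = ",")
    for (b in bl) {
      i <- match(paste(t$keys[b, row_axes], collapse = ","), rid)
      j <- match(paste(t$keys[b, col_axes], collapse = ","), cid)
      arr <- t$blocks[[b]]
      d <- dim(arr); if (is.null(d)) d <- length(arr)
      arr <- aperm(array(arr, dim = d), c(row_axes, col_axes))
      M[roff[i] + seq_len(rdims[i]), coff[j] + seq_len(cdims[j])] <-
        matrix(arr, rdims[i], cdims[j])
    }
    sv <- svd(M)
    q <- qn_decode(sc)
    per_sector[[as.character(sc)]] <- list(code = sc, n = q[1, "n"], s = q[1, "s"],
      u = sv$u, d = sv$d, v = sv$v, rkeys = rkeys, ckeys = ckeys,
      rdims = rdims, cdims = cdims, roff = roff, coff = coff)
    spec_vals <- c(spec_vals, sv$d)
    spec_n <- c(spec_n, rep(q[1, "n"], length(sv$d)))
    spec_s <- c(spec_s, rep(q[1, "s"], length(sv$d)))
  }

  keep <- select_kept_states(spec_vals, spec_n, spec_s, d_max = d_max,
                             weight_threshold = weight_threshold, mode = t$mode)
  total_w <- sum(spec_vals^2)
  disc_w <- if (total_w > 0) (total_w - sum(spec_vals[keep]^2)) / total_w else 0

  # map kept global indices back to sectors
  offset <- 0L
  bond_n <- integer(0); bond_s <- integer(0); bond_dim <- integer(0)
  spec_out <- data.frame(value = numeric(0), n = integer(0), s = integer(0))
  for (nm in names(per_sector)) {
    ps <- per_sector[[nm]]
    nloc <- length(ps$d)
    loc <- keep[keep > offset & keep <= offset + nloc] - offset
    offset <- offset + nloc
    per_sector[[nm]]$kept <- loc
    if (!length(loc)) next
    bond_n <- c(bond_n, ps$n); bond_s <- c(bond_s, ps$s)
    bond_dim <- c(bond_dim, length(loc))
    spec_out <- rbind(spec_out, data.frame(value = ps$d[loc],
                                           n = rep(ps$n, length(loc)),
                                           s = rep(ps$s, length(loc))))
  }
  bond_axis_out <- bt_axis(-1L, bond_n, bond_s, bond_dim)
  bond_axis_in <- bt_axis(1L, bond_n, bond_s, bond_dim)

  for (nm in names(per_sector)) {
    ps <- per_sector[[nm]]
    loc <- ps$kept
    if (!length(loc)) next
    U <- ps$u[, loc, drop = FALSE]
    SV <- diag(ps$d[loc], nrow = length(loc)) %*% t(ps$v[, loc, drop = FALSE])
    for (i in seq_along(ps$rkeys)) {
      blk <- U[ps$roff[i] + seq_len(ps$rdims[i]), , drop = FALSE]
      if (sum(blk^2) == 0) next
      rd <- dim_of_key(t, ps$rkeys[[i]], row_axes)
      left_keys[[length(left_keys) + 1L]] <- c(ps$rkeys[[i]], ps$code)
      left_blocks[[length(left_blocks) + 1L]] <- array(blk, dim = c(rd, length(loc)))
    }
    for (j in seq_along(ps$ckeys)) {
      blk <- SV[, ps$coff[j] + seq_len(ps$cdims[j]), drop = FALSE]
      if (sum(blk^2) == 0) next
      cd <- dim_of_key(t, ps$ckeys[[j]], col_axes)
      right_keys[[length(right_keys) + 1L]] <- c(ps$code, ps$ckeys[[j]])
      right_blocks[[length(right_blocks) + 1L]] <- array(blk, dim = c(length(loc), cd))
    }
  }

  left <- block_tensor(c(t$axes[row_axes], list(bond_axis_out)),
                       left_keys, left_blocks, charge = c(0L, 0L), mode = t$mode)
  right <- block_tensor(c(list(bond_axis_in), t$axes[col_axes]),
                        right_keys, right_blocks, charge = t$charge, mode = t$mode)
  list(left = left, spectrum = spec_out, right = right, discarded_weight = disc_w)
}
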