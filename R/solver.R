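# DMRG optimization loop: environments, two-site effective Hamiltonian,
# sweeps, convergence control.
#
# Environments are stored per MPO bond state: E[[id]] is a list of sector
# blocks keyed by the ket bond sector code, each a (bra x ket) matrix whose
# bra sector is shifted by the state's charge.  The two-site effective
# Hamiltonian at bond (i, i+1) is assembled as operators LL[gamma] on the
# fused (left-bond x phys_i) row space and RR[gamma] on the fused
# (phys_{i+1} x right-bond) column space, so that a matvec is
# sum_gamma LL[g] %*% Psi %*% t(RR[g]).

# attach precomputed lookup caches to an mpo (sector-code deltas are affine
# in the integer encoding: shifting by charge (dn, ds) adds dn*QN_BASE + ds)
mpo_prepare <- function(mpo) {
  if (!is.null(mpo$op_nz)) return(mpo)
  mpo$op_nz <- lapply(mpo$ops, function(m) {
    nz <- which(m != 0, arr.ind = TRUE)
    list(i = nz[, 1], j = nz[, 2], w = m[nz])
  })
  mpo$pcodes <- lapply(mpo$layout$sectors, function(s) qn_encode(s$n, s$s))
  mpo$pdelta <- lapply(mpo$layout$sectors, function(s) s$n * QN_BASE + s$s)
  mpo$pcodes_chr <- lapply(mpo$pcodes, as.character)
  mpo$qdelta <- lapply(mpo$bond_states, function(q) {
    d <- q$n * QN_BASE + q$s
    names(d) <- as.character(q$id)
    d
  })
  mpo$edge_cols <- lapply(mpo$edges, function(e)
    list(a = as.character(e$a), b = as.character(e$b), op = e$op, c = e$c))
  mpo
}

# lookup tables for one site tensor: by (l code, p code) and (r code, p code)
site_block_maps <- function(A) {
  bylp <- new.env(parent = emptyenv())
  byrp <- new.env(parent = emptyenv())
  mats <- vector("list", nrow(A$keys))
  for (b in seq_len(nrow(A$keys))) {
    d <- dim(A$blocks[[b]])
    lchr <- as.character(A$keys[b, 1])
    pchr <- as.character(A$keys[b, 2])
    rchr <- as.character(A$keys[b, 3])
    mats[[b]] <- list(mat = matrix(A$blocks[[b]], d[1], d[3]),
                      l = A$keys[b, 1], p = A$keys[b, 2], r = A$keys[b, 3],
                      lchr = lchr, rchr = rchr)
    if (is.null(bylp[[lchr]])) bylp[[lchr]] <- new.env(parent = emptyenv())
    bylp[[lchr]][[pchr]] <- b
    if (is.null(byrp[[rchr]])) byrp[[rchr]] <- new.env(parent = emptyenv())
    byrp[[rchr]][[pchr]] <- b
  }
  list(mats = mats, bylp = bylp, byrp = byrp)
}

env_boundary_left <- function() {
  blocks <- list(matrix(1, 1, 1))
  names(blocks) <- as.character(qn_encode(0L, 0L))
  e <- list(list(qd = 0L, blocks = blocks))
  names(e) <- as.character(STATE_S)
  e
}

env_boundary_right <- function(target) {
  blocks <- list(matrix(1, 1, 1))
  names(blocks) <- as.character(qn_encode(target[1], target[2]))
  e <- list(list(qd = 0L, blocks = blocks))
  names(e) <- as.character(STATE_F)
  e
}

# propagate a left environment across site k
env_left_update <- function(E, A, mpo, k, ledger = NULL) {
  sm <- site_block_maps(A)
  pchr <- mpo$pcodes_chr[[k]]
  ec <- mpo$edge_cols[[k]]
  qout <- mpo$qdelta[[k + 1L]]
  op_nz <- mpo$op_nz
  acc <- new.env(parent = emptyenv())
  env_flops <- 0
  for (ei in seq_along(ec$c)) {
    Ea <- E[[ec$a[ei]]]
    if (is.null(Ea)) next
    b <- ec$b[ei]
    nz <- op_nz[[ec$op[ei]]]
    cc <- ec$c[ei]
    qd <- Ea$qd
    kcn <- names(Ea$blocks)
    kci <- as.integer(kcn)
    bcn <- if (qd == 0L) kcn else as.character(kci + qd)
    for (t in seq_along(nz$w)) {
      pb <- pchr[nz$i[t]]; pk <- pchr[nz$j[t]]
      w <- nz$w[t] * cc
      for (u in seq_along(kcn)) {
        lk1 <- sm$bylp[[kcn[u]]]
        ket_b <- if (is.null(lk1)) NULL else lk1[[pk]]
        if (is.null(ket_b)) next
        lk2 <- sm$bylp[[bcn[u]]]
        bra_b <- if (is.null(lk2)) NULL else lk2[[pb]]
        if (is.null(bra_b)) next
        Mk <- sm$mats[[ket_b]]; Mb <- sm$mats[[bra_b]]
        Eb <- Ea$blocks[[u]]
        contrib <- crossprod(Mb$mat, Eb %*% Mk$mat) * w
        env_flops <- env_flops +
          2 * (nrow(Eb) * ncol(Eb) * ncol(Mk$mat) +
               ncol(Mb$mat) * nrow(Mb$mat) * ncol(Mk$mat))
        rc <- Mk$rchr
        slot <- acc[[b]]
        if (is.null(slot)) slot <- list(qd = qout[[b]], blocks = list())
        slot$blocks[[rc]] <- if (is.null(slot$blocks[[rc]])) contrib
                             else slot$blocks[[rc]] + contrib
        acc[[b]] <- slot
      }
    }
  }
  ledger_add(ledger, "env", env_flops)
  as.list(acc)
}

# propagate a right environment across site k (from bond k to bond k-1)
env_right_update <- function(E, A, mpo, k, ledger = NULL) {
  sm <- site_block_maps(A)
  pchr <- mpo$pcodes_chr[[k]]
  ec <- mpo$edge_cols[[k]]
  qout <- mpo$qdelta[[k]]
  op_nz <- mpo$op_nz
  acc <- new.env(parent = emptyenv())
  env_flops <- 0
  for (ei in seq_along(ec$c)) {
    Ed <- E[[ec$b[ei]]]
    if (is.null(Ed)) next
    a <- ec$a[ei]
    nz <- op_nz[[ec$op[ei]]]
    cc <- ec$c[ei]
    qd <- Ed$qd
    rcn <- names(Ed$blocks)
    rci <- as.integer(rcn)
    bcn <- if (qd == 0L) rcn else as.character(rci + qd)
    for (t in seq_along(nz$w)) {
      pb <- pchr[nz$i[t]]; pk <- pchr[nz$j[t]]
      w <- nz$w[t] * cc
      for (u in seq_along(rcn)) {
        lk1 <- sm$byrp[[rcn[u]]]
        ket_b <- if (is.null(lk1)) NULL else lk1[[pk]]
        if (is.null(ket_b)) next
        lk2 <- sm$byrp[[bcn[u]]]
        bra_b <- if (is.null(lk2)) NULL else lk2[[pb]]
        if (is.null(bra_b)) next
        Mk <- sm$mats[[ket_b]]; Mb <- sm$mats[[bra_b]]
        Eb <- Ed$blocks[[u]]
        contrib <- (Mb$mat %*% Eb %*% t(Mk$mat)) * w
        env_flops <- env_flops +
          2 * (nrow(Mb$mat) * nrow(Eb) * ncol(Eb) +
               nrow(Mb$mat) * ncol(Eb) * nrow(Mk$mat))
        lc <- Mk$lchr
        slot <- acc[[a]]
        if (is.null(slot)) slot <- list(qd = qout[[a]], blocks = list())
        slot$blocks[[lc]] <- if (is.null(slot$blocks[[lc]])) contrib
                             else slot$blocks[[lc]] + contrib
        acc[[a]] <- slot
      }
    }
  }
  ledger_add(ledger, "env", env_flops)
  as.list(acc)
}

#' Expectation value of an MPO on a matrix product state
#'
#' Contracts `<psi| O |psi>` exactly by propagating the operator
#' environment along the chain.  The state need not be normalized; divide by
#' `mps_norm(state)^2` for a Rayleigh quotient.
#'
#' @param state an `mps`.
#' @param mpo an `mpo` over the same chain layout.
#' @param ledger optional [flop_ledger()].
#' @return numeric expectation (Hartree for the Hamiltonian MPO).
#' @export
mps_expectation <- function(state, mpo, ledger = NULL) {
  stopifnot(state$n_sites == mpo$n_sites)
  mpo <- mpo_prepare(mpo)
  E <- env_boundary_left()
  for (k in seq_len(state$n_sites))
    E <- env_left_update(E, state$tensors[[k]], mpo, k, ledger)
  f <- E[[as.character(STATE_F)]]
  if (is.null(f)) return(0)
  tgt <- as.character(qn_encode(state$target[1], state$target[2]))
  if (is.null(f$blocks[[tgt]])) 0 else as.numeric(f$blocks[[tgt]])
}

# fused (left-bond x phys) row space and (phys x right-bond) column space.
# Each fused sector holds component vectors (bond code, phys code, dim,
# offset) plus an O(1) lookup from (bond code, phys code) to the component.
fuse_row_space <- function(bond_axis, sectors) {
  pcodes <- qn_encode(sectors$n, sectors$s)
  pdelta <- sectors$n * QN_BASE + sectors$s
  acc <- new.env(parent = emptyenv())
  for (li in seq_along(bond_axis$qn)) {
    for (pj in seq_along(pcodes)) {
      qf <- as.character(bond_axis$qn[li] + pdelta[pj])
      cur <- acc[[qf]]
      row <- c(bond_axis$qn[li], pcodes[pj], bond_axis$dim[li])
      acc[[qf]] <- if (is.null(cur)) list(row) else c(cur, list(row))
    }
  }
  res <- list()
  for (qf in ls(acc)) {
    m <- do.call(rbind, acc[[qf]])
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    off <- cumsum(m[, 3]) - m[, 3]
    lk <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(m))) {
      bchr <- as.character(m[i, 1]); pchr <- as.character(m[i, 2])
      if (is.null(lk[[bchr]])) lk[[bchr]] <- new.env(parent = emptyenv())
      lk[[bchr]][[pchr]] <- i
    }
    res[[qf]] <- list(dim = sum(m[, 3]), bcode = m[, 1], pcode = m[, 2],
                      d = m[, 3], off = off, lk = lk)
  }
  res
}

fuse_col_space <- function(sectors, bond_axis) {
  pcodes <- qn_encode(sectors$n, sectors$s)
  pdelta <- sectors$n * QN_BASE + sectors$s
  acc <- new.env(parent = emptyenv())
  for (ri in seq_along(bond_axis$qn)) {
    for (pj in seq_along(pcodes)) {
      qf <- as.character(bond_axis$qn[ri] - pdelta[pj])
      cur <- acc[[qf]]
      row <- c(bond_axis$qn[ri], pcodes[pj], bond_axis$dim[ri])
      acc[[qf]] <- if (is.null(cur)) list(row) else c(cur, list(row))
    }
  }
  res <- list()
  for (qf in ls(acc)) {
    m <- do.call(rbind, acc[[qf]])
    m <- m[order(m[, 2], m[, 1]), , drop = FALSE]
    off <- cumsum(m[, 3]) - m[, 3]
    lk <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(m))) {
      bchr <- as.character(m[i, 1]); pchr <- as.character(m[i, 2])
      if (is.null(lk[[bchr]])) lk[[bchr]] <- new.env(parent = emptyenv())
      lk[[bchr]][[pchr]] <- i
    }
    res[[qf]] <- list(dim = sum(m[, 3]), bcode = m[, 1], pcode = m[, 2],
                      d = m[, 3], off = off, lk = lk)
  }
  res
}

# assemble LL[gamma] on the row space from the left environment and site-i
# edges.  Contributions are collected first and the dense sector blocks are
# materialized once, so each fill is in place.
assemble_LL <- function(E, mpo, k, rowspace) {
  pchr <- mpo$pcodes_chr[[k]]
  pdelta <- mpo$pdelta[[k]]
  ec <- mpo$edge_cols[[k]]
  qout <- mpo$qdelta[[k + 1L]]
  op_nz <- mpo$op_nz
  cont <- new.env(parent = emptyenv())
  qd_of <- new.env(parent = emptyenv())
  for (ei in seq_along(ec$c)) {
    Ea <- E[[ec$a[ei]]]
    if (is.null(Ea)) next
    g <- ec$b[ei]
    nz <- op_nz[[ec$op[ei]]]
    cc <- ec$c[ei]
    qd <- Ea$qd
    qg <- qout[[g]]
    qd_of[[g]] <- qg
    kcn <- names(Ea$blocks)
    kci <- as.integer(kcn)
    bcn <- if (qd == 0L) kcn else as.character(kci + qd)
    for (t in seq_along(nz$w)) {
      pb <- pchr[nz$i[t]]; pk <- pchr[nz$j[t]]
      dpk <- pdelta[nz$j[t]]
      w <- nz$w[t] * cc
      qket_all <- kci + dpk
      qket_chr <- as.character(qket_all)
      qbra_chr <- if (qg == 0L) qket_chr else as.character(qket_all + qg)
      for (u in seq_along(kci)) {
        qket <- qket_chr[u]
        rs_ket <- rowspace[[qket]]
        if (is.null(rs_ket)) next
        rs_bra <- rowspace[[qbra_chr[u]]]
        if (is.null(rs_bra)) next
        l1 <- rs_ket$lk[[kcn[u]]]
        ci <- if (is.null(l1)) NULL else l1[[pk]]
        l2 <- rs_bra$lk[[bcn[u]]]
        bi <- if (is.null(l2)) NULL else l2[[pb]]
        if (is.null(ci) || is.null(bi)) next
        entry <- list(bi = bi, ci = ci, M = Ea$blocks[[u]], w = w,
                      nr = rs_bra$dim, nc = rs_ket$dim)
        sub <- cont[[g]]
        if (is.null(sub)) { sub <- new.env(parent = emptyenv()); cont[[g]] <- sub }
        cur <- sub[[qket]]
        sub[[qket]] <- if (is.null(cur)) list(entry) else c(cur, list(entry))
      }
    }
  }
  LL <- list()
  for (g in ls(cont)) {
    sub <- cont[[g]]
    slot <- list(qd = qd_of[[g]], blocks = list())
    for (qket in ls(sub)) {
      rs_ket <- rowspace[[qket]]
      rs_bra <- rowspace[[as.character(as.integer(qket) + qd_of[[g]])]]
      entries <- sub[[qket]]
      blk <- matrix(0, entries[[1]]$nr, entries[[1]]$nc)
      for (e in entries) {
        rows <- rs_bra$off[e$bi] + seq_len(rs_bra$d[e$bi])
        cols <- rs_ket$off[e$ci] + seq_len(rs_ket$d[e$ci])
        blk[rows, cols] <- blk[rows, cols] + e$M * e$w
      }
      slot$blocks[[qket]] <- blk
    }
    LL[[g]] <- slot
  }
  LL
}

# assemble RR[gamma] on the column space from the right environment and
# site-(i+1) edges
assemble_RR <- function(E, mpo, k, colspace) {
  pchr <- mpo$pcodes_chr[[k]]
  pdelta <- mpo$pdelta[[k]]
  ec <- mpo$edge_cols[[k]]
  qmid <- mpo$qdelta[[k]]
  op_nz <- mpo$op_nz
  cont <- new.env(parent = emptyenv())
  qd_of <- new.env(parent = emptyenv())
  for (ei in seq_along(ec$c)) {
    Ed <- E[[ec$b[ei]]]
    if (is.null(Ed)) next
    g <- ec$a[ei]
    nz <- op_nz[[ec$op[ei]]]
    cc <- ec$c[ei]
    qd <- Ed$qd
    qg <- qmid[[g]]
    qd_of[[g]] <- qg
    rcn <- names(Ed$blocks)
    rci <- as.integer(rcn)
    bcn <- if (qd == 0L) rcn else as.character(rci + qd)
    for (t in seq_along(nz$w)) {
      pb <- pchr[nz$i[t]]; pk <- pchr[nz$j[t]]
      dpk <- pdelta[nz$j[t]]
      w <- nz$w[t] * cc
      qket_all <- rci - dpk
      qket_chr <- as.character(qket_all)
      qbra_chr <- if (qg == 0L) qket_chr else as.character(qket_all + qg)
      for (u in seq_along(rci)) {
        qket <- qket_chr[u]
        cs_ket <- colspace[[qket]]
        if (is.null(cs_ket)) next
        cs_bra <- colspace[[qbra_chr[u]]]
        if (is.null(cs_bra)) next
        l1 <- cs_ket$lk[[rcn[u]]]
        ci <- if (is.null(l1)) NULL else l1[[pk]]
        l2 <- cs_bra$lk[[bcn[u]]]
        bi <- if (is.null(l2)) NULL else l2[[pb]]
        if (is.null(ci) || is.null(bi)) next
        entry <- list(bi = bi, ci = ci, M = Ed$blocks[[u]], w = w,
                      nr = cs_bra$dim, nc = cs_ket$dim)
        sub <- cont[[g]]
        if (is.null(sub)) { sub <- new.env(parent = emptyenv()); cont[[g]] <- sub }
        cur <- sub[[qket]]
        sub[[qket]] <- if (is.null(cur)) list(entry) else c(cur, list(entry))
      }
    }
  }
  RR <- list()
  for (g in ls(cont)) {
    sub <- cont[[g]]
    slot <- list(qd = qd_of[[g]], blocks = list())
    for (qket in ls(sub)) {
      cs_ket <- colspace[[qket]]
      cs_bra <- colspace[[as.character(as.integer(qket) + qd_of[[g]])]]
      entries <- sub[[qket]]
      blk <- matrix(0, entries[[1]]$nr, entries[[1]]$nc)
      for (e in entries) {
        rows <- cs_bra$off[e$bi] + seq_len(cs_bra$d[e$bi])
        cols <- cs_ket$off[e$ci] + seq_len(cs_ket$d[e$ci])
        blk[rows, cols] <- blk[rows, cols] + e$M * e$w
      }
      slot$blocks[[qket]] <- blk
    }
    RR[[g]] <- slot
  }
  RR
}

#' Two-site effective Hamiltonian
#'
#' Builds the effective operator `H_eff` acting on the two-site wave
#' function at bond `(site, site+1)` from precomputed left/right
#' environments.  The result carries the fused-space layout, a matvec
#' closure (flops logged under phase `"heff"`), and the operator diagonal
#' for preconditioning.
#'
#' @param mpo an `mpo`.
#' @param envL left environment at bond `site - 1`.
#' @param envR right environment at bond `site + 1`.
#' @param site left site index of the two-site window.
#' @param bondL,bondR bond axes of the current state around the window.
#' @param ledger optional [flop_ledger()].
#' @return list with `apply` (function on flattened vectors), `diag`,
#'   `layout`, and the assembled operator pieces.
#' @export
heff_operator <- function(mpo, envL, envR, site, bondL, bondR, ledger = NULL) {
  mpo <- mpo_prepare(mpo)
  sec_i <- mpo$layout$sectors[[site]]
  sec_j <- mpo$layout$sectors[[site + 1L]]
  rowspace <- fuse_row_space(bondL, sec_i)
  colspace <- fuse_col_space(sec_j, bondR)
  LL <- assemble_LL(envL, mpo, site, rowspace)
  RR <- assemble_RR(envR, mpo, site + 1L, colspace)
  universe <- intersect(names(rowspace), names(colspace))
  universe <- universe[order(as.integer(universe))]
  layout <- lapply(universe, function(q)
    list(q = q, nrow = rowspace[[q]]$dim, ncol = colspace[[q]]$dim))
  names(layout) <- universe
  sizes <- vapply(layout, function(l) l$nrow * l$ncol, 0)
  offsets <- cumsum(sizes) - sizes
  total <- sum(sizes)
  gammas <- intersect(names(LL), names(RR))

  unflatten <- function(x) {
    ps <- vector("list", length(universe))
    names(ps) <- universe
    for (i in seq_along(universe)) {
      l <- layout[[i]]
      ps[[i]] <- matrix(x[offsets[i] + seq_len(sizes[i])], l$nrow, l$ncol)
    }
    ps
  }
  flatten <- function(ps) {
    x <- numeric(total)
    for (i in seq_along(universe))
      x[offsets[i] + seq_len(sizes[i])] <- as.numeric(ps[[universe[i]]])
    x
  }
  # precompute the per-(gamma, sector) application plan once
  plan <- list()
  for (g in gammas) {
    Lg <- LL[[g]]; Rg <- RR[[g]]
    for (q in names(Lg$blocks)) {
      Rb <- Rg$blocks[[q]]
      if (is.null(Rb)) next
      qb <- as.character(as.integer(q) + Lg$qd)
      if (is.na(match(qb, universe)) || is.na(match(q, universe))) next
      plan[[length(plan) + 1L]] <- list(L = Lg$blocks[[q]], Rt = t(Rb),
                                        qi = match(q, universe),
                                        qo = match(qb, universe))
    }
  }
  plan_flops <- sum(vapply(plan, function(p)
    2 * (nrow(p$L) * ncol(p$L) * ncol(p$Rt) + nrow(p$L) * ncol(p$Rt) * nrow(p$Rt)), 0))
  apply_fn <- function(x) {
    psi <- unflatten(x)
    out <- lapply(layout, function(l) matrix(0, l$nrow, l$ncol))
    for (p in plan) {
      out[[p$qo]] <- out[[p$qo]] + p$L %*% psi[[p$qi]] %*% p$Rt
    }
    ledger_add(ledger, "heff", plan_flops)
    flatten(out)
  }
  diag_vec <- {
    d <- numeric(total)
    for (g in gammas) {
      Lg <- LL[[g]]
      if (Lg$qd != 0L) next
      for (q in names(Lg$blocks)) {
        Rb <- RR[[g]]$blocks[[q]]
        if (is.null(Rb)) next
        i <- match(q, universe)
        if (is.na(i)) next
        d[offsets[i] + seq_len(sizes[i])] <-
          d[offsets[i] + seq_len(sizes[i])] +
          as.numeric(outer(diag(Lg$blocks[[q]]), diag(Rb)))
      }
    }
    d
  }
  list(apply = apply_fn, diag = diag_vec, layout = layout, sizes = sizes,
       offsets = offsets, total = total, rowspace = rowspace,
       colspace = colspace, unflatten = unflatten, flatten = flatten,
       LL = LL, RR = RR)
}

#' Apply a two-site effective Hamiltonian
#'
#' @param heff operator from [heff_operator()].
#' @param x flattened two-site wave-function vector in the operator layout.
#' @return `H_eff x` as a flattened vector.
#' @export
apply_heff <- function(heff, x) heff$apply(x)

# two-site guess vector from the current state
two_site_guess <- function(state, site, heff) {
  A1 <- state$tensors[[site]]; A2 <- state$tensors[[site + 1L]]
  psi <- lapply(heff$layout, function(l) matrix(0, l$nrow, l$ncol))
  for (b1 in seq_len(nrow(A1$keys))) {
    q <- as.character(A1$keys[b1, 3])
    rs <- heff$rowspace[[q]]
    if (is.null(rs) || is.null(psi[[q]])) next
    d1 <- dim(A1$blocks[[b1]])
    M1 <- matrix(A1$blocks[[b1]], d1[1], d1[3])
    l1 <- rs$lk[[as.character(A1$keys[b1, 1])]]
    ri <- if (is.null(l1)) NULL else l1[[as.character(A1$keys[b1, 2])]]
    if (is.null(ri)) next
    rows <- rs$off[ri] + seq_len(rs$d[ri])
    for (b2 in seq_len(nrow(A2$keys))) {
      if (A2$keys[b2, 1] != A1$keys[b1, 3]) next
      cs <- heff$colspace[[q]]
      d2 <- dim(A2$blocks[[b2]])
      M2 <- matrix(A2$blocks[[b2]], d2[1], d2[3])
      l2 <- cs$lk[[as.character(A2$keys[b2, 3])]]
      ci <- if (is.null(l2)) NULL else l2[[as.character(A2$keys[b2, 2])]]
      if (is.null(ci)) next
      cols <- cs$off[ci] + seq_len(cs$d[ci])
      psi[[q]][rows, cols] <- psi[[q]][rows, cols] + M1 %*% M2
    }
  }
  heff$flatten(psi)
}

# split an optimized two-site vector back into site tensors, truncating the
# new bond; direction "right" leaves a left isometry at `site`, direction
# "left" a right isometry at `site+1`
two_site_split <- function(x, heff, state, site, d_max, weight_threshold,
                           direction, mode) {
  psi <- heff$unflatten(x)
  svds <- list()
  vals <- numeric(0); vn <- integer(0); vs <- integer(0)
  for (q in names(psi)) {
    M <- psi[[q]]
    if (!length(M) || sum(M^2) == 0) next
    sv <- svd(M)
    svds[[q]] <- sv
    qq <- qn_decode(as.integer(q))
    vals <- c(vals, sv$d)
    vn <- c(vn, rep(qq[1, "n"], length(sv$d)))
    vs <- c(vs, rep(qq[1, "s"], length(sv$d)))
  }
  keep <- select_kept_states(vals, vn, vs, d_max = d_max,
                             weight_threshold = weight_threshold, mode = mode)
  total_w <- sum(vals^2)
  disc <- if (total_w > 0) (total_w - sum(vals[keep]^2)) / total_w else 0
  kept_norm <- sqrt(sum(vals[keep]^2))

  bond_codes <- integer(0); bond_dims <- integer(0)
  kept_by_q <- list()
  off <- 0L
  for (q in names(svds)) {
    nloc <- length(svds[[q]]$d)
    loc <- keep[keep > off & keep <= off + nloc] - off
    off <- off + nloc
    if (!length(loc)) next
    kept_by_q[[q]] <- loc
    bond_codes <- c(bond_codes, as.integer(q))
    bond_dims <- c(bond_dims, length(loc))
  }
  o <- order(bond_codes)
  qd <- qn_decode(bond_codes[o])
  ax_out <- bt_axis(-1L, qd[, "n"], qd[, "s"], bond_dims[o])
  ax_in <- bt_axis(1L, qd[, "n"], qd[, "s"], bond_dims[o])

  spec <- data.frame(value = numeric(0), n = integer(0), s = integer(0))
  keys1 <- list(); blocks1 <- list()
  keys2 <- list(); blocks2 <- list()
  for (q in names(kept_by_q)) {
    sv <- svds[[q]]
    loc <- kept_by_q[[q]]
    qq <- qn_decode(as.integer(q))
    spec <- rbind(spec, data.frame(value = sv$d[loc],
                                   n = rep(qq[1, "n"], length(loc)),
                                   s = rep(qq[1, "s"], length(loc))))
    U <- sv$u[, loc, drop = FALSE]
    Vt <- t(sv$v[, loc, drop = FALSE])
    dvals <- sv$d[loc] / kept_norm
    if (direction == "right") {
      Vt <- Vt * dvals  # carrier S V^T (normalized)
    } else {
      U <- U * rep(dvals, each = nrow(U))  # carrier U S
    }
    rs <- heff$rowspace[[q]]
    for (ri in seq_along(rs$d)) {
      rows <- rs$off[ri] + seq_len(rs$d[ri])
      blk <- U[rows, , drop = FALSE]
      if (sum(blk^2) == 0) next
      keys1[[length(keys1) + 1L]] <- c(rs$bcode[ri], rs$pcode[ri], as.integer(q))
      blocks1[[length(blocks1) + 1L]] <- array(blk, dim = c(rs$d[ri], 1L, ncol(blk)))
    }
    cs <- heff$colspace[[q]]
    for (ci in seq_along(cs$d)) {
      cols <- cs$off[ci] + seq_len(cs$d[ci])
      blk <- Vt[, cols, drop = FALSE]
      if (sum(blk^2) == 0) next
      keys2[[length(keys2) + 1L]] <- c(as.integer(q), cs$pcode[ci], cs$bcode[ci])
      blocks2[[length(blocks2) + 1L]] <- array(blk, dim = c(nrow(blk), 1L, cs$d[ci]))
    }
  }
  axL <- state$tensors[[site]]$axes[[1]]
  axP1 <- state$tensors[[site]]$axes[[2]]
  axP2 <- state$tensors[[site + 1L]]$axes[[2]]
  axR <- state$tensors[[site + 1L]]$axes[[3]]
  T1 <- block_tensor(list(axL, axP1, ax_out), keys1, blocks1, mode = state$mode)
  T2 <- block_tensor(list(ax_in, axP2, axR), keys2, blocks2, mode = state$mode)
  list(T1 = T1, T2 = T2, spectrum = spec, discarded_weight = disc,
       d_u1 = sum(bond_dims), d_mult = su2_multiplet_count(spec$n, spec$s))
}

#' Sweep schedule
#'
#' Staged optimization protocol: each stage fixes the bond-dimension cap
#' (U(1) states or SU(2) multiplets depending on the run mode), the Davidson
#' residual tolerance, an optional wave-function noise amplitude, and the
#' number of sweeps to spend in the stage.  After the last stage, sweeping
#' continues at the final settings until the sweep-energy change falls below
#' `energy_tol` or `max_sweeps` is reached.
#'
#' @param d_max vector of per-stage bond-dimension caps (non-decreasing).
#' @param n_sweeps sweeps per stage (recycled).
#' @param davidson_tol per-stage Davidson residual tolerances (recycled).
#' @param noise per-stage wave-function perturbation amplitudes (recycled;
#'   0 disables).
#' @param max_sweeps overall sweep budget.
#' @param energy_tol convergence threshold on the sweep energy change
#'   (Hartree).
#' @return object of class `sweep_schedule`.
#' @export
sweep_schedule <- function(d_max, n_sweeps = 2L, davidson_tol = 1e-10,
                           noise = 0, max_sweeps = 30L, energy_tol = 1e-8) {
  k <- length(d_max)
  if (is.unsorted(d_max)) stop("sweep_schedule: d_max must be non-decreasing")
  stopifnot(all(davidson_tol > 0), energy_tol > 0)
  stages <- data.frame(d_max = as.numeric(d_max),
                       n_sweeps = rep_len(as.integer(n_sweeps), k),
                       davidson_tol = rep_len(davidson_tol, k),
                       noise = rep_len(noise, k))
  structure(list(stages = stages, max_sweeps = as.integer(max_sweeps),
                 energy_tol = energy_tol), class = "sweep_schedule")
}

stage_for_sweep <- function(schedule, sweep_idx) {
  cum <- cumsum(schedule$stages$n_sweeps)
  i <- which(sweep_idx <= cum)
  if (length(i)) i[1] else nrow(schedule$stages)
}

#' One DMRG sweep
#'
#' Visits every interior bond once in the given direction; at each bond the
#' two-site effective eigenproblem is solved with [davidson()], the bond is
#' truncated to the stage cap, and the canonical center moves on.  Returns
#' the updated state, refreshed environments, and the sweep record.
#'
#' @param state canonical `mps` (center at the first bond of the sweep).
#' @param mpo operator to minimize.
#' @param envs environment list from previous sweeps.
#' @param stage one-row data frame with `d_max`, `davidson_tol`, `noise`.
#' @param direction `"right"` (left-to-right) or `"left"`.
#' @param ledger optional [flop_ledger()].
#' @param davidson_max_iter cap on matvecs per bond solve.
#' @return list with `state`, `envs`, `record`.
#' @export
dmrg_sweep <- function(state, mpo, envs, stage, direction = "right",
                       ledger = NULL, davidson_max_iter = 100L) {
  n <- state$n_sites
  mpo <- mpo_prepare(mpo)
  bonds <- if (direction == "right") seq_len(n - 1L) else seq.int(n - 1L, 1L)
  min_e <- Inf; last_e <- NA_real_
  max_dw <- 0; iters <- 0L
  d_u1 <- 0L; d_mult <- 0L
  for (i in bonds) {
    heff <- heff_operator(mpo, envs$L[[i]], envs$R[[i + 2L]], i,
                          state$tensors[[i]]$axes[[1]],
                          state$tensors[[i + 1L]]$axes[[3]], ledger)
    guess <- two_site_guess(state, i, heff)
    if (stage$noise > 0)
      guess <- guess + stage$noise * sqrt(sum(guess^2)) * stats::rnorm(length(guess))
    sol <- davidson(heff$apply, guess, tol = stage$davidson_tol,
                    max_iter = davidson_max_iter,
                    diag_preconditioner = heff$diag)
    iters <- iters + sol$iterations
    min_e <- min(min_e, sol$value); last_e <- sol$value
    sp <- two_site_split(sol$vector, heff, state, i, stage$d_max, 0,
                         direction, state$mode)
    max_dw <- max(max_dw, sp$discarded_weight)
    d_u1 <- max(d_u1, sp$d_u1)
    # D counts multiplets in su2 mode, individual states otherwise
    d_mult <- max(d_mult, if (state$mode == "su2") sp$d_mult else sp$d_u1)
    state$tensors[[i]] <- sp$T1
    state$tensors[[i + 1L]] <- sp$T2
    if (direction == "right") {
      state$center <- i + 1L
      envs$L[[i + 1L]] <- env_left_update(envs$L[[i]], sp$T1, mpo, i, ledger)
    } else {
      state$center <- i
      envs$R[[i + 1L]] <- env_right_update(envs$R[[i + 2L]], sp$T2, mpo,
                                           i + 1L, ledger)
    }
  }
  record <- data.frame(energy = min_e, last_energy = last_e,
                       max_discarded_weight = max_dw,
                       realized_D_u1 = d_u1, realized_D = d_mult,
                       davidson_iterations = iters)
  list(state = state, envs = envs, record = record)
}

init_environments <- function(state, mpo, ledger = NULL) {
  n <- state$n_sites
  mpo <- mpo_prepare(mpo)
  L <- vector("list", n + 1L)
  R <- vector("list", n + 2L)
  L[[1]] <- env_boundary_left()
  R[[n + 2L]] <- NULL
  R[[n + 1L]] <- env_boundary_right(state$target)
  for (k in seq.int(n, 2L))
    R[[k]] <- env_right_update(R[[k + 1L]], state$tensors[[k]], mpo, k, ledger)
  list(L = L, R = R)
}

#' Run a DMRG ground-state optimization
#'
#' The main solver entry point.  Builds the Hamiltonian MPO for the
#' requested symmetry mode, prepares a seeded random starting state, and
#' performs two-site sweeps under the given schedule until the sweep energy
#' is converged.
#'
#' In `"u1"` mode the target is the (N_elec, 2Sz) sector.  In `"su2"` mode
#' the target spin 2S is enforced exactly at convergence by singlet
#' embedding (a non-interacting spin-S ancilla site closes the total spin to
#' zero) together with a total-S^2 penalty `lambda * S^2_total`; bond caps
#' then count SU(2) multiplets and truncation never splits a multiplet.
#'
#' @param table an [integral_table()].
#' @param target length-2 vector: `(n_elec, 2Sz)` in u1 mode, `(n_elec, 2S)`
#'   in su2 mode.  Defaults to the table's electron count and spin target.
#' @param schedule a [sweep_schedule()].
#' @param seed integer seed for the starting state (and any noise stream).
#' @param mode `"u1"` or `"su2"`.
#' @param penalty spin-penalty strength lambda in Hartree (su2 mode).
#' @param init_d bond dimension of the random starting state.
#' @param ledger optional [flop_ledger()]; created if missing.
#' @param davidson_max_iter cap on matvecs per bond solve.
#' @return list of class `dmrg_result`: `energy` (Hartree, expectation of
#'   the bare Hamiltonian), `objective` (last sweep eigenvalue of the
#'   optimized operator), `mps`, `records` (per-sweep data frame),
#'   `ledger`, `converged`, `s_squared` (su2 mode), `bond_spectra`
#'   (Schmidt spectra), `multiplet_spectra` (su2 mode), plus provenance
#'   fields (`seed`, `schedule`, `mode`, `target`).
#' @export
run_dmrg <- function(table, target = NULL, schedule = NULL, seed = 1,
                     mode = c("u1", "su2"), penalty = 1, init_d = 32L,
                     ledger = NULL, davidson_max_iter = 100L) {
  mode <- match.arg(mode)
  if (is.null(target)) target <- c(table$n_elec, table$two_s_target)
  if (is.null(schedule)) schedule <- sweep_schedule(d_max = c(16, 64, 256))
  if (is.null(ledger)) ledger <- flop_ledger()
  n <- table$n_orb
  if (mode == "su2") {
    two_s <- target[2]
    if (two_s < 0) stop("run_dmrg: su2 target spin must be >= 0")
    anc <- if (two_s > 0) as.integer(two_s) else 0L
    chain_target <- c(as.integer(target[1]), 0L)
    mpo <- build_mpo(table, "su2", penalty = penalty, ancilla_two_s = anc)
    bare <- build_mpo(table, "su2", penalty = 0, ancilla_two_s = anc)
    s2op <- build_s2_mpo(n, ancilla_two_s = anc)
  } else {
    anc <- 0L
    chain_target <- c(as.integer(target[1]), as.integer(target[2]))
    mpo <- build_mpo(table, "u1")
    bare <- mpo
    s2op <- NULL
  }
  mpo <- mpo_prepare(mpo)
  bare <- mpo_prepare(bare)
  if (!is.null(s2op)) s2op <- mpo_prepare(s2op)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  state <- mps_random_impl(chain_layout(n, anc), chain_target,
                           d = min(init_d, max(schedule$stages$d_max)), mode)
  envs <- init_environments(state, mpo, ledger)

  records <- NULL
  prev_e <- Inf
  converged <- FALSE
  direction <- "right"
  sweeps_done <- 0L
  forced <- sum(schedule$stages$n_sweeps)
  while (sweeps_done < schedule$max_sweeps) {
    sweeps_done <- sweeps_done + 1L
    stage <- schedule$stages[stage_for_sweep(schedule, sweeps_done), , drop = FALSE]
    out <- dmrg_sweep(state, mpo, envs, stage, direction, ledger,
                      davidson_max_iter = davidson_max_iter)
    state <- out$state; envs <- out$envs
    rec <- out$record
    rec$sweep <- sweeps_done
    rec$direction <- direction
    rec$d_max <- stage$d_max
    rec$flops_total <- ledger_total(ledger)
    rec$flops_heff <- ledger_phases(ledger)[["heff"]]
    records <- rbind(records, rec)
    de <- abs(rec$energy - prev_e)
    prev_e <- rec$energy
    if (sweeps_done >= forced && de < schedule$energy_tol) {
      converged <- TRUE
      break
    }
    direction <- if (direction == "right") "left" else "right"
  }
  energy <- mps_expectation(state, bare)
  s2 <- if (!is.null(s2op)) mps_expectation(state, s2op) else NA_real_
  spectra <- mps_schmidt_spectra(state)
  mult <- if (mode == "su2") mps_multiplet_spectra(state) else NULL
  structure(list(energy = energy, objective = records$energy[nrow(records)],
                 mps = state, records = records, ledger = ledger,
                 converged = converged, s_squared = s2,
                 bond_spectra = spectra, multiplet_spectra = mult,
                 seed = seed, schedule = schedule, mode = mode,
                 target = target, penalty = if (mode == "su2") penalty else 0),
            class = "dmrg_result")
}

#' @export
print.dmrg_result <- function(x, ...) {
  cat(sprintf("<dmrg_result> E = %.10f Ha (%s mode, target n=%d, %s=%d)%s\n",
              x$energy, x$mode, x$target[1],
              if (x$mode == "su2") "2S" else "2Sz", x$target[2],
              if (x$converged) ", converged" else ", NOT converged"))
  cat(sprintf("  sweeps: %d, final D_U(1) = %d, total flops = %s\n",
              nrow(x$records), x$records$realized_D_u1[nrow(x$records)],
              format(ledger_total(x$ledger), big.mark = ",")))
  invisible(x)
}
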