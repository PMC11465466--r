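# Bond-dimension scans: the measurement protocol behind cost-scaling and
# 1/D extrapolation analyses.

#' Scan ground-state runs over a ladder of bond dimensions
#'
#' Runs the DMRG solver at each cap in `d_list` (non-decreasing), either
#' warm-starting each run from the previous cap's state (the production
#' pattern; halves runtime) or cold-starting from a fresh seeded random
#' state (needed for strict variational-monotonicity checks).  After the
#' convergence sweeps at each cap, one measurement sweep with a fixed
#' Davidson iteration budget is performed so that the recorded
#' effective-Hamiltonian operation count reflects the matvec cost at that
#' bond dimension rather than a varying iteration count.
#'
#' @param table an [integral_table()].
#' @param d_list non-decreasing vector of bond-dimension caps (U(1) states
#'   in u1 mode, SU(2) multiplets in su2 mode).
#' @param target `(n_elec, spin_label)` as in [run_dmrg()].
#' @param mode `"u1"` or `"su2"`.
#' @param seed integer seed.
#' @param sweeps_per_d convergence sweeps at each cap before measuring.
#' @param measure_iters fixed Davidson matvec count of the measurement sweep
#'   (0 skips the measurement sweep).
#' @param warm_start reuse the previous cap's state (default TRUE).
#' @param penalty spin-penalty strength for su2 mode.
#' @param energy_tol early-exit threshold on the sweep energy change during
#'   the convergence sweeps at each cap.
#' @return data frame with one row per cap: `d_cap`, `energy` (best sweep
#'   eigenvalue at that cap), `realized_D_u1`, `realized_D`,
#'   `max_discarded_weight`, `heff_flops` (measurement sweep, or the last
#'   convergence sweep if measurement is disabled), `davidson_iterations`.
#' @export
scan_bond_dimension <- function(table, d_list, target = NULL,
                                mode = c("u1", "su2"), seed = 1,
                                sweeps_per_d = 6L, measure_iters = 3L,
                                warm_start = TRUE, penalty = 1,
                                energy_tol = 1e-9) {
  mode <- match.arg(mode)
  if (is.unsorted(d_list)) stop("scan_bond_dimension: d_list must be non-decreasing")
  if (is.null(target)) target <- c(table$n_elec, table$two_s_target)
  n <- table$n_orb
  if (mode == "su2") {
    anc <- if (target[2] > 0) as.integer(target[2]) else 0L
    chain_target <- c(as.integer(target[1]), 0L)
    mpo <- mpo_prepare(build_mpo(table, "su2", penalty = penalty, ancilla_two_s = anc))
  } else {
    anc <- 0L
    chain_target <- as.integer(target)
    mpo <- mpo_prepare(build_mpo(table, "u1"))
  }
  ledger <- flop_ledger()
  out <- NULL
  state <- NULL; envs <- NULL
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  direction <- "right"
  for (di in seq_along(d_list)) {
    d <- d_list[di]
    if (is.null(state) || !warm_start) {
      set.seed(seed)
      state <- mps_random_impl(chain_layout(n, anc), chain_target,
                               d = min(32, d * 4), mode)
      envs <- init_environments(state, mpo, ledger)
      direction <- "right"
    }
    stage <- data.frame(d_max = d, davidson_tol = 1e-10, noise = 0)
    prev_e <- Inf
    best_e <- Inf
    last_rec <- NULL
    for (sw in seq_len(sweeps_per_d)) {
      res <- dmrg_sweep(state, mpo, envs, stage, direction, ledger)
      state <- res$state; envs <- res$envs
      last_rec <- res$record
      best_e <- min(best_e, res$record$energy)
      de <- abs(res$record$energy - prev_e)
      prev_e <- res$record$energy
      direction <- if (direction == "right") "left" else "right"
      if (sw >= 2 && de < energy_tol) break
    }
    if (measure_iters > 0) {
      before <- ledger_phases(ledger)[["heff"]]
      if (is.null(before) || is.na(before)) before <- 0
      mstage <- data.frame(d_max = d, davidson_tol = 0, noise = 0)
      res <- dmrg_sweep(state, mpo, envs, mstage, direction, ledger,
                        davidson_max_iter = measure_iters)
      state <- res$state; envs <- res$envs
      last_rec <- res$record
      best_e <- min(best_e, res$record$energy)
      direction <- if (direction == "right") "left" else "right"
      heff <- ledger_phases(ledger)[["heff"]] - before
    } else {
      heff <- NA_real_
    }
    out <- rbind(out, data.frame(
      d_cap = d, energy = best_e,
      realized_D_u1 = last_rec$realized_D_u1,
      realized_D = last_rec$realized_D,
      max_discarded_weight = last_rec$max_discarded_weight,
      heff_flops = heff,
      davidson_iterations = last_rec$davidson_iterations))
  }
  attr(out, "mode") <- mode
  attr(out, "final_state") <- state
  out
}
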