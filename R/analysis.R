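# Post-processing: 1/D extrapolation of energies, spin gaps, and log-log
# cost-scaling fits.

#' Polynomial extrapolation of energies to the infinite-bond-dimension limit
#'
#' Fits an unweighted least-squares polynomial of the given order in
#' `x = 1/D` to converged energies and reports the intercept `a0` as the
#' truncation-free `D -> infinity` estimate.  `D` is the SU(2) multiplet
#' count in spin-adapted runs and should be the U(1) state count (labeled
#' as such) otherwise; never mix conventions within one fit.
#'
#' @param d_values strictly increasing bond dimensions.
#' @param energies energies in Hartree, one per `d_values` entry.
#' @param order polynomial order in 1/D (default 2).
#' @return object of class `extrapolation_fit`: list with `coefficients`
#'   (`a0` ... `a<order>`), `extrapolated` (= a0, Hartree), `residuals`,
#'   `d_values`, `energies`, `order`.
#' @examples
#' d <- c(100, 200, 400, 800)
#' e <- -10 + 2 / d + 5 / d^2
#' extrapolate_vs_inverse_d(d, e)$extrapolated  # -10
#' @export
extrapolate_vs_inverse_d <- function(d_values, energies, order = 2) {
  stopifnot(length(d_values) == length(energies))
  if (length(d_values) < order + 1)
    stop("extrapolate_vs_inverse_d: need at least order+1 points")
  if (any(diff(d_values) <= 0))
    stop("extrapolate_vs_inverse_d: d_values must be strictly increasing")
  x <- 1 / d_values
  fit <- stats::lm(energies ~ stats::poly(x, order, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  names(coefs) <- paste0("a", 0:order)
  structure(list(coefficients = coefs, extrapolated = coefs[["a0"]],
                 residuals = unname(stats::residuals(fit)),
                 d_values = d_values, energies = energies, order = order),
            class = "extrapolation_fit")
}

#' @export
print.extrapolation_fit <- function(x, ...) {
  cat(sprintf("<extrapolation_fit> order %d in 1/D, %d points\n", x$order,
              length(x$d_values)))
  cat(sprintf("  D -> inf intercept a0 = %.10f Ha (rms residual %.2e)\n",
              x$extrapolated, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Spin gap between two extrapolated states
#'
#' Difference of the `D -> infinity` intercepts of two extrapolation fits,
#' in milli-Hartree; positive when state `b` lies above state `a`.
#'
#' @param fit_a,fit_b [extrapolate_vs_inverse_d()] fits of the two spin
#'   states.
#' @return numeric gap in mHartree.
#' @export
spin_gap <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "extrapolation_fit"),
            inherits(fit_b, "extrapolation_fit"))
  1000 * (fit_b$extrapolated - fit_a$extrapolated)
}

#' Log-log scaling-exponent fit of cost versus bond dimension
#'
#' First-order polynomial fit of `log(cost)` against `log(D)`, restricted to
#' an explicit window of bond dimensions.  The slope estimates the scaling
#' exponent (3 for the matvec-dominated regime of DMRG).
#'
#' @param d_values bond dimensions.
#' @param costs positive costs (operation counts or times).
#' @param window length-2 numeric `(D_min, D_max)` of points to use
#'   (inclusive; default: all points).
#' @return object of class `scaling_fit`: list with `exponent`,
#'   `prefactor`, `window`, `residual` (rms in log space), `n_points`.
#' @examples
#' fit_scaling_exponent(c(8, 16, 32), 2 * c(8, 16, 32)^3)$exponent  # 3
#' @export
fit_scaling_exponent <- function(d_values, costs, window = NULL) {
  stopifnot(length(d_values) == length(costs))
  if (any(costs <= 0)) stop("fit_scaling_exponent: costs must be positive")
  if (is.null(window)) window <- range(d_values)
  sel <- d_values >= window[1] & d_values <= window[2]
  if (sum(sel) < 2) stop("fit_scaling_exponent: need at least 2 points inside the window")
  lx <- log(d_values[sel]); ly <- log(costs[sel])
  fit <- stats::lm(ly ~ lx)
  co <- stats::coef(fit)
  structure(list(exponent = unname(co[2]), prefactor = exp(unname(co[1])),
                 window = window, residual = sqrt(mean(stats::residuals(fit)^2)),
                 n_points = sum(sel)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> exponent %.3f over D in [%g, %g] (%d points, rms %.2e)\n",
              x$exponent, x$window[1], x$window[2], x$n_points, x$residual))
  invisible(x)
}

#' Tabular summary of a sweep history
#'
#' Per-sweep energies, energy changes, truncation, bond dimensions and
#' cumulative operation counts, with flags marking where the energy change
#' first falls below 1e-5 Hartree (the production convergence criterion for
#' large-scale runs) and below `energy_tol`.
#'
#' @param records per-sweep data frame from [run_dmrg()] (`$records`).
#' @param energy_tol configured convergence threshold (Hartree).
#' @return data frame with columns `sweep`, `energy`, `delta_e`,
#'   `max_discarded_weight`, `realized_D`, `realized_D_u1`,
#'   `davidson_iterations`, `flops_total`, `below_1e5`, `below_tol`.
#' @export
sweep_report <- function(records, energy_tol = 1e-8) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  de <- c(NA_real_, abs(diff(records$energy)))
  data.frame(sweep = records$sweep %||% seq_len(nrow(records)),
             energy = records$energy,
             delta_e = de,
             max_discarded_weight = records$max_discarded_weight,
             realized_D = records$realized_D,
             realized_D_u1 = records$realized_D_u1,
             davidson_iterations = records$davidson_iterations,
             flops_total = records$flops_total %||% NA_real_,
             below_1e5 = !is.na(de) & de < 1e-5,
             below_tol = !is.na(de) & de < energy_tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot an extrapolation fit
#'
#' Energy versus 1/D with the fitted polynomial, mirroring the usual
#' presentation of bond-dimension extrapolations.
#'
#' @param x an [extrapolate_vs_inverse_d()] fit.
#' @param ... passed to [plot()].
#' @export
plot.extrapolation_fit <- function(x, ...) {
  xi <- 1 / x$d_values
  graphics::plot(xi, x$energies, xlab = "1 / D", ylab = "Energy (Hartree)",
                 pch = 19, ...)
  xs <- seq(0, max(xi), length.out = 200)
  ys <- vapply(xs, function(v) sum(x$coefficients * v^(0:x$order)), 0)
  graphics::lines(xs, ys)
  graphics::points(0, x$extrapolated, pch = 4, col = 2)
  invisible(x)
}

#' Plot a cost-scaling data set with its fit
#'
#' @param x a [fit_scaling_exponent()] fit.
#' @param d_values,costs the data the fit was made on.
#' @param ... passed to [plot()].
#' @export
plot.scaling_fit <- function(x, d_values = NULL, costs = NULL, ...) {
  if (is.null(d_values) || is.null(costs))
    stop("plot.scaling_fit: supply d_values and costs")
  graphics::plot(d_values, costs, log = "xy", xlab = "Bond dimension D",
                 ylab = "Operation count", pch = 19, ...)
  xs <- exp(seq(log(x$window[1]), log(x$window[2]), length.out = 50))
  graphics::lines(xs, x$prefactor * xs^x$exponent, col = 2)
  invisible(x)
}
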