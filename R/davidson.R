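#' Davidson iteration for the lowest eigenpair
#'
#' Preconditioned Davidson method for the lowest eigenvalue of a hermitian
#' operator given as a matvec closure.  The search subspace grows to
#' `max_subspace` vectors and is then restarted from the two best Ritz
#' vectors; the diagonal preconditioner shifts by the current Ritz value.
#' Deterministic for a fixed guess.
#'
#' @param apply function(x) returning the operator applied to `x`.
#' @param guess numeric starting vector (need not be normalized).
#' @param tol residual-norm convergence threshold.
#' @param max_iter maximum number of matvec applications.
#' @param diag_preconditioner numeric vector approximating the operator
#'   diagonal (`NULL` disables preconditioning).
#' @param max_subspace subspace size before a restart.
#' @return list with `value` (lowest eigenvalue), `vector` (normalized),
#'   `iterations` (matvec count), `converged` (logical), `residual`.
#' @export
davidson <- function(apply, guess, tol = 1e-10, max_iter = 100,
                     diag_preconditioner = NULL, max_subspace = 20) {
  n <- length(guess)
  nrm <- sqrt(sum(guess^2))
  if (nrm == 0) {
    guess <- numeric(n); guess[1] <- 1; nrm <- 1
  }
  v <- guess / nrm
  V <- matrix(v, n, 1)
  W <- matrix(apply(v), n, 1)
  iters <- 1L
  lambda <- sum(v * W[, 1])
  x <- v
  repeat {
    m <- ncol(V)
    Hs <- crossprod(V, W)
    Hs <- (Hs + t(Hs)) / 2
    es <- eigen(Hs, symmetric = TRUE)
    theta <- es$values[m]
    y <- es$vectors[, m]
    x <- as.numeric(V %*% y)
    hx <- as.numeric(W %*% y)
    r <- hx - theta * x
    rn <- sqrt(sum(r^2))
    lambda <- theta
    if (rn <= tol || iters >= max_iter) {
      return(list(value = lambda, vector = x / sqrt(sum(x^2)),
                  iterations = iters, converged = rn <= tol, residual = rn))
    }
    if (m >= max_subspace) {
      # restart with the two lowest Ritz vectors
      keep <- es$vectors[, c(m, max(1L, m - 1L)), drop = FALSE]
      V <- V %*% keep
      W <- W %*% keep
      # re-orthonormalize (numerical hygiene)
      qr_ <- qr(V)
      V <- qr.Q(qr_)
      W <- W %*% solve(qr.R(qr_))
    }
    t_vec <- if (is.null(diag_preconditioner)) r else {
      denom <- diag_preconditioner - theta
      denom[abs(denom) < 1e-8] <- sign(denom[abs(denom) < 1e-8] + 1e-300) * 1e-8
      r / denom
    }
    # orthogonalize against the subspace (twice for stability)
    t_vec <- t_vec - V %*% crossprod(V, t_vec)
    t_vec <- t_vec - V %*% crossprod(V, t_vec)
    tn <- sqrt(sum(t_vec^2))
    if (tn < 1e-10 * sqrt(sum(r^2)) || tn < 1e-14) {
      # preconditioned residual collapsed onto the subspace (exactly
      # diagonal operators do this); fall back to the raw residual
      t_vec <- r - V %*% crossprod(V, r)
      t_vec <- t_vec - V %*% crossprod(V, t_vec)
      tn <- sqrt(sum(t_vec^2))
      if (tn < 1e-13) {
        return(list(value = lambda, vector = x / sqrt(sum(x^2)),
                    iterations = iters, converged = rn <= tol, residual = rn))
      }
    }
    t_vec <- as.numeric(t_vec / tn)
    V <- cbind(V, t_vec)
    W <- cbind(W, apply(t_vec))
    iters <- iters + 1L
  }
}
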