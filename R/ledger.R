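#' Floating-point operation ledger
#'
#' A mutable tally of floating-point operations performed by the tensor
#' engine, broken down by named phase (e.g. `"heff"` for effective-Hamiltonian
#' applications, `"env"` for environment updates).  Dense block
#' multiplications are counted with the matrix-multiply convention
#' `2 * m * n * k`; factorizations are not counted (retained state counts are
#' reported separately), so totals are exact integers reproducible across
#' runs and platforms.
#'
#' @return An object of class `flop_ledger`.
#' @examples
#' led <- flop_ledger()
#' ledger_add(led, "heff", 16)
#' ledger_total(led)
#' @export
flop_ledger <- function() {
  env <- new.env(parent = emptyenv())
  env$by_phase <- numeric(0)
  class(env) <- "flop_ledger"
  env
}

#' Add operations to a ledger phase
#'
#' @param ledger a [flop_ledger()] (may be `NULL`, in which case nothing is
#'   recorded).
#' @param phase character phase name.
#' @param flops non-negative operation count.
#' @return the ledger, invisibly.
#' @export
ledger_add <- function(ledger, phase, flops) {
  if (is.null(ledger)) return(invisible(NULL))
  stopifnot(inherits(ledger, "flop_ledger"), flops >= 0)
  cur <- ledger$by_phase
  if (is.na(match(phase, names(cur)))) {
    cur[phase] <- flops
  } else {
    cur[phase] <- cur[[phase]] + flops
  }
  ledger$by_phase <- cur
  invisible(ledger)
}

#' Total operation count of a ledger
#' @param ledger a [flop_ledger()].
#' @return numeric total (an exact integer value).
#' @export
ledger_total <- function(ledger) {
  if (is.null(ledger)) return(0)
  sum(ledger$by_phase)
}

#' Per-phase operation counts
#' @param ledger a [flop_ledger()].
#' @return named numeric vector of counts by phase.
#' @export
ledger_phases <- function(ledger) {
  if (is.null(ledger)) return(numeric(0))
  ledger$by_phase
}

#' Snapshot a ledger as a plain list
#' @param ledger a [flop_ledger()].
#' @return list with elements `total` and `by_phase`.
#' @export
ledger_snapshot <- function(ledger) {
  list(total = ledger_total(ledger), by_phase = as.list(ledger_phases(ledger)))
}

#' @export
print.flop_ledger <- function(x, ...) {
  cat("<flop_ledger> total =", format(ledger_total(x), big.mark = ","), "\n")
  ph <- ledger_phases(x)
  for (nm in names(ph)) cat("  ", nm, ": ", format(ph[[nm]], big.mark = ","), "\n", sep = "")
  invisible(x)
}
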