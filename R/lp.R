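#' Solve a bounded linear program
#'
#' Solves `max (or min) c'x` subject to `A x = b` and `lb <= x <= ub` with the
#' package's dense bounded-variable two-phase simplex. Solutions are always
#' basic (vertices of the feasible polytope), which the random flux sampler
#' relies on. The feasibility tolerance is fixed at 1e-9.
#'
#' @param A constraint matrix (rows = equality constraints).
#' @param b right-hand side vector.
#' @param c objective coefficient vector.
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param sense `"max"` or `"min"`.
#' @param max_iter simplex iteration cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x`, `objective`, `basis` (1-based column indices, structural and
#'   artificial), `duals`, `reduced_costs`, `iterations`.
#' @keywords internal
lp_solve <- function(A, b, c, lb, ub, sense = c("max", "min"),
                     max_iter = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  stopifnot(length(b) == nrow(A), length(c) == ncol(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  out <- .lp_solve_cpp(A, as.numeric(b), as.numeric(c), as.numeric(lb),
                       as.numeric(ub), sense == "max", as.integer(max_iter))
  if (out$status == "iteration_limit") {
    abort("LP solver hit the iteration limit; the problem may be degenerate.",
          class = "switchflux_lp_error")
  }
  out
}
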