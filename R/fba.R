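#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to steady state
#' (`S v = 0`) and flux bounds, returning an optimal vertex of the flux
#' polytope. Alternative optima are not resolved: any optimal vertex is a
#' valid answer, so downstream code should assert objective values and
#' feasibility, not individual fluxes.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimize; defaults to the model objective.
#' @param sense `"max"` or `"min"`.
#' @return a `flux_distribution`: tibble with columns `reaction`, `flux`, and
#'   attributes `objective_value`, `status` (`"optimal"`), `objective`,
#'   `basis`, `reduced_costs`. Infeasible or unbounded problems raise a
#'   condition of class `switchflux_infeasible` / `switchflux_unbounded`.
#' @export
fba <- function(model, objective = model$objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (!objective %in% model$reactions$id) {
    abort(paste0("objective reaction '", objective, "' not in model"),
          class = "switchflux_model_error")
  }
  S <- stoich_matrix(model)
  c_vec <- as.numeric(model$reactions$id == objective)
  sol <- lp_solve(S, rep(0, nrow(S)), c_vec,
                  model$reactions$lb, model$reactions$ub, sense)
  if (sol$status == "infeasible") {
    abort("FBA problem is infeasible", class = "switchflux_infeasible")
  }
  if (sol$status == "unbounded") {
    abort("FBA objective is unbounded", class = "switchflux_unbounded")
  }
  flux_distribution(model, sol, objective, sense)
}

#' FBA returning a status instead of raising conditions
#'
#' @inheritParams fba
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`)
#'   and, when optimal, `fluxes` (a `flux_distribution`) and
#'   `objective_value`.
#' @export
fba_status <- function(model, objective = model$objective,
                       sense = c("max", "min")) {
  sense <- match.arg(sense)
  res <- tryCatch(
    list(status = "optimal", fluxes = fba(model, objective, sense)),
    switchflux_infeasible = function(e) list(status = "infeasible"),
    switchflux_unbounded = function(e) list(status = "unbounded"))
  if (res$status == "optimal") {
    res$objective_value <- attr(res$fluxes, "objective_value")
  }
  res
}

flux_distribution <- function(model, sol, objective, sense) {
  out <- tibble(reaction = model$reactions$id, flux = sol$x)
  structure(out,
            class = c("flux_distribution", class(out)),
            objective = objective,
            sense = sense,
            objective_value = sol$objective,
            basis = sol$basis,
            duals = sol$duals,
            reduced_costs = sol$reduced_costs,
            status = "optimal")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> objective ", attr(x, "objective"), " = ",
      format(attr(x, "objective_value")), " (", attr(x, "sense"), ")\n",
      sep = "")
  NextMethod()
}

#' @rdname fba
#' @param x a `flux_distribution`.
#' @param ... unused.
#' @export
glance.flux_distribution <- function(x, ...) {
  tibble(objective = attr(x, "objective"),
         sense = attr(x, "sense"),
         objective_value = attr(x, "objective_value"),
         status = attr(x, "status"))
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux, optionally under the optimality
#' constraint `v_obj >= fraction * optimum` (for maximization objectives).
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to scan; default all.
#' @param fraction_of_optimum number in `[0, 1]`.
#' @return an `fva_result`: tibble with columns `reaction`, `min`, `max` and
#'   attribute `fraction_of_optimum`.
#' @export
fva <- function(model, reactions = model$reactions$id,
                fraction_of_optimum = 0) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  bad <- setdiff(reactions, model$reactions$id)
  if (length(bad)) {
    abort(paste0("unknown reaction(s): ", paste(bad, collapse = ", ")),
          class = "switchflux_model_error")
  }
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  b <- rep(0, nrow(S))
  if (fraction_of_optimum > 0) {
    obj_idx <- match(model$objective, model$reactions$id)
    c_vec <- as.numeric(seq_len(ncol(S)) == obj_idx)
    base <- lp_solve(S, b, c_vec, lb, ub, "max")
    if (base$status != "optimal") {
      abort(paste0("base FBA problem is ", base$status),
            class = "switchflux_infeasible")
    }
    lb[obj_idx] <- max(lb[obj_idx], fraction_of_optimum * base$objective)
  }
  idx <- match(reactions, model$reactions$id)
  res <- vapply(idx, function(i) {
    c_vec <- as.numeric(seq_len(ncol(S)) == i)
    lo <- lp_solve(S, b, c_vec, lb, ub, "min")
    hi <- lp_solve(S, b, c_vec, lb, ub, "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort(paste0("FVA subproblem for '", model$reactions$id[i], "' is ",
                   if (lo$status != "optimal") lo$status else hi$status),
            class = "switchflux_infeasible")
    }
    c(lo$objective, hi$objective)
  }, numeric(2))
  out <- tibble(reaction = reactions, min = res[1, ], max = res[2, ])
  structure(out, class = c("fva_result", class(out)),
            fraction_of_optimum = fraction_of_optimum)
}
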