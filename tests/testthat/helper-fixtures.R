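# Shared fixtures, built lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fx_cfg <- function() fx("cfg", function() toy_config(seed = 1))
fx_cfg0 <- function() fx("cfg0", function() toy_config(seed = 1, noise_sd = 0))
fx_gem <- function() fx("gem", function() build_toy_gem(fx_cfg(), "M145"))
fx_gem1152 <- function() fx("gem1152", function() build_toy_gem(fx_cfg(), "M1152"))
fx_tables <- function() fx("tables", function() make_thermo_kcats(fx_gem(), fx_cfg()))
fx_ec <- function() fx("ec", function() {
  tk <- fx_tables()
  add_enzyme_constraints(split_reversible(fx_gem()), tk$kcats, tk$proteins,
                         fx_cfg()$pool)
})
fx_ec1152 <- function() fx("ec1152", function() {
  tk <- fx_tables()
  kc <- dplyr::filter(tk$kcats,
                      reaction_id %in% fx_gem1152()$reactions$id)
  add_enzyme_constraints(split_reversible(fx_gem1152()), kc, tk$proteins,
                         fx_cfg()$pool)
})
fx_ts <- function(strain = "M145") {
  fx(paste0("ts_", strain), function() make_timeseries(fx_cfg(), strain))
}
fx_ts0 <- function(strain = "M145") {
  fx(paste0("ts0_", strain), function() make_timeseries(fx_cfg0(), strain))
}
fx_proteome <- function(strain = "M145") {
  fx(paste0("prot_", strain), function() {
    tk <- fx_tables()
    gem <- if (strain == "M145") fx_gem() else fx_gem1152()
    make_proteome(gem, fx_ts(strain), fx_cfg(), tk$kcats, tk$proteins)
  })
}
fx_conditions <- function(strain = "M145") {
  fx(paste0("conds_", strain), function() {
    make_conditions(fx_cfg(), strain, fx_proteome(strain), fx_ts(strain))
  })
}
# pre-switch (index 2) and post-switch (index 6) condition models
fx_condition_model <- function(strain = "M145", index = 2) {
  fx(paste0("cm_", strain, "_", index), function() {
    ec <- if (strain == "M145") fx_ec() else fx_ec1152()
    suppressMessages(apply_condition(ec, fx_conditions(strain)[[index]],
                                     0.05, flexibilize = TRUE))
  })
}
fx_samples <- function(strain = "M145", index = 2, n = 200) {
  fx(paste0("fss_", strain, "_", index), function() {
    sample_vertices(fx_condition_model(strain, index), n,
                    seed = fx_cfg()$seed + 500 + index)
  })
}

# tiny linear chain: uptake of A, conversion to B, secretion of B
chain_model <- function(bound = 10) {
  metabolic_model(
    tibble::tibble(id = c("A", "B"), name = c("A", "B"),
                   compartment = "c", formula = "", charge = NA_integer_),
    tibble::tibble(
      id = c("EX_A", "R1", "EX_B"),
      stoichiometry = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
      lb = 0, ub = bound, gene_rule = c("", "g1", ""),
      subsystem = "", pathway = ""),
    objective = "EX_B")
}

# brute-force LP oracle: enumerate all basic solutions over finite bounds
brute_lp <- function(A, b, c, lb, ub, sense = "max") {
  m <- nrow(A); n <- ncol(A)
  best <- NULL
  combs <- utils::combn(n, m)
  for (k in seq_len(ncol(combs))) {
    Bi <- combs[, k]
    Ni <- setdiff(seq_len(n), Bi)
    Bm <- A[, Bi, drop = FALSE]
    if (abs(det(Bm)) < 1e-10) next
    grid <- expand.grid(rep(list(c(1, 2)), length(Ni)))
    if (!length(Ni)) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      xN <- numeric(length(Ni))
      ok <- TRUE
      for (t in seq_along(Ni)) {
        v <- if (grid[g, t] == 1) lb[Ni[t]] else ub[Ni[t]]
        if (!is.finite(v)) { ok <- FALSE; break }
        xN[t] <- v
      }
      if (!ok) next
      rhs <- b - (if (length(Ni)) A[, Ni, drop = FALSE] %*% xN else 0)
      xB <- solve(Bm, rhs)
      if (any(xB < lb[Bi] - 1e-7) || any(xB > ub[Bi] + 1e-7)) next
      o <- sum(c[Bi] * xB) + (if (length(Ni)) sum(c[Ni] * xN) else 0)
      if (is.null(best) || (sense == "max" && o > best) ||
          (sense == "min" && o < best)) best <- o
    }
  }
  best   # NULL = infeasible
}
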