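test_that("model validation catches undeclared references and bad bounds", {
  mets <- tibble::tibble(id = "A", name = "A", compartment = "c",
                         formula = "", charge = NA_integer_)
  rx <- tibble::tibble(id = "R", stoichiometry = list(c(A = -1, X = 1)),
                       lb = 0, ub = 10, gene_rule = "", subsystem = "",
                       pathway = "")
  err <- tryCatch(metabolic_model(mets, rx, objective = "R"),
                  error = function(e) e)
  expect_s3_class(err, "switchflux_parse_error")
  expect_match(conditionMessage(err), "R")
  expect_match(conditionMessage(err), "X")

  rx2 <- tibble::tibble(id = "R", stoichiometry = list(c(A = -1)),
                        lb = 5, ub = 1, gene_rule = "", subsystem = "",
                        pathway = "")
  expect_error(metabolic_model(mets, rx2, objective = "R"),
               class = "switchflux_model_error")
})

test_that("exchange reactions are identified structurally, not by prefix", {
  m <- chain_model()
  m$reactions$id <- c("uptake_A", "R1", "EX_B")   # no EX_ prefix on uptake
  m$objective <- "EX_B"
  expect_setequal(exchange_reactions(m), c("uptake_A", "EX_B"))
})

test_that("gene rules parse, evaluate and expand to isozyme alternatives", {
  expect_true(switchflux:::eval_gene_rule("g1 and (g2 or g3)",
                                          deleted = "g2"))
  expect_false(switchflux:::eval_gene_rule("g1 and (g2 or g3)",
                                           deleted = c("g2", "g3")))
  expect_true(switchflux:::eval_gene_rule("", deleted = "g1"))
  dnf <- switchflux:::gene_rule_dnf("(g1 or g2) and g3")
  expect_setequal(vapply(dnf, paste, "", collapse = "+"),
                  c("g1+g3", "g2+g3"))
  expect_error(switchflux:::parse_gene_rule("g1 and (g2"),
               class = "switchflux_parse_error")
})

test_that("tabular and SBML round trips are the identity on model content", {
  gem <- fx_gem()
  same_model <- function(a, b) {
    expect_identical(a$reactions$id, b$reactions$id)
    expect_identical(a$reactions$lb, b$reactions$lb)   # bit-exact bounds
    expect_identical(a$reactions$ub, b$reactions$ub)
    expect_identical(a$reactions$gene_rule, b$reactions$gene_rule)
    expect_identical(a$reactions$subsystem, b$reactions$subsystem)
    expect_identical(a$reactions$pathway, b$reactions$pathway)
    expect_identical(a$metabolites$id, b$metabolites$id)
    expect_identical(a$metabolites$formula, b$metabolites$formula)
    expect_identical(a$objective, b$objective)
    for (i in seq_len(nrow(a$reactions))) {
      sa <- a$reactions$stoichiometry[[i]]
      sb <- b$reactions$stoichiometry[[i]]
      expect_equal(sa[sort(names(sa))], sb[sort(names(sb))])
    }
  }
  d <- withr::local_tempdir()
  model_io(d, "write", "tabular", model = gem)
  same_model(model_io(d, "read", "tabular"), gem)
  f <- withr::local_tempfile(fileext = ".xml")
  model_io(f, "write", "sbml", model = gem)
  back <- model_io(f, "read", "sbml")
  same_model(back, gem)
  expect_equal(attr(fba(back), "objective_value"), 0.4, tolerance = 1e-9)
})

test_that("written SBML is readable by an independent implementation", {
  # cobrapy (libsbml-based) must agree on model size and FBA optimum
  f <- withr::local_tempfile(fileext = ".xml")
  model_io(f, "write", "sbml", model = fx_gem())
  out <- system2("python", c("-c", shQuote(paste0(
    "import cobra;",
    "m = cobra.io.read_sbml_model('", f, "');",
    "print(len(m.reactions), len(m.metabolites), len(m.genes),",
    "round(m.optimize().objective_value, 9))"))),
    stdout = TRUE, stderr = FALSE)
  parts <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(as.numeric(parts), c(58, 51, 36, 0.4))
})

test_that("FBA satisfies steady state and bounds; chain examples solve", {
  m <- chain_model()
  expect_equal(attr(fba(m), "objective_value"), 10)
  m0 <- set_bounds(m, "EX_A", ub = 0)
  expect_equal(attr(fba(m0), "objective_value"), 0)
  gem <- fx_gem()
  sol <- fba(gem)
  expect_equal(attr(sol, "objective_value"), 0.4, tolerance = 1e-9)
  S <- stoich_matrix(gem)
  expect_lt(max(abs(S %*% sol$flux)), 1e-6)
  expect_true(all(sol$flux >= gem$reactions$lb - 1e-9))
  expect_true(all(sol$flux <= gem$reactions$ub + 1e-9))
  expect_error(fba(set_bounds(gem, "EX_pi", lb = 0, ub = 0) |>
                     set_bounds("BIOMASS", lb = 0.1)),
               class = "switchflux_infeasible")
})

test_that("FVA matches examples and the per-reaction two-LP brute force", {
  m <- chain_model()
  r <- fva(m, "R1", fraction_of_optimum = 0)
  expect_equal(c(r$min, r$max), c(0, 10))
  r1 <- fva(m, fraction_of_optimum = 1)
  expect_true(all(abs(r1$min - 10) < 1e-9) && all(abs(r1$max - 10) < 1e-9))

  # independent oracle: explicit two LPs per reaction with the optimality row
  gem <- fx_gem()
  S <- stoich_matrix(gem)
  lb <- gem$reactions$lb; ub <- gem$reactions$ub
  obj <- match(gem$objective, gem$reactions$id)
  copt <- as.numeric(seq_along(lb) == obj)
  base <- switchflux:::lp_solve(S, rep(0, nrow(S)), copt, lb, ub, "max")
  lb2 <- lb; lb2[obj] <- 0.9 * base$objective
  got <- fva(gem, fraction_of_optimum = 0.9)
  for (i in sample(seq_along(lb), 12)) {
    ci <- as.numeric(seq_along(lb) == i)
    lo <- switchflux:::lp_solve(S, rep(0, nrow(S)), ci, lb2, ub, "min")$objective
    hi <- switchflux:::lp_solve(S, rep(0, nrow(S)), ci, lb2, ub, "max")$objective
    expect_equal(got$min[i], lo, tolerance = 1e-6)
    expect_equal(got$max[i], hi, tolerance = 1e-6)
  }
  # fraction-0 ranges contain any FBA solution
  r0 <- fva(gem, fraction_of_optimum = 0)
  sol <- fba(gem)
  expect_true(all(sol$flux >= r0$min - 1e-7 & sol$flux <= r0$max + 1e-7))
})

test_that("biomass prosthetic-group update follows the proportional rule", {
  gem <- fx_gem()
  expect_identical(update_biomass_prosthetics(gem, tibble::tibble(
    protein_id = character(), abundance = numeric()),
    tibble::tibble(protein_id = character(), metabolite = character(),
                   stoichiometry = numeric())),
    gem)
  # one protein (abundance 2) carrying one heme-like group: coefficient =
  # mass_fraction * w / sum(w * mw) with w = 2, mw = 2 -> 0.01 * 2 / 4
  gem2 <- gem
  gem2$metabolites <- dplyr::bind_rows(
    gem2$metabolites,
    tibble::tibble(id = "heme_c", name = "heme", compartment = "c",
                   formula = "", charge = NA_integer_))
  pm <- tibble::tibble(protein_id = "P1", metabolite = "heme_c",
                       stoichiometry = 1)
  prot <- tibble::tibble(protein_id = "P1", abundance = 2)
  up <- update_biomass_prosthetics(gem2, prot, pm, mass_fraction = 0.01,
                                   group_mw = c(heme_c = 2))
  s <- up$reactions$stoichiometry[[match("BIOMASS", up$reactions$id)]]
  expect_equal(unname(s[["heme_c"]]), -0.01 * 2 / (2 * 2))
  # doubling abundances leaves coefficients unchanged
  up2 <- update_biomass_prosthetics(gem2, dplyr::mutate(prot,
                                                        abundance = 4),
                                    pm, 0.01, c(heme_c = 2))
  expect_equal(up2$reactions$stoichiometry[[match("BIOMASS", up2$reactions$id)]], s)
})
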