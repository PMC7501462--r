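test_that("splitting reversible reactions preserves flux space and optima", {
  m <- chain_model()
  m <- set_bounds(m, "R1", lb = -5, ub = 10)
  sp <- split_reversible(m)
  i <- match(c("R1", "R1_bwd"), sp$reactions$id)
  expect_equal(sp$reactions$lb[i], c(0, 0))
  expect_equal(sp$reactions$ub[i], c(10, 5))
  # irreversible reactions pass through unchanged
  expect_true("EX_B" %in% sp$reactions$id)
  expect_equal(attr(fba(sp), "objective_value"),
               attr(fba(m), "objective_value"))
  # toy model: optimum preserved
  expect_equal(attr(fba(split_reversible(fx_gem())), "objective_value"), 0.4,
               tolerance = 1e-9)
})

test_that("enzyme coupling enforces v <= kcat * e", {
  m <- chain_model(bound = 1000)
  sp <- split_reversible(m)
  kcats <- tibble::tibble(protein_id = "P1", reaction_id = "R1",
                          direction = "forward", kcat = 3600)
  prots <- tibble::tibble(protein_id = "P1", gene_id = "g1", mw = 40)
  ec <- add_enzyme_constraints(sp, kcats, prots, pool_params())
  ec <- apply_proteome(ec, tibble::tibble(protein_id = "P1",
                                          abundance = 0.001))
  expect_equal(attr(fba(ec), "objective_value"), 3.6, tolerance = 1e-9)
  # halving the abundance halves the achievable flux
  ec2 <- apply_proteome(add_enzyme_constraints(sp, kcats, prots,
                                               pool_params()),
                        tibble::tibble(protein_id = "P1", abundance = 5e-4))
  expect_equal(attr(fba(ec2), "objective_value"), 1.8, tolerance = 1e-9)
})

test_that("inactive enzyme constraints leave the optimum untouched", {
  ec <- fx_ec()
  ec_inf <- set_bounds(ec, "prot_pool_exchange", ub = 1e9)
  expect_equal(attr(fba(ec_inf), "objective_value"), 0.4, tolerance = 1e-6)
})

test_that("isozymes become parallel copies behind an arm reaction", {
  gem <- fx_gem()
  ec <- fx_ec()
  copies <- grep("^PGI_No", ec$reactions$id, value = TRUE)
  expect_equal(length(copies), 2)           # gPGI1 or gPGI2
  expect_true("PGI_arm" %in% ec$reactions$id)
  # arm flux equals total isozyme flux in any solution
  sol <- fba(ec)
  v <- setNames(sol$flux, sol$reaction)
  expect_equal(v[["PGI_arm"]], sum(v[copies]), tolerance = 1e-9)
  # AND complex: both subunits consumed by the same copy
  s <- ec$reactions$stoichiometry[[match("FAS", ec$reactions$id)]]
  expect_setequal(grep("^prot_", names(s), value = TRUE),
                  c("prot_P_FASa", "prot_P_FASb"))
})

test_that("kcat fallback to the model median is flagged", {
  m <- chain_model(bound = 1000)
  m$reactions$gene_rule <- c("", "g1", "g2")    # EX_B catalyzed, no kcat
  sp <- split_reversible(m)
  kcats <- tibble::tibble(protein_id = "P1", reaction_id = "R1",
                          direction = "forward", kcat = 100)
  prots <- tibble::tibble(protein_id = c("P1", "P2"),
                          gene_id = c("g1", "g2"), mw = 40)
  ec <- add_enzyme_constraints(sp, kcats, prots, pool_params())
  kt <- ec$kcat_table
  expect_identical(kt$match_level[kt$copy == "EX_B"], "median_fallback")
  expect_equal(kt$kcat[kt$copy == "EX_B"], 100)   # median of one entry
  expect_error(add_enzyme_constraints(
    sp, tibble::tibble(protein_id = "P1", reaction_id = "ZZZ",
                       direction = "forward", kcat = 1),
    prots, pool_params()),
    class = "switchflux_validation_error")
})

test_that("proteome integration bounds usage and reduces the pool", {
  ec <- fx_ec()
  prot <- fx_proteome("M145")
  sample <- prot[prot$time_h == sort(unique(prot$time_h))[2],
                 c("protein_id", "abundance")]
  ecp <- apply_proteome(ec, sample)
  meas <- ecp$enzymes[ecp$enzymes$measured, ]
  i <- match(meas$usage, ecp$reactions$id)
  expect_equal(ecp$reactions$ub[i],
               meas$abundance)
  expect_lt(ecp$pool$cap, ec$pool$cap)
  # huge abundances recover the pool-free optimum
  huge <- tibble::tibble(protein_id = ec$enzymes$protein_id, abundance = 1)
  expect_equal(attr(fba(apply_proteome(ec, huge)), "objective_value"), 0.4,
               tolerance = 1e-6)
  # empty sample: pure pool model
  empty <- tibble::tibble(protein_id = character(), abundance = numeric())
  expect_equal(apply_proteome(ec, empty)$pool$cap, ec$pool$cap)
})

test_that("condition models are self-consistent and diagnosable", {
  ec <- fx_ec()
  sol <- fba(ec)
  net <- ec_net_fluxes(ec, sol)
  rates <- net[net$reaction %in% c("EX_glc", "EX_glu"), ]
  names(rates) <- c("reaction", "rate")
  cs <- condition_spec("M145", 30, rates,
                       growth_rate = attr(sol, "objective_value"))
  cm <- apply_condition(ec, cs, tolerance_fraction = 0)
  expect_equal(attr(fba(cm), "objective_value"),
               attr(sol, "objective_value"), tolerance = 1e-6)
  # zero glucose uptake with growth demanded: infeasible, glucose named
  bad <- condition_spec("M145", 30,
                        tibble::tibble(reaction = "EX_glc", rate = 0),
                        growth_rate = 0.2)
  err <- tryCatch(apply_condition(ec, bad, 0.05), error = function(e) e)
  expect_s3_class(err, "switchflux_infeasible_condition")
  expect_match(conditionMessage(err), "EX_glc")
})

test_that("the producer strain runs more glycolytic flux than the mutant", {
  cmA <- fx_condition_model("M145", 2)
  cmB <- fx_condition_model("M1152", 2)
  vA <- ec_net_fluxes(cmA, fba(cmA))
  vB <- ec_net_fluxes(cmB, fba(cmB))
  hex <- function(v) v$flux[v$reaction == "HEX1"]
  expect_gt(hex(vA), hex(vB))
})

test_that("enzyme constraints shrink flux variability reaction-wise", {
  gem <- fx_gem()
  ec <- fx_ec()
  cmp <- ecfva_compare(gem, ec)
  expect_true(all(cmp$ec_width <= cmp$gem_width + 1e-6))
  expect_lte(median(cmp$ec_width), median(cmp$gem_width))
  # strictly smaller for a kcat-limited reaction
  m <- chain_model(bound = 1000)
  sp <- split_reversible(m)
  ecx <- add_enzyme_constraints(
    sp, tibble::tibble(protein_id = "P1", reaction_id = "R1",
                       direction = "forward", kcat = 100),
    tibble::tibble(protein_id = "P1", gene_id = "g1", mw = 40),
    pool_params())
  cmp2 <- ecfva_compare(m, ecx, "R1")
  expect_lt(cmp2$ec_width, cmp2$gem_width)
  # with effectively infinite pool the widths match the plain model
  ecy <- set_bounds(ecx, "prot_pool_exchange", ub = 1e9)
  cmp3 <- ecfva_compare(m, ecy, "R1")
  expect_equal(cmp3$ec_width, cmp3$gem_width, tolerance = 1e-6)
})

test_that("ec-model net fluxes project into the parent flux space", {
  gem <- fx_gem()
  ec <- fx_ec()
  fss <- sample_vertices(ec, 100, seed = 11)
  S <- stoich_matrix(gem)
  for (k in seq_len(nrow(fss$samples))) {
    vn <- ec_net_fluxes(ec, setNames(fss$samples[k, ],
                                     colnames(fss$samples)))
    v <- setNames(vn$flux, vn$reaction)[colnames(S)]
    expect_lt(max(abs(S %*% v)), 1e-6)
    expect_true(all(v >= gem$reactions$lb - 1e-9))
    expect_true(all(v <= gem$reactions$ub + 1e-9))
  }
})
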