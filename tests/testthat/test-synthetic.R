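test_that("generators are pure functions of (config, seed)", {
  cfg <- toy_config(seed = 17)
  expect_identical(build_toy_gem(cfg, "M145"), build_toy_gem(cfg, "M145"))
  g <- build_toy_gem(cfg, "M145")
  expect_identical(make_thermo_kcats(g, cfg), make_thermo_kcats(g, cfg))
  expect_identical(make_timeseries(cfg, "M1152"), make_timeseries(cfg, "M1152"))
  tk <- make_thermo_kcats(g, cfg)
  ts <- make_timeseries(cfg, "M145")
  expect_identical(make_proteome(g, ts, cfg, tk$kcats, tk$proteins),
                   make_proteome(g, ts, cfg, tk$kcats, tk$proteins))
  expect_identical(make_phenotype_tests(g, cfg), make_phenotype_tests(g, cfg))
})

test_that("toy model variants have the declared structure", {
  gem <- fx_gem()
  expect_equal(nrow(gem$reactions), 58)   # generator's declared count
  g1152 <- fx_gem1152()
  expect_equal(nrow(g1152$reactions), 58 - 12)
  # cluster pathways structurally deleted, germicidin analog retained
  expect_false(any(c("ACTS", "EX_act") %in% g1152$reactions$id))
  expect_true(all(c("GERMAS", "EX_germA") %in% g1152$reactions$id))
  # deletions only remove reactions: M1152 flux space nests inside M145's
  expect_true(all(g1152$reactions$id %in% gem$reactions$id))
  # planted maximal growth: phosphate-limited, uptake 0.2 / coefficient 0.5
  expect_equal(attr(fba(gem), "objective_value"), 0.4, tolerance = 1e-9)
  expect_equal(attr(fba(g1152), "objective_value"), 0.4, tolerance = 1e-9)
  # growth requires phosphate
  expect_error(fba(set_bounds(gem, "EX_pi", lb = 0) |>
                     set_bounds("BIOMASS", lb = 1e-3)),
               class = "switchflux_infeasible")
})

test_that("carbon-annotated reactions are elementally balanced", {
  gem <- fx_gem()
  carbon <- function(f) if (grepl("^C[0-9]+$", f)) as.numeric(sub("C", "", f))
    else if (f == "C") 1 else NA_real_
  cmap <- setNames(vapply(gem$metabolites$formula,
                          function(f) if (nzchar(f)) carbon(f) else NA_real_,
                          1), gem$metabolites$id)
  for (i in seq_len(nrow(gem$reactions))) {
    s <- gem$reactions$stoichiometry[[i]]
    if (length(s) < 2) next                    # exchanges exempt
    if (any(is.na(cmap[names(s)]))) next       # only fully annotated ones
    expect_equal(sum(s * cmap[names(s)]), 0,
                 info = gem$reactions$id[i])
  }
})

test_that("time series respect mass plausibility and planted kinetics", {
  cfg0 <- toy_config(seed = 1, noise_sd = 0)
  for (s in c("M145", "M1146", "M1152")) {
    ts <- make_timeseries(cfg0, s)
    ps <- cfg0$strains[[s]]
    dx <- diff(ts$cdw)
    dglc <- -diff(ts$glucose)
    dglu <- -diff(ts$glutamate)
    # biomass increase never exceeds yield-weighted substrate consumption
    expect_true(all(dx <= dglc / ps$n_glc + dglu / ps$n_glu + 1e-9))
    # substrates stay in excess; phosphate does not
    expect_true(all(ts$glucose > 0) && all(ts$glutamate > 0))
    expect_equal(min(ts$phosphate), 0)
    expect_equal(detect_depletion(ts, "phosphate", 0), ps$t_depletion)
  }
  # cluster products only post-depletion and only in the producer
  tsP <- make_timeseries(cfg0, "M145")
  expect_true(all(tsP$act[tsP$time_h <= 35] == 0))
  expect_gt(max(tsP$act), 0)
  expect_true(all(make_timeseries(cfg0, "M1152")$act == 0))
})

test_that("proteome allocation shifts at the switch and fits the budget", {
  cfg <- fx_cfg()
  prot <- fx_proteome("M145")
  tk <- fx_tables()
  ss <- switchflux:::subsystem_of_protein(fx_gem(), tk$proteins)
  ratio <- function(subsys) {
    ids <- names(ss)[unlist(ss) == subsys]
    pre <- mean(prot$abundance[prot$time_h < 35 & prot$protein_id %in% ids])
    post <- mean(prot$abundance[prot$time_h > 35 & prot$protein_id %in% ids])
    post / pre
  }
  expect_gt(ratio("Oxidative phosphorylation"), 1)
  expect_lt(ratio("Fatty acid biosynthesis"), 1)
  # measured mass within the modeled protein budget at every time point
  mw <- setNames(tk$proteins$mw, tk$proteins$protein_id)
  per_t <- vapply(split(prot, prot$time_h),
                  function(d) sum(d$abundance * mw[d$protein_id]), 1)
  expect_true(all(per_t <= cfg$pool$p_total * cfg$pool$f + 1e-9))
  # withheld fraction 0 measures every catalytic protein
  cfg2 <- toy_config(seed = 2)
  cfg2$proteome$withheld_fraction <- 0
  p2 <- make_proteome(fx_gem(), fx_ts("M145"), cfg2, tk$kcats, tk$proteins)
  expect_setequal(unique(p2$protein_id), tk$proteins$protein_id)
})

test_that("planted directionality is recovered from noisy Gibbs energies", {
  cfg <- fx_cfg()
  gem <- fx_gem()
  classify <- function(dg) ifelse(dg <= -30, "forward",
                                  ifelse(dg >= 30, "backward", "reversible"))
  # noise-free: 100% recovery
  cfg_nf <- toy_config(seed = 3)
  cfg_nf$thermo_sd <- 0
  tk0 <- make_thermo_kcats(gem, cfg_nf)
  expect_equal(mean(classify(tk0$thermo$delta_g) ==
                      tk0$thermo$planted_direction), 1)
  # sd 5 kJ/mol: at least 90% over 20 seeds
  rec <- vapply(1:20, function(s) {
    tk <- make_thermo_kcats(gem, toy_config(seed = s))
    mean(classify(tk$thermo$delta_g) == tk$thermo$planted_direction)
  }, 1)
  expect_true(all(rec >= 0.9))
  # kcats positive and reproducible
  tk <- fx_tables()
  expect_true(all(tk$kcats$kcat > 0))
})

test_that("phenotype tests plant the configured confusion structure", {
  gem <- fx_gem()
  cfg <- fx_cfg()
  tests <- make_phenotype_tests(gem, cfg)
  expect_equal(nrow(tests), 241)
  cm <- evaluate_phenotypes(gem, tests)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(155, 6, 38, 42))
  expect_equal(cm$accuracy, 0.80, tolerance = 0.03)
  expect_equal(cm$sensitivity, 0.96, tolerance = 0.03)
  expect_equal(cm$specificity, 0.48, tolerance = 0.03)
  # flip rates 0 -> perfect agreement
  cfg0 <- toy_config(seed = 4)
  cfg0$phenotype$flip_growth <- 0
  cfg0$phenotype$flip_nogrowth <- 0
  expect_equal(evaluate_phenotypes(gem, make_phenotype_tests(gem, cfg0))$mcc, 1)
})
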