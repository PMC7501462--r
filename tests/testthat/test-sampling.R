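test_that("vertex sampling is deterministic and hits the analytic mean", {
  # single free flux on [0, 10]: each vertex taken with probability 1/2
  m <- chain_model()
  m$reactions <- m$reactions[m$reactions$id != "R1", ]
  m$reactions$stoichiometry[[1]] <- c(A = 1)
  m$reactions$stoichiometry[[2]] <- c(A = -1)
  m$objective <- "EX_B"
  m <- metabolic_model(m$metabolites[m$metabolites$id == "A", ],
                       m$reactions, objective = "EX_B")
  fss <- sample_vertices(m, 10000, seed = 9)
  expect_lt(abs(mean(fss$samples[, "EX_B"]) - 5), 0.2)
  expect_true(all(fss$samples %in% c(0, 10)))
  # determinism
  fss2 <- sample_vertices(m, 50, seed = 123)
  fss3 <- sample_vertices(m, 50, seed = 123)
  expect_identical(fss2$samples, fss3$samples)
  # single-point feasible set: every sample equals that point
  pin <- set_bounds(chain_model(), "EX_B", lb = 4, ub = 4)
  fssp <- sample_vertices(pin, 20, seed = 2)
  expect_true(all(abs(fssp$samples - 4) < 1e-9))
})

test_that("samples satisfy steady state, bounds, and FVA containment", {
  gem <- fx_gem()
  fss <- sample_vertices(gem, 60, seed = 4)
  S <- stoich_matrix(gem)
  expect_lt(max(abs(S %*% t(fss$samples))), 1e-6)
  expect_true(all(t(fss$samples) >= gem$reactions$lb - 1e-9))
  expect_true(all(t(fss$samples) <= gem$reactions$ub + 1e-9))
  rng <- fva(gem, fraction_of_optimum = 0)
  mn <- sample_means(fss)
  expect_true(all(mn$flux >= rng$min - 1e-7 & mn$flux <= rng$max + 1e-7))
})

test_that("pathway activity is CO2-normalized and Z-scored per pathway", {
  fss <- fx_samples("M145", 2)
  # two identical conditions -> all zscores 0, flagged
  pa0 <- pathway_activity(list(`M145@1` = fss, `M145@2` = fss),
                          co2_rate = c(`M145@1` = 2, `M145@2` = 2),
                          top_k = 5)
  expect_true(all(pa0$zscore == 0))
  expect_true(all(pa0$flag == "zero_variance"))
  # row standardization: mean 0, sd 1 over the standardization set
  conds <- list(`M145@29` = fx_samples("M145", 2),
                `M145@40` = fx_samples("M145", 6),
                `M1152@41` = fx_samples("M1152", 2))
  co2 <- c(`M145@29` = 6, `M145@40` = 2, `M1152@41` = 4.5)
  pa <- pathway_activity(conds, co2_rate = co2, top_k = 8,
                         force_include = "Act biosynthesis")
  for (p in unique(pa$pathway)) {
    z <- pa$zscore[pa$pathway == p]
    if (all(pa$flag[pa$pathway == p] == "ok")) {
      expect_equal(mean(z), 0, tolerance = 1e-9)
      expect_equal(sd(z), 1, tolerance = 1e-9)
    }
  }
  expect_true("Act biosynthesis" %in% pa$pathway)
  # normalization divisor recorded
  expect_equal(attr(pa, "co2_rate"), co2)
})

test_that("the metabolic switch moves fatty-acid and respiration scores in
           opposite directions", {
  conds <- list(`M145@29` = fx_samples("M145", 2),
                `M145@40` = fx_samples("M145", 6))
  co2 <- attr(fx_conditions("M145"), "co2_rate")[c(2, 6)]
  names(co2) <- names(conds)
  pa <- pathway_activity(conds, co2_rate = co2, top_k = 12,
                         force_include = c("Fatty acid biosynthesis",
                                           "Oxidative phosphorylation"))
  zc <- function(p, cond) pa$zscore[which(pa$pathway == p & pa$condition == cond)]
  expect_lt(zc("Fatty acid biosynthesis", "M145@40"),
            zc("Fatty acid biosynthesis", "M145@29"))
  expect_gt(zc("Oxidative phosphorylation", "M145@40"),
            zc("Oxidative phosphorylation", "M145@29"))
})

test_that("metabolite budgets partition producers and consumers exactly", {
  m <- chain_model()
  fl <- tibble::tibble(reaction = c("EX_A", "R1", "EX_B"), flux = c(2, 2, 2))
  b <- metabolite_budget(fl, m, "A")
  expect_equal(attr(b, "production_total"), 2)
  expect_equal(attr(b, "consumption_total"), 2)
  expect_setequal(b$reaction[b$role == "producing"], "EX_A")
  # budgets balance for every sampled flux vector, not only means
  gem <- fx_gem()
  fss <- sample_vertices(gem, 15, seed = 21)
  for (k in 1:15) {
    fl <- tibble::tibble(reaction = colnames(fss$samples),
                         flux = fss$samples[k, ])
    bb <- metabolite_budget(fl, gem, "accoa_c")
    expect_equal(attr(bb, "production_total"),
                 attr(bb, "consumption_total"), tolerance = 1e-6)
  }
  # cluster-deletion strain has no cluster drains at all
  g2 <- fx_gem1152()
  fss2 <- fx_samples("M1152", 2)
  b2 <- metabolite_budget(sample_means(fss2), g2, "malcoa_c")
  expect_false(any(c("ACTS", "REDS", "CDAS", "CPKS") %in% b2$reaction))
})
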