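test_that("directionality proposals follow the symmetric threshold rule", {
  gem <- fx_gem()
  # GLUDH is reversible in the model; dG = -40 -> forward-only
  p <- propose_directionality(gem, tibble::tibble(reaction_id = "GLUDH",
                                                  delta_g = -40))
  expect_equal(nrow(p), 1)
  expect_equal(c(p$new_lb, p$new_ub), c(0, 1000))
  # already forward + strongly negative dG -> no proposal
  expect_equal(nrow(propose_directionality(
    gem, tibble::tibble(reaction_id = "PYK", delta_g = -40))), 0)
  # forward reaction with dG = +45 -> backward-only, lb opened to -1000
  p2 <- propose_directionality(gem, tibble::tibble(reaction_id = "PYK",
                                                   delta_g = 45))
  expect_equal(c(p2$new_lb, p2$new_ub), c(-1000, 0))
  # |dG| below threshold -> opened symmetrically
  p3 <- propose_directionality(gem, tibble::tibble(reaction_id = "PYK",
                                                   delta_g = -10))
  expect_equal(c(p3$new_lb, p3$new_ub), c(-1000, 1000))
  expect_error(propose_directionality(
    gem, tibble::tibble(reaction_id = "NOPE", delta_g = 0)),
    class = "switchflux_model_error")
})

test_that("proposals are idempotent: applying then re-proposing is empty", {
  gem <- fx_gem()
  thermo <- fx_tables()$thermo
  props <- propose_directionality(gem, thermo)
  m2 <- switchflux:::apply_proposals(gem, props)
  expect_equal(nrow(propose_directionality(m2, thermo)), 0)
})

test_that("ATP-driven curation respects exceptions and positive dG", {
  gem <- fx_gem()
  # GS: reversible ATP-consuming ligase, no dG record -> forward proposal
  p <- curate_atp_driven(gem)
  expect_true("GS" %in% p$reaction_id)
  expect_equal(p$new_lb[p$reaction_id == "GS"], 0)
  # ADK (adenylate-kinase analog, known reversible) spared via exceptions
  expect_false("ADK" %in% curate_atp_driven(gem, exceptions = "ADK")$reaction_id)
  # positive dG exempts
  p2 <- curate_atp_driven(gem, thermo = tibble::tibble(reaction_id = "GS",
                                                       delta_g = 12))
  expect_false("GS" %in% p2$reaction_id)
})

test_that("phenotype evaluation returns the full confusion summary", {
  gem <- fx_gem()
  ref <- c(EX_glc = 10, EX_glu = 6, EX_pi = 0.2, EX_nh4 = 10, EX_o2 = 1000)
  tests <- tibble::tibble(
    test_id = c("ref", "no_pi", "ko_ess", "ko_noness"),
    kind = c("growth_medium", "growth_medium", "knockout", "knockout"),
    spec = list(ref, ref[names(ref) != "EX_pi"], "gPYK", "gPGI1"),
    observed = c(TRUE, FALSE, FALSE, TRUE))
  cm <- evaluate_phenotypes(gem, tests)
  expect_equal(cm$mcc, 1)                        # all predictions correct
  # all observed and predicted positive -> specificity undefined, not 0
  cm2 <- evaluate_phenotypes(gem, tests[c(1, 4), ])
  expect_true(is.na(cm2$specificity))
  expect_equal(cm2$sensitivity, 1)
})

test_that("confusion metrics reproduce the printed summary arithmetic", {
  cm <- confusion_metrics(tp = 155, fp = 42, tn = 38, fn = 6)
  expect_equal(round(cm$accuracy, 2), 0.80)
  expect_equal(round(cm$sensitivity, 2), 0.96)
  expect_equal(round(cm$mcc, 2), 0.53)
})

test_that("recover_confusion brute force finds known splits", {
  r <- recover_confusion(4, accuracy = 0.75, sensitivity = 1.0,
                         specificity = 0.5)
  expect_equal(nrow(r), 1)
  expect_true(attr(r, "unique"))
  expect_equal(c(r$tp, r$fn, r$tn, r$fp), c(2, 0, 1, 1))
  # contradictory targets -> empty result, no error
  r2 <- recover_confusion(1, accuracy = 0.0, sensitivity = 1.0)
  expect_equal(nrow(r2), 0)
})

test_that("proposal arbitration reverts only MCC-degrading proposals", {
  gem <- fx_gem()
  ref <- c(EX_glc = 10, EX_glu = 6, EX_pi = 0.2, EX_nh4 = 10, EX_o2 = 1000)
  tests <- tibble::tibble(
    test_id = c("ref", "no_pi", "ko1", "ko2"),
    kind = c("growth_medium", "growth_medium", "knockout", "knockout"),
    spec = list(ref, ref[names(ref) != "EX_pi"], "gPYK", "gPGI1"),
    observed = c(TRUE, FALSE, FALSE, TRUE))
  # a harmless proposal (GLUDH forward-only) is accepted
  harmless <- tibble::tibble(reaction_id = "GLUDH", basis = "thermo",
                             old_lb = -1000, old_ub = 1000,
                             new_lb = 0, new_ub = 1000)
  out <- accept_proposals(gem, harmless, tests)
  expect_equal(nrow(out$accepted), 1)
  expect_equal(nrow(out$discarded), 0)
  # a growth-blocking proposal (shut PYK) turns a true positive into a
  # false negative and is discarded
  blocking <- tibble::tibble(reaction_id = "PYK", basis = "thermo",
                             old_lb = 0, old_ub = 1000,
                             new_lb = 0, new_ub = 0)
  out2 <- accept_proposals(gem, dplyr::bind_rows(harmless, blocking), tests)
  expect_true("PYK" %in% out2$discarded$reaction_id)
  expect_true("GLUDH" %in% out2$accepted$reaction_id)
  mcc_final <- evaluate_phenotypes(out2$model, tests)$mcc
  expect_equal(mcc_final, 1)
  # empty proposals: identity
  out3 <- accept_proposals(gem, harmless[0, ], tests)
  expect_identical(out3$model, gem)
  # conflicting proposals rejected before mutation
  expect_error(accept_proposals(gem, dplyr::bind_rows(harmless, harmless),
                                tests),
               class = "switchflux_validation_error")
})

test_that("curation never lowers MCC below the pre-proposal model", {
  gem <- fx_gem()
  cfg <- fx_cfg()
  tests <- make_phenotype_tests(gem, cfg)[c(1:40, 198:241), ]
  tk <- fx_tables()
  props <- dplyr::bind_rows(
    propose_directionality(gem, tk$thermo),
    curate_atp_driven(gem, thermo = tk$thermo,
                      exceptions = c("ATPS", "ADK")))
  props <- props[!duplicated(props$reaction_id), ]
  base_mcc <- evaluate_phenotypes(gem, tests)$mcc
  out <- accept_proposals(gem, props, tests)
  expect_gte(evaluate_phenotypes(out$model, tests)$mcc, base_mcc - 1e-12)
})
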