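#' Run the full synthetic analysis pipeline
#'
#' Orchestrates the desk-scale study end to end from one configuration:
#' synthetic fixtures, thermodynamics-guided curation with phenotype
#' arbitration, enzyme-constrained model construction, condition-specific
#' models, vertex sampling with pathway activity scores and metabolite
#' budgets, cultivation-rate estimation, production comparisons, regulon
#' alignment and proteome PCA. All tabular outputs are written as TSV into
#' `out_dir`, with a manifest recording the seed and stage status. Rerunning
#' with the same configuration reproduces the outputs.
#'
#' @param config a [toy_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param strains strains to process (first is the producer reference).
#' @param n_samples vertices per condition for flux sampling.
#' @param sampled_offsets which proteome sampling offsets (by index) get a
#'   condition model and flux sample; default one pre- and one post-switch
#'   point per strain to keep the run light.
#' @param tolerance_fraction relative tolerance on measured rates.
#' @return (invisibly) a list of result objects per stage.
#' @export
run_pipeline <- function(config = toy_config(), out_dir = NULL,
                         strains = c("M145", "M1152"), n_samples = 60,
                         sampled_offsets = c(3, 6),
                         tolerance_fraction = 0.05) {
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "switchflux_pipeline_error")
    })
  }

  res$models <- stage("synthetic_data", {
    lapply(setNames(strains, strains),
           function(s) build_toy_gem(config, s))
  })
  ref <- strains[1]
  gem <- res$models[[ref]]
  tk <- stage("synthetic_data", make_thermo_kcats(gem, config))
  res$tables <- tk

  res$timeseries <- stage("cultivation_rates", {
    lapply(setNames(strains, strains),
           function(s) make_timeseries(config, s))
  })
  res$growth <- stage("cultivation_rates", {
    bind_rows(lapply(res$timeseries,
                     function(ts) glance(estimate_growth_rate(ts))))
  })
  res$depletion <- stage("cultivation_rates", {
    tibble(strain = strains,
           t_depletion = vapply(res$timeseries, detect_depletion,
                                numeric(1), compound = "phosphate"))
  })
  res$rates <- stage("cultivation_rates", {
    bind_rows(lapply(res$timeseries, specific_rates))
  })
  res$production <- stage("cultivation_rates", {
    alt <- setdiff(strains, ref)
    bind_rows(lapply(alt, function(s) {
      tibble(strain = s, compound = c("germA", "germB"),
             reduction_pct = c(
               as.numeric(production_comparison(res$timeseries[[ref]],
                                                res$timeseries[[s]], "germA")),
               as.numeric(production_comparison(res$timeseries[[ref]],
                                                res$timeseries[[s]], "germB"))))
    }))
  })

  res$curation <- stage("thermo_curation", {
    tests <- make_phenotype_tests(gem, config)
    props <- bind_rows(
      propose_directionality(gem, tk$thermo),
      curate_atp_driven(gem, thermo = tk$thermo,
                        exceptions = c("ATPS", "ADK")))
    props <- props[!duplicated(props$reaction_id), ]
    out <- accept_proposals(gem, props, tests)
    out$metrics <- evaluate_phenotypes(out$model, tests)
    out$tests <- tests
    out
  })

  res$ec <- stage("enzyme_constraints", {
    lapply(res$models, function(m) {
      kc <- filter(tk$kcats, .data$reaction_id %in% m$reactions$id)
      if (!nrow(kc) || any(!is.finite(kc$kcat))) {
        abort("corrupt or empty kcat table")
      }
      add_enzyme_constraints(split_reversible(m), kc, tk$proteins,
                             config$pool)
    })
  })
  res$ecfva <- stage("enzyme_constraints",
                     ecfva_compare(gem, res$ec[[ref]]))

  res$proteomes <- stage("enzyme_constraints", {
    lapply(setNames(strains, strains), function(s) {
      make_proteome(res$models[[s]], res$timeseries[[s]], config,
                    tk$kcats, tk$proteins)
    })
  })
  res$conditions <- stage("enzyme_constraints", {
    lapply(setNames(strains, strains), function(s) {
      make_conditions(config, s, res$proteomes[[s]], res$timeseries[[s]])
    })
  })
  res$condition_models <- stage("enzyme_constraints", {
    out <- list()
    for (s in strains) {
      conds <- res$conditions[[s]][sampled_offsets]
      for (nm in names(conds)) {
        out[[nm]] <- apply_condition(res$ec[[s]], conds[[nm]],
                                     tolerance_fraction,
                                     flexibilize = TRUE)
      }
    }
    out
  })

  res$samples <- stage("flux_sampling", {
    out <- list()
    for (nm in names(res$condition_models)) {
      out[[nm]] <- sample_vertices(res$condition_models[[nm]], n_samples,
                                   seed = config$seed +
                                     match(nm, names(res$condition_models)))
    }
    out
  })
  co2 <- unlist(lapply(res$conditions, function(cs) attr(cs, "co2_rate")))
  names(co2) <- sub("^[^.]*\\.", "", names(co2))
  res$pathway_activity <- stage("flux_sampling", {
    pathway_activity(res$samples, co2_rate = co2,
                     force_include = c("Act biosynthesis", "Red biosynthesis",
                                       "Cda biosynthesis", "Cpk biosynthesis"))
  })
  res$budgets <- stage("flux_sampling", {
    lapply(res$samples, function(fss) {
      nm <- fss$model$condition
      metabolite_budget(sample_means(fss), res$models[[nm$strain]],
                        "malcoa_c")
    })
  })

  res$omics <- stage("omics_compare", {
    expr <- lapply(res$proteomes, proteome_expression)
    regulon <- toy_regulon(gem, tk$proteins)
    alignment <- if (length(strains) > 1) {
      align_by_regulon(expr[[1]], expr[[2]], regulon)
    } else NULL
    pca <- pca_scores(proteome_expression(bind_rows(res$proteomes)), 2)
    list(alignment = alignment, pca = pca)
  })

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
    w(res$growth, "growth_rates.tsv")
    w(res$depletion, "depletion_times.tsv")
    w(res$rates, "specific_rates.tsv")
    w(res$production, "production_comparison.tsv")
    w(bind_rows(accepted = res$curation$accepted,
                discarded = res$curation$discarded, .id = "status"),
      "curation_report.tsv")
    w(tidy(res$curation$metrics), "phenotype_metrics.tsv")
    w(as_tibble(res$ecfva), "ecfva_comparison.tsv")
    w(as_tibble(res$pathway_activity), "pathway_activity.tsv")
    w(bind_rows(lapply(res$budgets, as_tibble), .id = "condition"),
      "malonyl_budget.tsv")
    if (!is.null(res$omics$alignment)) {
      w(as_tibble(res$omics$alignment), "alignment.tsv")
    }
    w(res$omics$pca$scores, "pca_scores.tsv")
    mean_fluxes <- bind_rows(lapply(res$samples, sample_means),
                             .id = "condition")
    w(mean_fluxes, "mean_fluxes.tsv")
    manifest <- tibble(key = c("seed", "n_samples", "strains", "stages"),
                       value = c(config$seed, n_samples,
                                 paste(strains, collapse = ","),
                                 paste(names(res), collapse = ",")))
    w(manifest, "manifest.tsv")
  }
  invisible(res)
}
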