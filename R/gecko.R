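# GECKO-style enzyme-constrained model construction: reversible reactions
# are split into irreversible copies, isozyme alternatives become parallel
# copies behind an "arm" pseudo-reaction carrying the total flux, every
# catalyzed copy consumes its enzyme species at 1/kcat per unit flux, and
# enzymes are supplied either from measured per-protein usage bounds or
# from a shared protein pool capped by sigma * f * p_total.

#' Split reversible reactions into irreversible copies
#'
#' Each reversible reaction (lb < 0 < ub) is replaced by a forward copy
#' (original id, bounds `[0, ub]`) and a backward copy (`<id>_bwd`, negated
#' stoichiometry, bounds `[0, -lb]`). Backward-only reactions are flipped
#' into a single `<id>_bwd` copy. The original-to-copy mapping is recorded
#' in field `split_map`; net flux `v_fwd - v_bwd` reconstructs the original
#' flux and FBA optima are preserved.
#'
#' @param model a `metabolic_model`.
#' @return the split model with a `split_map` tibble field
#'   (`original`, `fwd`, `bwd`).
#' @export
split_reversible <- function(model) {
  rows <- list()
  maps <- list()
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    if (r$lb < 0 && r$ub > 0) {
      fwd <- r
      fwd$lb <- 0
      bwd <- r
      bwd$id <- paste0(r$id, "_bwd")
      bwd$stoichiometry <- list(-r$stoichiometry[[1]])
      bwd$lb <- 0
      bwd$ub <- -r$lb
      rows <- c(rows, list(fwd, bwd))
      maps[[length(maps) + 1]] <- tibble(original = r$id, fwd = r$id, bwd = bwd$id)
    } else if (r$ub <= 0 && r$lb < 0) {
      bwd <- r
      bwd$id <- paste0(r$id, "_bwd")
      bwd$stoichiometry <- list(-r$stoichiometry[[1]])
      bwd$lb <- -r$ub
      bwd$ub <- -r$lb
      rows <- c(rows, list(bwd))
      maps[[length(maps) + 1]] <- tibble(original = r$id, fwd = NA_character_,
                                         bwd = bwd$id)
    } else {
      rows <- c(rows, list(r))
      maps[[length(maps) + 1]] <- tibble(original = r$id, fwd = r$id,
                                         bwd = NA_character_)
    }
  }
  out <- metabolic_model(model$metabolites, bind_rows(rows),
                         objective = model$objective, genes = model$genes,
                         compartments = model$compartments)
  out$split_map <- bind_rows(maps)
  out
}

#' GECKO pool parameters
#'
#' @param p_total total cellular protein mass fraction, g/gDW.
#' @param f fraction of protein mass covered by the model's enzymes.
#' @param sigma average in-vivo enzyme saturation.
#' @return a `pool_params` list.
#' @export
pool_params <- function(p_total = 0.45, f = 0.4, sigma = 0.5) {
  stopifnot(p_total > 0, f > 0, f <= 1, sigma > 0, sigma <= 1)
  structure(list(p_total = p_total, f = f, sigma = sigma),
            class = "pool_params")
}

lookup_kcat <- function(kcats, protein, original, direction, med) {
  hit <- kcats$kcat[kcats$protein_id == protein &
                      kcats$reaction_id == original &
                      kcats$direction == direction]
  if (length(hit)) list(kcat = hit[1], match_level = "exact")
  else list(kcat = med, match_level = "median_fallback")
}

#' Add enzyme constraints to a split model
#'
#' Builds the enzyme-constrained model: one enzyme species and usage
#' reaction per protein, a shared protein pool capped at
#' `sigma * f * p_total`, and per-copy enzyme consumption at `1/kcat`.
#' OR branches of a gene rule become one reaction copy per isozyme behind
#' an arm reaction that carries the total flux; AND groups couple every
#' subunit at `1/kcat` each. Catalyzed reactions without a matching kcat
#' entry receive the model-median kcat, flagged `median_fallback`.
#'
#' @param model a split `metabolic_model` (see [split_reversible()]).
#' @param kcats tibble `protein_id`, `reaction_id` (original id),
#'   `direction` (`"forward"`/`"backward"`), `kcat` (1/h).
#' @param proteins tibble `protein_id`, `gene_id`, `mw` (g/mmol).
#' @param pool a [pool_params()] list.
#' @return an `ec_model` (a `metabolic_model` subclass with fields
#'   `split_map`, `net_map`, `enzymes`, `kcat_table`, `pool`).
#' @export
add_enzyme_constraints <- function(model, kcats, proteins,
                                   pool = pool_params()) {
  if (is.null(model$split_map)) {
    abort("model must be split first (see split_reversible())",
          class = "switchflux_usage_error")
  }
  kcats <- as_tibble(kcats)
  proteins <- as_tibble(proteins)
  stopifnot(all(kcats$kcat > 0), all(proteins$mw > 0))
  bad <- setdiff(kcats$reaction_id, model$split_map$original)
  if (length(bad)) {
    abort(paste0("kcat entries for unknown reaction(s): ",
                 paste(unique(bad), collapse = ", ")),
          class = "switchflux_validation_error")
  }
  bad_dir <- setdiff(kcats$direction, c("forward", "backward"))
  if (length(bad_dir)) {
    abort(paste0("unknown kcat direction(s): ", paste(bad_dir, collapse = ", ")),
          class = "switchflux_validation_error")
  }
  protein_of_gene <- setNames(proteins$protein_id, proteins$gene_id)
  med <- median(kcats$kcat)

  sm <- model$split_map
  dir_of_copy <- c(setNames(rep("forward", nrow(sm)), sm$fwd),
                  setNames(rep("backward", nrow(sm)), sm$bwd))
  orig_of_copy <- c(setNames(sm$original, sm$fwd), setNames(sm$original, sm$bwd))

  new_mets <- list()
  out_rows <- list()
  kcat_used <- list()
  rep_of_copy <- character()   # total-flux carrier per copy (arm or itself)

  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rule <- r$gene_rule
    if (!nzchar(rule)) {
      out_rows <- c(out_rows, list(r))
      rep_of_copy[r$id] <- r$id
      next
    }
    direction <- dir_of_copy[[r$id]]
    original <- orig_of_copy[[r$id]]
    alts <- gene_rule_dnf(rule)
    enzyme_cost <- function(genes) {
      cost <- numeric()
      lvl <- character()
      for (g in genes) {
        p <- protein_of_gene[[g]]
        if (is.null(p) || is.na(p)) {
          abort(paste0("gene '", g, "' has no protein record"),
                class = "switchflux_validation_error")
        }
        kc <- lookup_kcat(kcats, p, original, direction, med)
        pm <- paste0("prot_", p)
        cost[pm] <- (if (pm %in% names(cost)) cost[[pm]] else 0) - 1 / kc$kcat
        lvl <- c(lvl, kc$match_level)
        kcat_used[[length(kcat_used) + 1]] <<-
          tibble(protein_id = p, copy = r$id, reaction_id = original,
                 direction = direction, kcat = kc$kcat,
                 match_level = kc$match_level)
      }
      cost
    }
    if (length(alts) == 1) {
      s <- c(r$stoichiometry[[1]], enzyme_cost(alts[[1]]))
      r$stoichiometry <- list(s)
      out_rows <- c(out_rows, list(r))
      rep_of_copy[r$id] <- r$id
    } else {
      s <- r$stoichiometry[[1]]
      pmet <- paste0("pmet_", r$id)
      new_mets[[pmet]] <- pmet
      arm <- r
      arm$id <- paste0(r$id, "_arm")
      arm$stoichiometry <- list(c(s[s < 0], setNames(1, pmet)))
      arm$gene_rule <- ""
      out_rows <- c(out_rows, list(arm))
      rep_of_copy[r$id] <- arm$id
      for (t in seq_along(alts)) {
        cp <- r
        cp$id <- paste0(r$id, "_No", t)
        cp$stoichiometry <- list(c(setNames(-1, pmet), s[s > 0],
                                   enzyme_cost(alts[[t]])))
        cp$gene_rule <- paste(alts[[t]], collapse = " and ")
        out_rows <- c(out_rows, list(cp))
      }
    }
  }

  kcat_table <- bind_rows(kcat_used)
  used_prots <- unique(kcat_table$protein_id)
  enzymes <- filter(proteins, .data$protein_id %in% used_prots)
  enzymes <- mutate(enzymes,
                    metabolite = paste0("prot_", .data$protein_id),
                    usage = paste0("usage_prot_", .data$protein_id),
                    measured = FALSE, abundance = NA_real_)

  # usage reactions: draw enzyme mass from the shared pool
  for (k in seq_len(nrow(enzymes))) {
    out_rows <- c(out_rows, list(tibble(
      id = enzymes$usage[k],
      stoichiometry = list(setNames(c(-enzymes$mw[k], 1),
                                    c("prot_pool", enzymes$metabolite[k]))),
      lb = 0, ub = default_bound(), gene_rule = "",
      subsystem = "Enzyme usage", pathway = "Enzyme usage")))
  }
  cap <- pool$sigma * pool$f * pool$p_total
  out_rows <- c(out_rows, list(tibble(
    id = "prot_pool_exchange",
    stoichiometry = list(setNames(1, "prot_pool")),
    lb = 0, ub = cap, gene_rule = "",
    subsystem = "Enzyme usage", pathway = "Enzyme usage")))

  mets <- bind_rows(
    model$metabolites,
    tibble(id = c(unlist(new_mets, use.names = FALSE), "prot_pool",
                  enzymes$metabolite),
           name = c(unlist(new_mets, use.names = FALSE), "protein pool",
                    enzymes$protein_id),
           compartment = "c", formula = "", charge = NA_integer_))

  ec <- metabolic_model(mets, bind_rows(out_rows),
                        objective = model$objective,
                        genes = model$genes,
                        compartments = model$compartments)
  ec$split_map <- model$split_map
  ec$net_map <- mutate(model$split_map,
                       fwd = unname(rep_of_copy[.data$fwd]),
                       bwd = unname(rep_of_copy[.data$bwd]))
  ec$enzymes <- enzymes
  ec$kcat_table <- kcat_table
  ec$pool <- list(params = pool, cap = cap, exchange = "prot_pool_exchange")
  class(ec) <- c("ec_model", class(ec))
  ec
}

#' @export
print.ec_model <- function(x, ...) {
  cat("<ec_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ", nrow(x$enzymes), " enzymes, ",
      "pool cap ", format(x$pool$cap), " g/gDW\n",
      "objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Integrate measured protein abundances into an ec-model
#'
#' Measured proteins get a direct usage bound at their abundance (mmol/gDW)
#' instead of drawing from the pool; the pool cap is reduced by the
#' measured protein mass. With `flexibilize = TRUE` and a target
#' `growth_rate`, the single most limiting measured protein bound (largest
#' reduced cost at the growth optimum) is doubled, repeatedly, until the
#' target growth becomes achievable or the relaxation budget is exhausted.
#'
#' @param ec an `ec_model`.
#' @param sample tibble `protein_id`, `abundance` (mmol/gDW); proteins
#'   absent from the model are ignored with a message.
#' @param flexibilize logical.
#' @param growth_rate target growth (1/h), required when flexibilizing.
#' @param max_relax maximum number of bound relaxations.
#' @return the condition-ready `ec_model`; relaxations are recorded in
#'   field `relaxations`.
#' @export
apply_proteome <- function(ec, sample, flexibilize = FALSE,
                           growth_rate = NULL, max_relax = 20L) {
  sample <- as_tibble(sample)
  unknown <- setdiff(sample$protein_id, ec$enzymes$protein_id)
  if (length(unknown)) {
    inform(paste0("ignoring ", length(unknown),
                  " unmeasured-in-model protein(s): ",
                  paste(head(unknown, 5), collapse = ", ")))
    sample <- filter(sample, .data$protein_id %in% ec$enzymes$protein_id)
  }
  stopifnot(all(sample$abundance >= 0))
  for (k in seq_len(nrow(sample))) {
    j <- match(sample$protein_id[k], ec$enzymes$protein_id)
    usage <- ec$enzymes$usage[j]
    i <- match(usage, ec$reactions$id)
    ec$reactions$stoichiometry[[i]] <- setNames(1, ec$enzymes$metabolite[j])
    ec$reactions$ub[i] <- sample$abundance[k]
    ec$enzymes$measured[j] <- TRUE
    ec$enzymes$abundance[j] <- sample$abundance[k]
  }
  measured_mass <- sum(sample$abundance *
                         ec$enzymes$mw[match(sample$protein_id,
                                             ec$enzymes$protein_id)])
  p <- ec$pool$params
  ec$pool$cap <- max(0, p$sigma * (p$f * p$p_total - measured_mass))
  ec <- set_bounds(ec, ec$pool$exchange, ub = ec$pool$cap)

  ec$relaxations <- tibble(protein_id = character(), old_ub = numeric(),
                           new_ub = numeric())
  if (flexibilize) {
    if (is.null(growth_rate)) {
      abort("flexibilize = TRUE requires a growth_rate target",
            class = "switchflux_usage_error")
    }
    for (iter in seq_len(max_relax)) {
      sol <- fba_status(ec)
      if (sol$status == "optimal" && sol$objective_value >= growth_rate) {
        return(ec)
      }
      if (sol$status != "optimal") {
        abort("ec-model infeasible before proteome relaxation could help",
              class = "switchflux_infeasible")
      }
      fl <- sol$fluxes
      rc <- attr(fl, "reduced_costs")
      meas <- filter(ec$enzymes, .data$measured)
      idx <- match(meas$usage, ec$reactions$id)
      at_ub <- abs(fl$flux[idx] - ec$reactions$ub[idx]) < 1e-7
      score <- ifelse(at_ub, rc[idx], -Inf)
      if (all(!is.finite(score))) {
        abort("growth target unreachable: no measured protein is limiting",
              class = "switchflux_infeasible")
      }
      j <- which.max(score)
      i <- idx[j]
      old <- ec$reactions$ub[i]
      ec$reactions$ub[i] <- old * 2
      ec$enzymes$abundance[match(meas$protein_id[j], ec$enzymes$protein_id)] <- old * 2
      ec$relaxations <- bind_rows(ec$relaxations,
                                  tibble(protein_id = meas$protein_id[j],
                                         old_ub = old, new_ub = old * 2))
      inform(paste0("relaxed usage bound of ", meas$protein_id[j], " to ",
                    format(old * 2)))
    }
    sol <- fba_status(ec)
    if (!(sol$status == "optimal" && sol$objective_value >= growth_rate)) {
      abort(paste0("growth target ", growth_rate,
                   " still infeasible after ", max_relax, " relaxations; ",
                   "last limiting proteins: ",
                   paste(tail(ec$relaxations$protein_id, 3), collapse = ", ")),
            class = "switchflux_infeasible")
    }
  }
  ec
}

#' Condition specification for a strain/time point
#'
#' @param strain strain id.
#' @param time_h sampling time, h.
#' @param rates tibble `reaction` (original exchange id), `rate`
#'   (mmol/gDW/h, negative = uptake).
#' @param growth_rate measured specific growth rate, 1/h.
#' @param proteome optional tibble `protein_id`, `abundance`.
#' @return a `condition_spec` list.
#' @export
condition_spec <- function(strain, time_h, rates, growth_rate,
                           proteome = NULL) {
  structure(list(strain = strain, time_h = time_h, rates = as_tibble(rates),
                 growth_rate = growth_rate, proteome = proteome),
            class = "condition_spec")
}

#' Specialize an ec-model to measured condition rates
#'
#' Constrains each measured exchange to its rate +/- a relative tolerance
#' and bounds growth below at `(1 - tolerance) * growth_rate`, yielding a
#' time- and strain-specific model. If the rate set is inconsistent the
#' error names the constraints whose single relaxation restores
#' feasibility.
#'
#' @param ec an `ec_model`.
#' @param condition a [condition_spec()].
#' @param tolerance_fraction relative tolerance on measured rates.
#' @param flexibilize passed to [apply_proteome()] when the condition
#'   carries a proteome.
#' @return the condition-specific `ec_model` (field `condition` records
#'   strain and time).
#' @export
apply_condition <- function(ec, condition, tolerance_fraction = 0.05,
                            flexibilize = FALSE) {
  stopifnot(inherits(condition, "condition_spec"))
  if (!is.null(condition$proteome)) {
    ec <- apply_proteome(ec, condition$proteome, flexibilize = flexibilize,
                         growth_rate = condition$growth_rate)
  }
  rates <- condition$rates
  bad <- setdiff(rates$reaction, ec$split_map$original)
  if (length(bad)) {
    abort(paste0("rates for unknown exchange(s): ", paste(bad, collapse = ", ")),
          class = "switchflux_model_error")
  }
  pre <- ec
  tol <- tolerance_fraction
  for (k in seq_len(nrow(rates))) {
    rid <- rates$reaction[k]
    r <- rates$rate[k]
    lo <- r - tol * abs(r)
    hi <- r + tol * abs(r)
    mp <- ec$split_map[ec$split_map$original == rid, ]
    if (!is.na(mp$fwd) && !is.na(mp$bwd)) {
      ec <- set_bounds(ec, mp$fwd, lb = max(0, lo), ub = max(0, hi))
      ec <- set_bounds(ec, mp$bwd, lb = max(0, -hi), ub = max(0, -lo))
    } else if (!is.na(mp$fwd)) {
      ec <- set_bounds(ec, mp$fwd, lb = max(0, lo), ub = max(0, hi))
    } else {
      ec <- set_bounds(ec, mp$bwd, lb = max(0, -hi), ub = max(0, -lo))
    }
  }
  if (!is.null(condition$growth_rate)) {
    ec <- set_bounds(ec, ec$objective,
                     lb = (1 - tol) * condition$growth_rate)
  }
  sol <- fba_status(ec)
  if (sol$status != "optimal") {
    culprits <- character()
    for (k in seq_len(nrow(rates))) {
      rid <- rates$reaction[k]
      mp <- ec$split_map[ec$split_map$original == rid, ]
      test <- ec
      for (cp in stats::na.omit(c(mp$fwd, mp$bwd))) {
        i <- match(cp, pre$reactions$id)
        test <- set_bounds(test, cp, lb = pre$reactions$lb[i],
                           ub = pre$reactions$ub[i])
      }
      if (fba_status(test)$status == "optimal") culprits <- c(culprits, rid)
    }
    test <- set_bounds(ec, ec$objective, lb = 0)
    if (fba_status(test)$status == "optimal" &&
        fba_status(test)$objective_value <
          (1 - tol) * condition$growth_rate) {
      culprits <- c(culprits, paste0("growth_rate=", condition$growth_rate))
    }
    abort(paste0("inconsistent condition rates; relaxing any of {",
                 paste(culprits, collapse = ", "),
                 "} restores feasibility"),
          class = "switchflux_infeasible_condition")
  }
  ec$condition <- list(strain = condition$strain, time_h = condition$time_h)
  ec
}

#' Net fluxes of an ec-model solution on original reactions
#'
#' @param ec an `ec_model`.
#' @param fluxes a `flux_distribution` (or named flux vector) on `ec`.
#' @return tibble `reaction` (original id), `flux` (net).
#' @export
ec_net_fluxes <- function(ec, fluxes) {
  v <- if (is.data.frame(fluxes)) setNames(fluxes$flux, fluxes$reaction) else fluxes
  nm <- ec$net_map
  get0 <- function(id) if (is.na(id)) 0 else v[[id]]
  tibble(reaction = nm$original,
         flux = vapply(seq_len(nrow(nm)),
                       function(k) get0(nm$fwd[k]) - get0(nm$bwd[k]),
                       numeric(1)))
}

# augmented ec-model exposing one net-flux variable per split original
# reaction (v_net = v_fwd - v_bwd via an auxiliary balance row), so FVA on
# net fluxes never inflates ranges through futile fwd/bwd cycling
ec_with_net_variables <- function(ec, originals) {
  nm <- filter(ec$net_map, .data$original %in% originals)
  mets <- ec$metabolites
  rxns <- ec$reactions
  wide <- max(default_bound(), abs(rxns$lb), abs(rxns$ub))
  net_id <- character(nrow(nm))
  for (k in seq_len(nrow(nm))) {
    if (is.na(nm$fwd[k]) || is.na(nm$bwd[k])) {
      # unsplit: the single copy already is the net flux (sign-flipped if bwd)
      net_id[k] <- NA_character_
      next
    }
    nmet <- paste0("netm_", nm$original[k])
    mets <- bind_rows(mets, tibble(id = nmet, name = nmet, compartment = "c",
                                   formula = "", charge = NA_integer_))
    i <- match(nm$fwd[k], rxns$id)
    rxns$stoichiometry[[i]] <- c(rxns$stoichiometry[[i]], setNames(1, nmet))
    i <- match(nm$bwd[k], rxns$id)
    rxns$stoichiometry[[i]] <- c(rxns$stoichiometry[[i]], setNames(-1, nmet))
    nid <- paste0("net_", nm$original[k])
    rxns <- bind_rows(rxns, tibble(id = nid,
                                   stoichiometry = list(setNames(-1, nmet)),
                                   lb = -wide, ub = wide, gene_rule = "",
                                   subsystem = "", pathway = ""))
    net_id[k] <- nid
  }
  aug <- metabolic_model(mets, rxns, objective = ec$objective,
                         genes = ec$genes, compartments = ec$compartments)
  list(model = aug, map = mutate(nm, net = net_id))
}

#' Compare flux variability between a GEM and its ec-model
#'
#' Runs FVA (fraction of optimum 0) on the original model and net-flux FVA
#' on the enzyme-constrained model, pairing ranges per original reaction.
#' Enzyme constraints can only shrink ranges, so every ec width is at most
#' the GEM width (up to solver tolerance).
#'
#' @param gem the original `metabolic_model`.
#' @param ec the matching `ec_model`.
#' @param reactions original reaction ids; default all reactions of `gem`.
#' @return an `ecfva_comparison` tibble: `reaction`, `gem_min`, `gem_max`,
#'   `ec_min`, `ec_max`, `gem_width`, `ec_width`, with a `cumulative`
#'   attribute holding the sorted width distributions.
#' @export
ecfva_compare <- function(gem, ec, reactions = gem$reactions$id) {
  gem_rng <- fva(gem, reactions, fraction_of_optimum = 0)
  aug <- ec_with_net_variables(ec, reactions)
  map <- aug$map
  target <- ifelse(is.na(map$net),
                   ifelse(is.na(map$fwd), map$bwd, map$fwd), map$net)
  flip <- is.na(map$net) & is.na(map$fwd)
  ec_rng <- fva(aug$model, target, fraction_of_optimum = 0)
  lo <- ifelse(flip, -ec_rng$max, ec_rng$min)
  hi <- ifelse(flip, -ec_rng$min, ec_rng$max)
  out <- tibble(reaction = map$original,
                gem_min = gem_rng$min[match(map$original, gem_rng$reaction)],
                gem_max = gem_rng$max[match(map$original, gem_rng$reaction)],
                ec_min = lo, ec_max = hi) %>%
    mutate(gem_width = .data$gem_max - .data$gem_min,
           ec_width = .data$ec_max - .data$ec_min)
  structure(out,
            class = c("ecfva_comparison", class(out)),
            cumulative = tibble(
              fraction = seq_len(nrow(out)) / nrow(out),
              gem_width = sort(out$gem_width),
              ec_width = sort(out$ec_width)))
}
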