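#' Update biomass prosthetic-group coefficients from proteome data
#'
#' Sets the biomass coefficient of each prosthetic-group metabolite
#' proportional to the abundance-weighted sum over proteins annotated with
#' that group, scaled so that the total mass contribution of all groups
#' equals `mass_fraction` gram per gram biomass. All other biomass
#' coefficients are rescaled so one unit of biomass flux still corresponds
#' to 1 g of biomass. The allocation is invariant to rescaling all
#' abundances by a common factor.
#'
#' @param model a `metabolic_model` whose objective is the biomass reaction.
#' @param proteome tibble with columns `protein_id`, `abundance`
#'   (mmol/gDW).
#' @param prosthetic_map tibble with columns `protein_id`, `metabolite`
#'   (group metabolite id), `stoichiometry` (groups per protein).
#' @param mass_fraction total g of prosthetic groups per g biomass
#'   (default 0.01).
#' @param group_mw named vector of group molecular weights in g/mmol
#'   (default 1 for every group).
#' @param biomass id of the biomass reaction; defaults to the objective.
#' @return the updated model.
#' @export
update_biomass_prosthetics <- function(model, proteome, prosthetic_map,
                                       mass_fraction = 0.01, group_mw = NULL,
                                       biomass = model$objective) {
  i <- match(biomass, model$reactions$id)
  if (is.na(i)) {
    abort(paste0("biomass reaction '", biomass, "' not found"),
          class = "switchflux_config_error")
  }
  prosthetic_map <- as_tibble(prosthetic_map)
  if (!nrow(prosthetic_map)) return(model)
  groups <- unique(prosthetic_map$metabolite)
  missing_g <- setdiff(groups, model$metabolites$id)
  if (length(missing_g)) {
    abort(paste0("prosthetic-group metabolite(s) not in model: ",
                 paste(missing_g, collapse = ", ")),
          class = "switchflux_config_error")
  }
  if (is.null(group_mw)) group_mw <- setNames(rep(1, length(groups)), groups)

  ab <- setNames(proteome$abundance, proteome$protein_id)
  w <- vapply(groups, function(g) {
    rows <- prosthetic_map[prosthetic_map$metabolite == g, ]
    sum(ab[rows$protein_id] * rows$stoichiometry, na.rm = TRUE)
  }, numeric(1))
  if (sum(w * group_mw[groups]) <= 0) {
    abort("no measured abundance for any annotated protein",
          class = "switchflux_config_error")
  }
  # mmol of group per g biomass so total group mass equals mass_fraction
  coefs <- mass_fraction * w / sum(w * group_mw[groups])

  s <- model$reactions$stoichiometry[[i]]
  old_group_mass <- sum(-s[intersect(names(s), groups)] *
                          group_mw[intersect(names(s), groups)], na.rm = TRUE)
  # rescale remaining (consumed) precursors to keep 1 g biomass per unit flux
  rest <- setdiff(names(s)[s < 0], groups)
  scale_rest <- (1 - mass_fraction) / max(1 - old_group_mass, .Machine$double.eps)
  s[rest] <- s[rest] * scale_rest
  s[groups] <- -coefs
  s <- s[s != 0]
  model$reactions$stoichiometry[[i]] <- s
  model
}
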