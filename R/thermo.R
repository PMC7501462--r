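#' Propose reaction directionality from Gibbs-energy estimates
#'
#' Classifies each reaction with a standard transformed Gibbs energy
#' estimate using a lenient threshold (default -30 kJ/mol): strongly
#' negative reactions become forward-irreversible, strongly positive ones
#' backward-irreversible (the symmetric application of the threshold), and
#' reactions in between are opened to reversibility. A proposal is emitted
#' only where the implied bounds differ from the model's.
#'
#' @param model a `metabolic_model`.
#' @param thermo tibble with columns `reaction_id`, `delta_g` (kJ/mol) and
#'   optionally `uncertainty` (carried along, not used for classification).
#' @param threshold kJ/mol; `delta_g <= threshold` is called irreversible
#'   forward, `delta_g >= -threshold` irreversible backward.
#' @return tibble of proposals: `reaction_id`, `basis`, `old_lb`, `old_ub`,
#'   `new_lb`, `new_ub`.
#' @export
propose_directionality <- function(model, thermo, threshold = -30) {
  thermo <- as_tibble(thermo)
  unknown <- setdiff(thermo$reaction_id, model$reactions$id)
  if (length(unknown)) {
    abort(paste0("thermo records for unknown reaction(s): ",
                 paste(unknown, collapse = ", ")),
          class = "switchflux_model_error")
  }
  if (any(!is.finite(thermo$delta_g))) {
    abort("delta_g must be finite", class = "switchflux_model_error")
  }
  rows <- lapply(seq_len(nrow(thermo)), function(k) {
    rid <- thermo$reaction_id[k]
    dg <- thermo$delta_g[k]
    i <- match(rid, model$reactions$id)
    lb <- model$reactions$lb[i]
    ub <- model$reactions$ub[i]
    wide <- max(default_bound(), abs(lb), abs(ub))
    if (dg <= threshold) {            # forward-irreversible
      new <- c(0, if (ub > 0) ub else wide)
    } else if (dg >= -threshold) {    # backward-irreversible
      new <- c(if (lb < 0) lb else -wide, 0)
    } else {                          # reversible, opened symmetrically
      new <- c(-wide, wide)
    }
    if (new[1] == lb && new[2] == ub) return(NULL)
    tibble(reaction_id = rid, basis = "thermo",
           old_lb = lb, old_ub = ub, new_lb = new[1], new_ub = new[2])
  })
  bind_rows(rows)
}

#' Curate ATP-driven reactions to irreversibility
#'
#' Every reversible reaction consuming ATP (negative ATP coefficient as
#' written) is proposed forward-irreversible, unless its Gibbs energy
#' estimate is positive or it is listed among the known-reversible
#' exceptions (nucleoside diphosphate kinase, adenylate kinase, ATP
#' synthase and the like).
#'
#' @param model a `metabolic_model`.
#' @param atp_metabolite_id id of the ATP metabolite.
#' @param thermo optional thermo tibble (see [propose_directionality()]);
#'   reactions with `delta_g > 0` are exempted.
#' @param exceptions reaction ids never curated.
#' @return proposal tibble as in [propose_directionality()], basis
#'   `"atp_rule"`.
#' @export
curate_atp_driven <- function(model, atp_metabolite_id = "atp_c",
                              thermo = NULL, exceptions = character()) {
  if (!atp_metabolite_id %in% model$metabolites$id) {
    abort(paste0("ATP metabolite '", atp_metabolite_id, "' not in model"),
          class = "switchflux_model_error")
  }
  dg <- if (!is.null(thermo)) setNames(thermo$delta_g, thermo$reaction_id) else numeric()
  rows <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- r$stoichiometry[[1]]
    if (!(r$lb < 0 && r$ub > 0)) return(NULL)           # not reversible
    if (!atp_metabolite_id %in% names(s)) return(NULL)
    if (s[[atp_metabolite_id]] >= 0) return(NULL)       # not ATP-consuming
    if (r$id %in% exceptions) return(NULL)
    if (r$id %in% names(dg) && isTRUE(dg[[r$id]] > 0)) return(NULL)
    tibble(reaction_id = r$id, basis = "atp_rule",
           old_lb = r$lb, old_ub = r$ub, new_lb = 0, new_ub = r$ub)
  })
  bind_rows(rows)
}

apply_proposals <- function(model, proposals) {
  for (k in seq_len(nrow(proposals))) {
    model <- set_bounds(model, proposals$reaction_id[k],
                        lb = proposals$new_lb[k], ub = proposals$new_ub[k])
  }
  model
}

#' Accept or discard directionality proposals by phenotype arbitration
#'
#' Applies all proposals, then — in ascending reaction-id order — reverts
#' each proposal singly and keeps the reversion if and only if it strictly
#' increases the Matthews correlation coefficient of the phenotype
#' predictions, recomputing after every kept reversion. An undefined MCC is
#' treated as lower than any defined MCC.
#'
#' @param model a `metabolic_model`.
#' @param proposals proposal tibble (at most one proposal per reaction).
#' @param tests phenotype test tibble (see [evaluate_phenotypes()]).
#' @param growth_cutoff growth-call threshold in 1/h.
#' @return list with `model` (curated), `accepted` and `discarded` proposal
#'   tibbles.
#' @export
accept_proposals <- function(model, proposals, tests,
                             growth_cutoff = 1e-6) {
  if (!nrow(proposals)) {
    return(list(model = model, accepted = proposals, discarded = proposals))
  }
  if (anyDuplicated(proposals$reaction_id)) {
    dup <- unique(proposals$reaction_id[duplicated(proposals$reaction_id)])
    abort(paste0("conflicting proposals for reaction(s): ",
                 paste(dup, collapse = ", ")),
          class = "switchflux_validation_error")
  }
  proposals <- arrange(proposals, .data$reaction_id)
  cur <- apply_proposals(model, proposals)
  mcc_of <- function(m) {
    v <- evaluate_phenotypes(m, tests, growth_cutoff)$mcc
    if (is.na(v)) -Inf else v
  }
  cur_mcc <- mcc_of(cur)
  keep <- rep(TRUE, nrow(proposals))
  for (k in seq_len(nrow(proposals))) {
    reverted <- set_bounds(cur, proposals$reaction_id[k],
                           lb = proposals$old_lb[k], ub = proposals$old_ub[k])
    rev_mcc <- mcc_of(reverted)
    if (rev_mcc > cur_mcc) {
      cur <- reverted
      cur_mcc <- rev_mcc
      keep[k] <- FALSE
    }
  }
  list(model = cur, accepted = proposals[keep, ], discarded = proposals[!keep, ])
}
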