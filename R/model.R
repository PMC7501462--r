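#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` bundles a metabolite table, a reaction table (with
#' stoichiometry as a named-numeric list column), a gene set, an objective
#' reaction and a compartment set. Fluxes are in mmol/gDW/h; the biomass
#' reaction's flux is the specific growth rate in 1/h. The conventional
#' "infinite" flux bound is +/- 1000 mmol/gDW/h (see [default_bound()]).
#'
#' @param metabolites tibble with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`.
#' @param reactions tibble with columns `id`, `stoichiometry` (list of named
#'   numeric vectors, names are metabolite ids, negative = consumed), `lb`,
#'   `ub`, `gene_rule` (boolean expression over gene ids, `""` if none),
#'   `subsystem`, `pathway`.
#' @param objective id of the objective (typically biomass) reaction.
#' @param genes character vector of gene ids; derived from gene rules when
#'   omitted.
#' @param compartments declared compartment symbols; derived when omitted.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective,
                            genes = NULL, compartments = NULL) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- ""
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  for (col in c("gene_rule", "subsystem", "pathway")) {
    if (!col %in% names(reactions)) reactions[[col]] <- ""
    reactions[[col]][is.na(reactions[[col]])] <- ""
  }
  if (is.null(compartments)) compartments <- sort(unique(metabolites$compartment))
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gene_rule, gene_rule_genes))))
  }
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         genes = genes, objective = objective,
         compartments = compartments),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ", length(x$genes), " genes\n",
      "objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    abort(paste0("duplicated metabolite ids: ",
                 paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")),
          class = "switchflux_model_error")
  }
  if (anyDuplicated(rxns$id)) {
    abort(paste0("duplicated reaction ids: ",
                 paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")),
          class = "switchflux_model_error")
  }
  bad_comp <- setdiff(mets$compartment, model$compartments)
  if (length(bad_comp)) {
    abort(paste0("undeclared compartments: ", paste(bad_comp, collapse = ", ")),
          class = "switchflux_model_error")
  }
  for (i in seq_len(nrow(rxns))) {
    s <- rxns$stoichiometry[[i]]
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown)) {
      abort(paste0("reaction '", rxns$id[i],
                   "' references undeclared metabolite(s): ",
                   paste(unknown, collapse = ", ")),
            class = "switchflux_parse_error")
    }
  }
  if (any(rxns$lb > rxns$ub)) {
    bad <- rxns$id[rxns$lb > rxns$ub]
    abort(paste0("lower bound exceeds upper bound for: ",
                 paste(bad, collapse = ", ")),
          class = "switchflux_model_error")
  }
  if (!model$objective %in% rxns$id) {
    abort(paste0("objective reaction '", model$objective, "' not in model"),
          class = "switchflux_model_error")
  }
  invisible(model)
}

#' Default "infinite" flux bound
#'
#' @return 1000 (mmol/gDW/h), the conventional stand-in for an unbounded flux
#'   in genome-scale models.
#' @export
default_bound <- function() 1000

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (i in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoichiometry[[i]]
    S[names(s), i] <- s
  }
  S
}

#' Identify exchange reactions
#'
#' Exchanges are identified structurally as reactions touching exactly one
#' metabolite, never by id prefix (the "EX_" prefix is display convention).
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[vapply(model$reactions$stoichiometry, length, 1L) == 1L]
}

#' Update reaction bounds
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- match(id, model$reactions$id)
  if (any(is.na(i))) {
    abort(paste0("unknown reaction(s): ", paste(id[is.na(i)], collapse = ", ")),
          class = "switchflux_model_error")
  }
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  model
}

#' Apply gene knockouts
#'
#' Reactions whose gene rule evaluates to `FALSE` with the listed genes
#' deleted (AND = complex, OR = isozymes) have both flux bounds set to zero.
#' Gene-rule-free reactions are untouched.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of deleted gene ids.
#' @return the knockout model.
#' @export
knockout_genes <- function(model, genes) {
  for (i in seq_len(nrow(model$reactions))) {
    rule <- model$reactions$gene_rule[i]
    if (!nzchar(rule)) next
    if (!eval_gene_rule(rule, deleted = genes)) {
      model$reactions$lb[i] <- 0
      model$reactions$ub[i] <- 0
    }
  }
  model
}

#' Reactions as a tidy table
#'
#' @param model a `metabolic_model`.
#' @return tibble with one row per (reaction, metabolite) pair plus bounds
#'   and labels.
#' @export
reaction_table <- function(model) {
  rx <- model$reactions
  tidyr::unnest(
    mutate(rx, metabolite = lapply(.data$stoichiometry, names),
           coefficient = lapply(.data$stoichiometry, unname),
           stoichiometry = NULL),
    c("metabolite", "coefficient"))
}
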