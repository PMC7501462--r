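# SBML Level 3 Version 1 + fbc version 2 serialization, built on xml2.
# Conventions follow the constraint-based modelling community: "M_"/"R_"/"G_"
# id prefixes, flux bounds as shared-constant parameters referenced via
# fbc:lowerFluxBound / fbc:upperFluxBound, gene rules as nested fbc:and /
# fbc:or gene-product associations, subsystem/pathway as COBRA-style
# key-value <p> lines in the reaction notes. Bound values are written with
# 17 significant digits so that read(write(model)) reproduces them bit-exact.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

num17 <- function(x) sprintf("%.17g", x)

sbml_id <- function(prefix, id) {
  safe <- gsub("[^A-Za-z0-9_]", "_", id)
  paste0(prefix, safe)
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    "xmlns" = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "true")

  locomp <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in model$compartments) {
    xml2::xml_add_child(locomp, "compartment", id = cmp, constant = "true")
  }

  losp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      losp, "species", id = sbml_id("M_", m$id), name = m$name,
      compartment = m$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (nzchar(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge)) xml2::xml_set_attr(sp, "fbc:charge", as.character(m$charge))
  }

  lopar <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- sbml_id("R_", model$reactions$id[i])
    xml2::xml_add_child(lopar, "parameter", id = paste0(rid, "_lb"),
                        value = num17(model$reactions$lb[i]), constant = "true")
    xml2::xml_add_child(lopar, "parameter", id = paste0(rid, "_ub"),
                        value = num17(model$reactions$ub[i]), constant = "true")
  }

  lorx <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rid <- sbml_id("R_", r$id)
    rx <- xml2::xml_add_child(
      lorx, "reaction", id = rid,
      reversible = tolower(as.character(r$lb < 0)), fast = "false",
      "fbc:lowerFluxBound" = paste0(rid, "_lb"),
      "fbc:upperFluxBound" = paste0(rid, "_ub"))
    if (nzchar(r$subsystem) || nzchar(r$pathway)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
      if (nzchar(r$subsystem)) {
        xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
      }
      if (nzchar(r$pathway)) {
        xml2::xml_add_child(body, "p", paste0("PATHWAY: ", r$pathway))
      }
    }
    s <- r$stoichiometry[[1]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lo <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(reac)) {
        xml2::xml_add_child(lo, "speciesReference",
                            species = sbml_id("M_", names(reac)[k]),
                            stoichiometry = num17(abs(reac[k])),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lo <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prod)) {
        xml2::xml_add_child(lo, "speciesReference",
                            species = sbml_id("M_", names(prod)[k]),
                            stoichiometry = num17(prod[k]),
                            constant = "true")
      }
    }
    if (nzchar(r$gene_rule)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_gpa_node(gpa, parse_gene_rule(r$gene_rule))
    }
  }

  loobj <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(loobj, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  lofo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lofo, "fbc:fluxObjective",
                      "fbc:reaction" = sbml_id("R_", model$objective),
                      "fbc:coefficient" = "1")

  logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    xml2::xml_add_child(logp, "fbc:geneProduct",
                        "fbc:id" = sbml_id("G_", g), "fbc:label" = g)
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

add_gpa_node <- function(parent, ast) {
  if (is.character(ast)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sbml_id("G_", ast))
    return(invisible())
  }
  node <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
  for (a in ast$args) add_gpa_node(node, a)
  invisible()
}

strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS, x = XHTML_NS)

  comp_nodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  gp_nodes <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_id <- xml2::xml_attr(gp_nodes, "id")
  gp_label <- xml2::xml_attr(gp_nodes, "label")
  gene_of <- setNames(gp_label, gp_id)

  sid <- xml2::xml_attr(sp_nodes, "id")
  metabolites <- tibble(
    id = strip_prefix(sid, "M_"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           strip_prefix(sid, "M_")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = dplyr::coalesce(xml2::xml_attr(sp_nodes, "chemicalFormula"), ""),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp_nodes, "charge"))))

  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                      xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rows <- lapply(rx_nodes, function(rx) {
    rid_full <- xml2::xml_attr(rx, "id")
    rid <- strip_prefix(rid_full, "R_")
    get_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rx, xpath, ns)
      if (!length(refs)) return(numeric())
      setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
               strip_prefix(xml2::xml_attr(refs, "species"), "M_"))
    }
    stoich <- c(get_side("./s:listOfReactants/s:speciesReference", -1),
                get_side("./s:listOfProducts/s:speciesReference", 1))
    gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation/*", ns)
    rule <- if (inherits(gpa, "xml_node")) gpa_to_rule(gpa, gene_of, ns) else ""
    ps <- xml2::xml_text(xml2::xml_find_all(rx, "./s:notes//x:p", ns))
    if (!length(ps)) ps <- xml2::xml_text(xml2::xml_find_all(rx, "./s:notes//p", ns))
    grab <- function(key) {
      hit <- grep(paste0("^", key, ": "), ps, value = TRUE)
      if (length(hit)) sub(paste0("^", key, ": "), "", hit[1]) else ""
    }
    tibble(id = rid,
           stoichiometry = list(stoich),
           lb = par_val[[xml2::xml_attr(rx, "lowerFluxBound")]],
           ub = par_val[[xml2::xml_attr(rx, "upperFluxBound")]],
           gene_rule = rule,
           subsystem = grab("SUBSYSTEM"),
           pathway = grab("PATHWAY"))
  })
  reactions <- bind_rows(rows)

  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- strip_prefix(xml2::xml_attr(fo, "reaction"), "R_")

  metabolic_model(metabolites, reactions, objective = objective,
                  genes = sort(unname(gene_of)), compartments = compartments)
}

gpa_to_rule <- function(node, gene_of, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    g <- gene_of[[gid]]
    if (is.null(g)) g <- strip_prefix(gid, "G_")
    return(g)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, gpa_to_rule, character(1), gene_of = gene_of, ns = ns)
  wrap <- vapply(kids, function(k) xml2::xml_name(k) != "geneProductRef", logical(1))
  parts[wrap] <- paste0("(", parts[wrap], ")")
  paste(parts, collapse = paste0(" ", nm, " "))
}
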