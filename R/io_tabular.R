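# Flat tabular model dialect: a directory holding reactions.tsv
# (id, equation, lb, ub, gene_rule, subsystem, pathway), metabolites.tsv
# (id, name, compartment, formula, charge) and model.tsv (field, value;
# carries the objective id). Equations use "-->" (irreversible display) or
# "<=>" (reversible display); bounds, not the arrow, are authoritative.

format_equation <- function(stoich, reversible) {
  side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(abs(v) == 1, names(v),
                 paste(format(abs(v), trim = TRUE, scientific = FALSE), names(v))),
          collapse = " + ")
  }
  lhs <- side(stoich[stoich < 0])
  rhs <- side(stoich[stoich > 0])
  arrow <- if (reversible) "<=>" else "-->"
  trimws(paste(lhs, arrow, rhs))
}

parse_equation <- function(eq, reaction_id) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else if (grepl("-->", eq, fixed = TRUE)) "-->" else
    abort(paste0("reaction '", reaction_id, "': equation lacks '-->' or '<=>'"),
          class = "switchflux_parse_error")
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    terms <- strsplit(txt, "\\s*\\+\\s*")[[1]]
    out <- numeric()
    for (term in terms) {
      parts <- strsplit(trimws(term), "\\s+")[[1]]
      if (length(parts) == 1L) {
        out[parts] <- sign
      } else if (length(parts) == 2L) {
        coefficient <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coefficient)) {
          abort(paste0("reaction '", reaction_id, "': bad term '", term, "'"),
                class = "switchflux_parse_error")
        }
        out[parts[2]] <- sign * coefficient
      } else {
        abort(paste0("reaction '", reaction_id, "': bad term '", term, "'"),
              class = "switchflux_parse_error")
      }
    }
    out
  }
  c(parse_side(sides[1], -1), parse_side(sides[2], 1))
}

write_model_tabular <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  mets <- model$metabolites
  readr::write_tsv(mets[, c("id", "name", "compartment", "formula", "charge")],
                   file.path(path, "metabolites.tsv"))
  rx <- model$reactions
  eq <- vapply(seq_len(nrow(rx)), function(i) {
    format_equation(rx$stoichiometry[[i]], rx$lb[i] < 0 && rx$ub[i] > 0)
  }, character(1))
  readr::write_tsv(
    tibble(id = rx$id, equation = eq,
           lb = sprintf("%.17g", rx$lb), ub = sprintf("%.17g", rx$ub),
           gene_rule = rx$gene_rule, subsystem = rx$subsystem,
           pathway = rx$pathway),
    file.path(path, "reactions.tsv"))
  readr::write_tsv(tibble(field = "objective", value = model$objective),
                   file.path(path, "model.tsv"))
  invisible(path)
}

read_model_tabular <- function(path) {
  spec_m <- readr::cols(id = "c", name = "c", compartment = "c",
                        formula = "c", charge = "i")
  mets <- readr::read_tsv(file.path(path, "metabolites.tsv"),
                          col_types = spec_m, progress = FALSE)
  mets$formula[is.na(mets$formula)] <- ""
  rx <- readr::read_tsv(file.path(path, "reactions.tsv"),
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  info <- readr::read_tsv(file.path(path, "model.tsv"),
                          col_types = "cc", progress = FALSE)
  stoich <- lapply(seq_len(nrow(rx)),
                   function(i) parse_equation(rx$equation[i], rx$id[i]))
  reactions <- tibble(
    id = rx$id, stoichiometry = stoich,
    lb = as.numeric(rx$lb), ub = as.numeric(rx$ub),
    gene_rule = ifelse(is.na(rx$gene_rule), "", rx$gene_rule),
    subsystem = ifelse(is.na(rx$subsystem), "", rx$subsystem),
    pathway = ifelse(is.na(rx$pathway), "", rx$pathway))
  metabolic_model(mets, reactions,
                  objective = info$value[info$field == "objective"])
}

#' Read or write a metabolic model
#'
#' Dispatches on `dialect`: `"sbml"` (SBML Level 3 Version 1 with the fbc
#' package; a single `.xml` file) or `"tabular"` (a directory of TSV files).
#' Writing then reading is the identity on ids, stoichiometry, bounds, gene
#' rules and subsystem/pathway labels.
#'
#' @param path file (sbml) or directory (tabular) path.
#' @param direction `"read"` or `"write"`.
#' @param dialect `"sbml"` or `"tabular"`.
#' @param model the model to write (write direction only).
#' @return the read `metabolic_model`, or (invisibly) `path` after writing.
#' @export
model_io <- function(path, direction = c("read", "write"),
                     dialect = c("sbml", "tabular"), model = NULL) {
  direction <- match.arg(direction)
  dialect <- match.arg(dialect)
  if (direction == "read") {
    if (dialect == "sbml") read_model_sbml(path) else read_model_tabular(path)
  } else {
    if (is.null(model)) {
      abort("'model' is required when writing", class = "switchflux_usage_error")
    }
    if (dialect == "sbml") write_model_sbml(model, path)
    else write_model_tabular(model, path)
  }
}
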