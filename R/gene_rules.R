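# Gene-protein-reaction rule handling. Rules are boolean expressions over
# gene ids with `and` (complex subunits) and `or` (isozymes), e.g.
# "g1 and (g2 or g3)". Parsed by a small recursive-descent parser into a
# nested list AST: list(op = "and"|"or", args = ...) or a gene id string.

tokenize_rule <- function(rule) {
  rule <- gsub("\\(", " ( ", rule)
  rule <- gsub("\\)", " ) ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

parse_gene_rule <- function(rule) {
  toks <- tokenize_rule(rule)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) left else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) left else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) abort("unexpected end of gene rule", class = "switchflux_parse_error")
    if (t == "(") {
      take()
      inner <- parse_or()
      if (is.na(peek()) || peek() != ")")
        abort("unbalanced parentheses in gene rule", class = "switchflux_parse_error")
      take()
      return(inner)
    }
    if (tolower(t) %in% c("and", "or", ")"))
      abort(paste0("malformed gene rule near '", t, "'"),
            class = "switchflux_parse_error")
    take()
  }
  ast <- parse_or()
  if (pos <= length(toks))
    abort("trailing tokens in gene rule", class = "switchflux_parse_error")
  ast
}

gene_rule_genes <- function(rule) {
  if (is.na(rule) || !nzchar(rule)) return(character())
  ast <- parse_gene_rule(rule)
  collect <- function(node) {
    if (is.character(node)) return(node)
    unlist(lapply(node$args, collect))
  }
  unique(collect(ast))
}

# Evaluate a rule with the given genes deleted (deleted genes are FALSE,
# all others TRUE). An empty rule evaluates TRUE (non-enzymatic reaction).
eval_gene_rule <- function(rule, deleted = character()) {
  if (is.na(rule) || !nzchar(rule)) return(TRUE)
  ast <- parse_gene_rule(rule)
  ev <- function(node) {
    if (is.character(node)) return(!(node %in% deleted))
    vals <- vapply(node$args, ev, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  ev(ast)
}

# Expand a rule to disjunctive normal form: a list of character vectors,
# each vector one isozyme alternative (an AND-group of subunit genes).
gene_rule_dnf <- function(rule) {
  if (is.na(rule) || !nzchar(rule)) return(list())
  ast <- parse_gene_rule(rule)
  dnf <- function(node) {
    if (is.character(node)) return(list(node))
    parts <- lapply(node$args, dnf)
    if (node$op == "or") return(unlist(parts, recursive = FALSE))
    # and: cartesian product of alternatives
    out <- list(character())
    for (p in parts) {
      out <- unlist(lapply(out, function(pre) {
        lapply(p, function(alt) unique(c(pre, alt)))
      }), recursive = FALSE)
    }
    out
  }
  alts <- dnf(ast)
  unique(lapply(alts, sort))
}
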