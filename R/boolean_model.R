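#' Construct a Boolean logical model
#'
#' A `boolean_model` is a named collection of nodes with Boolean update
#' rules. Rules are unevaluated R expressions over node identifiers using
#' `&`, `|`, `!` and parentheses, or the logical constants `TRUE`/`FALSE`.
#' Nodes without a rule have no upstream regulation: they are *inputs*
#' whose value is user-set (clamped) rather than computed. Constant rules
#' are rules, not inputs: a constant node is regulated (to a constant),
#' an input remains user-settable.
#'
#' @param nodes character vector of unique node identifiers; the vector
#'   order is the canonical node order of the model.
#' @param rules named list mapping a node identifier to its update rule
#'   (a quoted expression, e.g. `quote(A & !B)`, or `TRUE`/`FALSE`).
#'   Nodes absent from `rules` are inputs.
#' @param phenotypes named character vector mapping phenotype nodes to a
#'   category, `"cell_specific"` (apoptosis, proliferation, migration ...)
#'   or `"joint_level"` (inflammation, angiogenesis, matrix degradation ...).
#' @param celltype named character vector mapping nodes to a cell-type
#'   label; unlisted nodes are `"shared"`.
#' @param annotations named list mapping nodes to character vectors of
#'   external identifiers (e.g. HGNC symbols) used for symbol resolution.
#' @param labels named character vector of display names.
#'
#' @return an object of class `boolean_model` with elements `nodes`,
#'   `rules`, `inputs`, `phenotypes`, `celltype`, `annotations`, `labels`.
#' @examples
#' m <- boolean_model(
#'   nodes = c("L", "R", "P"),
#'   rules = list(R = quote(L), P = quote(R)),
#'   phenotypes = c(P = "cell_specific")
#' )
#' model_stats(m)
#' @export
boolean_model <- function(nodes, rules = list(), phenotypes = character(0),
                          celltype = character(0), annotations = list(),
                          labels = character(0)) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  rules <- as.list(rules)
  bad <- setdiff(names(rules), nodes)
  if (length(bad)) stop("rules for undeclared nodes: ", paste(bad, collapse = ", "))
  for (n in names(rules)) {
    refs <- rule_regulators(rules[[n]])
    missing <- setdiff(refs, nodes)
    if (length(missing)) {
      stop("rule for '", n, "' references unknown node(s): ",
           paste(missing, collapse = ", "))
    }
  }
  ct <- setNames(rep("shared", length(nodes)), nodes)
  ct[names(celltype)] <- celltype
  model <- structure(list(
    nodes = nodes,
    rules = rules[intersect(nodes, names(rules))],
    inputs = setdiff(nodes, names(rules)),
    phenotypes = phenotypes[intersect(names(phenotypes), nodes)],
    celltype = ct,
    annotations = annotations[intersect(names(annotations), nodes)],
    labels = labels[intersect(names(labels), nodes)]
  ), class = "boolean_model")
  model
}

#' @export
print.boolean_model <- function(x, ...) {
  s <- model_stats(x)
  cat("Boolean model: ", s$n_nodes, " nodes, ", s$n_inputs, " inputs, ",
      s$n_interactions, " interactions\n", sep = "")
  if (length(x$phenotypes)) {
    cat("Phenotypes: ", paste(names(x$phenotypes), collapse = ", "), "\n", sep = "")
  }
  cts <- setdiff(unique(x$celltype), "shared")
  if (length(cts)) cat("Cell types: ", paste(cts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## regulators of a single rule (unique node identifiers appearing in it)
rule_regulators <- function(rule) {
  if (is.logical(rule)) return(character(0))
  unique(all.vars(rule))
}

#' Regulator edges of a model
#'
#' One edge per distinct (regulator, target) pair, regardless of how many
#' times the regulator appears in the target's rule.
#'
#' @param model a `boolean_model`.
#' @return data.frame with columns `regulator`, `target`.
#' @export
model_edges <- function(model) {
  regs <- lapply(model$rules, rule_regulators)
  data.frame(
    regulator = unlist(regs, use.names = FALSE),
    target = rep(names(regs), lengths(regs)),
    stringsAsFactors = FALSE
  )
}

#' Summary statistics of a Boolean model
#'
#' @param model a `boolean_model`.
#' @return list of class `model_stats` with `n_nodes`, `n_inputs` and
#'   `n_interactions` (distinct regulator-to-target edges).
#' @export
model_stats <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  structure(list(
    n_nodes = length(model$nodes),
    n_inputs = length(model$inputs),
    n_interactions = nrow(model_edges(model))
  ), class = "model_stats")
}

#' @export
print.model_stats <- function(x, ...) {
  cat("nodes: ", x$n_nodes, ", inputs: ", x$n_inputs,
      ", interactions: ", x$n_interactions, "\n", sep = "")
  invisible(x)
}

#' Extract the submodel upstream of a set of phenotype nodes
#'
#' Computes the backward closure of `targets` over regulator edges and
#' returns the induced submodel. Rules are restricted to kept nodes; since
#' the closure keeps every regulator of a kept rule, rules never lose a
#' regulator. Nodes downstream-only of the targets are dropped, mirroring
#' the practice of discarding nodes not involved in regulating the
#' phenotypes of interest.
#'
#' @param model a `boolean_model`.
#' @param targets character vector of nodes (typically phenotype nodes).
#' @return the induced `boolean_model`.
#' @export
upstream_subset <- function(model, targets) {
  stopifnot(inherits(model, "boolean_model"))
  unknown <- setdiff(targets, model$nodes)
  if (length(unknown)) {
    stop("unknown target node(s): ", paste(unknown, collapse = ", "))
  }
  edges <- model_edges(model)
  keep <- targets
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges, directed = TRUE,
      vertices = data.frame(name = model$nodes)
    )
    keep <- unique(unlist(lapply(targets, function(t) {
      names(igraph::subcomponent(g, t, mode = "in"))
    })))
  }
  keep <- model$nodes[model$nodes %in% keep]
  boolean_model(
    nodes = keep,
    rules = model$rules[intersect(names(model$rules), keep)],
    phenotypes = model$phenotypes[intersect(names(model$phenotypes), keep)],
    celltype = model$celltype[keep],
    annotations = model$annotations[intersect(names(model$annotations), keep)],
    labels = model$labels[intersect(names(model$labels), keep)]
  )
}

## Resolve a symbol to model node(s): exact id match, then annotation
## (e.g. HGNC) match, then case-insensitive display-name match.
## With multiple = FALSE an ambiguous match is an error, never a guess.
resolve_symbol <- function(model, symbol, celltype = NULL, multiple = FALSE) {
  nodes <- model$nodes
  if (!is.null(celltype)) nodes <- nodes[model$celltype[nodes] == celltype]
  hit <- nodes[nodes == symbol]
  if (!length(hit)) {
    ann <- model$annotations[intersect(names(model$annotations), nodes)]
    hit <- names(ann)[vapply(ann, function(a) symbol %in% a, logical(1))]
  }
  if (!length(hit) && length(model$labels)) {
    lab <- model$labels[intersect(names(model$labels), nodes)]
    hit <- names(lab)[tolower(lab) == tolower(symbol)]
  }
  if (!length(hit)) return(character(0))
  if (!multiple && length(hit) > 1L) {
    stop("ambiguous symbol '", symbol, "': matches ",
         paste(hit, collapse = ", "))
  }
  hit
}

## Substitute node identifiers in a rule expression according to a named map.
rule_substitute <- function(rule, map) {
  if (is.logical(rule)) return(rule)
  walk <- function(e) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (!is.null(map[[nm]])) return(as.symbol(map[[nm]]))
      return(e)
    }
    if (is.call(e)) {
      for (i in seq_along(e)[-1]) e[[i]] <- walk(e[[i]])
      return(e)
    }
    e
  }
  walk(rule)
}

## Render a rule as text (for printing / TSV export).
rule_to_text <- function(rule) {
  if (is.logical(rule)) return(if (rule) "TRUE" else "FALSE")
  paste(deparse(rule), collapse = " ")
}
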