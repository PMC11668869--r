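## Expression-based model calibration.
##
## Differential-expression knowledge enters the pipeline as a discretized
## observed profile: overexpressed molecules map to 1, under-expressed to
## 0. Enumerated steady states are filtered by literature-derived
## phenotype constraints, scored against the profile, and the top-scoring
## states are averaged into the calibrated state of the model.

#' Build an observed profile from a discretized differential-expression table
#'
#' @param table data.frame with columns `node` and `direction`
#'   (`"up"` -> 1, `"down"` -> 0) and optionally `source`
#'   (`"literature"` or `"dataset"`).
#' @param model optional `boolean_model`; if given, node symbols are
#'   resolved against it (exact id, then annotation, then display name).
#' @param lenient if `TRUE`, unresolvable symbols are skipped with a
#'   warning instead of raising an error.
#' @return object of class `observed_profile`: list with `values` (named
#'   0/1 integer vector) and `provenance` (named character vector).
#' @export
discretize_profile <- function(table, model = NULL, lenient = FALSE) {
  stopifnot(all(c("node", "direction") %in% names(table)))
  dir <- tolower(as.character(table$direction))
  if (!all(dir %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'")
  }
  nodes <- as.character(table$node)
  src <- if ("source" %in% names(table)) as.character(table$source) else
    rep("dataset", length(nodes))
  if (!is.null(model)) {
    resolved <- character(length(nodes))
    keep <- logical(length(nodes))
    for (i in seq_along(nodes)) {
      hit <- resolve_symbol(model, nodes[i])
      if (length(hit) == 1L) {
        resolved[i] <- hit
        keep[i] <- TRUE
      } else if (lenient) {
        warning("profile entry '", nodes[i], "' does not resolve to a model ",
                "node; skipped", call. = FALSE)
      } else {
        stop("profile entry '", nodes[i], "' does not resolve to a model node")
      }
    }
    nodes <- resolved[keep]
    dir <- dir[keep]
    src <- src[keep]
  }
  vals <- ifelse(dir == "up", 1L, 0L)
  dup <- unique(nodes[duplicated(nodes)])
  for (d in dup) {
    if (length(unique(vals[nodes == d])) > 1L) {
      stop("conflicting directions for node '", d, "'")
    }
  }
  first <- !duplicated(nodes)
  structure(list(
    values = setNames(vals[first], nodes[first]),
    provenance = setNames(src[first], nodes[first])
  ), class = "observed_profile")
}

#' @export
print.observed_profile <- function(x, ...) {
  cat("Observed profile: ", length(x$values), " nodes (",
      sum(x$values == 1L), " up, ", sum(x$values == 0L), " down)\n", sep = "")
  invisible(x)
}

#' Filter steady states by phenotype constraints
#'
#' Keeps the states whose phenotype nodes take their biologically coherent
#' values (e.g. in hyperplastic synovial fibroblasts: apoptosis OFF,
#' proliferation ON, migration ON). Row order is preserved.
#'
#' @param states integer state matrix (rows = states) or list of named
#'   state vectors.
#' @param constraints named 0/1 vector over phenotype nodes.
#' @return the matching subset, same representation as `states`.
#' @export
phenotype_filter <- function(states, constraints) {
  if (is.list(states) && !is.matrix(states)) {
    states <- do.call(rbind, states)
  }
  if (!length(constraints)) return(states)
  missing <- setdiff(names(constraints), colnames(states))
  if (length(missing)) {
    stop("constraint on unknown node(s): ", paste(missing, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(states))
  for (p in names(constraints)) {
    keep <- keep & states[, p] == constraints[[p]]
  }
  out <- states[keep, , drop = FALSE]
  if (!nrow(out)) {
    warning("no steady state satisfies the phenotype constraints",
            call. = FALSE)
  }
  out
}

#' Similarity of a state to an observed profile
#'
#' Fraction of profile nodes, among those present in the state, whose
#' state value equals the observed discretized value.
#'
#' @param state named 0/1 vector (a steady state).
#' @param profile an `observed_profile`.
#' @return numeric in `[0, 1]`.
#' @export
similarity_score <- function(state, profile) {
  obs <- profile$values
  mapped <- intersect(names(obs), names(state))
  if (!length(mapped)) stop("no profile node maps into the state")
  mean(state[mapped] == obs[mapped])
}

#' Calibrate a model state from steady states and an observed profile
#'
#' Scores every steady state against the profile, selects all states
#' attaining the highest score (ties all included), and averages them.
#' Nodes whose mean is exactly 0 or 1 are *fixed*; the rest are *free*.
#' The reproduction percentage is the share of mapped observed values
#' matched by a fixed node of the calibrated state; a free node counts as
#' not reproducing its observation.
#'
#' @param states integer state matrix (rows = steady states) or list of
#'   named state vectors; must be non-empty.
#' @param profile an `observed_profile`.
#' @return object of class `calibrated_state`: list with `mean` (named
#'   numeric), `fixed`, `free` (character vectors), `n_selected`,
#'   `best_score` and `reproduction_pct`.
#' @export
calibrate <- function(states, profile) {
  if (is.list(states) && !is.matrix(states)) states <- do.call(rbind, states)
  if (is.null(states) || nrow(states) == 0L) stop("no states to calibrate from")
  scores <- apply(states, 1L, function(s) {
    similarity_score(setNames(s, colnames(states)), profile)
  })
  best <- max(scores)
  sel <- states[scores == best, , drop = FALSE]
  m <- colMeans(sel)
  fixed <- names(m)[m == 0 | m == 1]
  mapped <- intersect(names(profile$values), colnames(states))
  matched <- sum(vapply(mapped, function(n) {
    n %in% fixed && m[[n]] == profile$values[[n]]
  }, logical(1)))
  structure(list(
    mean = m,
    fixed = fixed,
    free = setdiff(colnames(states), fixed),
    n_selected = nrow(sel),
    best_score = best,
    reproduction_pct = 100 * matched / length(mapped)
  ), class = "calibrated_state")
}

#' @export
print.calibrated_state <- function(x, ...) {
  cat("Calibrated state over ", x$n_selected, " top-scoring steady state(s)\n",
      "  fixed nodes: ", length(x$fixed), ", free nodes: ", length(x$free),
      "\n  best similarity: ", format(x$best_score, digits = 4),
      ", reproduction: ", format(x$reproduction_pct, digits = 4), "%\n",
      sep = "")
  invisible(x)
}

#' Clamp inputs according to an observed profile
#'
#' Inputs present in the profile are fixed at their observed value
#' (overexpressed inputs at 1, under-expressed inputs at 0) before
#' steady-state enumeration, shrinking the free-input combination space.
#' Non-profile inputs stay free unless `default_one = TRUE`, in which case
#' they are fixed at 1 (the default input value of some analysis tools).
#'
#' @param model a `boolean_model`.
#' @param profile an `observed_profile`.
#' @param default_one fix non-profile inputs at 1 instead of leaving them
#'   free.
#' @return named 0/1 vector of input clamps.
#' @export
input_clamps_from_profile <- function(model, profile, default_one = FALSE) {
  obs <- profile$values
  fixed <- obs[intersect(names(obs), model$inputs)]
  if (default_one) {
    rest <- setdiff(model$inputs, names(fixed))
    fixed <- c(fixed, setNames(rep(1L, length(rest)), rest))
  }
  fixed
}
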