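## In silico knockout screening.
##
## A knockout clamps the target node(s) to 0, mimicking pharmacological
## inhibition, and simulates the model synchronously from the calibrated
## state. Phenotype changes are reported relative to the calibrated
## reference: "down" for an active phenotype that switches off, "up" for
## an inactive phenotype that switches on.

INHIBITOR_PATTERN <- "inhibit|antagonist|blocker"

#' Map a therapeutic-target table onto model nodes
#'
#' Keeps the entries whose mode of action is inhibitor-class and resolves
#' their symbols to model nodes. In a multi-cellular model one symbol may
#' map to several namespaced nodes (one per cell type); a knockout clamps
#' all of them. Entries that do not resolve are reported, not kept.
#'
#' @param entries data.frame with columns `symbol` and `moa` (mode of
#'   action; entries matching inhibitor/antagonist/blocker are kept).
#' @param model a `boolean_model`.
#' @return list of `target_entry` objects (each with `symbol`, `moa`,
#'   `mapped_nodes`), with attribute `unmapped`: character vector of
#'   inhibitor-class symbols that did not resolve.
#' @export
map_targets <- function(entries, model) {
  stopifnot(all(c("symbol", "moa") %in% names(entries)))
  if (!nrow(entries)) stop("empty target table")
  inhib <- grepl(INHIBITOR_PATTERN, tolower(as.character(entries$moa)))
  entries <- entries[inhib, , drop = FALSE]
  out <- list()
  unmapped <- character(0)
  for (i in seq_len(nrow(entries))) {
    sym <- as.character(entries$symbol[i])
    nodes <- resolve_symbol(model, sym, multiple = TRUE)
    if (!length(nodes)) {
      unmapped <- c(unmapped, sym)
      next
    }
    out[[length(out) + 1L]] <- structure(list(
      symbol = sym,
      moa = as.character(entries$moa[i]),
      mapped_nodes = nodes
    ), class = "target_entry")
  }
  attr(out, "unmapped") <- unique(unmapped)
  out
}

#' Initial state from a calibrated state
#'
#' Fixed nodes take their calibrated 0/1 value; free nodes take
#' `free_init` (default 0).
#'
#' @param model a `boolean_model`.
#' @param calibrated a `calibrated_state` or `partial_state`.
#' @param free_init value for free/undetermined nodes, 0 or 1.
#' @return named 0/1 integer vector over all model nodes.
#' @export
initial_from_calibrated <- function(model, calibrated, free_init = 0L) {
  if (inherits(calibrated, "calibrated_state")) {
    mean <- calibrated$mean
    fixed <- calibrated$fixed
  } else {
    mean <- as.numeric(calibrated)
    names(mean) <- names(calibrated)
    fixed <- names(mean)[!is.na(mean)]
  }
  s <- setNames(rep(as.integer(free_init), length(model$nodes)), model$nodes)
  fixed <- intersect(fixed, model$nodes)
  s[fixed] <- as.integer(round(mean[fixed]))
  s
}

#' Run a single knockout simulation
#'
#' Clamps the target node(s) to 0 on top of the fixed inputs, simulates
#' synchronously from the calibrated state (free nodes initialised per
#' `free_init`), and compares the phenotype values of the resulting
#' attractor with the calibrated reference. For a cyclic attractor a
#' phenotype counts as active when its activity level over the cycle is
#' at least 0.5; the calibrated reference is active when its mean is at
#' least 0.5. If the simulation does not converge within `max_steps`,
#' deltas are computed on the activity of the last `window` steps and the
#' outcome is flagged as truncated.
#'
#' @param model a `boolean_model`.
#' @param calibrated a `calibrated_state` or `partial_state` (the
#'   reference and initial condition).
#' @param fixed_inputs named 0/1 vector of clamped inputs.
#' @param targets character vector of node(s) to knock out (clamped to 0).
#' @param max_steps simulation horizon (default 100).
#' @param window sliding-window length for activity levels (default 50).
#' @param free_init initial value of free nodes (default 0).
#' @return object of class `perturbation_outcome`: list with `targets`,
#'   `phenotype_delta` (named character: `"up"`, `"down"`,
#'   `"unchanged"`), `phenotype_state`, `reference_state`, `converged`,
#'   `attractor_kind` (`"steady"`, `"cycle"` or `"truncated"`) and
#'   `effective` (any non-unchanged delta).
#' @export
run_knockout <- function(model, calibrated, fixed_inputs = NULL,
                         targets = character(0), max_steps = 100L,
                         window = 50L, free_init = 0L) {
  bad <- setdiff(targets, model$nodes)
  if (length(bad)) stop("unknown target node(s): ", paste(bad, collapse = ", "))
  clamps <- check_clamps(model, fixed_inputs)
  ko <- setNames(rep(0L, length(targets)), targets)
  clamps <- c(clamps[setdiff(names(clamps), targets)], ko)
  initial <- initial_from_calibrated(model, calibrated, free_init)
  sim <- simulate_model(model, initial, clamps, max_steps = max_steps)

  phen <- names(model$phenotypes)
  ref_mean <- if (inherits(calibrated, "calibrated_state")) calibrated$mean else {
    v <- as.numeric(calibrated); names(v) <- names(calibrated); v
  }
  ref_mean[is.na(ref_mean)] <- as.numeric(free_init)
  ref_active <- ref_mean[phen] >= 0.5

  if (sim$converged) {
    kind <- sim$attractor$kind
    if (kind == "steady") {
      pert_active <- sim$attractor$states[1L, phen] == 1L
    } else {
      pert_active <- colMeans(sim$attractor$states)[phen] >= 0.5
    }
    att <- sim$attractor$states
  } else {
    kind <- "truncated"
    warning("knockout simulation did not converge within ", max_steps,
            " steps; deltas computed on window activity", call. = FALSE)
    pert_active <- activity_levels(sim$trajectory, window)[phen] >= 0.5
    att <- sim$trajectory
  }
  # clamp dominance: every attractor/trajectory state holds the KO at 0
  if (length(targets) && any(att[, targets, drop = FALSE] != 0L)) {
    stop("internal error: knocked-out node active despite clamp")
  }

  delta <- rep("unchanged", length(phen))
  delta[ref_active & !pert_active] <- "down"
  delta[!ref_active & pert_active] <- "up"
  names(delta) <- phen
  structure(list(
    targets = targets,
    phenotype_delta = delta,
    phenotype_state = setNames(as.integer(pert_active), phen),
    reference_state = setNames(as.integer(ref_active), phen),
    converged = sim$converged,
    attractor_kind = kind,
    effective = any(delta != "unchanged")
  ), class = "perturbation_outcome")
}

#' @export
print.perturbation_outcome <- function(x, ...) {
  cat("KO ", paste(x$targets, collapse = " + "), " [", x$attractor_kind, "]\n",
      sep = "")
  ch <- x$phenotype_delta[x$phenotype_delta != "unchanged"]
  if (length(ch)) {
    cat(paste0("  ", names(ch), ": ", ch, collapse = "\n"), "\n", sep = "")
  } else {
    cat("  no phenotype change\n")
  }
  invisible(x)
}

#' Single-knockout screen
#'
#' Runs [run_knockout()] for each target entry (all of an entry's mapped
#' nodes are clamped together) and flags entries whose deltas are all
#' unchanged as ineffective. Order follows the target list.
#'
#' @inheritParams run_knockout
#' @param targets list of `target_entry`s from [map_targets()], or a
#'   character vector of node names (one KO each).
#' @return list of `perturbation_outcome`s.
#' @export
single_ko_screen <- function(model, calibrated, fixed_inputs = NULL, targets,
                             max_steps = 100L, window = 50L, free_init = 0L) {
  if (!length(targets)) stop("empty target list")
  if (is.character(targets)) targets <- as.list(targets)
  lapply(targets, function(t) {
    nodes <- if (inherits(t, "target_entry")) t$mapped_nodes else t
    out <- run_knockout(model, calibrated, fixed_inputs, nodes,
                        max_steps, window, free_init)
    if (inherits(t, "target_entry")) out$symbol <- t$symbol
    out
  })
}

#' All unordered target pairs
#'
#' Enumerates the `C(n, 2)` pairs (without repetition) screened by a
#' double-knockout run, in deterministic order.
#'
#' @param targets list of `target_entry`s or character vector.
#' @return data.frame with columns `a`, `b` (indices into `targets`) and
#'   `label_a`, `label_b`.
#' @export
target_pairs <- function(targets) {
  n <- length(targets)
  if (n < 2L) stop("need at least two targets to form pairs")
  idx <- utils::combn(n, 2L)
  lab <- vapply(seq_len(n), function(i) {
    t <- targets[[i]]
    if (inherits(t, "target_entry")) t$symbol else as.character(t)
  }, character(1))
  data.frame(a = idx[1L, ], b = idx[2L, ],
             label_a = lab[idx[1L, ]], label_b = lab[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Double-knockout screen over all target pairs
#'
#' Iterates every unordered pair of targets and clamps both entries'
#' nodes to 0 in a single run.
#'
#' @inheritParams single_ko_screen
#' @param pairs_range optional `c(from, to)` (1-based, inclusive) slice of
#'   the pair list for sharded execution.
#' @return list of `perturbation_outcome`s, one per pair, in
#'   [target_pairs()] order.
#' @export
double_ko_screen <- function(model, calibrated, fixed_inputs = NULL, targets,
                             max_steps = 100L, window = 50L, free_init = 0L,
                             pairs_range = NULL) {
  if (is.character(targets)) targets <- as.list(targets)
  pairs <- target_pairs(targets)
  rows <- seq_len(nrow(pairs))
  if (!is.null(pairs_range)) {
    rows <- rows[rows >= pairs_range[1] & rows <= pairs_range[2]]
  }
  lapply(rows, function(r) {
    ta <- targets[[pairs$a[r]]]
    tb <- targets[[pairs$b[r]]]
    nodes <- unique(c(
      if (inherits(ta, "target_entry")) ta$mapped_nodes else ta,
      if (inherits(tb, "target_entry")) tb$mapped_nodes else tb
    ))
    out <- run_knockout(model, calibrated, fixed_inputs, nodes,
                        max_steps, window, free_init)
    out$pair <- c(pairs$label_a[r], pairs$label_b[r])
    out
  })
}

#' Detect synergy in a double-knockout outcome
#'
#' A pair is synergistic when it changes at least one phenotype that
#' neither single knockout changes: an emergent effect absent from both
#' monotherapies.
#'
#' @param pair_outcome `perturbation_outcome` of the double knockout.
#' @param single_a,single_b outcomes of the two single knockouts.
#' @return list with `synergy` (logical) and `phenotypes` (character
#'   vector of emergent-change phenotypes).
#' @export
detect_synergy <- function(pair_outcome, single_a, single_b) {
  phen <- names(pair_outcome$phenotype_delta)
  if (!setequal(phen, names(single_a$phenotype_delta)) ||
      !setequal(phen, names(single_b$phenotype_delta))) {
    stop("outcomes do not share the same phenotype set")
  }
  emergent <- phen[
    pair_outcome$phenotype_delta[phen] != "unchanged" &
    single_a$phenotype_delta[phen] == "unchanged" &
    single_b$phenotype_delta[phen] == "unchanged"
  ]
  list(synergy = length(emergent) > 0L, phenotypes = emergent)
}
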