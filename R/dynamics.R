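## Synchronous Boolean dynamics and exhaustive steady-state enumeration.
##
## States are named integer vectors (0/1) in model node order. Clamps hold
## a node at a constant value throughout a simulation: fixed inputs and
## knocked-out nodes are both expressed as clamps.

## validate + coerce a state to the model's node order
as_state <- function(model, state) {
  if (is.null(names(state))) {
    if (length(state) != length(model$nodes)) {
      stop("unnamed state of wrong length")
    }
    names(state) <- model$nodes
  }
  missing <- setdiff(model$nodes, names(state))
  if (length(missing)) {
    stop("state is missing node(s): ", paste(missing, collapse = ", "))
  }
  s <- as.integer(state[model$nodes])
  if (any(is.na(s) | !(s %in% c(0L, 1L)))) stop("state values must be 0 or 1")
  setNames(s, model$nodes)
}

check_clamps <- function(model, clamps) {
  if (is.null(clamps) || !length(clamps)) return(setNames(integer(0), character(0)))
  bad <- setdiff(names(clamps), model$nodes)
  if (length(bad)) stop("clamp on unknown node(s): ", paste(bad, collapse = ", "))
  v <- as.integer(clamps)
  if (any(is.na(v) | !(v %in% c(0L, 1L)))) stop("clamp values must be 0 or 1")
  setNames(v, names(clamps))
}

#' One synchronous update step
#'
#' Every unclamped rule-bearing node takes the value of its rule evaluated
#' on the current state; clamped nodes keep their clamp value; unclamped
#' inputs keep their current value (they have no rule).
#'
#' @param model a `boolean_model`.
#' @param state named 0/1 vector over all model nodes.
#' @param clamps optional named 0/1 vector of nodes held constant.
#' @return the successor state (named integer vector).
#' @export
sync_step <- function(model, state, clamps = NULL) {
  state <- as_state(model, state)
  clamps <- check_clamps(model, clamps)
  env <- as.list(state == 1L)
  nxt <- state
  for (n in names(model$rules)) {
    nxt[[n]] <- as.integer(isTRUE(eval(model$rules[[n]], env)))
  }
  if (length(clamps)) nxt[names(clamps)] <- clamps
  nxt
}

#' Simulate a synchronous trajectory until an attractor is reached
#'
#' Iterates [sync_step()] from `initial`, recording visited states, and
#' stops at the first revisited state. The recurrent segment is the
#' attractor: a steady state if its period is 1, a cycle otherwise. If no
#' state is revisited within `max_steps` the result is flagged as
#' non-converged and no attractor is reported.
#'
#' @param model a `boolean_model`.
#' @param initial named 0/1 vector over all nodes; clamped nodes are
#'   forced to their clamp value from step 0.
#' @param clamps optional named 0/1 vector of clamped nodes.
#' @param max_steps maximum number of update steps (>= 1).
#' @return list with `trajectory` (matrix, one row per visited state
#'   including the initial one), `attractor` (list with `states` matrix and
#'   `kind` = `"steady"` or `"cycle"`, or `NULL` if non-converged) and
#'   `converged` (logical).
#' @export
simulate_model <- function(model, initial, clamps = NULL, max_steps = 100L) {
  stopifnot(max_steps >= 1L)
  state <- as_state(model, initial)
  clamps <- check_clamps(model, clamps)
  if (length(clamps)) state[names(clamps)] <- clamps
  n <- length(model$nodes)
  traj <- matrix(NA_integer_, nrow = max_steps + 1L, ncol = n,
                 dimnames = list(NULL, model$nodes))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- paste(state, collapse = "")
  traj[1L, ] <- state
  assign(key, 1L, envir = seen)
  for (step in seq_len(max_steps)) {
    state <- sync_step(model, state, clamps)
    key <- paste(state, collapse = "")
    first <- seen[[key]]
    if (!is.null(first)) {
      traj <- traj[seq_len(step), , drop = FALSE]
      att_states <- traj[seq(first, step), , drop = FALSE]
      return(list(
        trajectory = traj,
        attractor = list(
          states = att_states,
          kind = if (nrow(att_states) == 1L) "steady" else "cycle"
        ),
        converged = TRUE
      ))
    }
    traj[step + 1L, ] <- state
    assign(key, step + 1L, envir = seen)
  }
  list(trajectory = traj, attractor = NULL, converged = FALSE)
}

## Three-valued (Kleene) evaluation of a rule; vals is a named integer
## vector with NA for undetermined nodes.
eval3 <- function(e, vals) {
  if (is.logical(e)) return(as.integer(e))
  if (is.symbol(e)) return(vals[[as.character(e)]])
  op <- as.character(e[[1]])
  if (op == "(") return(eval3(e[[2]], vals))
  if (op == "!") {
    v <- eval3(e[[2]], vals)
    return(if (is.na(v)) NA_integer_ else 1L - v)
  }
  if (op %in% c("&", "&&")) {
    a <- eval3(e[[2]], vals)
    if (!is.na(a) && a == 0L) return(0L)
    b <- eval3(e[[3]], vals)
    if (!is.na(b) && b == 0L) return(0L)
    if (!is.na(a) && !is.na(b)) return(1L)
    return(NA_integer_)
  }
  if (op %in% c("|", "||")) {
    a <- eval3(e[[2]], vals)
    if (!is.na(a) && a == 1L) return(1L)
    b <- eval3(e[[3]], vals)
    if (!is.na(b) && b == 1L) return(1L)
    if (!is.na(a) && !is.na(b)) return(0L)
    return(NA_integer_)
  }
  stop("unsupported operator in rule: ", op)
}

#' All fixpoints of a model under clamps
#'
#' Solves `x = f(x)` by branch-and-propagate: rules whose value is
#' determined under three-valued logic are propagated; on a contradiction
#' the branch is abandoned; otherwise an undetermined node is branched on
#' both values. A clamped node contributes only the constraint
#' `x = clamp` (the clamp overrides its rule during updates). Unclamped
#' inputs are unconstrained, so both of their values are explored.
#'
#' @param model a `boolean_model`.
#' @param clamps named 0/1 vector of clamped nodes.
#' @return integer matrix, one row per fixpoint (possibly zero rows),
#'   columns in model node order, rows sorted lexicographically.
#' @export
solve_fixpoints <- function(model, clamps = NULL) {
  clamps <- check_clamps(model, clamps)
  vals <- setNames(rep(NA_integer_, length(model$nodes)), model$nodes)
  vals[names(clamps)] <- clamps
  rule_nodes <- setdiff(names(model$rules), names(clamps))
  rules <- model$rules[rule_nodes]

  propagate <- function(vals) {
    repeat {
      changed <- FALSE
      for (n in rule_nodes) {
        v <- eval3(rules[[n]], vals)
        if (is.na(v)) next
        cur <- vals[[n]]
        if (is.na(cur)) {
          vals[[n]] <- v
          changed <- TRUE
        } else if (cur != v) {
          return(NULL)  # contradiction: not a fixpoint on this branch
        }
      }
      if (!changed) return(vals)
    }
  }

  solutions <- list()
  recurse <- function(vals) {
    vals <- propagate(vals)
    if (is.null(vals)) return(invisible())
    und <- names(vals)[is.na(vals)]
    if (!length(und)) {
      solutions[[length(solutions) + 1L]] <<- vals
      return(invisible())
    }
    # branch on the first undetermined rule-bearing node if any (their
    # assignments constrain others); otherwise on an undetermined input
    pick <- und[und %in% rule_nodes][1]
    if (is.na(pick)) pick <- und[1]
    for (v in c(0L, 1L)) {
      trial <- vals
      trial[[pick]] <- v
      recurse(trial)
    }
    invisible()
  }
  recurse(vals)
  out <- if (length(solutions)) do.call(rbind, solutions) else
    matrix(integer(0), nrow = 0, ncol = length(model$nodes))
  colnames(out) <- model$nodes
  if (nrow(out) > 1L) {
    keys <- apply(out, 1L, paste, collapse = "")
    out <- out[order(keys), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Enumerate steady states over all free-input combinations
#'
#' Iterates every assignment of the free inputs (in lexicographic order,
#' free inputs sorted by node identifier) and, for each combination,
#' returns all fixpoints `x = f(x)` consistent with the clamps, found by
#' [solve_fixpoints()]. Reducing the free-input set by fixing
#' differentially expressed inputs beforehand is how large models are made
#' tractable.
#'
#' @param model a `boolean_model`.
#' @param fixed_inputs named 0/1 vector of inputs (or other nodes) held
#'   constant across all combinations.
#' @param free_inputs character vector of input nodes to enumerate over;
#'   defaults to all inputs not in `fixed_inputs`.
#' @param cap refuse to enumerate more than `2^cap` combinations
#'   (default 24); fix more inputs or shard via `range` instead.
#' @param range optional integer vector `c(from, to)` (0-based, half-open)
#'   selecting a slice of the combination index space for sharded runs.
#' @return named list: one element per input combination (name = the 0/1
#'   assignment string over the sorted free inputs), each an integer matrix
#'   of steady states (rows, possibly zero) over all model nodes.
#' @export
enumerate_steady_states <- function(model, fixed_inputs = NULL,
                                    free_inputs = NULL, cap = 24L,
                                    range = NULL) {
  fixed_inputs <- check_clamps(model, fixed_inputs)
  if (is.null(free_inputs)) {
    free_inputs <- setdiff(model$inputs, names(fixed_inputs))
  }
  if (length(intersect(free_inputs, names(fixed_inputs)))) {
    stop("free_inputs overlap fixed_inputs")
  }
  bad <- setdiff(free_inputs, model$inputs)
  if (length(bad)) {
    stop("free_inputs must be model inputs; not inputs: ",
         paste(bad, collapse = ", "))
  }
  free_inputs <- sort(free_inputs)
  k <- length(free_inputs)
  if (k > cap) {
    stop("refusing to enumerate 2^", k, " input combinations (cap 2^", cap,
         "); fix more inputs or shard with `range`")
  }
  n_combo <- 2^k
  idx <- seq_len(n_combo) - 1
  if (!is.null(range)) {
    stopifnot(length(range) == 2, range[1] >= 0, range[2] <= n_combo)
    idx <- idx[idx >= range[1] & idx < range[2]]
  }
  out <- vector("list", length(idx))
  keys <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    # lexicographic order over assignment tuples: first input varies slowest
    bits <- integer(k)
    rem <- i
    for (b in seq_len(k)) {
      bits[k - b + 1L] <- rem %% 2
      rem <- rem %/% 2
    }
    combo <- setNames(as.integer(bits), free_inputs)
    keys[j] <- paste(bits, collapse = "")
    out[[j]] <- solve_fixpoints(model, c(fixed_inputs, combo))
  }
  names(out) <- keys
  out
}

#' Activity levels over the tail of a trajectory
#'
#' Per-node fraction of active steps among the last `min(window, length)`
#' steps of a trajectory, matching the sliding-window activity display of
#' interactive simulation platforms: a node active 20 of the last 100
#' steps under a window of 100 has activity 0.20 (20%).
#'
#' @param trajectory state matrix (rows = steps, columns = nodes).
#' @param window sliding-window length in steps (>= 1).
#' @return named numeric vector of activities in `[0, 1]`.
#' @export
activity_levels <- function(trajectory, window) {
  if (is.null(dim(trajectory)) || nrow(trajectory) < 1L) {
    stop("empty trajectory")
  }
  stopifnot(window >= 1L)
  w <- min(window, nrow(trajectory))
  tail_rows <- trajectory[seq(nrow(trajectory) - w + 1L, nrow(trajectory)),
                          , drop = FALSE]
  colMeans(tail_rows)
}
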