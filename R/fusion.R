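## Model fusion: evidence-filtered intercellular interactions wire the
## cell-specific models into one multi-cellular model.
##
## The interaction table is long-format: one row per evidence record, with
## an interaction identified by the 4-tuple (sender_celltype, ligand,
## receiver_celltype, receptor). Approaches are "literature",
## "cellphonedb" (database mining) or "icellnet"/"disir" (omics
## inference); omics records carry the pair of datasets they were
## inferred from.

OMICS_APPROACHES <- c("icellnet", "disir")

interaction_key <- function(tbl) {
  paste(tbl$sender_celltype, tbl$ligand, tbl$receiver_celltype, tbl$receptor,
        sep = "\r")
}

#' Filter candidate intercellular interactions by evidence
#'
#' Keeps the interactions identified with at least two different pairs of
#' datasets (across omics evidence) or at least two different approaches;
#' everything else is dropped. Row order is preserved.
#'
#' @param candidates data.frame with columns `sender_celltype`, `ligand`,
#'   `receiver_celltype`, `receptor`, `approach` and optionally
#'   `dataset_a`, `dataset_b` (required, non-empty, for omics approaches).
#' @return the kept rows of `candidates` (all evidence rows of kept
#'   interactions).
#' @export
filter_lr_evidence <- function(candidates) {
  req <- c("sender_celltype", "ligand", "receiver_celltype", "receptor",
           "approach")
  stopifnot(all(req %in% names(candidates)))
  if (any(candidates$ligand == "" | candidates$receptor == "")) {
    stop("ligand and receptor symbols must be non-empty")
  }
  appr <- tolower(as.character(candidates$approach))
  da <- if ("dataset_a" %in% names(candidates)) as.character(candidates$dataset_a) else
    rep("", nrow(candidates))
  db <- if ("dataset_b" %in% names(candidates)) as.character(candidates$dataset_b) else
    rep("", nrow(candidates))
  da[is.na(da)] <- ""
  db[is.na(db)] <- ""
  omics <- appr %in% OMICS_APPROACHES
  if (any(omics & (da == "" | db == ""))) {
    stop("omics evidence (icellnet/disir) must carry a dataset pair")
  }
  pair <- ifelse(omics, paste(da, db, sep = "|"), NA_character_)
  key <- interaction_key(candidates)
  keep_key <- vapply(unique(key), function(k) {
    i <- key == k
    n_pairs <- length(unique(stats::na.omit(pair[i])))
    n_appr <- length(unique(appr[i]))
    n_pairs >= 2L || n_appr >= 2L
  }, logical(1))
  candidates[key %in% names(keep_key)[keep_key], , drop = FALSE]
}

#' Fuse cell-specific Boolean models via intercellular interactions
#'
#' Namespaces every node as `celltype::node` and takes the disjoint union
#' of the models; then, for each interaction, adds the sender's ligand
#' node as an activating regulator of the receiver's receptor node. The
#' ligand term is combined with the receptor's existing rule by OR (the
#' ligand-transport/binding semantics imply activation; `combine = "and"`
#' requires ligand and prior activation together). A receptor that was an
#' input gains a rule and ceases to be an input. Ligand and receptor
#' symbols are resolved within their cell's namespace: exact node id,
#' then annotation, then display name; ambiguity is an error.
#'
#' @param models named list of `boolean_model`s, names = cell-type labels.
#' @param interactions optional interaction data.frame (see
#'   [filter_lr_evidence()]); evidence columns are ignored here and
#'   duplicate 4-tuples are wired once.
#' @param combine how a new ligand regulator joins an existing rule,
#'   `"or"` (default) or `"and"`.
#' @return a `boolean_model` with an extra element `wired`: data.frame of
#'   the namespaced (ligand, receptor) pairs that were added.
#' @export
merge_models <- function(models, interactions = NULL, combine = c("or", "and")) {
  combine <- match.arg(combine)
  stopifnot(is.list(models), length(models) >= 1L, !is.null(names(models)))
  ns_models <- list()
  for (ct in names(models)) {
    m <- models[[ct]]
    stopifnot(inherits(m, "boolean_model"))
    map <- setNames(paste0(ct, "::", m$nodes), m$nodes)
    ns_models[[ct]] <- list(
      orig = m,
      map = map,
      nodes = unname(map),
      rules = setNames(
        lapply(m$rules, rule_substitute, map = as.list(map)),
        map[names(m$rules)]
      ),
      phenotypes = setNames(m$phenotypes, map[names(m$phenotypes)]),
      annotations = setNames(m$annotations, map[names(m$annotations)]),
      labels = setNames(m$labels, map[names(m$labels)]),
      celltype = setNames(rep(ct, length(m$nodes)), unname(map))
    )
  }

  wired <- data.frame(ligand = character(0), receptor = character(0),
                      stringsAsFactors = FALSE)
  new_regs <- list()  # namespaced receptor -> namespaced ligand nodes
  if (!is.null(interactions) && nrow(interactions)) {
    uniq <- interactions[!duplicated(interaction_key(interactions)), ,
                         drop = FALSE]
    for (i in seq_len(nrow(uniq))) {
      s_ct <- as.character(uniq$sender_celltype[i])
      r_ct <- as.character(uniq$receiver_celltype[i])
      for (ct in c(s_ct, r_ct)) {
        if (!(ct %in% names(models))) stop("unknown cell type '", ct, "'")
      }
      lig <- resolve_in_cell(ns_models[[s_ct]], as.character(uniq$ligand[i]))
      rec <- resolve_in_cell(ns_models[[r_ct]], as.character(uniq$receptor[i]))
      new_regs[[rec]] <- unique(c(new_regs[[rec]], lig))
      wired <- rbind(wired, data.frame(ligand = lig, receptor = rec,
                                       stringsAsFactors = FALSE))
    }
  }

  nodes <- unlist(lapply(ns_models, `[[`, "nodes"), use.names = FALSE)
  rules <- do.call(c, unname(lapply(ns_models, `[[`, "rules")))
  for (rec in names(new_regs)) {
    lig_expr <- Reduce(function(a, b) call("|", a, b),
                       lapply(new_regs[[rec]], as.symbol))
    old <- rules[[rec]]
    rules[[rec]] <- if (is.null(old)) lig_expr else {
      op <- if (combine == "or") "|" else "&"
      call(op, call("(", old), call("(", lig_expr))
    }
  }
  merged <- boolean_model(
    nodes = nodes,
    rules = rules,
    phenotypes = do.call(c, unname(lapply(ns_models, `[[`, "phenotypes"))),
    celltype = do.call(c, unname(lapply(ns_models, `[[`, "celltype"))),
    annotations = do.call(c, unname(lapply(ns_models, `[[`, "annotations"))),
    labels = do.call(c, unname(lapply(ns_models, `[[`, "labels")))
  )
  merged$wired <- wired
  merged
}

## resolve a ligand/receptor symbol inside one namespaced cell model
resolve_in_cell <- function(nsm, symbol) {
  m <- nsm$orig
  hit <- resolve_symbol(m, symbol, multiple = TRUE)
  if (!length(hit)) {
    cand <- utils::head(sort(unique(c(
      m$nodes[startsWith(tolower(m$nodes), tolower(substr(symbol, 1, 2)))],
      unlist(m$annotations, use.names = FALSE)))), 5L)
    stop("symbol '", symbol, "' does not resolve in cell model; candidates: ",
         paste(cand, collapse = ", "))
  }
  if (length(hit) > 1L) {
    stop("ambiguous symbol '", symbol, "' in cell model: matches ",
         paste(hit, collapse = ", "))
  }
  unname(nsm$map[hit])
}

#' Combine cell-specific calibrated states on the merged model
#'
#' Takes the union of the per-cell calibrated assignments on namespaced
#' nodes. Fixed nodes carry their 0/1 value; free nodes are `NA` (FREE).
#' Any receptor that gained a new ligand regulator during merging is reset
#' to FREE so that its value is re-determined by attractor search on the
#' fused model. Nodes absent from all cell states are FREE.
#'
#' @param cell_states named list of `calibrated_state`s, names = cell-type
#'   labels matching those used in [merge_models()].
#' @param merged the merged `boolean_model` (with its `wired` element).
#' @return object of class `partial_state`: named numeric vector over all
#'   merged-model nodes with values 0, 1 or `NA` (FREE).
#' @export
combine_calibrated_states <- function(cell_states, merged) {
  stopifnot(inherits(merged, "boolean_model"))
  ps <- setNames(rep(NA_real_, length(merged$nodes)), merged$nodes)
  for (ct in names(cell_states)) {
    cs <- cell_states[[ct]]
    stopifnot(inherits(cs, "calibrated_state"))
    nms <- paste0(ct, "::", names(cs$mean))
    missing <- setdiff(nms, merged$nodes)
    if (length(missing)) {
      stop("calibrated nodes absent from merged model: ",
           paste(missing, collapse = ", "))
    }
    vals <- ifelse(names(cs$mean) %in% cs$fixed, cs$mean, NA_real_)
    clash <- !is.na(ps[nms]) & !is.na(vals) & ps[nms] != vals
    if (any(clash)) {
      stop("conflicting assignments for node(s): ",
           paste(nms[clash], collapse = ", "))
    }
    ps[nms] <- ifelse(is.na(vals), ps[nms], vals)
  }
  if (!is.null(merged$wired) && nrow(merged$wired)) {
    ps[unique(merged$wired$receptor)] <- NA_real_
  }
  structure(ps, class = "partial_state")
}

#' @export
print.partial_state <- function(x, ...) {
  cat("Partial state: ", sum(!is.na(x)), " fixed, ", sum(is.na(x)),
      " FREE of ", length(x), " nodes\n", sep = "")
  invisible(x)
}

#' Input-fixing accounting for a combined model state
#'
#' Book-keeps how many model inputs are fixed by the combination of the
#' cell-specific calibrated states, how many additional inputs a
#' literature/expression table fixes, and how many remain free for
#' enumeration.
#'
#' @param model the merged `boolean_model`.
#' @param state a `partial_state` from [combine_calibrated_states()].
#' @param literature optional named 0/1 vector of additional input fixes
#'   (entries for already-fixed or non-input nodes are ignored).
#' @return list with the updated `state`, `n_inputs`,
#'   `n_fixed_combination`, `n_fixed_literature`, `n_fixed_total`,
#'   `n_free` and `free_inputs`.
#' @export
fix_inputs <- function(model, state, literature = NULL) {
  inputs <- model$inputs
  n_comb <- sum(!is.na(state[inputs]))
  n_lit <- 0L
  if (!is.null(literature) && length(literature)) {
    lit <- literature[intersect(names(literature), inputs)]
    lit <- lit[is.na(state[names(lit)])]
    state[names(lit)] <- as.numeric(lit)
    n_lit <- length(lit)
  }
  free <- inputs[is.na(state[inputs])]
  list(
    state = state,
    n_inputs = length(inputs),
    n_fixed_combination = n_comb,
    n_fixed_literature = n_lit,
    n_fixed_total = n_comb + n_lit,
    n_free = length(free),
    free_inputs = free
  )
}
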