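## Seeded synthetic-data generator.
##
## Random Boolean models with a planted steady state stand in for the
## curated cell-specific disease maps; noisy partial observations of the
## planted state stand in for discretized differential-expression lists;
## toy intercellular and target tables stand in for ligand-receptor and
## therapeutic-target mining. Everything is reproducible from an integer
## seed.

#' Synthetic model specification
#'
#' @param n_nodes total number of nodes.
#' @param n_inputs number of input nodes (no upstream regulation).
#' @param n_phenotypes number of phenotype nodes (sinks).
#' @param max_indegree maximum regulators per rule.
#' @param feedback_p probability of adding one feedback regulator to an
#'   internal node (creates cycles, so that non-steady attractors exist
#'   and get filtered, as in real model analysis).
#' @param coverage fraction of non-input nodes covered by a generated
#'   observed profile.
#' @param flip_rate per-entry probability that a profile observation is
#'   flipped (noise).
#' @param seed integer RNG seed; identical specs generate identical data.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_nodes = 12L, n_inputs = 3L, n_phenotypes = 2L,
                       max_indegree = 3L, feedback_p = 0.1,
                       coverage = 1.0, flip_rate = 0.0, seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1, flip_rate >= 0, flip_rate <= 1,
            max_indegree >= 1, n_phenotypes >= 0)
  if (n_inputs + n_phenotypes > n_nodes) {
    stop("n_inputs + n_phenotypes must not exceed n_nodes")
  }
  if (n_inputs >= n_nodes) stop("need at least one non-input node")
  structure(list(
    n_nodes = as.integer(n_nodes), n_inputs = as.integer(n_inputs),
    n_phenotypes = as.integer(n_phenotypes),
    max_indegree = as.integer(max_indegree), feedback_p = feedback_p,
    coverage = coverage, flip_rate = flip_rate, seed = as.integer(seed)
  ), class = "synth_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

## truth table (outputs over 2^k rows, regulator 1 = least-significant bit)
## to a DNF expression
tt_to_expr <- function(regs, outputs) {
  k <- length(regs)
  ones <- which(outputs == 1L) - 1L
  if (!length(ones)) return(FALSE)
  if (length(ones) == 2^k) return(TRUE)
  minterm <- function(row) {
    lits <- lapply(seq_len(k), function(j) {
      bit <- (row %/% 2^(j - 1L)) %% 2L
      if (bit == 1L) as.symbol(regs[j]) else call("!", as.symbol(regs[j]))
    })
    Reduce(function(a, b) call("&", a, b), lits)
  }
  terms <- lapply(ones, minterm)
  Reduce(function(a, b) call("|", call("(", a), call("(", b)), terms)
}

tt_row_index <- function(regs, state) {
  sum(state[regs] * 2^(seq_along(regs) - 1L)) + 1L
}

#' Generate a random Boolean model with a planted steady state
#'
#' Wires a random DAG (inputs first, then internal nodes, phenotype nodes
#' as sinks) with per-node indegree at most `max_indegree`, optionally
#' adds feedback edges, draws each rule as a random Boolean function of
#' its regulators, and then adjusts each rule's output on the planted row
#' only, so that the planted state is a fixpoint when inputs are clamped
#' to their planted values. Rule randomness is preserved everywhere else.
#'
#' @param spec a [synth_spec()].
#' @return list with `model` (a `boolean_model`) and `planted` (named 0/1
#'   vector, a steady state of the model under planted input clamps).
#' @export
gen_model <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_nodes
    n_in <- spec$n_inputs
    n_ph <- spec$n_phenotypes
    n_int <- n - n_in - n_ph
    inputs <- sprintf("I%02d", seq_len(n_in))
    internal <- if (n_int > 0) sprintf("V%02d", seq_len(n_int)) else character(0)
    phen <- if (n_ph > 0) sprintf("P%02d", seq_len(n_ph)) else character(0)
    nodes <- c(inputs, internal, phen)
    nonphen <- c(inputs, internal)

    regs <- list()
    for (j in seq_along(internal)) {
      pool <- nonphen[seq_len(n_in + j - 1L)]  # earlier non-phenotype nodes
      k <- sample.int(min(spec$max_indegree, length(pool)), 1L)
      r <- sample(pool, k)
      # feedback: one regulator from a later internal node
      later <- internal[internal > internal[j]]
      if (length(later) && length(r) < spec$max_indegree &&
          stats::runif(1) < spec$feedback_p) {
        r <- c(r, sample(later, 1L))
      }
      regs[[internal[j]]] <- r
    }
    for (p in phen) {
      k <- sample.int(min(spec$max_indegree, length(nonphen)), 1L)
      regs[[p]] <- sample(nonphen, k)
    }

    planted <- setNames(sample(0:1, n, replace = TRUE), nodes)
    rules <- list()
    for (tgt in names(regs)) {
      r <- regs[[tgt]]
      outputs <- sample(0:1, 2^length(r), replace = TRUE)
      outputs[tt_row_index(r, planted)] <- planted[[tgt]]  # plant the fixpoint
      rules[[tgt]] <- tt_to_expr(r, outputs)
    }
    ann <- setNames(as.list(paste0("g", nodes)), nodes)
    model <- boolean_model(
      nodes = nodes, rules = rules,
      phenotypes = setNames(rep("cell_specific", length(phen)), phen),
      annotations = ann,
      labels = setNames(tolower(nodes), nodes)
    )
    list(model = model, planted = planted)
  })
}

#' Generate an observed profile from a planted state
#'
#' Samples `ceiling(coverage * #non-input nodes)` non-input nodes without
#' replacement and reports the planted value of each, independently
#' flipped with probability `flip_rate` — emulating a discretized
#' differential-expression list with controllable coverage and noise.
#'
#' @param planted named 0/1 state vector (the answer key).
#' @param model the matching `boolean_model`.
#' @param spec a [synth_spec()] supplying `coverage`, `flip_rate` and
#'   `seed`.
#' @param seed optional RNG seed overriding `spec$seed` (so several
#'   profiles can be drawn from one planted state).
#' @return an `observed_profile`.
#' @export
gen_profile <- function(planted, model, spec, seed = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  pool <- setdiff(model$nodes, model$inputs)
  n_obs <- ceiling(spec$coverage * length(pool))
  if (n_obs == 0L) stop("coverage produces an empty profile")
  with_seed(if (is.null(seed)) spec$seed + 1L else seed, {
    covered <- sort(sample(pool, n_obs))
    vals <- planted[covered]
    flip <- stats::runif(n_obs) < spec$flip_rate
    vals[flip] <- 1L - vals[flip]
    structure(list(
      values = setNames(as.integer(vals), covered),
      provenance = setNames(rep("dataset", n_obs), covered)
    ), class = "observed_profile")
  })
}

#' Generate a multi-cellular test fixture
#'
#' Builds `n_cells` planted cell-specific models, an intercellular
#' interaction table wiring random internal (ligand) nodes of one cell to
#' input (receptor) nodes of another — each interaction carrying one to
#' three synthetic evidence records, with both single-evidence
#' (filtered out) and multi-evidence (kept) interactions present — plus
#' per-cell observed profiles and a therapeutic-target table mixing
#' mappable inhibitors, unmappable inhibitors and non-inhibitors.
#'
#' @param n_cells number of cell-specific models (cell types are labelled
#'   `M1`, `Fib`, `Th1`, `M2`, then `cell5`, ...).
#' @param spec a [synth_spec()] for the per-cell models (per-cell seeds
#'   are derived from `spec$seed`).
#' @param n_interactions number of directed ligand-receptor interactions.
#' @return list with `models` (named list), `interactions` (evidence
#'   table), `profiles` (named list of `observed_profile`s), `targets`
#'   (data.frame with `symbol`, `moa`, `drug`, `status`), `planted`
#'   (named list of planted states) and `spec`.
#' @export
gen_multicell_fixture <- function(n_cells = 2L, spec = synth_spec(),
                                  n_interactions = 2L) {
  labels <- c("M1", "Fib", "Th1", "M2")
  cts <- if (n_cells <= length(labels)) labels[seq_len(n_cells)] else
    c(labels, sprintf("cell%d", seq(length(labels) + 1L, n_cells)))
  models <- list()
  planted <- list()
  profiles <- list()
  for (i in seq_len(n_cells)) {
    s <- spec
    s$seed <- spec$seed + 1000L * i
    gm <- gen_model(s)
    models[[cts[i]]] <- gm$model
    planted[[cts[i]]] <- gm$planted
    profiles[[cts[i]]] <- gen_profile(gm$planted, gm$model, s)
  }

  interactions <- with_seed(spec$seed + 7L, {
    rows <- list()
    datasets <- c("DSA", "DSB", "DSC")
    used_receptors <- character(0)
    for (j in seq_len(n_interactions)) {
      s_ct <- cts[((j - 1L) %% n_cells) + 1L]
      r_ct <- cts[(j %% n_cells) + 1L]
      lig_pool <- setdiff(models[[s_ct]]$nodes,
                          c(models[[s_ct]]$inputs,
                            names(models[[s_ct]]$phenotypes)))
      taken <- sub("^.*::", "", used_receptors[startsWith(used_receptors,
                                                          paste0(r_ct, "::"))])
      rec_pool <- setdiff(models[[r_ct]]$inputs, taken)
      if (!length(rec_pool)) rec_pool <- models[[r_ct]]$inputs
      lig <- sample(lig_pool, 1L)
      rec <- sample(rec_pool, 1L)
      used_receptors <- c(used_receptors, paste0(r_ct, "::", rec))
      # alternate single-evidence (dropped by the filter) and
      # multi-evidence (kept) interactions
      if (j %% 2L == 1L) {
        ev <- data.frame(approach = "literature",
                         dataset_a = "", dataset_b = "",
                         stringsAsFactors = FALSE)
      } else {
        n_ev <- sample(2:3, 1L)
        appr <- sample(c("icellnet", "disir"), n_ev, replace = TRUE)
        ev <- data.frame(
          approach = appr,
          dataset_a = sample(datasets, n_ev, replace = TRUE),
          dataset_b = sample(datasets, n_ev, replace = TRUE),
          stringsAsFactors = FALSE
        )
        # guarantee >= 2 distinct approaches or dataset pairs
        if (length(unique(appr)) < 2L) {
          ev$dataset_a[1:2] <- datasets[1:2]
          ev$dataset_b[1:2] <- datasets[2:1]
        }
      }
      ev$sender_celltype <- s_ct
      ev$ligand <- lig
      ev$receiver_celltype <- r_ct
      ev$receptor <- rec
      rows[[j]] <- ev
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(sender_celltype = character(0), ligand = character(0),
                 receiver_celltype = character(0), receptor = character(0),
                 approach = character(0), dataset_a = character(0),
                 dataset_b = character(0), stringsAsFactors = FALSE)
  })

  targets <- with_seed(spec$seed + 13L, {
    mappable <- unique(unlist(lapply(models, function(m) {
      setdiff(m$nodes, c(m$inputs, names(m$phenotypes)))
    })))
    n_map <- min(4L, length(mappable))
    data.frame(
      symbol = c(sample(mappable, n_map), "FAKE1", "FAKE2", "AGON1"),
      moa = c(rep("Inhibitor", n_map + 2L), "Agonist"),
      drug = sprintf("drug%d", seq_len(n_map + 3L)),
      status = "Investigative",
      stringsAsFactors = FALSE
    )
  })

  list(models = models, interactions = interactions, profiles = profiles,
       targets = targets, planted = planted, spec = spec)
}
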