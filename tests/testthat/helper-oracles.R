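# Independent oracles and tiny fixtures used across the suite.

# Brute-force fixpoint enumeration: scan all 2^n states consistent with
# the clamps and keep those with sync_step(s) == s. Vectorized over the
# whole state space; independent of the branch-and-propagate solver.
brute_force_fixpoints <- function(model, clamps = NULL) {
  n <- length(model$nodes)
  grid <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- model$nodes
  if (length(clamps)) {
    keep <- rep(TRUE, nrow(grid))
    for (nm in names(clamps)) keep <- keep & grid[, nm] == clamps[[nm]]
    grid <- grid[keep, , drop = FALSE]
  }
  if (!nrow(grid)) return(grid)
  env <- as.data.frame(grid == 1, optional = TRUE)
  nxt <- grid
  for (nm in names(model$rules)) {
    v <- eval(model$rules[[nm]], env)
    nxt[, nm] <- as.integer(rep(v, length.out = nrow(grid)))
  }
  if (length(clamps)) {
    for (nm in names(clamps)) nxt[, nm] <- clamps[[nm]]
  }
  fix <- rowSums(nxt != grid) == 0
  out <- grid[fix, , drop = FALSE]
  if (nrow(out) > 1L) {
    out <- out[order(apply(out, 1L, paste, collapse = "")), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Rule equivalence by truth table over the union of the two rules'
# regulators (node order independent).
rules_equivalent <- function(r1, r2) {
  regs <- union(mcboolnet:::rule_regulators(r1), mcboolnet:::rule_regulators(r2))
  if (!length(regs)) {
    return(isTRUE(eval(r1, list())) == isTRUE(eval(r2, list())))
  }
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(regs)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- regs
  for (i in seq_len(nrow(grid))) {
    env <- as.list(grid[i, , drop = FALSE])
    if (isTRUE(eval(r1, env)) != isTRUE(eval(r2, env))) return(FALSE)
  }
  TRUE
}

models_equivalent <- function(m1, m2) {
  if (!setequal(m1$nodes, m2$nodes)) return(FALSE)
  if (!setequal(m1$inputs, m2$inputs)) return(FALSE)
  if (!setequal(names(m1$rules), names(m2$rules))) return(FALSE)
  all(vapply(names(m1$rules), function(n) {
    rules_equivalent(m1$rules[[n]], m2$rules[[n]])
  }, logical(1)))
}

# Tiny hand-built signalling cascade: ligand -> receptor -> kinase ->
# phenotype, with an apoptosis branch repressed by the kinase.
toy_cascade <- function() {
  boolean_model(
    nodes = c("LIG", "REC", "KIN", "PROLIF", "APOP"),
    rules = list(
      REC = quote(LIG),
      KIN = quote(REC),
      PROLIF = quote(KIN),
      APOP = quote(!KIN)
    ),
    phenotypes = c(PROLIF = "cell_specific", APOP = "cell_specific"),
    annotations = list(LIG = "gLIG", REC = "gREC", KIN = "gKIN"),
    labels = c(LIG = "ligand", REC = "receptor", KIN = "kinase")
  )
}

make_outcome <- function(delta, targets = "T") {
  structure(list(
    targets = targets,
    phenotype_delta = delta,
    phenotype_state = setNames(rep(0L, length(delta)), names(delta)),
    reference_state = setNames(rep(0L, length(delta)), names(delta)),
    converged = TRUE,
    attractor_kind = "steady",
    effective = any(delta != "unchanged")
  ), class = "perturbation_outcome")
}
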