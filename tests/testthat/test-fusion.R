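lr_row <- function(sender = "M1", ligand = "LIG", receiver = "Fib",
                   receptor = "REC", approach = "literature",
                   dataset_a = "", dataset_b = "") {
  data.frame(sender_celltype = sender, ligand = ligand,
             receiver_celltype = receiver, receptor = receptor,
             approach = approach, dataset_a = dataset_a,
             dataset_b = dataset_b, stringsAsFactors = FALSE)
}

test_that("evidence filter keeps >=2 dataset pairs or >=2 approaches", {
  # single literature record: dropped
  expect_equal(nrow(filter_lr_evidence(lr_row(approach = "literature"))), 0)

  # two different approaches on the same dataset pair: kept
  two_appr <- rbind(
    lr_row(approach = "icellnet", dataset_a = "SDY", dataset_b = "SDY"),
    lr_row(approach = "disir", dataset_a = "SDY", dataset_b = "SDY")
  )
  expect_equal(nrow(filter_lr_evidence(two_appr)), 2)

  # one approach, two different dataset pairs: kept
  two_pairs <- rbind(
    lr_row(approach = "icellnet", dataset_a = "SDY", dataset_b = "SDY"),
    lr_row(approach = "icellnet", dataset_a = "EMTAB", dataset_b = "SDY")
  )
  expect_equal(nrow(filter_lr_evidence(two_pairs)), 2)

  # one approach, one dataset pair seen twice: dropped
  one_pair <- rbind(
    lr_row(approach = "icellnet", dataset_a = "SDY", dataset_b = "SDY"),
    lr_row(approach = "icellnet", dataset_a = "SDY", dataset_b = "SDY")
  )
  expect_equal(nrow(filter_lr_evidence(one_pair)), 0)

  # omics evidence must carry its dataset pair
  expect_error(filter_lr_evidence(lr_row(approach = "disir")), "dataset pair")
  expect_error(filter_lr_evidence(lr_row(ligand = "")), "non-empty")
})

test_that("evidence filter is monotone in added evidence", {
  base <- rbind(
    lr_row(approach = "icellnet", dataset_a = "A", dataset_b = "B"),
    lr_row(approach = "disir", dataset_a = "A", dataset_b = "B")
  )
  expect_equal(nrow(filter_lr_evidence(base)), 2)
  for (extra in list(
    lr_row(approach = "literature"),
    lr_row(approach = "cellphonedb"),
    lr_row(approach = "icellnet", dataset_a = "C", dataset_b = "D")
  )) {
    grown <- rbind(base, extra)
    expect_equal(nrow(filter_lr_evidence(grown)), nrow(grown))
  }
})

test_that("merging with no interactions is a namespaced disjoint union", {
  a <- boolean_model(c("I", "X"), rules = list(X = quote(I)))
  b <- boolean_model(c("J", "Y"), rules = list(Y = quote(!J)))
  merged <- merge_models(list(M1 = a, Fib = b))
  expect_setequal(merged$nodes, c("M1::I", "M1::X", "Fib::J", "Fib::Y"))
  expect_setequal(merged$inputs, c("M1::I", "Fib::J"))
  s <- model_stats(merged)
  expect_equal(s$n_nodes, 4)
  expect_equal(s$n_interactions,
               model_stats(a)$n_interactions + model_stats(b)$n_interactions)
})

test_that("a wired receptor gains the ligand regulator and stops being an input", {
  a <- boolean_model(c("I", "L"), rules = list(L = quote(I)),
                     annotations = list(L = "gL"))
  b <- boolean_model(c("R", "Y"), rules = list(Y = quote(R)),
                     annotations = list(R = "gR"))
  tbl <- lr_row(sender = "M1", ligand = "gL", receiver = "Fib",
                receptor = "gR")
  merged <- merge_models(list(M1 = a, Fib = b), tbl)
  expect_equal(model_stats(merged)$n_nodes, 4)
  expect_equal(model_stats(merged)$n_interactions,
               model_stats(a)$n_interactions + model_stats(b)$n_interactions + 1)
  expect_false("Fib::R" %in% merged$inputs)
  expect_true(rules_equivalent(merged$rules[["Fib::R"]], quote(`M1::L`)))
  expect_equal(merged$wired$receptor, "Fib::R")

  # an already-regulated receptor keeps its rule, OR-extended
  c_ <- boolean_model(c("U", "R2"), rules = list(R2 = quote(U)),
                      annotations = list(R2 = "gR2"))
  merged2 <- merge_models(list(M1 = a, Fib = c_),
                          lr_row(ligand = "gL", receptor = "gR2"))
  expect_true(rules_equivalent(merged2$rules[["Fib::R2"]],
                               quote(`Fib::U` | `M1::L`)))
  merged3 <- merge_models(list(M1 = a, Fib = c_),
                          lr_row(ligand = "gL", receptor = "gR2"),
                          combine = "and")
  expect_true(rules_equivalent(merged3$rules[["Fib::R2"]],
                               quote(`Fib::U` & `M1::L`)))
})

test_that("merge resolution errors name the problem", {
  a <- boolean_model(c("I", "L"), rules = list(L = quote(I)))
  b <- boolean_model(c("R", "Y"), rules = list(Y = quote(R)))
  expect_error(merge_models(list(M1 = a, Fib = b),
                            lr_row(ligand = "NOPE", receptor = "R")),
               "does not resolve")
  expect_error(merge_models(list(M1 = a, Fib = b),
                            lr_row(sender = "Th1", ligand = "L",
                                   receptor = "R")),
               "unknown cell type")
})

test_that("merged node and interaction counts add up on synthetic fixtures", {
  for (seed in c(1, 2, 3)) {
    fx <- gen_multicell_fixture(
      n_cells = 3, n_interactions = 4,
      spec = synth_spec(n_nodes = 10, n_inputs = 3, n_phenotypes = 1,
                        seed = seed))
    merged <- merge_models(fx$models, fx$interactions)
    per <- lapply(fx$models, model_stats)
    expect_equal(model_stats(merged)$n_nodes,
                 sum(vapply(per, `[[`, numeric(1), "n_nodes")))
    n_wired <- nrow(merged$wired)
    expect_equal(model_stats(merged)$n_interactions,
                 sum(vapply(per, `[[`, numeric(1), "n_interactions")) + n_wired)
    # every wired receptor was an input, so the merged input count shrinks
    expect_equal(length(merged$inputs),
                 sum(vapply(fx$models, function(m) length(m$inputs),
                            numeric(1))) - length(unique(merged$wired$receptor)))
  }
})

cal_state <- function(mean, fixed = names(mean)[mean %in% c(0, 1)]) {
  structure(list(mean = mean, fixed = fixed,
                 free = setdiff(names(mean), fixed),
                 n_selected = 1L, best_score = 1,
                 reproduction_pct = 100), class = "calibrated_state")
}

test_that("combining calibrated states unions assignments and frees receptors", {
  a <- boolean_model(c("I", "L"), rules = list(L = quote(I)),
                     annotations = list(L = "gL"))
  b <- boolean_model(c("R", "Y"), rules = list(Y = quote(R)),
                     annotations = list(R = "gR"))

  # no interactions, fully fixed cell states: every namespaced node fixed
  merged0 <- merge_models(list(M1 = a, Fib = b))
  ps0 <- combine_calibrated_states(
    list(M1 = cal_state(c(I = 1, L = 1)), Fib = cal_state(c(R = 0, Y = 0))),
    merged0)
  expect_true(all(!is.na(ps0)))
  expect_equal(unname(ps0["Fib::R"]), 0)

  # the receptor was fixed at 0 in its cell state but gets wired: FREE again
  merged1 <- merge_models(list(M1 = a, Fib = b),
                          lr_row(ligand = "gL", receptor = "gR"))
  ps1 <- combine_calibrated_states(
    list(M1 = cal_state(c(I = 1, L = 1)), Fib = cal_state(c(R = 0, Y = 0))),
    merged1)
  expect_true(is.na(ps1[["Fib::R"]]))
  expect_equal(unname(ps1["Fib::Y"]), 0)

  # free cell-state nodes stay FREE
  ps2 <- combine_calibrated_states(
    list(M1 = cal_state(c(I = 1, L = 0.5), fixed = "I"),
         Fib = cal_state(c(R = 0, Y = 0))),
    merged0)
  expect_true(is.na(ps2[["M1::L"]]))
})

test_that("input-fixing accounting adds literature fixes to combination fixes", {
  m <- boolean_model(c("I1", "I2", "I3", "X"), rules = list(X = quote(I1)))
  ps <- structure(setNames(c(1, NA, NA, NA), m$nodes), class = "partial_state")
  acc <- fix_inputs(m, ps, literature = c(I2 = 0, I9 = 1, I1 = 0))
  expect_equal(acc$n_inputs, 3)
  expect_equal(acc$n_fixed_combination, 1)
  expect_equal(acc$n_fixed_literature, 1)  # I9 unknown, I1 already fixed
  expect_equal(acc$n_fixed_total, 2)
  expect_equal(acc$n_free, 1)
  expect_equal(acc$free_inputs, "I3")
  expect_equal(unname(acc$state["I1"]), 1)  # combination fix wins
})
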