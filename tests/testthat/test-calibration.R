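test_that("profiles discretize up/down and reject conflicts", {
  p <- discretize_profile(data.frame(node = "TNF", direction = "up"))
  expect_equal(p$values, c(TNF = 1L))

  expect_error(discretize_profile(
    data.frame(node = c("X", "X"), direction = c("up", "down"))),
    "conflicting")

  # duplicate consistent entries collapse
  p2 <- discretize_profile(
    data.frame(node = c("X", "X"), direction = c("up", "up")))
  expect_equal(p2$values, c(X = 1L))

  m <- toy_cascade()
  expect_error(discretize_profile(
    data.frame(node = "GHOST", direction = "up"), model = m),
    "does not resolve")
  expect_warning(p3 <- discretize_profile(
    data.frame(node = c("gKIN", "GHOST"), direction = c("up", "down")),
    model = m, lenient = TRUE), "skipped")
  expect_equal(p3$values, c(KIN = 1L))  # resolved via annotation
})

test_that("profiles generated from a planted state honour the contract", {
  spec <- synth_spec(n_nodes = 12, n_inputs = 3, n_phenotypes = 2,
                     coverage = 1, flip_rate = 0, seed = 3)
  gm <- gen_model(spec)
  prof <- gen_profile(gm$planted, gm$model, spec)
  nonin <- setdiff(gm$model$nodes, gm$model$inputs)
  expect_setequal(names(prof$values), nonin)
  expect_equal(prof$values[names(prof$values)],
               gm$planted[names(prof$values)])

  spec$flip_rate <- 1
  prof1 <- gen_profile(gm$planted, gm$model, spec)
  expect_equal(unname(prof1$values), unname(1L - gm$planted[names(prof1$values)]))

  spec$coverage <- 0
  expect_error(gen_profile(gm$planted, gm$model, spec), "empty profile")
})

test_that("flip noise hits at the requested binomial rate", {
  spec <- synth_spec(n_nodes = 53, n_inputs = 3, n_phenotypes = 0,
                     coverage = 1, flip_rate = 0.2, seed = 11)
  gm <- gen_model(spec)
  flipped <- vapply(1:100, function(s) {
    prof <- gen_profile(gm$planted, gm$model, spec, seed = 10000 + s)
    mean(prof$values != gm$planted[names(prof$values)])
  }, numeric(1))
  expect_gt(mean(flipped), 0.15)
  expect_lt(mean(flipped), 0.25)
})

test_that("phenotype filtering keeps exactly the matching states", {
  set.seed(99)
  states <- matrix(sample(0:1, 50 * 5, replace = TRUE), ncol = 5,
                   dimnames = list(NULL, c("A", "B", "Apop", "Prolif", "Migr")))
  cons <- c(Apop = 0, Prolif = 1, Migr = 1)
  kept <- phenotype_filter(states, cons)
  # independent scan
  want <- states[states[, "Apop"] == 0 & states[, "Prolif"] == 1 &
                 states[, "Migr"] == 1, , drop = FALSE]
  expect_identical(kept, want)

  expect_identical(phenotype_filter(states, c()), states)
  imposs <- matrix(c(1L, 1L), 1, dimnames = list(NULL, c("Apop", "Prolif")))
  expect_warning(phenotype_filter(imposs, c(Apop = 0)), "no steady state")
  expect_error(phenotype_filter(states, c(GHOST = 1)), "GHOST")
})

test_that("similarity score is the matched fraction of mapped profile nodes", {
  prof <- structure(list(values = c(A = 1L, B = 0L, C = 1L, D = 0L),
                         provenance = NULL), class = "observed_profile")
  s_all <- c(A = 1, B = 0, C = 1, D = 0, E = 1)
  expect_equal(similarity_score(s_all, prof), 1)
  s_three <- c(A = 1, B = 0, C = 1, D = 1, E = 0)
  expect_equal(similarity_score(s_three, prof), 0.75)
  s_none <- c(A = 0, B = 1, C = 0, D = 1)
  expect_equal(similarity_score(s_none, prof), 0)
  expect_error(similarity_score(c(Z = 1), prof), "no profile node")

  # invariant to profile row order and state node order
  perm <- structure(list(values = prof$values[c(3, 1, 4, 2)],
                         provenance = NULL), class = "observed_profile")
  expect_equal(similarity_score(s_three[c(5, 2, 4, 1, 3)], perm), 0.75)
})

test_that("calibration averages the tied top-scoring states", {
  prof <- structure(list(values = c(A = 1L, B = 0L), provenance = NULL),
                    class = "observed_profile")
  # all selected states identical: everything fixed, 100% of the profile
  same <- matrix(rep(c(1L, 0L, 1L), 3), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("A", "B", "Z")))
  cs <- calibrate(same, prof)
  expect_equal(length(cs$fixed), 3)
  expect_equal(cs$n_selected, 3)
  expect_equal(cs$best_score, 1)
  expect_equal(cs$reproduction_pct, 100)

  # two top states differing only in Z: Z free, the rest fixed
  two <- matrix(c(1L, 0L, 0L,
                  1L, 0L, 1L), nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B", "Z")))
  cs2 <- calibrate(two, prof)
  expect_setequal(cs2$fixed, c("A", "B"))
  expect_equal(cs2$free, "Z")
  expect_equal(unname(cs2$mean["Z"]), 0.5)
  expect_equal(cs2$reproduction_pct, 100)

  # a free node counts against reproduction of its observed value
  profz <- structure(list(values = c(A = 1L, Z = 1L), provenance = NULL),
                     class = "observed_profile")
  cs3 <- calibrate(two, profz)
  expect_equal(cs3$n_selected, 1)  # the (1,0,1) state scores 1, alone on top
  cs4 <- calibrate(rbind(two, two), profz)
  expect_equal(cs4$reproduction_pct, 100)
  expect_error(calibrate(two[0, , drop = FALSE], prof), "no states")
})

test_that("calibration recovers the planted state at zero noise", {
  for (seed in 1:20) {
    spec <- synth_spec(n_nodes = 10, n_inputs = 3, n_phenotypes = 1,
                       coverage = 1, flip_rate = 0, seed = seed)
    gm <- gen_model(spec)
    m <- gm$model
    prof <- gen_profile(gm$planted, m, spec)
    clamps <- input_clamps_from_profile(m, prof)
    clamps <- c(clamps, gm$planted[setdiff(m$inputs, names(clamps))])
    res <- enumerate_steady_states(m, fixed_inputs = clamps,
                                   free_inputs = character(0))
    states <- do.call(rbind, res)
    expect_gte(nrow(states), 1)
    scores <- apply(states, 1, function(s)
      similarity_score(setNames(s, m$nodes), prof))
    expect_equal(max(scores), 1)  # the planted state attains score 1
    cs <- calibrate(states, prof)
    expect_equal(cs$best_score, 1)
    # fixed nodes agree with the planted state wherever fixed
    expect_equal(cs$mean[cs$fixed], gm$planted[cs$fixed] + 0.0)
  }
})

test_that("expected best score degrades monotonically with flip noise", {
  mean_best <- function(flip) {
    mean(vapply(1:20, function(seed) {
      spec <- synth_spec(n_nodes = 10, n_inputs = 3, n_phenotypes = 1,
                         coverage = 1, flip_rate = flip, seed = seed)
      gm <- gen_model(spec)
      prof <- gen_profile(gm$planted, gm$model, spec)
      res <- enumerate_steady_states(gm$model,
                                     fixed_inputs = gm$planted[gm$model$inputs],
                                     free_inputs = character(0))
      states <- do.call(rbind, res)
      cs <- calibrate(states, prof)
      cs$best_score
    }, numeric(1)))
  }
  b0 <- mean_best(0)
  b1 <- mean_best(0.1)
  b3 <- mean_best(0.3)
  expect_gte(b0, b1)
  expect_gte(b1, b3)
})

test_that("input clamps follow the observed profile", {
  m <- boolean_model(c("I1", "I2", "I3", "X"),
                     rules = list(X = quote(I1 & I2)))
  prof <- structure(list(values = c(I1 = 1L, X = 0L), provenance = NULL),
                    class = "observed_profile")
  expect_equal(input_clamps_from_profile(m, prof), c(I1 = 1L))
  all_in <- input_clamps_from_profile(m, prof, default_one = TRUE)
  expect_equal(all_in[c("I1", "I2", "I3")], c(I1 = 1L, I2 = 1L, I3 = 1L))
})
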