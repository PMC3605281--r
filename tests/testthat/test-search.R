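# a scaffold + dataset whose ground truth is a known sub-model
planted_problem <- function(seed = 1, n = 5) {
  set.seed(seed)
  net <- random_dag_pkn(n, p_neg = 0.2)
  sc <- expand_gates(net, max_and_arity = 2)
  if (sc$n_gates < 3 || sc$n_gates > 12) return(planted_problem(seed + 100, n))
  true_bits <- as.integer(stats::runif(sc$n_gates) < 0.4)
  stim <- net$nodes[1]
  sigs <- net$nodes[length(net$nodes)]
  truth_fn <- function(tr) {
    s <- oracle_steady(sc, true_bits, stats::setNames(unname(tr[stim]), stim))
    v <- s$state[sigs]
    v[is.na(v)] <- 0.5
    v
  }
  d <- design_midas(stim, sigs, truth_fn)
  list(sc = sc, data = d, true_bits = true_bits)
}

test_that("the GA matches the exhaustive optimum on planted problems", {
  for (seed in c(2, 7, 13)) {
    pb <- planted_problem(seed)
    obj <- boolean_objective(pb$sc, pb$data, 2,
                             scoring_config(alpha = 1e-3))
    ex <- exhaustive_optimize(pb$sc$n_gates, obj, tolerance = 0)
    ga <- ga_optimize(pb$sc$n_gates, obj,
                      ga_config(pop_size = 20, generations = 80,
                                stall = 25, seed = seed))
    expect_equal(ga$best_score, ex$best_score, tolerance = 1e-12)
  }
})

test_that("exhaustive search enumerates every model exactly once", {
  pb <- planted_problem(3)
  obj <- boolean_objective(pb$sc, pb$data, 2, scoring_config(alpha = 0.01))
  ex <- exhaustive_optimize(pb$sc$n_gates, obj)
  expect_equal(nrow(ex$archive), 2^pb$sc$n_gates)
  expect_equal(anyDuplicated(ex$archive$bits), 0)
  # the empty model's score is present in the archive
  empty_key <- paste(rep(0, pb$sc$n_gates), collapse = "")
  expect_true(empty_key %in% ex$archive$bits)
  expect_error(exhaustive_optimize(25, function(b) 0), "2\\^25")
})

test_that("identical seeds give bit-identical search results", {
  pb <- planted_problem(5)
  obj <- boolean_objective(pb$sc, pb$data, 2, scoring_config(alpha = 0.01))
  cfg <- ga_config(pop_size = 15, generations = 30, stall = 10, seed = 99)
  r1 <- ga_optimize(pb$sc$n_gates, obj, cfg)
  r2 <- ga_optimize(pb$sc$n_gates, obj, cfg)
  expect_identical(r1$best_bits, r2$best_bits)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$frequency, r2$frequency)
})

test_that("GA best never exceeds the empty- and full-model baselines", {
  for (seed in c(4, 9)) {
    pb <- planted_problem(seed)
    obj <- boolean_objective(pb$sc, pb$data, 2, scoring_config(alpha = 0.05))
    res <- ga_optimize(pb$sc$n_gates, obj,
                       ga_config(pop_size = 10, generations = 10,
                                 stall = 5, seed = 1))
    expect_lte(res$best_score, obj(integer(pb$sc$n_gates)))
    expect_lte(res$best_score, obj(rep(1L, pb$sc$n_gates)))
  }
})

test_that("tolerance shapes the model family and its frequencies", {
  pb <- planted_problem(6)
  obj <- boolean_objective(pb$sc, pb$data, 2, scoring_config(alpha = 0.02))
  ex0 <- exhaustive_optimize(pb$sc$n_gates, obj, tolerance = 0)
  # tolerance 0: every family member attains the optimum
  fam_scores <- apply(ex0$family, 1, obj)
  expect_true(all(abs(fam_scores - ex0$best_score) < 1e-9))
  # frequencies live in [0,1]; a gate in every member has frequency 1
  expect_true(all(ex0$frequency >= 0 & ex0$frequency <= 1))
  always <- which(ex0$frequency == 1)
  if (length(always))
    expect_true(all(ex0$family[, always] == 1))
  # widening the tolerance can only grow the family
  ex1 <- exhaustive_optimize(pb$sc$n_gates, obj, tolerance = 0.5)
  expect_gte(nrow(ex1$family), nrow(ex0$family))
})

test_that("search masks fix bits and degenerate masks warn", {
  pb <- planted_problem(8)
  obj <- boolean_objective(pb$sc, pb$data, 2, scoring_config(alpha = 0.01))
  mask <- rep(NA_real_, pb$sc$n_gates)
  mask[1] <- 1
  res <- ga_optimize(pb$sc$n_gates, obj,
                     ga_config(pop_size = 10, generations = 15, stall = 5,
                               seed = 3), search_mask = mask)
  expect_true(all(sapply(strsplit(res$archive$bits, ""),
                         function(b) b[1] == "1")))
  full_mask <- rep(0, pb$sc$n_gates)
  expect_warning(r2 <- ga_optimize(pb$sc$n_gates, obj,
                                   search_mask = full_mask), "fixed")
  expect_equal(nrow(r2$archive), 1)
})

test_that("planted gates outrank spurious gates in family frequency", {
  # cascade truth: data generated by the two single-input gates only
  net <- pkn(edges_df("S", 1, "A", "A", 1, "B", "S", 1, "B"))
  sc <- expand_gates(net, max_and_arity = 2)
  labels <- vapply(sc$gates, `[[`, "", "label")
  true_bits <- as.integer(labels %in% c("S=A", "A=B"))
  d <- design_midas("S", c("A", "B"), function(tr) {
    s <- oracle_steady(sc, true_bits, stats::setNames(unname(tr["S"]), "S"))
    s$state[c("A", "B")]
  })
  obj <- boolean_objective(sc, d, 2, scoring_config(alpha = 0.01))
  ex <- exhaustive_optimize(sc$n_gates, obj, tolerance = 0.1)
  expect_gte(ex$frequency[labels == "S=A"],
             max(ex$frequency[labels == "A+S=B"]))
})

test_that("archives dump to CSV with scores and generations", {
  pb <- planted_problem(10)
  obj <- boolean_objective(pb$sc, pb$data, 2, scoring_config(alpha = 0.01))
  res <- ga_optimize(pb$sc$n_gates, obj,
                     ga_config(pop_size = 8, generations = 5, stall = 3,
                               seed = 2))
  p <- tempfile(fileext = ".csv")
  write_archive(res, p)
  tab <- read.csv(p, colClasses = c(bits = "character"))
  expect_equal(nrow(tab), res$n_evaluated)
  expect_true(all(c("bits", "score", "generation") %in% names(tab)))
})
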