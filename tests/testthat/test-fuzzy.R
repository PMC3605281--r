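steep_tf <- function() transfer(10, 0.5)

steep_menu <- function() list(steep_tf())

test_that("normalized Hill transfers are anchored at 0 and their gain", {
  for (tf in transfer_menu()) {
    expect_equal(eval_transfer(tf, 0), 0)
    expect_equal(eval_transfer(tf, 1), if (is.na(tf$n_h)) 1 else tf$g)
    xs <- seq(0, 1, 0.05)
    expect_true(all(diff(eval_transfer(tf, xs)) >= -1e-12))
  }
  # full-gain transfers are exactly Boolean-consistent at the extremes
  for (tf in transfer_menu(g = 1)) expect_equal(eval_transfer(tf, 1), 1)
  # hand evaluation: n=2, K=0.5 at x=0.5 -> 0.25*1.25/0.5 = 0.625
  expect_equal(eval_transfer(transfer(2, 0.5), 0.5), 0.625)
  # identity option passes values through
  expect_equal(eval_transfer(transfer(NA, NA), 0.3), 0.3)
  expect_warning(eval_transfer(transfer(2, 0.5), 1.2), "clip")
  expect_error(transfer(2, NA), "both")
  expect_error(transfer(-1, 0.5), "n_h")
})

test_that("fuzzy gates use min for AND and max for OR", {
  # two OR-ed single-input gates through identity transfers
  net <- pkn(edges_df("X", 1, "Z", "Y", 1, "Z"))
  sc <- expand_gates(net)
  labels <- vapply(sc$gates, `[[`, "", "label")
  idt <- transfer(NA, NA)
  bits_or <- as.integer(labels %in% c("X=Z", "Y=Z"))
  model <- fuzzy_model_for(sc, bits_or, idt)
  d <- midas(c("X", "Y"), character(), "Z", c(0, 10),
             matrix(c(0.0, 1), 1, 2), array(0, c(1, 1, 2)))
  # fractional stimuli exercise the continuous algebra
  d$treatments[1, ] <- c(1, 1)
  sim <- simulate_fuzzy(sc, model, d)
  # clamps are binary here; use explicit states instead
  st <- fuzzy_states(sc, model, c(X = 0.3, Y = 0.7))
  expect_equal(unname(st["Z"]), 0.7)  # OR = max

  bits_and <- as.integer(labels == "X+Y=Z")
  st2 <- fuzzy_states(sc, fuzzy_model_for(sc, bits_and, idt),
                      c(X = 0.3, Y = 0.7))
  expect_equal(unname(st2["Z"]), 0.3)  # AND = min
})

test_that("steep transfers on Boolean inputs reproduce Boolean simulation", {
  set.seed(21)
  for (rep in 1:6) {
    net <- random_dag_pkn(5, p_neg = 0.3)
    sc <- expand_gates(net)
    if (sc$n_gates == 0) next
    bits <- as.integer(stats::runif(sc$n_gates) < 0.6)
    model <- fuzzy_model_for(sc, bits, steep_tf())
    stim <- stats::setNames(1, net$nodes[1])
    b <- simulate_steady(sc, bits, stimuli = stim)
    d <- design_midas(net$nodes[1], net$nodes[length(net$nodes)],
                      function(tr) 0)
    fz <- simulate_fuzzy(sc, model, d, max_iter = 50)
    if (b$converged) {
      expect_equal(unname(fz$states[2, ]), unname(b$state),
                   tolerance = 1e-3)
    }
  }
})

test_that("vertex inputs give Boolean gate outputs for every transfer", {
  # single AND gate with a negated literal, all full-gain menu transfers
  net <- pkn(edges_df("X", 1, "Z", "Y", -1, "Z"))
  sc <- expand_gates(net)
  labels <- vapply(sc$gates, `[[`, "", "label")
  bits <- as.integer(labels == "X+!Y=Z")
  for (tf in transfer_menu(g = 1)) {
    model <- fuzzy_model_for(sc, bits, tf)
    for (x in c(0, 1)) for (y in c(0, 1)) {
      st <- fuzzy_states(sc, model, c(X = x, Y = y))
      expect_equal(unname(st["Z"]), x * (1 - y))
    }
  }
  # a capped gain scales the active vertex by g and leaves 0 at 0
  gtf <- transfer(4, 0.5, g = 0.6)
  model <- fuzzy_model_for(sc, bits, gtf)
  st <- fuzzy_states(sc, model, c(X = 1, Y = 0))
  expect_equal(unname(st["Z"]), 0.6)
  expect_equal(unname(fuzzy_states(sc, model, c(X = 0, Y = 0))["Z"]), 0)
})

test_that("fuzzy training fits a partial activation below any Boolean fit", {
  # Z responds at half maximum: a gain-capped transfer can say 0.5, while
  # the Boolean model must round to 0 or 1
  net <- pkn(edges_df("X", 1, "Z"))
  sc <- expand_gates(net)
  vals <- array(NA_real_, c(2, 1, 2))
  vals[, 1, 2] <- c(0, 0.5)
  d <- midas("X", character(), "Z", c(0, 10), matrix(c(0, 1), 2, 1), vals)
  cfg <- scoring_config(alpha = 1e-3)
  fz <- train_fuzzy(sc, d, 2, cfg,
                    ga = ga_config(pop_size = 20, generations = 60,
                                   mutation = 1.5, stall = 25, seed = 2))
  bool <- exhaustive_optimize(sc$n_gates,
                              boolean_objective(sc, d, 2, cfg))
  expect_lt(fz$best, bool$best_score)
  # the fitted prediction is genuinely intermediate, not a rounded call
  sim <- simulate_fuzzy(sc, fz$model, d)
  expect_lt(abs(sim$states[2, "Z"] - 0.5), 0.1)
  # continuous refinement can only improve, moving closer to the datum
  ref <- refine_and_reduce(sc, fz$model, d, 2, cfg)
  expect_lte(attr(ref, "theta"), fz$best + 1e-9)
})

test_that("a single steep-menu fuzzy fit matches the Boolean optimum", {
  pbnet <- pkn(edges_df("S", 1, "A", "A", 1, "B", "S", 1, "B"))
  sc <- expand_gates(pbnet)
  labels <- vapply(sc$gates, `[[`, "", "label")
  true_bits <- as.integer(labels %in% c("S=A", "A=B"))
  d <- design_midas("S", c("A", "B"), function(tr) {
    s <- oracle_steady(sc, true_bits, stats::setNames(unname(tr["S"]), "S"))
    s$state[c("A", "B")]
  })
  cfg <- scoring_config(alpha = 0.01)
  fz <- train_fuzzy(sc, d, 2, cfg, menu = steep_menu(),
                    ga = ga_config(pop_size = 15, generations = 50,
                                   stall = 20, seed = 5))
  bool <- exhaustive_optimize(sc$n_gates,
                              boolean_objective(sc, d, 2, cfg))
  expect_equal(fz$best, bool$best_score, tolerance = 1e-6)
})

test_that("refinement recovers off-menu parameters and lowers theta", {
  # data generated with (n=3, K=0.42), deliberately off the menu
  net <- pkn(edges_df("X", 1, "Z"))
  sc <- expand_gates(net)
  gen <- transfer(3, 0.42)
  xs <- c(0.25, 0.5, 0.75)
  vals <- array(NA_real_, c(3, 1, 2))
  vals[, 1, 2] <- eval_transfer(gen, xs)
  d <- midas("X", character(), "Z", c(0, 10),
             matrix(1, 3, 1), vals)
  # treatments are binary; emulate graded stimulation via direct states
  model0 <- fuzzy_model_for(sc, 1L, transfer(2, 0.55))
  direct_theta <- function(m) {
    pred <- vapply(xs, function(x)
      unname(fuzzy_states(sc, m, c(X = x))["Z"]), 0)
    mean((pred - vals[, 1, 2])^2)
  }
  t0 <- direct_theta(model0)
  opt <- stats::optim(c(2, 0.55), function(p)
    direct_theta(fuzzy_model_for(sc, 1L, transfer(p[1], p[2]))),
    method = "L-BFGS-B", lower = c(1, 0.01), upper = c(10, 1))
  expect_lt(opt$value, t0)
  expect_lt(abs(opt$par[2] - 0.42), 0.05)
})

test_that("reduction trims redundant gates within the threshold", {
  net <- pkn(edges_df("S", 1, "A", "A", 1, "B", "S", 1, "B"))
  sc <- expand_gates(net)
  labels <- vapply(sc$gates, `[[`, "", "label")
  true_bits <- as.integer(labels %in% c("S=A", "A=B"))
  d <- design_midas("S", c("A", "B"), function(tr) {
    s <- oracle_steady(sc, true_bits, stats::setNames(unname(tr["S"]), "S"))
    s$state[c("A", "B")]
  })
  cfg <- scoring_config(alpha = 1e-3)
  # start from a model with a redundant extra gate S=B
  bits <- as.integer(labels %in% c("S=A", "A=B", "S=B"))
  model <- fuzzy_model_for(sc, bits, steep_tf())
  red <- refine_and_reduce(sc, model, d, 2, cfg,
                           reduction_threshold = 1e-4)
  expect_lt(sum(red$bits), sum(bits))
  expect_lte(attr(red, "theta"),
             fuzzy_theta_public(sc, model, d, 2, cfg) + 1e-4)

  # threshold zero with strictly valuable gates: model unchanged
  model2 <- fuzzy_model_for(sc, true_bits, steep_tf())
  red2 <- refine_and_reduce(sc, model2, d, 2, cfg,
                            reduction_threshold = 0)
  expect_equal(red2$bits, true_bits)
})
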