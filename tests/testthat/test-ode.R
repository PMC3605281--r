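single_edge_problem <- function() {
  net <- pkn(edges_df("S", 1, "Y"))
  sc <- expand_gates(net)
  list(sc = sc, bits = rep(1L, sc$n_gates))
}

params_for <- function(sc, bits, n_h, K, tau_val) {
  # identical transfer on every used edge, identical tau on every node
  logic_edges <- list()
  tau_nodes <- character()
  for (g in which(bits == 1)) {
    tgt <- sc$gates[[g]]$output
    tau_nodes <- c(tau_nodes, tgt)
    for (src in sc$gates[[g]]$inputs$node)
      logic_edges[[length(logic_edges) + 1L]] <-
        data.frame(target = tgt, input = src, n_h = n_h, K = K,
                   stringsAsFactors = FALSE)
  }
  edges <- unique(do.call(rbind, logic_edges))
  ode_params(edges, stats::setNames(rep(tau_val, length(unique(tau_nodes))),
                                    unique(tau_nodes)))
}

test_that("multilinear interpolation gives the OR and AND surfaces", {
  # OR of two activating inputs: w1 + w2 - w1 w2
  net <- pkn(edges_df("X", 1, "Z", "Y", 1, "Z"))
  sc <- expand_gates(net)
  labels <- vapply(sc$gates, `[[`, "", "label")
  bits_or <- as.integer(labels %in% c("X=Z", "Y=Z"))
  p <- params_for(sc, bits_or, 2, 0.5, 1)
  rhs <- build_rhs(sc, bits_or, p)
  tfv <- function(x) eval_transfer(transfer(2, 0.5), x)
  for (x in c(0, 0.3, 0.8, 1)) for (y in c(0, 0.4, 1)) {
    st <- c(X = x, Y = y, Z = 0)[order(c("X", "Y", "Z"))]
    st <- stats::setNames(c(x, y, 0), c("X", "Y", "Z"))[sc$nodes]
    dz <- rhs(st)["Z"]
    w1 <- tfv(x); w2 <- tfv(y)
    expect_equal(unname(dz), (w1 + w2 - w1 * w2 - 0) / 1, tolerance = 1e-12)
  }

  # AND: w1 * w2
  bits_and <- as.integer(labels == "X+Y=Z")
  p2 <- params_for(sc, bits_and, 2, 0.5, 1)
  rhs2 <- build_rhs(sc, bits_and, p2)
  for (x in c(0, 0.3, 1)) for (y in c(0, 0.7, 1)) {
    st <- stats::setNames(c(x, y, 0), c("X", "Y", "Z"))[sc$nodes]
    w1 <- tfv(x); w2 <- tfv(y)
    expect_equal(unname(rhs2(st)["Z"]), w1 * w2, tolerance = 1e-12)
  }
})

test_that("Boolean vertices are fixed points of the transferred logic", {
  # every sign pattern and gate combination with up to 3 inputs
  set.seed(8)
  for (rep in 1:10) {
    net <- random_dag_pkn(4, p_neg = 0.4)
    sc <- expand_gates(net, max_and_arity = 3)
    if (sc$n_gates == 0) next
    bits <- as.integer(stats::runif(sc$n_gates) < 0.6)
    if (!sum(bits)) next
    p <- params_for(sc, bits, 3, 0.4, 1)
    rhs <- build_rhs(sc, bits, p)
    dyn <- unique(vapply(sc$gates[bits == 1], `[[`, "", "output"))
    N <- length(sc$nodes)
    for (code in 0:(2^N - 1)) {
      x <- stats::setNames(as.numeric(intToBits(code)[1:N]), sc$nodes)
      dx <- rhs(x)
      for (nd in dyn) {
        b <- oracle_step(sc, bits, unname(x), rep(NA_real_, N))
        expect_equal(unname(dx[nd]), b[match(nd, sc$nodes)] - x[[nd]],
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("a single activating edge follows the closed-form relaxation", {
  pb <- single_edge_problem()
  p <- params_for(pb$sc, pb$bits, 2, 0.5, 1)
  tr <- matrix(1, 1, 1)
  times <- c(0, 0.5, 1, 2)
  d <- midas("S", character(), "Y", times, tr,
             array(NA_real_, c(1, 1, 4)))
  traj <- integrate_ode(pb$sc, pb$bits, p, d, rtol = 1e-10, atol = 1e-10)
  # S clamped at 1 -> input transfer is 1 -> dy/dt = (1 - y), y(0) = 0
  expect_equal(traj[1, "Y", "1"], 1 - exp(-1), tolerance = 1e-6)
  expect_equal(traj[1, "Y", "2"], 1 - exp(-2), tolerance = 1e-6)
})

test_that("states stay inside [0,1] and relax to 0 without input", {
  d <- toy_data(toy_spec(noise_sd = 0))
  sc <- attr(d, "scaffold")
  traj <- integrate_ode(sc, attr(d, "true_bits"), attr(d, "true_params"), d)
  expect_true(all(traj >= -1e-6 & traj <= 1 + 1e-6))
  # unstimulated condition: everything stays at rest
  expect_true(all(abs(traj[1, , ]) < 1e-6))
})

test_that("the fitted optimum is at least as good as the planted truth", {
  pb <- single_edge_problem()
  p_true <- params_for(pb$sc, pb$bits, 3, 0.4, 2)
  times <- seq(0, 10, 0.5)
  d0 <- midas("S", character(), "Y", times, matrix(1, 1, 1),
              array(NA_real_, c(1, 1, length(times))))
  traj <- integrate_ode(pb$sc, pb$bits, p_true, d0)
  d <- midas("S", character(), "Y", times, matrix(1, 1, 1),
             array(traj[, "Y", , drop = FALSE], c(1, 1, length(times))))
  fit <- fit_ode(pb$sc, pb$bits, d, seed = 3, generations = 40)
  mse_true <- lognet:::ode_mse(pb$sc, pb$bits, p_true, d)
  expect_lte(fit$mse, mse_true + 1e-6)
})

test_that("tau is recovered within 5% from dense noiseless data", {
  pb <- single_edge_problem()
  tau_star <- 2
  p_true <- params_for(pb$sc, pb$bits, 3, 0.4, tau_star)
  times <- seq(0, 10, 0.25)
  d0 <- midas("S", character(), "Y", times, matrix(1, 1, 1),
              array(NA_real_, c(1, 1, length(times))))
  traj <- integrate_ode(pb$sc, pb$bits, p_true, d0)
  d <- midas("S", character(), "Y", times, matrix(1, 1, 1),
             array(traj[, "Y", , drop = FALSE], c(1, 1, length(times))))
  fit <- fit_ode(pb$sc, pb$bits, d, seed = 7, generations = 60)
  tau_hat <- unname(fit$params$tau["Y"])
  expect_lt(abs(tau_hat - tau_star) / tau_star, 0.05)
})

test_that("identical seeds give identical ODE fits", {
  pb <- single_edge_problem()
  p_true <- params_for(pb$sc, pb$bits, 2, 0.5, 1)
  times <- seq(0, 6, 1)
  d0 <- midas("S", character(), "Y", times, matrix(1, 1, 1),
              array(NA_real_, c(1, 1, length(times))))
  traj <- integrate_ode(pb$sc, pb$bits, p_true, d0)
  d <- midas("S", character(), "Y", times, matrix(1, 1, 1),
             array(traj[, "Y", , drop = FALSE], c(1, 1, length(times))))
  f1 <- fit_ode(pb$sc, pb$bits, d, seed = 11, generations = 10)
  f2 <- fit_ode(pb$sc, pb$bits, d, seed = 11, generations = 10)
  expect_identical(f1$mse, f2$mse)
  expect_identical(f1$params$edges, f2$params$edges)
})

test_that("parameter errors are reported by name", {
  pb <- single_edge_problem()
  p <- params_for(pb$sc, pb$bits, 2, 0.5, 1)
  p$edges$input <- "WRONG"
  d <- midas("S", character(), "Y", c(0, 1, 2), matrix(1, 1, 1),
             array(NA_real_, c(1, 1, 3)))
  expect_error(integrate_ode(pb$sc, pb$bits, p, d), "S -> Y")
  expect_error(fit_ode(pb$sc, integer(pb$sc$n_gates), d), "no selected")
  expect_error(fit_ode(pb$sc, pb$bits,
                       midas("S", character(), "Y", c(0, 1), matrix(1, 1, 1),
                             array(0, c(1, 1, 2)))), "3 time")
})
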