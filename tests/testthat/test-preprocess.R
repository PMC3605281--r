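toy_status_data <- function() {
  design_midas(c("EGF", "TNFa"), c("ERK", "p38", "NFkB"),
               function(tr) c(0, 0, 0))
}

test_that("node status is marked from the design, case-insensitively", {
  net <- cascade_pkn()
  d <- design_midas("EGF", "erk", function(tr) 0)
  st <- mark_status(net, d)
  expect_true(st$stimulated[st$node == "EGF"])
  expect_true(st$measured[st$node == "ERK"])  # matched despite lower case
  expect_false(st$designated[st$node == "SOS-1"])

  d2 <- design_midas("EGF", "FOO", function(tr) 0)
  expect_error(mark_status(net, d2), "FOO")
})

test_that("non-controllable and non-observable nodes are pruned", {
  net <- pkn(edges_df("EGF", 1, "A", "A", 1, "ERK",
                      "X", 1, "Y"),       # disconnected from cues+signals
             nodes = c("EGF", "A", "ERK", "X", "Y", "iso"))
  d <- design_midas("EGF", "ERK", function(tr) 0)
  st <- mark_status(net, d)
  cut <- cut_unreachable(net, st)
  expect_setequal(cut$nodes, c("EGF", "A", "ERK"))

  # designated but disconnected nodes are kept, with a warning
  net2 <- pkn(edges_df("EGF", 1, "ERK"), nodes = c("EGF", "ERK", "p38"))
  d2 <- design_midas("EGF", c("ERK", "p38"), function(tr) c(0, 0))
  expect_warning(cut2 <- cut_unreachable(net2, mark_status(net2, d2)),
                 "p38")
  expect_true("p38" %in% cut2$nodes)
})

test_that("compression splices pass-through nodes with sign products", {
  # A -> x -> B, x undesignated: collapses to A -> B (+)
  net <- pkn(edges_df("A", 1, "x", "x", 1, "B"))
  d <- design_midas("A", "B", function(tr) 0)
  st <- mark_status(net, d)
  comp <- compress_network(net, st)
  expect_setequal(comp$nodes, c("A", "B"))
  expect_equal(comp$edges$sign, 1L)
  expect_equal(attr(comp, "compressed"), "x")

  # sign product: A -> x (+), x -| B (-) gives A -| B
  net2 <- pkn(edges_df("A", 1, "x", "x", -1, "B"))
  comp2 <- compress_network(net2, mark_status(net2, d))
  expect_equal(comp2$edges$sign, -1L)

  # self-loop guard: 2-cycle through undesignated x keeps x
  net3 <- pkn(edges_df("A", 1, "x", "x", 1, "A", "A", 1, "B"))
  comp3 <- compress_network(net3, mark_status(net3, d))
  expect_true("x" %in% comp3$nodes)
})

test_that("compression never removes designated nodes", {
  d <- toy_status_data()
  net <- toy_pkn()
  st <- mark_status(net, d)
  comp <- compress_network(cut_unreachable(net, st), st)
  expect_true(all(c("EGF", "TNFa", "ERK", "p38", "NFkB") %in% comp$nodes))
  expect_false(any(c("EGF", "TNFa", "ERK", "p38", "NFkB") %in%
                     attr(comp, "compressed")))
})

test_that("compression preserves designated steady states on random DAGs", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(5:9, 1)
    net <- random_dag_pkn(n)
    stim <- net$nodes[1]
    sigs <- net$nodes[n]
    d <- design_midas(stim, sigs, function(tr) 0)
    st <- mark_status(net, d)
    net_c <- suppressWarnings(cut_unreachable(net, st))
    comp <- compress_network(net_c, st)
    # simulate both networks with all single-input gates selected
    # (expansion with arity 1 keeps OR-of-edges semantics on both sides)
    sc_full <- expand_gates(net_c, max_and_arity = 1)
    sc_comp <- expand_gates(comp, max_and_arity = 1)
    for (v in c(0, 1)) {
      s_full <- oracle_steady(sc_full, rep(1L, sc_full$n_gates),
                              stats::setNames(v, stim))
      s_comp <- oracle_steady(sc_comp, rep(1L, sc_comp$n_gates),
                              stats::setNames(v, stim))
      des <- intersect(c(stim, sigs), comp$nodes)
      expect_equal(s_comp$state[des], s_full$state[des])
    }
  }
})

test_that("expansion produces the documented gate combinatorics", {
  # two activating inputs: 3 hyperedges spanning the 4 logic options
  net <- pkn(edges_df("B", 1, "A", "C", 1, "A"))
  sc <- expand_gates(net, max_and_arity = 2)
  expect_equal(sc$n_gates, 3)
  labels <- vapply(sc$gates, `[[`, "", "label")
  expect_setequal(labels, c("B=A", "C=A", "B+C=A"))
  expect_equal(sc$v_es, 4)  # 1 + 1 + 2

  # single input: one gate
  net1 <- pkn(edges_df("B", 1, "A"))
  expect_equal(expand_gates(net1)$n_gates, 1)

  # negative sign carried into the literal
  net2 <- pkn(edges_df("B", 1, "A", "C", -1, "A"))
  labels2 <- vapply(expand_gates(net2)$gates, `[[`, "", "label")
  expect_setequal(labels2, c("B=A", "!C=A", "B+!C=A"))

  expect_error(expand_gates(net, max_and_arity = 0), "max_and_arity")
})

test_that("gate counts follow d + choose(d, 2) and arity is monotone", {
  for (d in 2:5) {
    srcs <- paste0("I", seq_len(d))
    net <- pkn(data.frame(source = srcs, sign = 1, target = "A"))
    sc2 <- expand_gates(net, max_and_arity = 2)
    expect_equal(sc2$n_gates, d + choose(d, 2))
    sc3 <- expand_gates(net, max_and_arity = 3)
    expect_equal(sc3$n_gates, d + choose(d, 2) + choose(d, 3))
    # raising arity only adds gates
    l2 <- vapply(sc2$gates, `[[`, "", "label")
    l3 <- vapply(sc3$gates, `[[`, "", "label")
    expect_true(all(l2 %in% l3))
  }
})

test_that("gate ordering is deterministic and scaffold serializes", {
  net <- toy_pkn()
  d <- toy_status_data()
  sc1 <- preprocess(net, d)
  sc2 <- preprocess(net, d)
  expect_identical(vapply(sc1$gates, `[[`, "", "label"),
                   vapply(sc2$gates, `[[`, "", "label"))
  expect_equal(sc1$v_es, sum(sc1$v_e))

  prefix <- file.path(tempdir(), "scaffoldtest")
  paths <- write_scaffold(sc1, prefix)
  expect_true(file.exists(paths["sif"]))
  js <- jsonlite::read_json(paths["json"])
  expect_length(js$gates, sc1$n_gates)
  # AND gates routed through auxiliary and_k nodes in the SIF dialect
  sif <- readLines(paths["sif"])
  expect_true(any(grepl("^and_", sif) | grepl("\tand_", sif)))
})
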