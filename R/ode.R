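#' Parameter set for a logic-based ODE model
#'
#' Continuous dynamics are derived from a selected Boolean model: every
#' species `i` follows `dx_i/dt = (Bbar_i(x) - x_i) / tau_i`, where
#' `Bbar_i` is a smooth \[0,1\] activation function agreeing with the
#' Boolean update of node `i` at 0/1 inputs, and `tau_i` sets the species'
#' response time. `Bbar_i` is the multilinear (Boolean-cube) interpolation
#' of the node's Boolean update function, evaluated on inputs transformed
#' by normalized Hill functions (the "normalized HillCube" construction):
#' for an OR of two inputs it reduces to `w1 + w2 - w1*w2`, for an AND to
#' `w1*w2`, with `w_j` the Hill-transformed inputs.
#'
#' Transfer parameters are per incoming edge of each dynamic node (an
#' input shared by several gates of the same node is transformed once),
#' time constants per node.
#'
#' @param edges data.frame with columns `target`, `input`, `n_h`, `K`: one
#'   row per (dynamic node, input node) pair used by a selected gate.
#' @param tau named numeric vector, dynamic node -> time constant (> 0,
#'   data-time units).
#' @return a list of class `ode_params`.
#' @export
ode_params <- function(edges, tau) {
  stopifnot(is.data.frame(edges),
            all(c("target", "input", "n_h", "K") %in% names(edges)),
            all(tau > 0))
  structure(list(edges = edges, tau = tau), class = "ode_params")
}

# distinct inputs of each node under the selected gates, and the node's
# Boolean update truth table over those inputs
node_logic <- function(scaffold, bits) {
  sel <- which(bits == 1)
  sel_by_target <- split(sel, scaffold$gate_target[sel])
  out <- list()
  for (tgt in names(sel_by_target)) {
    gs <- sel_by_target[[tgt]]
    ins <- sort(unique(unlist(scaffold$gate_inputs[gs])))
    d <- length(ins)
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
    tt <- apply(grid, 1L, function(v) {
      val <- 0
      for (g in gs) {
        idx <- match(scaffold$gate_inputs[[g]], ins)
        lit <- v[idx]
        lit[scaffold$gate_neg[[g]]] <- 1 - lit[scaffold$gate_neg[[g]]]
        val <- max(val, min(lit))
      }
      val
    })
    out[[tgt]] <- list(target = as.integer(tgt), inputs = ins,
                       grid = grid, truth = tt)
  }
  out
}

# multilinear interpolation of a truth table at continuous inputs w;
# weights built column-wise (the cube has at most a handful of inputs)
interp_cube <- function(logic, w) {
  weights <- rep(1, nrow(logic$grid))
  for (j in seq_along(w)) {
    gj <- logic$grid[, j]
    weights <- weights * (gj * w[j] + (1 - gj) * (1 - w[j]))
  }
  sum(weights * logic$truth)
}

#' Build the right-hand side of the logic ODE system
#'
#' @param scaffold a `scaffold`.
#' @param bits selected Boolean model (fixed topology).
#' @param params an [ode_params()] covering every (node, input) pair and
#'   every dynamic node of the selected model.
#' @return a function `(x, stimuli, inhibited) -> dx/dt` over named state
#'   vectors: stimulus nodes are held at their treatment value, inhibited
#'   nodes at 0, nodes with no selected input relax to 0.
#' @export
build_rhs <- function(scaffold, bits, params) {
  check_bits(scaffold, bits)
  logic <- node_logic(scaffold, bits)
  nodes <- scaffold$nodes
  # per dynamic node: transfer parameters aligned with its input list
  for (tgt in names(logic)) {
    lg <- logic[[tgt]]
    tname <- nodes[lg$target]
    nh <- Ks <- numeric(length(lg$inputs))
    for (j in seq_along(lg$inputs)) {
      row <- which(params$edges$target == tname &
                   params$edges$input == nodes[lg$inputs[j]])
      if (length(row) != 1L)
        stop(sprintf("missing ODE parameters for edge %s -> %s",
                     nodes[lg$inputs[j]], tname))
      nh[j] <- params$edges$n_h[row]; Ks[j] <- params$edges$K[row]
    }
    logic[[tgt]]$n_h <- nh; logic[[tgt]]$K <- Ks
    logic[[tgt]]$Kn <- Ks^nh  # constant across evaluations
    if (is.na(params$tau[tname]))
      stop(sprintf("missing tau for node %s", tname))
    logic[[tgt]]$tau <- unname(params$tau[tname])
  }
  # flattened specification for the compiled vector field
  cpp_spec <- lapply(logic, function(lg)
    list(inputs0 = as.integer(lg$inputs - 1L), n_h = as.numeric(lg$n_h),
         Kn = as.numeric(lg$Kn), grid = lg$grid + 0.0,
         truth = as.numeric(lg$truth), target0 = as.integer(lg$target - 1L),
         tau = lg$tau))
  function(x, stimuli = numeric(), inhibited = character(),
           fixed_idx = NULL) {
    if (is.null(fixed_idx)) fixed_idx <- integer()
    if (length(stimuli))
      fixed_idx <- c(fixed_idx, match(names(stimuli), nodes))
    if (length(inhibited))
      fixed_idx <- c(fixed_idx, match(inhibited, nodes))
    dx <- .logic_ode_rhs(as.numeric(x), cpp_spec,
                         as.integer(fixed_idx) - 1L)
    names(dx) <- names(x)
    dx
  }
}

#' Integrate the logic ODE system for every condition of a dataset
#'
#' Uses a stiff-capable solver (`deSolve::lsoda`). Stimulus nodes start
#' and stay at their treatment value, inhibited nodes at 0, every other
#' node at 0.
#'
#' @param scaffold,bits,params see [build_rhs()].
#' @param data a [midas] (its treatments define the conditions).
#' @param times output times (default `data$times`).
#' @param aliases name map.
#' @param rtol,atol solver tolerances.
#' @return array conditions x nodes x times, plus attribute `sig_idx`.
#' @export
integrate_ode <- function(scaffold, bits, params, data, times = data$times,
                          aliases = NULL, rtol = 1e-8, atol = 1e-8) {
  rhs <- build_rhs(scaffold, bits, params)
  setup <- condition_setup(scaffold, data, aliases)
  nodes <- scaffold$nodes
  C <- n_conditions(data)
  t0 <- min(times, 0)
  tgrid <- sort(unique(c(t0, times)))
  out <- array(NA_real_, dim = c(C, length(nodes), length(times)),
               dimnames = list(NULL, nodes, as.character(times)))
  for (k in seq_len(C)) {
    fixed_idx <- which(!is.na(setup$clamp[k, ]))  # cues: stimuli + drugs
    x0 <- setup$init[k, ]
    names(x0) <- nodes
    deriv <- function(t, x, p) list(rhs(x, fixed_idx = fixed_idx))
    sol <- deSolve::lsoda(x0, tgrid, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE solver failure in condition %d", k))
    out[k, , ] <- t(sol[match(times, tgrid), nodes, drop = FALSE])
  }
  attr(out, "sig_idx") <- setup$sig_idx
  out
}

ode_param_template <- function(scaffold, bits) {
  logic <- node_logic(scaffold, bits)
  nodes <- scaffold$nodes
  rows <- list()
  tau_nodes <- character()
  for (lg in logic) {
    tau_nodes <- c(tau_nodes, nodes[lg$target])
    for (i in lg$inputs)
      rows[[length(rows) + 1L]] <- data.frame(target = nodes[lg$target],
                                              input = nodes[i],
                                              stringsAsFactors = FALSE)
  }
  list(edges = do.call(rbind, rows), tau_nodes = tau_nodes)
}

pack_params <- function(template, n_h, K, tau) {
  edges <- template$edges
  edges$n_h <- n_h; edges$K <- K
  ode_params(edges, stats::setNames(tau, template$tau_nodes))
}

ode_mse <- function(scaffold, bits, params, data, aliases = NULL,
                    rtol = 1e-4, atol = 1e-4) {
  traj <- try(integrate_ode(scaffold, bits, params, data,
                            aliases = aliases, rtol = rtol, atol = atol),
              silent = TRUE)
  if (inherits(traj, "try-error")) return(1e6)
  sig_idx <- attr(traj, "sig_idx")
  pred <- traj[, sig_idx, , drop = FALSE]
  ok <- !is.na(data$values)
  mean((pred[ok] - data$values[ok])^2)
}

#' Differential-evolution global optimizer
#'
#' Compact rand/1/bin differential evolution over a box; the default
#' global optimizer for ODE parameter fitting, and the reference shape of
#' the pluggable optimizer interface: any function with signature
#' `(fn, lower, upper, seed, ...) -> list(par, value)` can replace it.
#'
#' @param fn objective, bounded real vector -> scalar cost.
#' @param lower,upper box bounds.
#' @param seed integer seed (runs are reproducible).
#' @param pop_size population (default `10 * n` capped at 40).
#' @param generations number of generations.
#' @param F,CR differential weight and crossover probability.
#' @return list with `par`, `value`, `n_eval`.
#' @export
de_optim <- function(fn, lower, upper, seed = 1, pop_size = NULL,
                     generations = 60, F = 0.7, CR = 0.9) {
  n <- length(lower)
  stopifnot(length(upper) == n, all(upper >= lower))
  if (is.null(pop_size)) pop_size <- min(40L, max(10L, 10L * n))
  set.seed(seed)
  pop <- matrix(stats::runif(pop_size * n, lower, upper), pop_size, n,
                byrow = TRUE)
  cost <- apply(pop, 1, fn)
  n_eval <- pop_size
  for (gen in seq_len(generations)) {
    for (i in seq_len(pop_size)) {
      abc <- sample(setdiff(seq_len(pop_size), i), 3L)
      donor <- pop[abc[1], ] + F * (pop[abc[2], ] - pop[abc[3], ])
      cross <- stats::runif(n) < CR
      cross[sample.int(n, 1L)] <- TRUE
      trial <- ifelse(cross, donor, pop[i, ])
      trial <- pmin(upper, pmax(lower, trial))
      tc <- fn(trial)
      n_eval <- n_eval + 1L
      if (tc <= cost[i]) { pop[i, ] <- trial; cost[i] <- tc }
    }
  }
  b <- which.min(cost)
  list(par = pop[b, ], value = cost[b], n_eval = n_eval)
}

#' Fit ODE parameters to time-course data
#'
#' The topology is fixed (train it first with one of the discrete
#' formalisms); the continuous parameters -- per-edge (n_h, K) and
#' per-node tau -- are fitted by minimizing the mean squared deviation
#' over all matched condition/signal/time points with a bound-constrained
#' global optimizer. K and tau are searched on a log scale.
#'
#' @param scaffold a `scaffold`.
#' @param bits fixed topology.
#' @param data a normalized [midas] with time courses (>= 3 times).
#' @param optimizer pluggable optimizer with the [de_optim()] interface.
#' @param seed integer seed passed to the optimizer.
#' @param n_h_bounds,K_bounds,tau_bounds parameter boxes; `tau_bounds`
#'   defaults to `c(0.01, 10 * max(data$times))`.
#' @param aliases name map.
#' @param ... passed on to the optimizer (e.g. `generations`).
#' @return list of class `ode_fit`: `params` (an [ode_params()]), `mse`,
#'   `n_eval`, `template`.
#' @export
fit_ode <- function(scaffold, bits, data, optimizer = de_optim, seed = 1,
                    n_h_bounds = c(1, 10), K_bounds = c(0.01, 1),
                    tau_bounds = NULL, aliases = NULL, ...) {
  if (length(data$times) < 3)
    stop("ODE fitting needs time courses (>= 3 time points)")
  if (is.null(tau_bounds)) tau_bounds <- c(0.01, 10 * max(data$times))
  template <- ode_param_template(scaffold, bits)
  n_e <- if (is.null(template$edges)) 0L else nrow(template$edges)
  n_t <- length(template$tau_nodes)
  if (n_e == 0L)
    stop("no selected gates: nothing to parameterize")
  sig_nodes <- resolve_names(data$signals, scaffold$nodes, aliases, "signal")
  dyn <- unique(c(template$edges$target, template$tau_nodes))
  if (!any(sig_nodes %in% dyn) )
    warning("no measured species downstream of any parameterized gate; fit is unidentifiable")
  unpack <- function(par) {
    nh <- par[seq_len(n_e)]
    Kl <- par[n_e + seq_len(n_e)]
    tl <- par[2 * n_e + seq_len(n_t)]
    pack_params(template, nh, exp(Kl), exp(tl))
  }
  fn <- function(par) ode_mse(scaffold, bits, unpack(par), data, aliases)
  lower <- c(rep(n_h_bounds[1], n_e), rep(log(K_bounds[1]), n_e),
             rep(log(tau_bounds[1]), n_t))
  upper <- c(rep(n_h_bounds[2], n_e), rep(log(K_bounds[2]), n_e),
             rep(log(tau_bounds[2]), n_t))
  opt <- optimizer(fn, lower, upper, seed = seed, ...)
  structure(list(params = unpack(opt$par), mse = opt$value,
                 n_eval = opt$n_eval, template = template),
            class = "ode_fit")
}

#' Serialize fitted ODE parameters to JSON
#'
#' @param fit an `ode_fit` (or [ode_params()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ode_params <- function(fit, path) {
  p <- if (inherits(fit, "ode_fit")) fit$params else fit
  jsonlite::write_json(list(edges = p$edges, tau = as.list(p$tau)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
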