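#' Normalized Hill transfer function with gain
#'
#' `f(x) = g * x^n (1 + K^n) / (x^n + K^n)`: a Hill curve rescaled so that
#' `f(0) = 0` and `f(1) = g` exactly. With full gain (`g = 1`, the
#' default) the normalization makes a fuzzy (or ODE) gate agree with the
#' corresponding Boolean gate whenever its inputs sit at the extreme
#' values 0/1, while intermediate inputs are shaped by the steepness `n`
#' and midpoint `K`. A sub-maximal gain (`g < 1`) caps the output of an
#' interaction, which is how a constrained fuzzy model represents partial
#' activation of a target even under saturating upstream input;
#' vertex-to-vertex Boolean consistency then holds up to the factor `g`.
#' `transfer(NA, NA)` is the identity ("dummy") transfer `f(x) = x`.
#'
#' @param n_h Hill exponent (dimensionless, > 0), or `NA` for identity.
#' @param K midpoint in (0, 1\], or `NA` for identity.
#' @param g gain in (0, 1\]: the value of `f(1)`.
#' @return a list of class `transfer_function`.
#' @export
transfer <- function(n_h, K, g = 1) {
  if (is.na(n_h) != is.na(K)) stop("set both n_h and K, or both NA")
  if (!is.na(n_h) && (n_h <= 0 || K <= 0 || K > 1))
    stop("need n_h > 0 and K in (0, 1]")
  if (g <= 0 || g > 1) stop("need gain g in (0, 1]")
  structure(list(n_h = n_h, K = K, g = g), class = "transfer_function")
}

#' Evaluate a transfer function
#'
#' @param tf a [transfer()] (or a list with `n_h`, `K`).
#' @param x input in \[0,1\] (values outside are clipped with a warning).
#' @return `f(x)` in \[0,1\].
#' @export
eval_transfer <- function(tf, x) {
  if (any(x < -1e-9 | x > 1 + 1e-9, na.rm = TRUE))
    warning("transfer input outside [0,1]; clipping")
  x <- pmin(1, pmax(0, x))
  if (is.na(tf$n_h)) return(x)
  g <- if (is.null(tf$g)) 1 else tf$g
  g * x^tf$n_h * (1 + tf$K^tf$n_h) / (x^tf$n_h + tf$K^tf$n_h)
}

#' Default transfer-function menu
#'
#' The discrete set of (n_h, K, g) triples the fuzzy GA chooses from for
#' each gate input: midpoints at two steepness levels crossed with a small
#' set of gains, plus the identity transfer. The sub-maximal gains are
#' essential: under binary cues the synchronous update maps Boolean
#' states to Boolean states for any full-gain transfer (that is exactly
#' the Boolean-consistency normalization), so only a capped gain lets the
#' model hold a node at partial activation. Kept small on purpose -- the
#' refinement step fine-tunes the winning parameters continuously
#' afterwards.
#'
#' @param K midpoint grid.
#' @param n_h exponent grid.
#' @param g gain grid.
#' @param identity include the identity transfer as the last entry.
#' @return list of [transfer()] objects.
#' @export
transfer_menu <- function(K = c(0.3, 0.5, 0.7), n_h = c(2, 4),
                          g = c(0.25, 0.5, 0.75, 1), identity = TRUE) {
  menu <- list()
  for (nh in n_h) for (k in K) for (gg in g)
    menu[[length(menu) + 1L]] <- transfer(nh, k, gg)
  if (identity) menu[[length(menu) + 1L]] <- transfer(NA, NA)
  menu
}

#' Construct a fuzzy model
#'
#' A fuzzy model is a gate selection plus one transfer function per input
#' of every gate (entries for unselected gates are carried but unused).
#'
#' @param bits 0/1 gate-selection vector over a scaffold's gates.
#' @param tfs list parallel to the scaffold gates; element `g` is a list
#'   of [transfer()] objects, one per input of gate `g`. A single
#'   [transfer()] may be given to use it for every input of every gate.
#' @param scaffold required when `tfs` is a single transfer function.
#' @return an object of class `fuzzy_model`.
#' @export
fuzzy_model <- function(bits, tfs, scaffold = NULL) {
  if (inherits(tfs, "transfer_function")) {
    stopifnot(!is.null(scaffold))
    tfs <- lapply(scaffold$v_e, function(k) rep(list(tfs), k))
  }
  structure(list(bits = bits, tfs = tfs), class = "fuzzy_model")
}

#' Fuzzy steady state under explicit clamps
#'
#' Single-condition counterpart of [simulate_fuzzy()] taking an arbitrary
#' set of clamped node values in \[0,1\] (e.g. graded stimuli), useful for
#' probing the continuous gate algebra directly.
#'
#' @param scaffold a `scaffold`.
#' @param model a [fuzzy_model()].
#' @param clamped named numeric vector, node -> held value in \[0,1\].
#' @param tol,max_iter as in [simulate_fuzzy()].
#' @return named numeric vector of steady-state node values (`NA` =
#'   non-converged).
#' @export
fuzzy_steady <- function(scaffold, model, clamped = numeric(), tol = 1e-4,
                         max_iter = 100L) {
  check_bits(scaffold, model$bits)
  N <- length(scaffold$nodes)
  clamp <- matrix(NA_real_, 1, N)
  init <- matrix(0, 1, N)
  if (length(clamped)) {
    i <- match(names(clamped), scaffold$nodes)
    if (anyNA(i)) stop("unknown clamped node")
    clamp[1, i] <- clamped
    init[1, i] <- clamped
  }
  res <- fuzzy_fixpoint(scaffold, model, init, clamp, tol, max_iter)
  stats::setNames(res$states[1, ], scaffold$nodes)
}

# One synchronous fuzzy update: literal = input (or 1 - input for negative
# sign) pushed through its transfer; AND = min over a gate's transferred
# literals; OR = max over the selected gates of a node.
fuzzy_step <- function(states, scaffold, sel, tfs, clamp) {
  new <- states
  sel_by_target <- split(sel, scaffold$gate_target[sel])
  for (tgt in names(sel_by_target)) {
    acc <- NULL
    for (g in sel_by_target[[tgt]]) {
      idx <- scaffold$gate_inputs[[g]]
      neg <- scaffold$gate_neg[[g]]
      lit <- states[, idx, drop = FALSE]
      if (any(neg)) lit[, neg] <- 1 - lit[, neg, drop = FALSE]
      for (j in seq_along(idx)) lit[, j] <- eval_transfer(tfs[[g]][[j]],
                                                         lit[, j])
      val <- if (ncol(lit) == 1L) lit[, 1L] else do.call(pmin, asplit(lit, 2))
      acc <- if (is.null(acc)) val else pmax(acc, val)
    }
    new[, as.integer(tgt)] <- acc
  }
  fixed <- !is.na(clamp)
  new[fixed] <- clamp[fixed]
  new
}

fuzzy_fixpoint <- function(scaffold, model, init, clamp, tol = 1e-4,
                           max_iter = 100L) {
  sel <- which(model$bits == 1)
  states <- init
  fixed <- !is.na(clamp)
  states[fixed] <- clamp[fixed]
  iter <- 0L
  conv_all <- FALSE
  repeat {
    if (iter >= max_iter) break
    new <- fuzzy_step(states, scaffold, sel, model$tfs, clamp)
    iter <- iter + 1L
    if (max(abs(new - states)) < tol) { states <- new; conv_all <- TRUE; break }
    states <- new
  }
  conv <- rep(TRUE, nrow(states))
  if (!conv_all) {
    probe <- fuzzy_step(states, scaffold, sel, model$tfs, clamp)
    changed <- abs(probe - states) >= tol
    conv <- rowSums(changed) == 0L
    states[changed] <- NA_real_
  }
  list(states = states, converged = conv, iterations = iter)
}

#' Simulate a fuzzy model to its continuous steady state
#'
#' Synchronous fixed-point iteration of the fuzzy update (AND = min of
#' transferred literals, OR = max over selected gates) until the largest
#' node change falls below `tol`. Cues are clamped exactly as in the
#' Boolean engine. With step-like (very steep Hill) transfers and 0/1
#' inputs this reproduces the Boolean steady state.
#'
#' @param scaffold a `scaffold`.
#' @param model a `fuzzy_model` (`bits` + per-gate-input [transfer()]s).
#' @param data,aliases as in [simulate_all()].
#' @param tol fixed-point tolerance (default 1e-4).
#' @param max_iter iteration cap.
#' @return a `sim_result` with continuous states (`NA` = non-converged).
#' @export
simulate_fuzzy <- function(scaffold, model, data, aliases = NULL,
                           tol = 1e-4, max_iter = 100L) {
  check_bits(scaffold, model$bits)
  setup <- condition_setup(scaffold, data, aliases)
  res <- fuzzy_fixpoint(scaffold, model, setup$init, setup$clamp, tol,
                        max_iter)
  structure(list(states = `colnames<-`(res$states, scaffold$nodes),
                 converged = res$converged, iterations = res$iterations,
                 sig_idx = setup$sig_idx),
            class = "sim_result")
}

# chromosome layout: r gate bits, then for every gate input (in gate
# order) ceil(log2(menu size)) bits indexing the transfer menu (wrapping).
fuzzy_chromosome_spec <- function(scaffold, menu) {
  n_menu_bits <- max(1L, ceiling(log2(length(menu))))
  list(r = scaffold$n_gates, n_menu_bits = n_menu_bits,
       len = scaffold$n_gates + n_menu_bits * scaffold$v_es)
}

decode_fuzzy <- function(chrom, scaffold, menu, spec) {
  bits <- chrom[seq_len(spec$r)]
  tfs <- vector("list", spec$r)
  pos <- spec$r
  for (g in seq_len(spec$r)) {
    k <- scaffold$v_e[g]
    tfs[[g]] <- vector("list", k)
    for (j in seq_len(k)) {
      gene <- chrom[(pos + 1L):(pos + spec$n_menu_bits)]
      idx <- sum(gene * 2^(seq_along(gene) - 1L)) %% length(menu) + 1L
      tfs[[g]][[j]] <- menu[[idx]]
      pos <- pos + spec$n_menu_bits
    }
  }
  fuzzy_model(bits, tfs)
}

fuzzy_theta <- function(scaffold, model, data, time_index, cfg, aliases,
                        tol, max_iter) {
  sim <- simulate_fuzzy(scaffold, model, data, aliases, tol, max_iter)
  tf <- theta_f(sim, data, time_index, cfg$na_penalty)
  as.numeric(tf) + cfg$alpha * theta_s(scaffold, model$bits)
}

#' Train a constrained fuzzy logic model
#'
#' Jointly optimizes the topology (gate bitstring) and, for every gate
#' input, the choice of transfer function from a discrete menu, by genetic
#' algorithm on an extended chromosome. The continuous fit term lets the
#' model reproduce partial activations a Boolean model must round to 0 or
#' 1.
#'
#' @param scaffold a `scaffold`.
#' @param data a normalized [midas] (one pseudo-steady-state time).
#' @param time_index index of the scored time.
#' @param cfg a [scoring_config()].
#' @param menu transfer menu, see [transfer_menu()].
#' @param ga a [ga_config()].
#' @param aliases,tol,max_iter as in [simulate_fuzzy()].
#' @return list of class `fuzzy_result`: `model` (best `fuzzy_model`),
#'   `search` (`search_result` over the extended chromosome), `best`
#'   (score), `menu`.
#' @export
train_fuzzy <- function(scaffold, data, time_index, cfg,
                        menu = transfer_menu(), ga = ga_config(),
                        aliases = NULL, tol = 1e-4, max_iter = 100L) {
  spec <- fuzzy_chromosome_spec(scaffold, menu)
  objective <- function(chrom) {
    model <- decode_fuzzy(chrom, scaffold, menu, spec)
    fuzzy_theta(scaffold, model, data, time_index, cfg, aliases, tol,
                max_iter)
  }
  res <- ga_optimize(spec$len, objective, ga)
  model <- decode_fuzzy(res$best_bits, scaffold, menu, spec)
  structure(list(model = model, search = res,
                 best = fuzzy_theta(scaffold, model, data, time_index, cfg,
                                    aliases, tol, max_iter),
                 menu = menu),
            class = "fuzzy_result")
}

#' Refine transfer parameters and reduce model complexity
#'
#' Refinement: continuous local optimization (L-BFGS-B) of the (n_h, K)
#' parameters of all selected non-identity gate inputs, starting from the
#' discrete menu optimum; never worsens the score. Reduction: greedily
#' drop each selected gate, or replace each transfer by the identity,
#' whenever the score worsens by less than `reduction_threshold`
#' (absolute), trimming complexity the data cannot justify.
#'
#' @param scaffold,data,time_index,cfg,aliases,tol,max_iter as in
#'   [train_fuzzy()].
#' @param model a `fuzzy_model` to refine.
#' @param reduction_threshold maximum tolerated absolute score worsening
#'   per simplification (default 1e-4).
#' @return the refined and reduced `fuzzy_model`, with attribute `theta`.
#' @export
refine_and_reduce <- function(scaffold, model, data, time_index, cfg,
                              reduction_threshold = 1e-4, aliases = NULL,
                              tol = 1e-4, max_iter = 100L) {
  score_of <- function(m) fuzzy_theta(scaffold, m, data, time_index, cfg,
                                      aliases, tol, max_iter)
  base <- score_of(model)

  # --- refinement: continuous (n_h, K) of selected, non-identity inputs
  sel <- which(model$bits == 1)
  slots <- list()
  for (gg in sel) for (j in seq_along(model$tfs[[gg]]))
    if (!is.na(model$tfs[[gg]][[j]]$n_h))
      slots[[length(slots) + 1L]] <- c(gg, j)
  if (length(slots)) {
    par0 <- unlist(lapply(slots, function(s) {
      tf <- model$tfs[[s[1]]][[s[2]]]
      c(tf$n_h, tf$K, if (is.null(tf$g)) 1 else tf$g)
    }))
    with_par <- function(par) {
      m <- model
      for (i in seq_along(slots)) {
        s <- slots[[i]]
        m$tfs[[s[1]]][[s[2]]] <- transfer(par[3 * i - 2], par[3 * i - 1],
                                          par[3 * i])
      }
      m
    }
    opt <- stats::optim(par0, function(par) score_of(with_par(par)),
                        method = "L-BFGS-B",
                        lower = rep(c(1, 0.01, 0.01), length(slots)),
                        upper = rep(c(10, 1, 1), length(slots)),
                        control = list(maxit = 50))
    if (opt$value <= base) {
      model <- with_par(opt$par)
      base <- opt$value
    }
  }

  # --- reduction: greedy gate removal, then transfer simplification
  repeat {
    improved <- FALSE
    for (g in which(model$bits == 1)) {
      cand <- model
      cand$bits[g] <- 0
      sc <- score_of(cand)
      if (sc - base <= reduction_threshold) {
        model <- cand; base <- sc; improved <- TRUE
      }
    }
    if (!improved) break
  }
  for (g in which(model$bits == 1)) {
    for (j in seq_along(model$tfs[[g]])) {
      if (is.na(model$tfs[[g]][[j]]$n_h)) next
      cand <- model
      cand$tfs[[g]][[j]] <- transfer(NA, NA)
      sc <- score_of(cand)
      if (sc - base <= reduction_threshold) {
        model <- cand; base <- sc
      }
    }
  }
  attr(model, "theta") <- base
  model
}

#' Serialize a fuzzy model to JSON
#'
#' @param scaffold the model's scaffold.
#' @param model a `fuzzy_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fuzzy_model <- function(scaffold, model, path) {
  gates <- list()
  for (g in which(model$bits == 1)) {
    gates[[scaffold$gates[[g]]$label]] <- lapply(
      seq_along(model$tfs[[g]]), function(j)
        list(input = scaffold$gates[[g]]$inputs$node[j],
             sign = scaffold$gates[[g]]$inputs$sign[j],
             n_h = model$tfs[[g]][[j]]$n_h,
             K = model$tfs[[g]][[j]]$K,
             g = model$tfs[[g]][[j]]$g))
  }
  jsonlite::write_json(gates, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
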