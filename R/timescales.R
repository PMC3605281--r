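#' Simulate the second pseudo-steady state of a two-time-scale model
#'
#' The model trained at the first time point (tau1) is simulated to its
#' steady state; additional gates assumed to become active only at the
#' later time (tau2) are then applied as locks: each node receiving a
#' selected tau2 gate is set to the value of that gate evaluated at the
#' tau1 steady state (OR across several tau2 gates on the same node) and
#' held there, while the remaining nodes are relaxed to a new fixpoint
#' under the tau1 gates. Locking is what makes slow negative feedback
#' representable: if A activates B and B (slowly) represses A, the tau2
#' repression locks A permanently OFF instead of oscillating.
#'
#' @param scaffold a `scaffold`.
#' @param bits1 gates of the tau1 model.
#' @param bits2 gates of the tau2 layer (must be disjoint from `bits1`).
#' @param data,aliases,max_iter as in [simulate_all()].
#' @return a `sim_result` for the tau2 state, with extra element
#'   `locked` (conditions x nodes logical matrix).
#' @export
simulate_two_step <- function(scaffold, bits1, bits2, data, aliases = NULL,
                              max_iter = NULL) {
  check_bits(scaffold, bits1); check_bits(scaffold, bits2)
  if (any(bits1 == 1 & bits2 == 1))
    stop("tau2 gates must be disjoint from the tau1 model")
  if (is.null(max_iter)) max_iter <- default_max_iter(scaffold)
  setup <- condition_setup(scaffold, data, aliases)
  s1 <- bool_fixpoint(scaffold, bits1, setup$init, setup$clamp, max_iter)
  st <- s1$states
  st[is.na(st)] <- 0  # unresolved tau1 nodes enter tau2 at rest

  # evaluate the tau2 gates on the tau1 steady state and lock their targets
  sel2 <- which(bits2 == 1)
  clamp2 <- setup$clamp
  locked <- matrix(FALSE, nrow(st), ncol(st))
  if (length(sel2)) {
    sel_by_target <- split(sel2, scaffold$gate_target[sel2])
    for (tgt in names(sel_by_target)) {
      ti <- as.integer(tgt)
      acc <- NULL
      for (g in sel_by_target[[tgt]]) {
        idx <- scaffold$gate_inputs[[g]]
        neg <- scaffold$gate_neg[[g]]
        lit <- st[, idx, drop = FALSE]
        if (any(neg)) lit[, neg] <- 1 - lit[, neg, drop = FALSE]
        val <- if (ncol(lit) == 1L) lit[, 1L] else do.call(pmin, asplit(lit, 2))
        acc <- if (is.null(acc)) val else pmax(acc, val)
      }
      # a tau2 mechanism may switch off even a stimulated receptor
      # (desensitization), but a drug clamp is never overridden
      free <- !setup$inh_mask[, ti]
      clamp2[free, ti] <- acc[free]
      locked[free, ti] <- TRUE
    }
  }
  s2 <- bool_fixpoint(scaffold, bits1, st, clamp2, max_iter)
  structure(list(states = `colnames<-`(s2$states, scaffold$nodes),
                 converged = s2$converged, iterations = s2$iterations,
                 sig_idx = setup$sig_idx, locked = locked,
                 tau1_states = `colnames<-`(s1$states, scaffold$nodes)),
            class = "sim_result")
}

#' Train a Boolean model at two pseudo-steady states
#'
#' Step 1 trains an ordinary steady-state Boolean model against the
#' measurements at `t1_index`. Step 2 searches only the gates absent from
#' the best tau1 model, scoring against `t2_index`: the candidate tau2
#' gates are evaluated on the tau1 steady state and lock their target
#' nodes (see [simulate_two_step()]), capturing mechanisms that act on a
#' slower time scale (e.g. feedback through de novo protein expression).
#'
#' @param scaffold a `scaffold`.
#' @param data a normalized [midas] with at least two post-baseline times.
#' @param t1_index,t2_index distinct indices into `data$times`.
#' @param scoring a [scoring_config()].
#' @param ga a [ga_config()]; step 2 derives its seed from `ga$seed`.
#' @param aliases,max_iter as in [simulate_all()].
#' @return list of class `two_step_result`: `tau1` and `tau2`
#'   (`search_result`s; tau2 bitstrings span the full scaffold with the
#'   tau1 gates masked out), `bits1`, `bits2`, and `locked_nodes` per
#'   condition.
#' @export
train_two_steps <- function(scaffold, data, t1_index, t2_index, scoring,
                            ga = ga_config(), aliases = NULL,
                            max_iter = NULL) {
  if (t1_index == t2_index) stop("t1_index and t2_index must differ")
  obj1 <- boolean_objective(scaffold, data, t1_index, scoring, aliases,
                            max_iter)
  res1 <- ga_optimize(scaffold$n_gates, obj1, ga)
  bits1 <- res1$best_bits

  mask <- rep(NA_real_, scaffold$n_gates)
  mask[bits1 == 1] <- 0  # tau2 searches the complement of the tau1 model
  obj2 <- function(bits2) {
    sim <- simulate_two_step(scaffold, bits1, bits2, data, aliases, max_iter)
    tf <- theta_f(sim, data, t2_index, scoring$na_penalty)
    as.numeric(tf) + scoring$alpha * theta_s(scaffold, bits2)
  }
  ga2 <- ga
  ga2$seed <- ga$seed + 1L
  res2 <- ga_optimize(scaffold$n_gates, obj2, ga2, search_mask = mask)
  bits2 <- res2$best_bits

  sim2 <- simulate_two_step(scaffold, bits1, bits2, data, aliases, max_iter)
  structure(list(tau1 = res1, tau2 = res2, bits1 = bits1, bits2 = bits2,
                 sim2 = sim2,
                 locked_nodes = lapply(seq_len(nrow(sim2$locked)), function(k)
                   scaffold$nodes[sim2$locked[k, ]])),
            class = "two_step_result")
}
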