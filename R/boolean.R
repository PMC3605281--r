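#' @keywords internal
#' Map dataset cues/signals onto scaffold node indices.
#' Returns per-condition clamp and initial-state matrices plus the signal
#' column index of every readout.
condition_setup <- function(scaffold, data, aliases = NULL) {
  nodes <- scaffold$nodes
  stim <- resolve_names(data$stimuli, nodes, aliases, "stimulus")
  inh <- if (length(data$inhibitors))
    resolve_names(data$inhibitors, nodes, aliases, "inhibitor")
  else character()
  sig <- resolve_names(data$signals, nodes, aliases, "signal")
  C <- n_conditions(data); N <- length(nodes)
  clamp <- matrix(NA_real_, C, N)
  init <- matrix(0, C, N)
  for (j in seq_along(stim)) {
    v <- data$treatments[, data$stimuli[j]]
    ni <- match(stim[j], nodes)
    clamp[, ni] <- v
    init[, ni] <- v
  }
  inh_mask <- matrix(FALSE, C, N)
  for (j in seq_along(inh)) {
    on <- data$treatments[, data$inhibitors[j]] == 1
    ni <- match(inh[j], nodes)
    clamp[on, ni] <- 0
    init[on, ni] <- 0
    inh_mask[on, ni] <- TRUE
  }
  list(clamp = clamp, init = init, inh_mask = inh_mask,
       sig_idx = match(sig, nodes),
       stim_nodes = unname(stim), inh_nodes = unname(inh))
}

gates_by_target <- function(scaffold) {
  split(seq_len(scaffold$n_gates), scaffold$gate_target)
}

# One synchronous update of all rows of a state matrix (conditions x nodes).
# Selected gates: OR (max) over gates targeting a node of AND (min) over the
# gate's literals; a negative literal reads 1 - state. Nodes with no
# selected incoming gate hold their value; clamps are re-applied afterwards.
bool_step <- function(states, scaffold, sel_by_target, clamp) {
  new <- states
  for (tgt in names(sel_by_target)) {
    gs <- sel_by_target[[tgt]]
    acc <- NULL
    for (g in gs) {
      idx <- scaffold$gate_inputs[[g]]
      neg <- scaffold$gate_neg[[g]]
      lit <- states[, idx, drop = FALSE]
      if (any(neg)) lit[, neg] <- 1 - lit[, neg, drop = FALSE]
      val <- if (ncol(lit) == 1L) lit[, 1L] else do.call(pmin, asplit(lit, 2))
      acc <- if (is.null(acc)) val else pmax(acc, val)
    }
    new[, as.integer(tgt)] <- acc
  }
  fixed <- !is.na(clamp)
  new[fixed] <- clamp[fixed]
  new
}

bool_fixpoint <- function(scaffold, bits, init, clamp, max_iter) {
  sel <- which(bits == 1)
  sel_by_target <- split(sel, scaffold$gate_target[sel])
  states <- init
  fixed <- !is.na(clamp)
  states[fixed] <- clamp[fixed]
  iter <- 0L
  converged_all <- FALSE
  repeat {
    if (iter >= max_iter) break
    new <- bool_step(states, scaffold, sel_by_target, clamp)
    iter <- iter + 1L
    if (identical(new, states)) { converged_all <- TRUE; states <- new; break }
    states <- new
  }
  conv <- rep(TRUE, nrow(states))
  if (!converged_all) {
    # walk the residual attractor: any node that still varies is oscillating
    # and never reaches a steady state
    ref <- states
    cur <- states
    changed <- matrix(FALSE, nrow(states), ncol(states))
    for (s in seq_len(max(4L, max_iter))) {
      nxt <- bool_step(cur, scaffold, sel_by_target, clamp)
      changed <- changed | (nxt != cur)
      cur <- nxt
      if (identical(cur, ref)) break
    }
    conv <- rowSums(changed) == 0L
    states[changed] <- NA_real_
  }
  list(states = states, converged = conv, iterations = iter)
}

default_max_iter <- function(scaffold) as.integer(ceiling(1.2 * length(scaffold$nodes)))

#' Simulate one condition to Boolean steady state
#'
#' Synchronous updating from the resting state (all nodes 0 except clamped
#' cues) until a fixpoint or `max_iter` steps. Stimulus nodes are clamped
#' to their treatment value for the whole simulation; inhibited nodes are
#' clamped to 0 (a drug is modeled as a full block). In a non-converged
#' condition the nodes still changing in the final step are reported as
#' `NA` (unresolved): species caught in e.g. a negative feedback loop
#' oscillate under synchronous updating and have no steady state.
#'
#' @param scaffold a `scaffold` from [expand_gates()].
#' @param bits 0/1 vector of length `scaffold$n_gates` selecting gates.
#' @param stimuli named numeric vector, stimulus node -> clamp value.
#' @param inhibited character vector of node names clamped to 0.
#' @param max_iter iteration cap (default `ceiling(1.2 * n_nodes)`).
#' @return list with `state` (named numeric, `NA` = unresolved),
#'   `converged` (logical), `iterations`.
#' @export
simulate_steady <- function(scaffold, bits, stimuli = numeric(),
                            inhibited = character(), max_iter = NULL) {
  check_bits(scaffold, bits)
  if (is.null(max_iter)) max_iter <- default_max_iter(scaffold)
  N <- length(scaffold$nodes)
  clamp <- matrix(NA_real_, 1, N)
  init <- matrix(0, 1, N)
  if (length(stimuli)) {
    si <- match(names(stimuli), scaffold$nodes)
    if (anyNA(si)) stop("unknown stimulus node")
    clamp[1, si] <- stimuli
    init[1, si] <- stimuli
  }
  if (length(inhibited)) {
    ii <- match(inhibited, scaffold$nodes)
    if (anyNA(ii)) stop("unknown inhibited node")
    clamp[1, ii] <- 0
    init[1, ii] <- 0
  }
  res <- bool_fixpoint(scaffold, bits, init, clamp, max_iter)
  list(state = stats::setNames(res$states[1, ], scaffold$nodes),
       converged = res$converged[1], iterations = res$iterations)
}

check_bits <- function(scaffold, bits) {
  if (length(bits) != scaffold$n_gates)
    stop(sprintf("bitstring length %d does not match scaffold gate count %d",
                 length(bits), scaffold$n_gates))
  if (!all(bits %in% c(0, 1))) stop("bits must be 0 or 1")
  invisible(TRUE)
}

#' Simulate every condition of a dataset to Boolean steady state
#'
#' @inheritParams simulate_steady
#' @param data a [midas] object; its treatment matrix defines the clamps of
#'   each condition.
#' @param aliases optional dataset-name to node-name map (see
#'   [mark_status()]).
#' @return list of class `sim_result`: `states` (conditions x nodes matrix,
#'   `NA` = unresolved), `converged` (per condition), `iterations`,
#'   `sig_idx` (node column of each dataset signal).
#' @export
simulate_all <- function(scaffold, bits, data, aliases = NULL,
                         max_iter = NULL) {
  check_bits(scaffold, bits)
  if (is.null(max_iter)) max_iter <- default_max_iter(scaffold)
  setup <- condition_setup(scaffold, data, aliases)
  res <- bool_fixpoint(scaffold, bits, setup$init, setup$clamp, max_iter)
  structure(list(states = `colnames<-`(res$states, scaffold$nodes),
                 converged = res$converged,
                 iterations = res$iterations,
                 sig_idx = setup$sig_idx),
            class = "sim_result")
}
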