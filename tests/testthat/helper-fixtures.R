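# Shared in-code fixtures: tiny networks, datasets and brute-force oracles.

edges_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], sign = as.integer(m[, 2]), target = m[, 3],
             stringsAsFactors = FALSE)
}

# EGF -> SOS-1 -> ERK linear cascade
cascade_pkn <- function() {
  pkn(edges_df("EGF", 1, "SOS-1", "SOS-1", 1, "ERK"))
}

# one-condition dataset builder: signals measured at the given times
tiny_midas <- function(stimuli, signals, times, treatments, values,
                       inhibitors = character()) {
  midas(stimuli, inhibitors, signals, times, treatments, values)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force synchronous Boolean oracle, written against the update
# definition directly (independent of the package's simulator internals):
# enumerates each node's update via its selected gates on explicit state
# vectors, steps until repeat or cap.
oracle_step <- function(scaffold, bits, state, clamp) {
  new <- state
  for (ni in seq_along(state)) {
    gs <- which(bits == 1 & scaffold$gate_target == ni)
    if (!length(gs)) next
    vals <- vapply(gs, function(g) {
      lit <- state[scaffold$gate_inputs[[g]]]
      lit[scaffold$gate_neg[[g]]] <- 1 - lit[scaffold$gate_neg[[g]]]
      min(lit)
    }, 0)
    new[ni] <- max(vals)
  }
  new[!is.na(clamp)] <- clamp[!is.na(clamp)]
  new
}

oracle_steady <- function(scaffold, bits, stimuli = numeric(),
                          inhibited = character(), max_iter = 100) {
  N <- length(scaffold$nodes)
  clamp <- rep(NA_real_, N)
  state <- rep(0, N)
  if (length(stimuli)) {
    i <- match(names(stimuli), scaffold$nodes)
    clamp[i] <- stimuli; state[i] <- stimuli
  }
  if (length(inhibited)) {
    i <- match(inhibited, scaffold$nodes)
    clamp[i] <- 0; state[i] <- 0
  }
  for (it in seq_len(max_iter)) {
    new <- oracle_step(scaffold, bits, state, clamp)
    if (identical(new, state))
      return(list(state = stats::setNames(state, scaffold$nodes),
                  converged = TRUE))
    state <- new
  }
  # non-convergent: traverse the attractor and blank every varying node
  ref <- state; cur <- state
  changed <- rep(FALSE, length(state))
  for (s in seq_len(200)) {
    nxt <- oracle_step(scaffold, bits, cur, clamp)
    changed <- changed | (nxt != cur)
    cur <- nxt
    if (identical(cur, ref)) break
  }
  state[changed] <- NA_real_
  list(state = stats::setNames(state, scaffold$nodes), converged = FALSE)
}

# all fixpoints of the clamped synchronous map, by full state enumeration
oracle_fixpoints <- function(scaffold, bits, stimuli = numeric(),
                             inhibited = character()) {
  N <- length(scaffold$nodes)
  clamp <- rep(NA_real_, N)
  if (length(stimuli)) clamp[match(names(stimuli), scaffold$nodes)] <- stimuli
  if (length(inhibited)) clamp[match(inhibited, scaffold$nodes)] <- 0
  fps <- list()
  for (code in 0:(2^N - 1)) {
    s <- as.numeric(intToBits(code)[1:N])
    if (any(!is.na(clamp) & s != clamp)) next
    if (identical(oracle_step(scaffold, bits, s, clamp), s))
      fps[[length(fps) + 1L]] <- s
  }
  fps
}

# random signed DAG over n nodes (node i only feeds higher-numbered nodes)
random_dag_pkn <- function(n, p_edge = 0.35, p_neg = 0.25) {
  src <- c(); sgn <- c(); tgt <- c()
  names <- paste0("n", seq_len(n))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) {
      src <- c(src, names[i]); tgt <- c(tgt, names[j])
      sgn <- c(sgn, if (stats::runif(1) < p_neg) -1 else 1)
    }
  }
  if (!length(src)) return(random_dag_pkn(n, p_edge, p_neg))
  pkn(data.frame(source = src, sign = sgn, target = tgt,
                 stringsAsFactors = FALSE), nodes = names)
}

# dataset over all cue combinations of `stimuli`, one post-baseline time,
# with values produced by a supplied function(condition treatments) -> named
# signal values
design_midas <- function(stimuli, signals, value_fn,
                         inhibitors = character(), times = c(0, 10)) {
  tr <- as.matrix(expand.grid(rep(list(c(0, 1)),
                                  length(stimuli) + length(inhibitors))))
  colnames(tr) <- c(stimuli, inhibitors)
  vals <- array(0, c(nrow(tr), length(signals), length(times)))
  for (k in seq_len(nrow(tr)))
    vals[k, , length(times)] <- value_fn(tr[k, ])
  midas(stimuli, inhibitors, signals, times, tr, vals)
}

# fuzzy test utilities built on the exported API
fuzzy_model_for <- function(sc, bits, tf) fuzzy_model(bits, tf, sc)

fuzzy_states <- function(sc, model, clamped) fuzzy_steady(sc, model, clamped)

fuzzy_theta_public <- function(sc, model, d, time_index, cfg) {
  sim <- simulate_fuzzy(sc, model, d)
  as.numeric(theta_f(sim, d, time_index, cfg$na_penalty)) +
    cfg$alpha * theta_s(sc, model$bits)
}
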