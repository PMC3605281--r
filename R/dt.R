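#' Simulate a Boolean trajectory
#'
#' Synchronous updates as in [simulate_steady()], but every step from 0 to
#' `n_steps` is recorded and no convergence is required: oscillations
#' driven by negative feedback appear as periodic columns of the
#' trajectory.
#'
#' @inheritParams simulate_steady
#' @param n_steps number of update steps (>= 1).
#' @return `(n_steps + 1) x nodes` matrix; row `i` is the state after
#'   `i - 1` updates.
#' @export
simulate_trajectory <- function(scaffold, bits, stimuli = numeric(),
                                inhibited = character(), n_steps) {
  check_bits(scaffold, bits)
  if (n_steps < 1) stop("n_steps must be >= 1")
  N <- length(scaffold$nodes)
  clamp <- matrix(NA_real_, 1, N)
  init <- matrix(0, 1, N)
  if (length(stimuli)) {
    si <- match(names(stimuli), scaffold$nodes)
    clamp[1, si] <- stimuli; init[1, si] <- stimuli
  }
  if (length(inhibited)) {
    ii <- match(inhibited, scaffold$nodes)
    clamp[1, ii] <- 0; init[1, ii] <- 0
  }
  traj_core(scaffold, bits, init, clamp, n_steps)[, 1, , drop = TRUE]
}

# all-conditions trajectory: array (steps+1) x conditions x nodes
traj_core <- function(scaffold, bits, init, clamp, n_steps) {
  sel <- which(bits == 1)
  sel_by_target <- split(sel, scaffold$gate_target[sel])
  states <- init
  fixed <- !is.na(clamp)
  states[fixed] <- clamp[fixed]
  out <- array(NA_real_, dim = c(n_steps + 1L, nrow(init), ncol(init)),
               dimnames = list(NULL, NULL, scaffold$nodes))
  out[1L, , ] <- states
  for (s in seq_len(n_steps)) {
    states <- bool_step(states, scaffold, sel_by_target, clamp)
    out[s + 1L, , ] <- states
  }
  out
}

#' Score a Boolean model against full time courses
#'
#' A single time-scale factor `delta` (data-time units per synchronous
#' update step) stretches the simulated trajectory onto the measurement
#' times: the prediction at data time `t` is the Boolean state after
#' `round(t / delta)` updates (the trajectory holds its last state beyond
#' `n_steps`). The fit term is the mean squared deviation over all
#' condition/signal/time cells, including the baseline time at step 0,
#' plus the usual size penalty.
#'
#' @param scaffold a `scaffold`.
#' @param bits gate-selection vector.
#' @param delta time-scale factor (> 0), data-time per update step.
#' @param data a normalized [midas].
#' @param cfg a [scoring_config()].
#' @param aliases name map, see [mark_status()].
#' @param n_steps trajectory length; default
#'   `min(1000, ceiling(max(times) / delta))`.
#' @return list with `theta`, `theta_f`, `theta_s`, `n_g`.
#' @export
score_dt <- function(scaffold, bits, delta, data, cfg, aliases = NULL,
                     n_steps = NULL) {
  check_bits(scaffold, bits)
  stopifnot(delta > 0)
  if (is.null(n_steps))
    n_steps <- max(1L, min(1000L, as.integer(ceiling(max(data$times) / delta))))
  setup <- condition_setup(scaffold, data, aliases)
  traj <- traj_core(scaffold, bits, setup$init, setup$clamp, n_steps)
  steps <- pmin(round(data$times / delta), n_steps) + 1L
  sq <- 0; n_g <- 0L
  for (ti in seq_along(data$times)) {
    pred <- traj[steps[ti], , setup$sig_idx, drop = FALSE]
    dim(pred) <- dim(pred)[2:3]
    obs <- data$values[, , ti, drop = FALSE]
    dim(obs) <- dim(obs)[1:2]
    ok <- !is.na(obs)
    sq <- sq + sum((pred - obs)[ok]^2)
    n_g <- n_g + sum(ok)
  }
  if (n_g == 0L) stop("no comparable data points (n_g = 0)")
  tf <- sq / n_g
  ts <- theta_s(scaffold, bits)
  list(theta = tf + cfg$alpha * ts, theta_f = tf, theta_s = ts, n_g = n_g)
}

#' Default time-scale search grid
#'
#' Log-spaced candidate values for the time-scale factor.
#'
#' @param delta_min,delta_max bounds in data-time units per step.
#' @param n grid size.
#' @return numeric vector of length `n`.
#' @export
delta_grid <- function(delta_min, delta_max, n = 20) {
  stopifnot(delta_min > 0, delta_max >= delta_min, n >= 1)
  if (n == 1) return(delta_min)
  exp(seq(log(delta_min), log(delta_max), length.out = n))
}

# the delta gene is appended to the chromosome as a plain binary counter;
# values beyond the grid wrap around so every chromosome is valid
decode_delta <- function(gene_bits, grid) {
  idx <- sum(gene_bits * 2^(seq_along(gene_bits) - 1L)) %% length(grid) + 1L
  grid[idx]
}

#' Train topology and time-scale factor against time courses
#'
#' The GA chromosome is the gate bitstring extended by a binary-encoded
#' index into a discrete grid of time-scale values, so the topology and
#' the single timing parameter are optimized jointly by the same search
#' machinery.
#'
#' @inheritParams score_dt
#' @param grid candidate `delta` values (see [delta_grid()]).
#' @param ga a [ga_config()].
#' @return list of class `dt_result`: `search` (a `search_result` over the
#'   extended chromosome), `best_bits`, `best_delta`, `best` (score
#'   breakdown), `grid`, `n_gene_bits`.
#' @export
train_dt <- function(scaffold, data, cfg, grid = delta_grid(
                       max(diff(data$times)) / 10, max(data$times)),
                     ga = ga_config(), aliases = NULL, n_steps = NULL) {
  r <- scaffold$n_gates
  n_gene <- max(1L, ceiling(log2(length(grid))))
  objective <- function(chrom) {
    bits <- chrom[seq_len(r)]
    delta <- decode_delta(chrom[(r + 1L):(r + n_gene)], grid)
    score_dt(scaffold, bits, delta, data, cfg, aliases, n_steps)$theta
  }
  res <- ga_optimize(r + n_gene, objective, ga)
  best_bits <- res$best_bits[seq_len(r)]
  best_delta <- decode_delta(res$best_bits[(r + 1L):(r + n_gene)], grid)
  structure(list(search = res, best_bits = best_bits,
                 best_delta = best_delta,
                 best = score_dt(scaffold, best_bits, best_delta, data, cfg,
                                 aliases, n_steps),
                 grid = grid, n_gene_bits = n_gene),
            class = "dt_result")
}

#' Export trajectories as long-format CSV
#'
#' @param scaffold,bits,data,aliases,n_steps as in [score_dt()].
#' @param path output path; columns `condition`, `node`, `step`, `value`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(scaffold, bits, data, path, aliases = NULL,
                               n_steps = 50) {
  setup <- condition_setup(scaffold, data, aliases)
  traj <- traj_core(scaffold, bits, setup$init, setup$clamp, n_steps)
  long <- expand.grid(step = 0:n_steps,
                      condition = seq_len(dim(traj)[2]),
                      node = scaffold$nodes, stringsAsFactors = FALSE)
  long$value <- as.vector(traj)
  utils::write.csv(long[, c("condition", "node", "step", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
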