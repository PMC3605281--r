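#' Scoring settings
#'
#' @param alpha weight of the model-size penalty relative to the fit term
#'   (dimensionless, `>= 0`). There is no universally sensible default: it
#'   trades off parsimony against fit and should be chosen relative to the
#'   experimental error (e.g. `0.1` gives the size term a tenth of the
#'   weight of a full-scale mismatch).
#' @param na_penalty squared deviation charged for every data point whose
#'   prediction is unresolved (an oscillating, non-converged node); default
#'   1.0, i.e. an oscillating prediction counts as a maximal mismatch.
#' @return a list of class `scoring_config`.
#' @export
scoring_config <- function(alpha, na_penalty = 1.0) {
  stopifnot(alpha >= 0, na_penalty >= 0)
  structure(list(alpha = alpha, na_penalty = na_penalty),
            class = "scoring_config")
}

#' Fit term: mean squared deviation between prediction and data
#'
#' Averages the squared deviation between the predicted state of each
#' measured species and the normalized measurement over all matched
#' (condition, signal, time) cells. Missing measurements are excluded from
#' both the sum and the denominator `n_g`; unresolved predictions
#' contribute `na_penalty`. Because the data is normalized but not
#' discretized, an intermediate measurement (say 0.5) penalizes either
#' Boolean prediction equally and mildly, reflecting the uncertainty about
#' its on/off call.
#'
#' @param sim a `sim_result` from [simulate_all()] (or any conditions x
#'   nodes matrix with attribute-free states passed via `states`).
#' @param data the [midas] dataset the simulation was aligned to.
#' @param time_index index into `data$times` of the pseudo-steady-state
#'   time being scored (may be a vector to score several times against the
#'   same steady state).
#' @param na_penalty see [scoring_config()].
#' @return the mean squared deviation, with attribute `n_g` (number of
#'   matched points).
#' @export
theta_f <- function(sim, data, time_index, na_penalty = 1.0) {
  pred <- sim$states[, sim$sig_idx, drop = FALSE]
  sq <- 0
  n_g <- 0L
  for (ti in time_index) {
    obs <- data$values[, , ti, drop = FALSE]
    dim(obs) <- dim(obs)[1:2]
    ok <- !is.na(obs)
    n_g <- n_g + sum(ok)
    dev2 <- (pred - obs)^2
    dev2[is.na(pred) & ok] <- na_penalty  # oscillating node = mismatch
    sq <- sq + sum(dev2[ok])
  }
  if (n_g == 0L) stop("no comparable data points (n_g = 0)")
  structure(sq / n_g, n_g = n_g)
}

#' Size term: normalized count of selected gate inputs
#'
#' `theta_s = (1/v_es) * sum_e v_e * P_e` where `v_e` is the number of
#' inputs of gate `e` and `v_es` the total input count of the scaffold, so
#' the empty model scores 0 and the full scaffold 1.
#'
#' @param scaffold a `scaffold`.
#' @param bits 0/1 gate-selection vector.
#' @return the size penalty in \[0,1\].
#' @export
theta_s <- function(scaffold, bits) {
  check_bits(scaffold, bits)
  if (scaffold$v_es == 0) stop("empty scaffold (v_es = 0)")
  sum(scaffold$v_e * bits) / scaffold$v_es
}

#' Total bipartite score
#'
#' `theta = theta_f + alpha * theta_s`: fit to data plus a size penalty, so
#' that of two models explaining the data equally well the simpler one
#' wins.
#'
#' @inheritParams theta_s
#' @param sim,data,time_index see [theta_f()].
#' @param cfg a [scoring_config()].
#' @return list with `theta`, `theta_f`, `theta_s`, `n_g`.
#' @export
theta_score <- function(scaffold, bits, sim, data, time_index, cfg) {
  tf <- theta_f(sim, data, time_index, cfg$na_penalty)
  ts <- theta_s(scaffold, bits)
  list(theta = as.numeric(tf) + cfg$alpha * ts,
       theta_f = as.numeric(tf), theta_s = ts, n_g = attr(tf, "n_g"))
}

#' Objective closure for Boolean steady-state training
#'
#' Builds the `bits -> theta` function the optimizers minimize.
#'
#' @inheritParams simulate_all
#' @param time_index pseudo-steady-state time index scored against.
#' @param cfg a [scoring_config()].
#' @return a function of a bitstring returning the scalar score.
#' @export
boolean_objective <- function(scaffold, data, time_index, cfg,
                              aliases = NULL, max_iter = NULL) {
  force(scaffold); force(data); force(time_index); force(cfg)
  function(bits) {
    sim <- simulate_all(scaffold, bits, data, aliases, max_iter)
    theta_score(scaffold, bits, sim, data, time_index, cfg)$theta
  }
}

#' Write a score report as JSON
#'
#' @param report list as returned by [theta_score()] (optionally with extra
#'   entries, e.g. a per-readout residual table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
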