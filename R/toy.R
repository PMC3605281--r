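#' Toy prior knowledge network
#'
#' A small network of the canonical pathways downstream of EGF and TNFa:
#' an EGF -> SOS-1 -> ras -> ERK cascade with a slow negative feedback
#' from ERK back to SOS-1 (transient ERK activation), a TNFa -> map3k ->
#' ikk -> NFkB branch with NFkB inducing its own inhibitor IkB which
#' represses NFkB (oscillations), and p38 fed by both branches (ras and
#' map3k). EGF and TNFa are the stimuli; ERK, p38 and NFkB are measured.
#'
#' @return a [pkn] with 10 nodes and 11 edges, exactly 2 of them negative.
#' @export
toy_pkn <- function() {
  pkn(data.frame(
    source = c("EGF", "SOS-1", "ras", "ERK",
               "TNFa", "map3k", "ikk", "NFkB", "IkB",
               "ras", "map3k"),
    sign   = c(1, 1, 1, -1,
               1, 1, 1, 1, -1,
               1, 1),
    target = c("SOS-1", "ras", "ERK", "SOS-1",
               "map3k", "ikk", "NFkB", "IkB", "NFkB",
               "p38", "p38"),
    stringsAsFactors = FALSE))
}

#' Settings for the simulated toy dataset
#'
#' The defaults define the reference simulation: all three planted
#' behaviors on, measurements every 2 time units over \[0, 30\] (the
#' transient ERK peak, about one NFkB oscillation period and the slow p38
#' rise all fall inside this window), and a small additive Gaussian noise
#' (sd 0.01 on the \[0,1\] activation scale) truncated to \[0,1\].
#'
#' @param seed integer seed for the measurement noise.
#' @param noise_sd standard deviation of the additive noise.
#' @param times sampling times (same units as the kinetic time constants).
#' @param erk_feedback plant the slow negative feedback ERK -| SOS-1
#'   (transient ERK); if `FALSE` the generator uses a plain EGF -> SOS-1
#'   activation.
#' @param nfkb_feedback plant the NFkB -> IkB -| NFkB loop (oscillations);
#'   if `FALSE`, NFkB is plainly activated by ikk.
#' @param partial_p38 make p38 an AND of the two branches with gentle
#'   transfer functions (about half-maximal activation, reached only under
#'   EGF+TNFa co-stimulation); if `FALSE`, p38 is fully activated by
#'   map3k alone.
#' @return a list of class `toy_spec`.
#' @export
toy_spec <- function(seed = 1, noise_sd = 0.01, times = seq(0, 30, by = 2),
                     erk_feedback = TRUE, nfkb_feedback = TRUE,
                     partial_p38 = TRUE) {
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 times = times, erk_feedback = erk_feedback,
                 nfkb_feedback = nfkb_feedback, partial_p38 = partial_p38),
            class = "toy_spec")
}

# Ground-truth gates and kinetics of the generator. The ERK branch is an
# incoherent loop: SOS-1 responds fast, the ERK read-back is gentle
# (n=2) so the loop settles at a low-ERK interior equilibrium after a
# mid-window peak. The NFkB/IkB loop uses very steep transfers and equal
# slow time constants, giving a visibly damped oscillation within the
# sampling window. p38 integrates both branches slowly (tau = 8) through
# gentle transfers, reaching about half-maximum -- and only under
# co-stimulation, since it needs both ras and map3k.
toy_truth <- function(spec) {
  gates <- c(
    if (spec$erk_feedback) "EGF+!ERK=SOS-1" else "EGF=SOS-1",
    "SOS-1=ras", "ras=ERK",
    "TNFa=map3k", "map3k=ikk",
    if (spec$nfkb_feedback) "!IkB+ikk=NFkB" else "ikk=NFkB",
    "NFkB=IkB",
    if (spec$partial_p38) "map3k+ras=p38" else "map3k=p38")
  edges <- data.frame(
    target = c("SOS-1", "SOS-1", "ras", "ERK", "map3k", "ikk",
               "NFkB", "NFkB", "IkB", "p38", "p38"),
    input  = c("EGF", "ERK", "SOS-1", "ras", "TNFa", "map3k",
               "ikk", "IkB", "NFkB", "ras", "map3k"),
    n_h    = c(3, 2, 3, 3, 3, 3, 3, 24, 24, 2, 2),
    K      = c(0.3, 0.2, 0.52, 0.4, 0.3, 0.3, 0.3, 0.5, 0.5, 0.3, 0.3),
    stringsAsFactors = FALSE)
  tau <- c("SOS-1" = 4, ras = 3, ERK = 1.5, map3k = 1, ikk = 1,
           NFkB = 1.5, IkB = 8, p38 = 8)
  list(gates = gates, edges = edges, tau = tau)
}

#' Simulated toy perturbation dataset
#'
#' Integrates the ground-truth logic ODE model of [toy_pkn()] under the
#' four cue combinations (none, EGF, TNFa, EGF+TNFa), samples the measured
#' readouts (ERK, p38, NFkB) at `spec$times` and adds truncated Gaussian
#' noise. With all behaviors planted the data shows a transient ERK peak
#' (maximum before the last time), NFkB oscillations, and a partial
#' (about 0.5) p38 activation only under co-stimulation. Values are
#' activation levels already on the \[0,1\] scale used for scoring, so no
#' further normalization is needed.
#'
#' @param spec a [toy_spec()].
#' @param path optional path; if given the dataset is also written as a
#'   MIDAS CSV.
#' @return a [midas] with 4 conditions, 3 signals and `length(spec$times)`
#'   times. The ground truth is attached as attributes `true_bits` (on the
#'   full-network scaffold returned in attribute `scaffold`) and
#'   `true_params`.
#' @export
toy_data <- function(spec = toy_spec(), path = NULL) {
  net <- toy_pkn()
  sc <- expand_gates(net, max_and_arity = 2)
  truth <- toy_truth(spec)
  labels <- vapply(sc$gates, `[[`, "", "label")
  bits <- as.integer(labels %in% truth$gates)
  stopifnot(sum(bits) == length(truth$gates))
  params <- ode_params(truth$edges, truth$tau)

  treatments <- as.matrix(expand.grid(EGF = c(0, 1), TNFa = c(0, 1)))
  signals <- c("ERK", "p38", "NFkB")
  skel <- midas(stimuli = c("EGF", "TNFa"), inhibitors = character(),
                signals = signals, times = spec$times,
                treatments = treatments,
                values = array(NA_real_, c(nrow(treatments), 3,
                                           length(spec$times))))
  traj <- integrate_ode(sc, bits, params, skel, times = spec$times)
  sig_idx <- attr(traj, "sig_idx")
  vals <- traj[, sig_idx, , drop = FALSE]
  set.seed(spec$seed)
  noise <- array(stats::rnorm(length(vals), 0, spec$noise_sd), dim(vals))
  vals <- pmin(1, pmax(0, vals + noise))
  out <- midas(stimuli = skel$stimuli, inhibitors = character(),
               signals = signals, times = spec$times,
               treatments = treatments, values = vals)
  attr(out, "scaffold") <- sc
  attr(out, "true_bits") <- bits
  attr(out, "true_params") <- params
  if (!is.null(path)) write_midas(out, path)
  out
}
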