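#' Configuration of a full analysis run
#'
#' Bundles every choice of a pipeline run so that a finished analysis can
#' be reproduced from its manifest alone.
#'
#' @param sif path to the prior knowledge network (SIF).
#' @param midas path to the dataset (MIDAS CSV).
#' @param outdir output directory (created if missing).
#' @param formalism one of `"bool_ss"`, `"bool_2t"`, `"dt"`, `"fuzzy"`,
#'   `"ode"`.
#' @param alpha size-penalty weight (see [scoring_config()]).
#' @param seed integer seed for the whole run.
#' @param normalize apply [normalize_midas()] to the raw data; set to
#'   `FALSE` for data already on the \[0,1\] scale.
#' @param norm a [normalization_config()].
#' @param ga a [ga_config()] (its seed is overridden by `seed`).
#' @param time_index scored time for `bool_ss` / `fuzzy` (default: last).
#' @param t1_index,t2_index the two pseudo-steady-state times for
#'   `bool_2t` (defaults: middle and last time).
#' @param max_and_arity scaffold expansion limit, see [expand_gates()].
#' @param aliases dataset-to-network name map, see [mark_status()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(sif, midas, outdir, formalism = c("bool_ss",
                         "bool_2t", "dt", "fuzzy", "ode"),
                       alpha = 0.1, seed = 1, normalize = TRUE,
                       norm = normalization_config(), ga = ga_config(),
                       time_index = NULL, t1_index = NULL, t2_index = NULL,
                       max_and_arity = 2, aliases = NULL) {
  formalism <- match.arg(formalism)
  structure(list(sif = sif, midas = midas, outdir = outdir,
                 formalism = formalism, alpha = alpha,
                 seed = as.integer(seed), normalize = normalize,
                 norm = norm, ga = ga, time_index = time_index,
                 t1_index = t1_index, t2_index = t2_index,
                 max_and_arity = max_and_arity, aliases = aliases),
            class = "run_config")
}

validate_run <- function(cfg, data) {
  n_post <- sum(data$times > min(data$times))
  if (cfg$formalism == "bool_2t" && n_post < 2)
    stop("bool_2t needs at least 2 post-baseline time points")
  if (cfg$formalism %in% c("dt", "ode") && length(data$times) < 3)
    stop(sprintf("%s needs time courses (>= 3 time points)", cfg$formalism))
  invisible(TRUE)
}

#' Run the complete training pipeline
#'
#' Reads the network and data, normalizes, builds the scaffold, trains
#' under the requested formalism and writes every artifact of the analysis
#' to `cfg$outdir`: the normalized dataset, the scaffold (SIF + JSON), the
#' search archive, edge-frequency and node-status attribute files with a
#' DOT export, the best model as SIF, per-readout fit plots, a JSON score
#' summary and a reproducibility manifest.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with the trained objects (`scaffold`,
#'   `result`, `scores`, paths of all artifacts).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "import"
  out <- try({
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    net <- read_sif(cfg$sif)
    data <- read_midas(cfg$midas)
    validate_run(cfg, data)
    if (cfg$normalize) data <- normalize_midas(data, cfg$norm)
    write_midas(data, file.path(cfg$outdir, "normalized_midas.csv"))

    stage <- "preprocess"
    sc <- preprocess(net, data, aliases = cfg$aliases,
                     max_and_arity = cfg$max_and_arity)
    write_scaffold(sc, file.path(cfg$outdir, "scaffold"))

    stage <- "train"
    ga <- cfg$ga
    ga$seed <- cfg$seed
    scoring <- scoring_config(alpha = cfg$alpha)
    ti <- if (is.null(cfg$time_index)) length(data$times) else cfg$time_index
    trained <- switch(cfg$formalism,
      bool_ss = {
        res <- ga_optimize(sc$n_gates,
                           boolean_objective(sc, data, ti, scoring,
                                             cfg$aliases), ga)
        list(result = res, bits = res$best_bits, freq = res$frequency,
             time_index = ti)
      },
      bool_2t = {
        t1 <- if (is.null(cfg$t1_index))
          max(2L, ceiling(length(data$times) / 2)) else cfg$t1_index
        t2 <- if (is.null(cfg$t2_index)) length(data$times) else cfg$t2_index
        res <- train_two_steps(sc, data, t1, t2, scoring, ga, cfg$aliases)
        list(result = res, bits = pmax(res$bits1, res$bits2),
             freq = pmax(res$tau1$frequency, res$tau2$frequency),
             time_index = t2)
      },
      dt = {
        res <- train_dt(sc, data, scoring, ga = ga, aliases = cfg$aliases)
        list(result = res, bits = res$best_bits,
             freq = res$search$frequency[seq_len(sc$n_gates)],
             delta = res$best_delta)
      },
      fuzzy = {
        res <- train_fuzzy(sc, data, ti, scoring, ga = ga,
                           aliases = cfg$aliases)
        list(result = res, bits = res$model$bits,
             freq = res$search$frequency[seq_len(sc$n_gates)],
             time_index = ti, model = res$model)
      },
      ode = {
        pre <- ga_optimize(sc$n_gates,
                           boolean_objective(sc, data, ti, scoring,
                                             cfg$aliases), ga)
        fit <- fit_ode(sc, pre$best_bits, data, seed = cfg$seed,
                       aliases = cfg$aliases)
        write_ode_params(fit, file.path(cfg$outdir, "ode_params.json"))
        list(result = fit, bits = pre$best_bits, freq = pre$frequency,
             pre = pre)
      })

    stage <- "report"
    report_run(cfg, net, data, sc, trained)
  }, silent = TRUE)
  if (inherits(out, "try-error"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(attr(out, "condition"))))
  invisible(out)
}

run_scores <- function(cfg, data, sc, trained) {
  scoring <- scoring_config(alpha = cfg$alpha)
  switch(cfg$formalism,
    bool_ss = {
      sim <- simulate_all(sc, trained$bits, data, cfg$aliases)
      theta_score(sc, trained$bits, sim, data, trained$time_index, scoring)
    },
    bool_2t = {
      r <- trained$result
      c(list(theta_tau1 = r$tau1$best_score,
             theta_tau2 = r$tau2$best_score),
        n_tau2_gates = sum(r$bits2))
    },
    dt = trained$result$best,
    fuzzy = list(theta = trained$result$best),
    ode = list(mse = trained$result$mse))
}

# simulated values for the scored time(s), per condition x signal
run_predictions <- function(cfg, data, sc, trained) {
  switch(cfg$formalism,
    bool_ss = {
      sim <- simulate_all(sc, trained$bits, data, cfg$aliases)
      sim$states[, sim$sig_idx, drop = FALSE]
    },
    bool_2t = {
      sim <- trained$result$sim2
      sim$states[, sim$sig_idx, drop = FALSE]
    },
    dt = {
      setup <- condition_setup(sc, data, cfg$aliases)
      delta <- trained$delta
      n_steps <- max(1L, min(1000L,
                             as.integer(ceiling(max(data$times) / delta))))
      traj <- traj_core(sc, trained$bits, setup$init, setup$clamp, n_steps)
      steps <- pmin(round(data$times / delta), n_steps) + 1L
      out <- array(NA_real_, c(dim(traj)[2], length(setup$sig_idx),
                               length(data$times)))
      for (ti in seq_along(steps))
        out[, , ti] <- traj[steps[ti], , setup$sig_idx]
      out
    },
    fuzzy = {
      sim <- simulate_fuzzy(sc, trained$model, data, cfg$aliases)
      sim$states[, sim$sig_idx, drop = FALSE]
    },
    ode = {
      traj <- integrate_ode(sc, trained$bits, trained$result$params, data,
                            aliases = cfg$aliases)
      traj[, attr(traj, "sig_idx"), , drop = FALSE]
    })
}

report_run <- function(cfg, net, data, sc, trained) {
  outdir <- cfg$outdir
  status <- attr(sc, "status")
  lab <- function(s) {
    if (s$stimulated) "stimulated" else if (s$inhibited) "inhibited"
    else if (s$measured) "measured" else "unknown"
  }
  node_status <- stats::setNames(
    vapply(seq_len(nrow(status)), function(i) lab(status[i, ]), ""),
    status$node)
  comp_net <- sc$pkn
  freq <- edge_frequencies(sc, trained$freq)
  write_network_outputs(comp_net, file.path(outdir, "model"),
                        node_status = node_status, edge_frequency = freq)

  best_sc <- scaffold_new(sc$nodes, sc$gates[trained$bits == 1], sc$pkn)
  write_scaffold(best_sc, file.path(outdir, "best_model"))
  if (inherits(trained$result, "search_result"))
    write_archive(trained$result, file.path(outdir, "archive.csv"))
  else if (!is.null(trained$result$search))
    write_archive(trained$result$search, file.path(outdir, "archive.csv"))
  else if (!is.null(trained$result$tau1)) {
    write_archive(trained$result$tau1, file.path(outdir, "archive_tau1.csv"))
    write_archive(trained$result$tau2, file.path(outdir, "archive_tau2.csv"))
  }

  scores <- run_scores(cfg, data, sc, trained)
  write_score_report(scores, file.path(outdir, "scores.json"))
  plot_fit(cfg, data, sc, trained, file.path(outdir, "fit.png"))

  manifest <- list(
    config = cfg[setdiff(names(cfg), c("ga", "norm"))],
    ga = unclass(cfg$ga), norm = unclass(cfg$norm),
    package_version = as.character(utils::packageVersion("lognet")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  list(scaffold = sc, trained = trained, scores = scores, outdir = outdir)
}

# One panel per readout: measurements (lines+points per condition) with
# model predictions (dashed); green/red background shading per condition
# column encodes whether the prediction is closer to the data than the
# opposite extreme call.
plot_fit <- function(cfg, data, sc, trained, path) {
  grDevices::png(path, width = 1400, height = 420 * length(data$signals),
                 res = 110)
  on.exit(grDevices::dev.off())
  C <- n_conditions(data)
  timecourse <- cfg$formalism %in% c("dt", "ode")
  graphics::par(mfrow = c(length(data$signals), 1),
                mar = c(3.5, 4, 2, 1))
  pred <- run_predictions(cfg, data, sc, trained)
  for (l in seq_along(data$signals)) {
    if (timecourse) {
      graphics::matplot(data$times, t(data$values[, l, ]), type = "b",
                        pch = 16, lty = 1, ylim = c(0, 1),
                        xlab = "time", ylab = data$signals[l])
      graphics::matlines(data$times, t(pred[, l, ]), lty = 2)
    } else {
      obs <- data$values[, l, trained$time_index]
      prd <- pred[, l]
      graphics::plot(seq_len(C), obs, pch = 16, ylim = c(0, 1),
                     xlab = "condition", ylab = data$signals[l],
                     xaxt = "n")
      graphics::axis(1, at = seq_len(C))
      good <- !is.na(prd) & !is.na(obs) &
        (abs(prd - obs) <= abs((1 - round(prd)) - obs))
      for (k in seq_len(C))
        graphics::rect(k - 0.4, -0.04, k + 0.4, 1.04, border = NA,
                       col = if (is.na(obs[k])) "grey90"
                             else if (good[k]) grDevices::rgb(0, 1, 0, 0.15)
                             else grDevices::rgb(1, 0, 0, 0.15))
      graphics::points(seq_len(C), obs, pch = 16)
      graphics::points(seq_len(C), prd, pch = 4, col = "blue", cex = 1.4)
    }
    graphics::title(data$signals[l])
  }
  invisible(path)
}

#' Two-time-scale benchmark driver
#'
#' Runs the full two-pseudo-steady-state analysis on a user-supplied
#' network and dataset and reports the summary statistics used to compare
#' against published results: scaffold interaction count, empty- and
#' full-model scores at the first time scale, and average trained scores
#' at both time scales over independent optimization runs.
#'
#' @param sif,midas input paths.
#' @param t1_index,t2_index scored time indices.
#' @param alpha size-penalty weight.
#' @param n_runs independent GA trainings to average over (default 3).
#' @param ga a [ga_config()]; run `i` uses `seed + i`.
#' @param normalize,norm,aliases as in [run_config()].
#' @return list: `n_interactions` (scaffold gate-input count per the SIF
#'   convention: one interaction per hyperedge), `empty_score`,
#'   `full_score`, `mean_theta_tau1`, `mean_theta_tau2`, `runs`.
#' @export
benchmark_two_step <- function(sif, midas, t1_index, t2_index, alpha = 1e-4,
                               n_runs = 3, ga = ga_config(),
                               normalize = TRUE,
                               norm = normalization_config(),
                               aliases = NULL) {
  net <- read_sif(sif)
  data <- read_midas(midas)
  if (normalize) data <- normalize_midas(data, norm)
  sc <- preprocess(net, data, aliases = aliases)
  scoring <- scoring_config(alpha = alpha)
  obj <- boolean_objective(sc, data, t1_index, scoring, aliases)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    gi <- ga
    gi$seed <- ga$seed + i
    runs[[i]] <- train_two_steps(sc, data, t1_index, t2_index, scoring, gi,
                                 aliases)
  }
  list(n_interactions = sc$n_gates,
       empty_score = obj(integer(sc$n_gates)),
       full_score = obj(rep(1L, sc$n_gates)),
       mean_theta_tau1 = mean(vapply(runs, function(r) r$tau1$best_score, 0)),
       mean_theta_tau2 = mean(vapply(runs, function(r) r$tau2$best_score, 0)),
       runs = runs)
}
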