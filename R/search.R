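#' Genetic-algorithm settings
#'
#' Defaults are deliberately generous (population 50, up to 500
#' generations) with early stopping after `stall` generations without
#' improvement; the per-bit mutation probability is `mutation / n_bits` so
#' that on average `mutation` bits flip per chromosome.
#'
#' @param pop_size population size (>= 2).
#' @param generations maximum number of generations.
#' @param mutation expected number of bit flips per chromosome per
#'   generation (per-bit rate is `mutation / n_bits`).
#' @param crossover probability of uniform crossover for each offspring.
#' @param elitism number of best chromosomes copied unchanged.
#' @param stall stop after this many generations without improvement.
#' @param seed integer random seed (reproducible searches).
#' @param tolerance relative tolerance defining the reported model family:
#'   all evaluated models with score `<= (1 + tolerance) * best` (e.g. 0.1
#'   keeps models within 10\% of the optimum). The appropriate value
#'   depends on the experimental error of the dataset.
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50, generations = 500, mutation = 0.5,
                      crossover = 0.8, elitism = 2, stall = 100,
                      seed = 1, tolerance = 0.1) {
  stopifnot(pop_size >= 2, generations >= 1, mutation >= 0,
            crossover >= 0, crossover <= 1, elitism >= 0, stall >= 1,
            tolerance >= 0)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation = mutation, crossover = crossover,
                 elitism = as.integer(elitism), stall = as.integer(stall),
                 seed = as.integer(seed), tolerance = tolerance),
            class = "ga_config")
}

archive_new <- function() {
  env <- new.env(parent = emptyenv())
  env$scores <- new.env(parent = emptyenv())
  env$order <- character()
  env$generation <- integer()
  env
}

archive_eval <- function(arch, bits, objective, generation = 0L) {
  key <- paste(bits, collapse = "")
  if (!is.null(arch$scores[[key]])) return(arch$scores[[key]])
  s <- objective(bits)
  arch$scores[[key]] <- s
  arch$order <- c(arch$order, key)
  arch$generation <- c(arch$generation, generation)
  s
}

archive_table <- function(arch) {
  data.frame(bits = arch$order,
             score = vapply(arch$order, function(k) arch$scores[[k]], 0,
                            USE.NAMES = FALSE),
             generation = arch$generation,
             stringsAsFactors = FALSE)
}

key_to_bits <- function(key) as.integer(strsplit(key, "")[[1]])

search_result <- function(arch, n_bits, tolerance) {
  tab <- archive_table(arch)
  best_i <- which.min(tab$score)
  best_score <- tab$score[best_i]
  cutoff <- if (best_score >= 0) (1 + tolerance) * best_score
            else (1 - tolerance) * best_score
  fam_keys <- tab$bits[tab$score <= cutoff + 1e-12]
  fam <- do.call(rbind, lapply(fam_keys, key_to_bits))
  freq <- if (length(fam_keys)) colMeans(fam) else rep(NA_real_, n_bits)
  structure(list(best_bits = key_to_bits(tab$bits[best_i]),
                 best_score = best_score,
                 archive = tab,
                 family = fam,
                 frequency = freq,
                 n_evaluated = nrow(tab)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(paste0("Search result: best score %.6g ",
                     "(%d gates selected), %d models evaluated, ",
                     "family of %d\n"),
              x$best_score, sum(x$best_bits), x$n_evaluated,
              nrow(x$family)))
  invisible(x)
}

apply_mask <- function(bits, mask) {
  if (is.null(mask)) return(bits)
  fixed <- !is.na(mask)
  bits[fixed] <- mask[fixed]
  bits
}

#' Train a model by genetic algorithm
#'
#' Minimizes an arbitrary objective over gate-selection bitstrings.
#' Tournament selection, uniform crossover, per-bit mutation, elitism. The
#' empty and the full model are injected into the initial population so
#' both baselines are always part of the search. Every evaluated bitstring
#' is archived exactly once; the reported model family is all evaluated
#' models within the relative tolerance of the best score, with per-gate
#' selection frequencies across the family.
#'
#' @param n_bits chromosome length (e.g. `scaffold$n_gates`).
#' @param objective function `bits -> scalar score` to minimize.
#' @param cfg a [ga_config()].
#' @param search_mask optional vector of length `n_bits`: `NA` for bits
#'   searched by the GA, `0`/`1` for bits fixed by the user (edges known to
#'   be absent/present).
#' @return a `search_result`: `best_bits`, `best_score`, `archive`
#'   (data.frame bits/score/generation), `family` (matrix), `frequency`
#'   (per-gate selection frequency in the family), `n_evaluated`.
#' @export
ga_optimize <- function(n_bits, objective, cfg = ga_config(),
                        search_mask = NULL) {
  stopifnot(n_bits >= 1)
  if (!is.null(search_mask) && length(search_mask) != n_bits)
    stop("search_mask length must equal n_bits")
  arch <- archive_new()
  free <- if (is.null(search_mask)) seq_len(n_bits) else which(is.na(search_mask))
  if (!length(free)) {
    warning("all bits fixed by search_mask; nothing to optimize")
    bits <- apply_mask(integer(n_bits), search_mask)
    archive_eval(arch, bits, objective)
    return(search_result(arch, n_bits, cfg$tolerance))
  }
  set.seed(cfg$seed)
  p_bit <- min(1, cfg$mutation / length(free))
  pop <- matrix(as.integer(stats::runif(cfg$pop_size * n_bits) < 0.5),
                cfg$pop_size, n_bits)
  pop[1, ] <- 0L  # empty model baseline
  pop[2, ] <- 1L  # full scaffold baseline
  pop <- t(apply(pop, 1, apply_mask, mask = search_mask))
  if (n_bits == 1L) pop <- matrix(as.integer(pop), ncol = 1L)

  scores <- apply(pop, 1, archive_eval, arch = arch, objective = objective,
                  generation = 0L)
  best <- min(scores)
  stall_count <- 0L
  for (gen in seq_len(cfg$generations)) {
    ord <- order(scores)
    newpop <- pop[ord[seq_len(min(cfg$elitism, cfg$pop_size))], ,
                  drop = FALSE]
    while (nrow(newpop) < cfg$pop_size) {
      # binary tournament selection
      pick <- function() {
        ij <- sample.int(cfg$pop_size, 2L)
        ij[which.min(scores[ij])]
      }
      a <- pop[pick(), ]; b <- pop[pick(), ]
      child <- if (stats::runif(1) < cfg$crossover) {
        take_a <- stats::runif(n_bits) < 0.5
        ifelse(take_a, a, b)
      } else a
      flip <- which(stats::runif(length(free)) < p_bit)
      if (length(flip)) child[free[flip]] <- 1L - child[free[flip]]
      child <- apply_mask(child, search_mask)
      newpop <- rbind(newpop, child)
    }
    pop <- newpop
    scores <- apply(pop, 1, archive_eval, arch = arch,
                    objective = objective, generation = gen)
    gen_best <- min(scores)
    if (gen_best < best - 1e-12) {
      best <- gen_best
      stall_count <- 0L
    } else stall_count <- stall_count + 1L
    if (stall_count >= cfg$stall) break
  }
  search_result(arch, n_bits, cfg$tolerance)
}

#' Exhaustive search over all bitstrings
#'
#' Enumerates every model in the scaffold (or masked subspace) and returns
#' the global optimum. Intended as a ground-truth oracle for small
#' scaffolds; refuses more than 20 free bits.
#'
#' @inheritParams ga_optimize
#' @param tolerance family tolerance (see [ga_config()]).
#' @return a `search_result` whose archive contains all `2^n_free` models.
#' @export
exhaustive_optimize <- function(n_bits, objective, tolerance = 0.1,
                                search_mask = NULL) {
  free <- if (is.null(search_mask)) seq_len(n_bits) else which(is.na(search_mask))
  if (length(free) > 20L)
    stop(sprintf("refusing exhaustive search over 2^%d models", length(free)))
  arch <- archive_new()
  base <- apply_mask(integer(n_bits), search_mask)
  for (i in 0:(2^length(free) - 1L)) {
    bits <- base
    bits[free] <- as.integer(intToBits(i)[seq_along(free)])
    archive_eval(arch, bits, objective)
  }
  search_result(arch, n_bits, tolerance)
}

#' Dump a search archive to CSV
#'
#' @param result a `search_result`.
#' @param path output path; columns `bits`, `score`, `generation`.
#' @return `path`, invisibly.
#' @export
write_archive <- function(result, path) {
  utils::write.csv(result$archive, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-PKN-edge selection frequency
#'
#' Projects per-gate selection frequencies back onto the edges of the
#' originating network: an edge's frequency is the maximum frequency of any
#' gate whose provenance includes it.
#'
#' @param scaffold a `scaffold`.
#' @param frequency per-gate frequencies (`search_result$frequency`).
#' @return named numeric vector keyed by `"source sign target"`.
#' @export
edge_frequencies <- function(scaffold, frequency) {
  out <- numeric()
  for (g in seq_len(scaffold$n_gates)) {
    for (ek in scaffold$provenance[[g]]) {
      out[ek] <- max(out[ek], frequency[g], na.rm = TRUE)
    }
  }
  out
}
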