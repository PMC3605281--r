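#' Normalization settings for raw measurements
#'
#' Raw (phospho)proteomic intensities are mapped to \[0,1\] before logic
#' modeling: each measurement is turned into a fold change relative to the
#' within-condition baseline, squashed through a Hill function, and then
#' multiplied by a penalty that down-weights signals close to the
#' background of the assay. The data is never discretized, only rescaled.
#'
#' @param mode `"increase"` (fold change `max(0, (x - x0)/x0)`, readouts
#'   expected to rise above baseline), `"decrease"` (`max(0, (x0 - x)/x0)`)
#'   or `"two_sided"` (`abs(x - x0)/x0`, direction-agnostic).
#' @param hill_exponent Hill coefficient `k > 0` applied to the fold change
#'   (dimensionless; default 2).
#' @param hill_ec50 fold change at which the Hill transform reaches one
#'   half (fold-change units; default 0.5).
#' @param background_threshold raw intensities at or below this value are
#'   treated as background and set to 0 (raw signal units; default 0).
#' @return a list of class `normalization_config`.
#' @export
normalization_config <- function(mode = c("increase", "decrease", "two_sided"),
                                 hill_exponent = 2, hill_ec50 = 0.5,
                                 background_threshold = 0) {
  mode <- match.arg(mode)
  if (hill_exponent <= 0) stop("hill_exponent must be > 0")
  if (hill_ec50 <= 0) stop("hill_ec50 must be > 0")
  structure(list(mode = mode, hill_exponent = hill_exponent,
                 hill_ec50 = hill_ec50,
                 background_threshold = background_threshold),
            class = "normalization_config")
}

#' Normalize raw measurements to \[0,1\]
#'
#' For each condition/signal/time cell with raw value `x`, baseline value
#' `x0` (same condition and signal at the earliest time) and `M` the maximum
#' raw measurement of that signal across all conditions and times:
#' \deqn{fc = \max(0, (x - x0)/x0), \quad
#'       H(fc) = fc^k / (ec50^k + fc^k), \quad
#'       out = H(fc) \cdot \min(1, x/M)}
#' (increase mode; see [normalization_config()] for the other fold-change
#' modes). Values at or below the background threshold map to 0. Cells with
#' a zero baseline cannot be expressed as a fold change and are flagged
#' missing. The transform is monotone in `x` and bounded in \[0,1\].
#'
#' @param data a [midas] object with raw values.
#' @param cfg a [normalization_config()].
#' @return a [midas] object with values in \[0,1\] (or `NA`).
#' @export
normalize_midas <- function(data, cfg = normalization_config()) {
  stopifnot(inherits(data, "midas"), inherits(cfg, "normalization_config"))
  v <- data$values
  out <- array(NA_real_, dim = dim(v), dimnames = dimnames(v))
  k <- cfg$hill_exponent; ec50 <- cfg$hill_ec50
  baseline <- 1L  # smallest time in the file is the control
  for (l in seq_along(data$signals)) {
    M <- suppressWarnings(max(v[, l, ], na.rm = TRUE))
    if (!is.finite(M)) {
      warning(sprintf("signal %s has no measurements; left missing",
                      data$signals[l]))
      next
    }
    for (cond in seq_len(nrow(data$treatments))) {
      x0 <- v[cond, l, baseline]
      for (ti in seq_along(data$times)) {
        x <- v[cond, l, ti]
        if (is.na(x)) next
        if (x <= cfg$background_threshold) { out[cond, l, ti] <- 0; next }
        if (is.na(x0) || x0 == 0) next  # no fold change defined -> missing
        fc <- switch(cfg$mode,
                     increase = max(0, (x - x0) / x0),
                     decrease = max(0, (x0 - x) / x0),
                     two_sided = abs(x - x0) / x0)
        H <- if (fc == 0) 0 else fc^k / (ec50^k + fc^k)
        pen <- min(1, x / M)
        out[cond, l, ti] <- H * pen
      }
    }
  }
  data$values <- out
  data
}
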