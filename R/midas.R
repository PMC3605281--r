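#' Construct a perturbation dataset
#'
#' Container for a perturbation experiment: a set of conditions (combinations
#' of stimuli and inhibitors applied to the cells), a set of measured
#' readouts (signals, typically phosphoproteins), and measurements on a
#' common time grid. This is the in-memory form of a MIDAS file.
#'
#' @param stimuli character vector of stimulus cue names.
#' @param inhibitors character vector of inhibitor cue names (the species
#'   blocked by the drug, without any column-name suffix). Must be disjoint
#'   from `stimuli`.
#' @param signals character vector of readout names.
#' @param times numeric vector of measurement times, strictly increasing;
#'   the smallest is taken as the baseline (control) time.
#' @param treatments conditions x (stimuli + inhibitors) matrix of 0/1
#'   entries; column order is `c(stimuli, inhibitors)`.
#' @param values conditions x signals x times numeric array; `NA` marks a
#'   missing measurement.
#' @return an object of class `midas`.
#' @export
midas <- function(stimuli, inhibitors, signals, times, treatments, values) {
  stimuli <- as.character(stimuli); inhibitors <- as.character(inhibitors)
  signals <- as.character(signals)
  if (length(intersect(stimuli, inhibitors)))
    stop("stimuli and inhibitors must be disjoint")
  times <- as.numeric(times)
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  treatments <- as.matrix(treatments)
  if (!all(treatments %in% c(0, 1)))
    stop("treatment entries must be 0 or 1")
  if (ncol(treatments) != length(stimuli) + length(inhibitors))
    stop("treatment matrix has wrong number of columns")
  colnames(treatments) <- c(stimuli, inhibitors)
  values <- array(as.numeric(values),
                  dim = c(nrow(treatments), length(signals), length(times)),
                  dimnames = list(NULL, signals, as.character(times)))
  structure(list(stimuli = stimuli, inhibitors = inhibitors,
                 signals = signals, times = times,
                 treatments = treatments, values = values),
            class = "midas")
}

#' @export
print.midas <- function(x, ...) {
  cat(sprintf(paste0("MIDAS dataset: %d conditions, %d signals, %d times\n",
                     "  stimuli:    %s\n  inhibitors: %s\n  signals:    %s\n",
                     "  times:      %s\n"),
              nrow(x$treatments), length(x$signals), length(x$times),
              paste(x$stimuli, collapse = ", "),
              if (length(x$inhibitors)) paste(x$inhibitors, collapse = ", ") else "(none)",
              paste(x$signals, collapse = ", "),
              paste(x$times, collapse = ", ")))
  invisible(x)
}

n_conditions <- function(data) nrow(data$treatments)

#' Read a MIDAS CSV file
#'
#' MIDAS is a flat CSV format for perturbation data: one row per
#' condition/time combination, a `TR:` column per cue (0 = absent,
#' 1 = present), and per readout a `DA:` column (measurement time) paired
#' with a `DV:` column (measured value). A single `DA:ALL` column may stand
#' for all readouts. `TR:...:CellLine` annotation columns are ignored.
#'
#' Inhibitor cues are recognized by a column-name suffix on the `TR:` label
#' (default `"i"`, e.g. `TR:Raf1i` means the drug inhibiting Raf1); the
#' suffix is stripped to recover the target species name. For dialects that
#' do not follow the suffix convention, name the inhibited species directly
#' via `inhibitor_map`.
#'
#' @param path path to the CSV file.
#' @param inhibitor_suffix suffix marking inhibitor `TR:` columns.
#' @param inhibitor_map optional named character vector mapping a `TR:`
#'   column cue name to the inhibited species, overriding suffix detection
#'   (e.g. `c(PD325901 = "MEK")`).
#' @param merge_duplicates if `TRUE`, rows measuring the same
#'   condition/signal/time cell are averaged; if `FALSE` (default) duplicate
#'   cells are an error, since silent averaging hides data problems.
#' @return a [midas] object.
#' @export
read_midas <- function(path, inhibitor_suffix = "i", inhibitor_map = NULL,
                       merge_duplicates = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(df)
  tr_cols <- grep("^TR:", hdr, value = TRUE)
  tr_cols <- tr_cols[!grepl(":CellLine$", tr_cols, ignore.case = TRUE)]
  if (!length(tr_cols)) stop("MIDAS format error: no TR: columns")
  da_cols <- grep("^DA:", hdr, value = TRUE)
  dv_cols <- grep("^DV:", hdr, value = TRUE)
  signals <- sub("^DV:", "", dv_cols)
  if (!length(dv_cols)) stop("MIDAS format error: no DV: columns")
  da_names <- sub("^DA:", "", da_cols)
  if (identical(toupper(da_names), "ALL")) {
    da_for_signal <- stats::setNames(rep(da_cols, length(signals)), signals)
  } else {
    missing_dv <- setdiff(da_names, signals)
    if (length(missing_dv))
      stop(sprintf("MIDAS format error: DA: column without matching DV: (%s)",
                   paste(missing_dv, collapse = ", ")))
    missing_da <- setdiff(signals, da_names)
    if (length(missing_da))
      stop(sprintf("MIDAS format error: DV: column without matching DA: (%s)",
                   paste(missing_da, collapse = ", ")))
    da_for_signal <- stats::setNames(paste0("DA:", signals), signals)
  }

  trm <- as.matrix(df[, tr_cols, drop = FALSE])
  if (!all(trm %in% c(0, 1)))
    stop("MIDAS format error: non-binary TR: entry")
  cues <- sub("^TR:", "", tr_cols)
  is_inh <- logical(length(cues))
  targets <- cues
  for (j in seq_along(cues)) {
    if (!is.null(inhibitor_map) && cues[j] %in% names(inhibitor_map)) {
      is_inh[j] <- TRUE
      targets[j] <- unname(inhibitor_map[cues[j]])
    } else if (nzchar(inhibitor_suffix) &&
               endsWith(cues[j], inhibitor_suffix) &&
               nchar(cues[j]) > nchar(inhibitor_suffix)) {
      is_inh[j] <- TRUE
      targets[j] <- substr(cues[j], 1L,
                           nchar(cues[j]) - nchar(inhibitor_suffix))
    }
  }
  stimuli <- targets[!is_inh]
  inhibitors <- targets[is_inh]

  cond_key <- apply(trm, 1L, paste, collapse = ",")
  cond_levels <- unique(cond_key)
  cond_of_row <- match(cond_key, cond_levels)
  treatments <- trm[match(cond_levels, cond_key), , drop = FALSE]
  colnames(treatments) <- targets
  treatments <- treatments[, c(which(!is_inh), which(is_inh)), drop = FALSE]

  times <- sort(unique(stats::na.omit(unlist(df[, da_cols, drop = FALSE]))))
  if (!length(times)) stop("MIDAS format error: no measurement times")

  values <- array(NA_real_, dim = c(length(cond_levels), length(signals),
                                    length(times)))
  counts <- array(0L, dim = dim(values))
  for (r in seq_len(nrow(df))) {
    k <- cond_of_row[r]
    for (l in seq_along(signals)) {
      tval <- df[r, da_for_signal[signals[l]]]
      v <- df[r, paste0("DV:", signals[l])]
      if (is.na(tval) || is.na(v)) next
      ti <- match(tval, times)
      if (counts[k, l, ti] > 0L && !merge_duplicates)
        stop(sprintf(paste0("duplicate measurement cell (condition %d, ",
                            "signal %s, time %g); set merge_duplicates=TRUE ",
                            "to average"), k, signals[l], tval))
      n0 <- counts[k, l, ti]
      prev <- if (n0 > 0L) values[k, l, ti] else 0
      values[k, l, ti] <- (prev * n0 + v) / (n0 + 1L)
      counts[k, l, ti] <- n0 + 1L
    }
  }
  midas(stimuli, inhibitors, signals, times, treatments, values)
}

#' Write a dataset to a MIDAS CSV file
#'
#' One row per condition/time combination; inhibitor columns carry the
#' suffix (`TR:<node><suffix>`) so [read_midas()] round-trips.
#'
#' @param data a [midas] object.
#' @param path output path.
#' @param inhibitor_suffix suffix appended to inhibitor cue names.
#' @return `path`, invisibly.
#' @export
write_midas <- function(data, path, inhibitor_suffix = "i") {
  stopifnot(inherits(data, "midas"))
  tr_names <- c(paste0("TR:", data$stimuli),
                if (length(data$inhibitors))
                  paste0("TR:", data$inhibitors, inhibitor_suffix))
  rows <- matrix(NA_real_, n_conditions(data) * length(data$times),
                 ncol(data$treatments) + 2L * length(data$signals))
  i <- 0L
  for (k in seq_len(n_conditions(data))) {
    for (ti in seq_along(data$times)) {
      i <- i + 1L
      rows[i, ] <- c(data$treatments[k, ],
                     rep(data$times[ti], length(data$signals)),
                     data$values[k, , ti])
    }
  }
  out <- as.data.frame(rows)
  names(out) <- c(tr_names, paste0("DA:", data$signals),
                  paste0("DV:", data$signals))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
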