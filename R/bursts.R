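#' Detect network bursts in a homogeneous culture
#'
#' Homogeneous cultures show all-or-none collective events (network bursts)
#' rather than community structure. ROIs are grid elements (the standard
#' layout is a 30 x 30 grid per cavity, ~5-10 neurons per element). A burst
#' is a firing sequence (chaining rule of [detect_sequences()]) in which at
#' least `min_fraction` of all ROIs participate; its time is the first
#' onset.
#'
#' @param onsets `ca_onsets` or named list of onset-time vectors over the
#'   grid ROIs.
#' @param window chaining window in seconds (default 0.2).
#' @param min_fraction minimum participating ROI fraction (default 0.5).
#' @return object of class `ca_bursts`: `times`, `participation` (fraction
#'   per burst), `n_roi`, `duration`.
#' @export
detect_network_bursts <- function(onsets, window = 0.2, min_fraction = 0.5) {
  stopifnot(length(onsets) >= 1, min_fraction >= 0, min_fraction <= 1)
  n_roi <- length(onsets)
  seqs <- detect_sequences(onsets, window = window)
  frac <- vapply(seqs$sequences, function(s) length(s$members) / n_roi,
                 numeric(1))
  keep <- frac >= min_fraction
  structure(list(
    times = vapply(seqs$sequences[keep], `[[`, numeric(1), "start"),
    participation = frac[keep],
    n_roi = n_roi,
    duration = attr(onsets, "duration")
  ), class = "ca_bursts")
}

#' @export
print.ca_bursts <- function(x, ...) {
  cat(sprintf("<ca_bursts> %d bursts over %d ROIs, mean participation %.2f\n",
              length(x$times), x$n_roi,
              if (length(x$times)) mean(x$participation) else NA))
  invisible(x)
}

#' Drift-corrected burst-rate ratio
#'
#' Ratio of burst counts after/before the chemical application, divided by
#' the control cavity's after/before burst ratio (same drift logic as the
#' firing-rate correction). Recordings of equal duration are assumed unless
#' durations are supplied.
#'
#' @param before,after `ca_bursts` of the perturbed cavity.
#' @param control_before,control_after `ca_bursts` of the control cavity.
#' @param duration_before,duration_after recording durations in seconds
#'   (default equal, so they cancel).
#' @return the corrected ratio (scalar).
#' @export
burst_rate_ratio <- function(before, after, control_before, control_after,
                             duration_before = 1, duration_after = 1) {
  nb <- length(before$times); na <- length(after$times)
  cb <- length(control_before$times); ca <- length(control_after$times)
  if (nb == 0) stop("perturbed cavity has no bursts before perturbation")
  if (cb == 0 || ca == 0) stop("control cavity has no bursts: drift unmeasurable")
  (na / duration_after / (nb / duration_before)) /
    (ca / duration_after / (cb / duration_before))
}
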