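#' Detect cluster activation onsets in fluorescence traces
#'
#' A cluster firing ramps the fluorescence up sharply, so onsets are frames
#' where the baseline-subtracted amplitude and the signal derivative are
#' concurrently high. Per ROI: the baseline is a running 10th percentile
#' over a `baseline_window` window; the noise s.d. is a robust MAD estimate
#' of the residual (thresholds are centered on the residual median, since
#' the percentile baseline sits below the noise mean); the derivative is
#' the forward difference of a 3-frame smoothed trace. Candidate events are
#' runs of at least `min_frames` consecutive frames above the `amp_k`
#' amplitude threshold (noise excursions last one or two frames, calcium
#' transients around a hundred) whose peak reaches twice the amplitude
#' threshold (rejecting threshold-grazing excursions on decay tails); the
#' onset is the first frame of the run at which the derivative also exceeds
#' its `deriv_k` threshold, and onsets closer than `refractory` merge into
#' one.
#'
#' @param recording a `ca_recording` (see [render_traces()], [read_traces_csv()]).
#' @param amp_k amplitude threshold in noise s.d. multiples (default 3).
#' @param deriv_k derivative threshold in derivative s.d. multiples (default 2).
#' @param refractory minimum separation between onsets, seconds (default 0.5).
#' @param baseline_window running-percentile window, seconds (default 30).
#' @param min_frames minimum run length of the amplitude criterion (frames).
#' @return an object of class `ca_onsets`: a named list of sorted onset-time
#'   vectors (seconds), with attributes `duration` and `params`.
#' @export
detect_onsets <- function(recording, amp_k = 3, deriv_k = 2,
                          refractory = 0.5, baseline_window = 30,
                          min_frames = 3L) {
  stopifnot(inherits(recording, "ca_recording"))
  if (!(amp_k > 0 && deriv_k > 0)) stop("`amp_k` and `deriv_k` must be > 0")
  tr <- recording$traces
  if (anyNA(tr)) stop("traces contain NA/NaN values")
  dt <- recording$frame_dt
  nt <- nrow(tr)
  out <- vector("list", ncol(tr))
  names(out) <- recording$roi_ids
  if (nt == 0L) return(new_onsets(out, duration = 0,
                                  params = list(amp_k = amp_k, deriv_k = deriv_k,
                                                refractory = refractory)))
  wf <- max(3L, round(baseline_window / dt))
  for (j in seq_len(ncol(tr))) {
    x <- tr[, j]
    base <- running_percentile(x, wf, p = 0.1)
    resid <- x - base
    sdn <- mad(resid)
    if (sdn == 0) sdn <- sd(resid)
    # 3-frame centered smoothing, then forward difference
    xs <- if (nt >= 3L) as.numeric(filter(x, rep(1 / 3, 3), sides = 2)) else x
    xs[is.na(xs)] <- x[is.na(xs)]
    dv <- c(diff(xs), 0)
    sdd <- mad(dv)
    if (sdd == 0) sdd <- sd(dv)
    if (is.na(sdn) || sdn == 0 || is.na(sdd) || sdd == 0) {
      out[[j]] <- numeric(0)  # constant trace
      next
    }
    amp_hit <- resid > median(resid) + amp_k * sdn
    dv_hit <- dv > deriv_k * sdd
    r <- rle(amp_hit)
    ends <- cumsum(r$lengths)
    ok <- r$values & r$lengths >= min_frames
    starts <- integer(0)
    peak_thr <- median(resid) + 2 * amp_k * sdn
    for (k in which(ok)) {
      run <- (ends[k] - r$lengths[k] + 1L):ends[k]
      if (max(resid[run]) <= peak_thr) next
      f <- run[dv_hit[run]]
      if (length(f)) starts <- c(starts, f[1])
    }
    if (length(starts) == 0L) { out[[j]] <- numeric(0); next }
    tt <- (starts - 1L) * dt
    # merge runs closer than the refractory period into one onset
    res <- tt[1]
    for (t in tt[-1]) if (t - res[length(res)] >= refractory) res <- c(res, t)
    out[[j]] <- res
  }
  new_onsets(out, duration = nt * dt,
             params = list(amp_k = amp_k, deriv_k = deriv_k,
                           refractory = refractory))
}

new_onsets <- function(x, duration = NULL, params = NULL) {
  structure(x, class = "ca_onsets", duration = duration, params = params)
}

#' @export
print.ca_onsets <- function(x, ...) {
  cat(sprintf("<ca_onsets> %d clusters, %d onsets", length(x),
              sum(lengths(x))))
  d <- attr(x, "duration")
  if (!is.null(d) && d > 0)
    cat(sprintf(", mean rate %.2f /min over %.1f min",
                mean(lengths(x)) / d * 60, d / 60))
  cat("\n")
  invisible(x)
}

# Running percentile by block quantiles at half-window steps, linearly
# interpolated back to every frame (fast approximation adequate for a
# slowly-varying baseline).
running_percentile <- function(x, w, p = 0.1) {
  n <- length(x)
  if (n <= w) return(rep(quantile(x, p, names = FALSE), n))
  step <- max(1L, w %/% 2L)
  centers <- unique(c(seq(1L, n, by = step), n))
  qs <- vapply(centers, function(c) {
    lo <- max(1L, c - w %/% 2L); hi <- min(n, c + w %/% 2L)
    quantile(x[lo:hi], p, names = FALSE)
  }, numeric(1))
  stats::approx(centers, qs, xout = seq_len(n), rule = 2)$y
}

#' Match detected onsets against ground truth
#'
#' Greedy one-to-one matching of detected to true onsets within `tol`
#' seconds, per cluster; returns precision, recall and counts. Used to
#' benchmark [detect_onsets()] on synthetic recordings.
#'
#' @param detected,truth `ca_onsets` or plain lists of onset-time vectors
#'   over the same clusters.
#' @param tol matching tolerance in seconds (default 0.04, i.e. 2 frames).
#' @return list with `precision`, `recall`, `n_detected`, `n_true`, `n_matched`.
#' @export
onset_recovery <- function(detected, truth, tol = 0.04) {
  stopifnot(length(detected) == length(truth))
  n_match <- 0L
  for (i in seq_along(truth)) {
    d <- detected[[i]]; tr <- truth[[i]]
    used <- logical(length(d))
    for (t0 in tr) {
      j <- which(!used & abs(d - t0) <= tol)
      if (length(j)) { used[j[1]] <- TRUE; n_match <- n_match + 1L }
    }
  }
  nd <- sum(lengths(detected)); ntr <- sum(lengths(truth))
  list(precision = if (nd > 0) n_match / nd else NA_real_,
       recall = if (ntr > 0) n_match / ntr else NA_real_,
       n_detected = nd, n_true = ntr, n_matched = n_match)
}
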