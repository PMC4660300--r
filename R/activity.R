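#' Summarize spontaneous activity of a recording
#'
#' Computes the per-cluster firing rate phi_i (firings/min), the mean
#' clusters' firing rate Phi (mean of phi over all clusters, silent clusters
#' included at zero), and the sequences' occurrence rate Psi (number of
#' detected firing sequences per minute).
#'
#' @param onsets a `ca_onsets` object or named list of onset-time vectors.
#' @param sequences a `ca_sequences` object for the same recording.
#' @param duration recording duration in seconds.
#' @param condition optional condition label (`"before"` or `"after"`).
#' @return an object of class `ca_activity_summary` with `phi` (named,
#'   firings/min), `Phi`, `Psi` (per min), `n_sequences`, `duration`,
#'   `condition`.
#' @export
summarize_activity <- function(onsets, sequences = NULL, duration = NULL,
                               condition = NA_character_) {
  duration <- duration %||% attr(onsets, "duration")
  if (is.null(duration) || !is.numeric(duration) || duration <= 0)
    stop("`duration` must be > 0")
  phi <- lengths(onsets) / duration * 60
  names(phi) <- names(onsets) %||% cluster_ids(length(onsets))
  M <- if (is.null(sequences)) NA_integer_ else length(sequences$sequences)
  structure(list(phi = phi, Phi = mean(phi),
                 Psi = if (is.na(M)) NA_real_ else M / duration * 60,
                 n_sequences = M, duration = duration,
                 condition = condition),
            class = "ca_activity_summary")
}

#' @export
print.ca_activity_summary <- function(x, ...) {
  cat(sprintf("<ca_activity_summary>%s Phi = %.3f /min, Psi = %s /min (%d clusters, %.1f min)\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$Phi,
              if (is.na(x$Psi)) "NA" else sprintf("%.3f", x$Psi),
              length(x$phi), x$duration / 60))
  invisible(x)
}

#' Drift-correct perturbed-cavity activity with the control cavity
#'
#' Temperature or evaporation changes shift the activity of every cavity
#' between the first and second recording; this artifact is quantified as
#' the control ratio `r = Phi_C2 / Phi_C1` (and its sequence-rate analogue
#' `r_psi = Psi_C2 / Psi_C1`), and the perturbed cavity's second-recording
#' quantities are divided by it: `phi_corr = phi / r`, `Phi_corr = Phi / r`,
#' `Psi_corr = Psi / r_psi`.
#'
#' @param perturbed_after `ca_activity_summary` of the perturbed cavity,
#'   second recording.
#' @param control_before,control_after control-cavity summaries of the first
#'   and second recording.
#' @return list with `corrected` (the drift-corrected after-summary) and
#'   `drift` (class `ca_drift`: `r`, `r_psi`).
#' @export
drift_correct <- function(perturbed_after, control_before, control_after) {
  stopifnot(inherits(perturbed_after, "ca_activity_summary"),
            inherits(control_before, "ca_activity_summary"),
            inherits(control_after, "ca_activity_summary"))
  if (!(control_before$Phi > 0) || !(control_after$Phi > 0))
    stop("control cavity silent: drift is unmeasurable")
  r <- control_after$Phi / control_before$Phi
  if (!is.na(control_before$Psi) && !is.na(control_after$Psi) &&
      control_before$Psi > 0 && control_after$Psi > 0) {
    r_psi <- control_after$Psi / control_before$Psi
  } else {
    warning("control cavity has no sequences in one recording; using the firing-rate drift ratio for Psi")
    r_psi <- r
  }
  corr <- perturbed_after
  corr$phi <- corr$phi / r
  corr$Phi <- corr$Phi / r
  if (!is.na(corr$Psi)) corr$Psi <- corr$Psi / r_psi
  corr$drift_corrected <- TRUE
  list(corrected = corr,
       drift = structure(list(r = r, r_psi = r_psi), class = "ca_drift"))
}

#' @export
print.ca_drift <- function(x, ...) {
  cat(sprintf("<ca_drift> r = %.3f (firing rate), r_psi = %.3f (sequence rate)\n",
              x$r, x$r_psi))
  invisible(x)
}

#' Per-cluster firing-rate difference summary
#'
#' Computes the per-cluster rate change `delta_phi = phi_after - phi_before`
#' and its bounded normalization `(phi_after - phi_before) /
#' (phi_after + phi_before)` in [-1, 1] (0 when both rates are zero; -1 for
#' a cluster that falls silent). Reports the Fisher bias-corrected sample
#' skewness `gamma` of the normalized differences and a Gaussian
#' least-squares fit (mu, sigma) to their Freedman-Diaconis histogram.
#'
#' @param before `ca_activity_summary` of the first recording.
#' @param after `ca_activity_summary` of the (drift-corrected) second
#'   recording, same cluster set.
#' @return object of class `ca_difference_summary` with `delta_phi`,
#'   `delta_phi_norm`, `gamma`, `mu`, `sigma`.
#' @export
difference_summary <- function(before, after) {
  stopifnot(inherits(before, "ca_activity_summary"),
            inherits(after, "ca_activity_summary"))
  if (length(before$phi) != length(after$phi))
    stop("`before` and `after` must cover the same cluster set")
  d <- after$phi - before$phi
  s <- after$phi + before$phi
  dn <- ifelse(s > 0, d / s, 0)
  fit <- gaussian_hist_fit(dn)
  structure(list(delta_phi = d, delta_phi_norm = dn,
                 gamma = sample_skewness(dn),
                 mu = fit$mu, sigma = fit$sigma),
            class = "ca_difference_summary")
}

#' @export
print.ca_difference_summary <- function(x, ...) {
  cat(sprintf("<ca_difference_summary> n = %d, mu = %.3f, sigma = %.3f, gamma = %.3f\n",
              length(x$delta_phi_norm), x$mu, x$sigma, x$gamma))
  invisible(x)
}

# Gaussian least-squares fit to a Freedman-Diaconis histogram; falls back
# to the sample mean/sd when the fit is degenerate or fails to converge.
gaussian_hist_fit <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L || sd(x) == 0)
    return(list(mu = mean(x), sigma = if (length(x)) sd(x) else NA_real_))
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  df <- data.frame(m = h$mids, d = h$density)
  fit <- tryCatch(
    suppressWarnings(
      nls(d ~ A * exp(-(m - mu)^2 / (2 * sg^2)), data = df,
          start = list(A = max(h$density), mu = mean(x), sg = sd(x)),
          control = list(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(mu = mean(x), sigma = sd(x)))
  cf <- coef(fit)
  list(mu = unname(cf["mu"]), sigma = abs(unname(cf["sg"])))
}

#' Compare two samples of activity measures
#'
#' Two-sided Student's t-test (clustered cultures) or Kolmogorov-Smirnov
#' test (comparisons across culture types with unequal realization counts).
#' The significance convention is `*` for p < 0.05 and `**` for p < 0.005.
#'
#' @param values_a,values_b numeric samples (each >= 2 values).
#' @param test `"t"` or `"KS"`.
#' @return list with `p_value`, `stars`, `test`.
#' @export
compare_conditions <- function(values_a, values_b, test = c("t", "KS")) {
  test <- match.arg(test)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each sample must contain at least 2 values")
  if (test == "t" && sd(values_a) == 0 && sd(values_b) == 0) {
    if (isTRUE(all.equal(mean(values_a), mean(values_b)))) {
      p <- 1  # identical constants: no evidence of difference
    } else {
      stop("degenerate constant samples with different means")
    }
  } else {
    p <- if (test == "t") t.test(values_a, values_b)$p.value
    else suppressWarnings(ks.test(values_a, values_b))$p.value
  }
  list(p_value = p, stars = significance_stars(p), test = test)
}

#' Significance stars
#'
#' `**` for p < 0.005, `*` for p < 0.05, empty otherwise.
#' @param p p-value(s).
#' @return character vector of star labels.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.005, "**", ifelse(p < 0.05, "*", ""))
}
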