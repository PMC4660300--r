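#' Generate a ground-truth clustered-culture network
#'
#' Places `n_clusters` neuronal clusters uniformly inside a 3.5 mm circular
#' cavity and assigns them to `n_communities` spatially contiguous
#' communities (consecutive angular sectors around the cavity centre, so
#' community sizes differ by at most one cluster). Community events ignite as
#' a Poisson process; each member joins an event of its own community with
#' probability `participation` and events of other communities with
#' probability `cross_participation`; activation delays within an event are
#' exponential with scale `delay_scale`, so a 5-15 cluster sequence spans
#' roughly 100 ms. A small independent per-cluster firing rate models
#' clusters that fire outside collective events.
#'
#' The defaults emulate a typical cavity: 30-40 clusters firing 1-2 times
#' per minute, collective sequences of 5-15 clusters lasting about 100 ms
#' and separated by 1-10 s.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param n_communities number of communities (<= n_clusters).
#' @param seed integer RNG seed; fixed seed gives identical networks.
#' @param ignition_rate per-community collective-event rate (events/min).
#' @param participation probability a member joins its community's event.
#' @param cross_participation probability of joining another community's event.
#' @param independent_rate per-cluster independent firing rate (firings/min).
#' @param delay_scale within-sequence activation delay scale (seconds).
#' @param cavity_diameter cavity diameter in mm.
#' @return an object of class `ca_network`.
#' @export
#' @examples
#' net <- generate_network(36, 3, seed = 1)
#' table(net$community_of)
generate_network <- function(n_clusters, n_communities, seed = NULL,
                             ignition_rate = 2, participation = 0.75,
                             cross_participation = 0.05,
                             independent_rate = 0.1,
                             delay_scale = 0.03,
                             cavity_diameter = 3.5) {
  if (!is.numeric(n_clusters) || n_clusters < 2 || n_clusters != round(n_clusters))
    stop("`n_clusters` must be an integer >= 2")
  if (!is.numeric(n_communities) || n_communities < 1 ||
      n_communities != round(n_communities) || n_communities > n_clusters)
    stop("`n_communities` must be an integer in [1, n_clusters]")
  stopifnot(ignition_rate >= 0, independent_rate >= 0, delay_scale > 0,
            participation >= 0, participation <= 1,
            cross_participation >= 0, cross_participation <= 1)
  n <- as.integer(n_clusters)
  k <- as.integer(n_communities)
  with_seed(seed, {
    # uniform in the cavity disc
    r <- (cavity_diameter / 2) * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    pos <- cbind(x = r * cos(th), y = r * sin(th))
    # contiguous angular sectors -> spatially contiguous, near-equal sizes
    ang <- atan2(pos[, 2] - mean(pos[, 2]), pos[, 1] - mean(pos[, 1]))
    ord <- order(ang)
    comm <- integer(n)
    comm[ord] <- rep(seq_len(k), times = diff(round(seq(0, n, length.out = k + 1))))
    net <- structure(list(
      n_clusters = n,
      positions = pos,
      community_of = comm,
      ignition_rate = rep(ignition_rate, k),
      participation = rep(participation, n),
      cross_participation = rep(cross_participation, n),
      independent_rate = rep(independent_rate, n),
      delay_scale = delay_scale,
      cavity_diameter = cavity_diameter
    ), class = "ca_network")
    net$mass0 <- recruitment_mass(net)
    net
  })
}

# Per-community recruitment mass: summed participation of members plus
# cross-participation of outsiders. The effective ignition rate scales with
# mass relative to the network's unperturbed mass (collective events are a
# recruitment phenomenon: silencing or weakening lowers ignition).
recruitment_mass <- function(net) {
  k <- max(net$community_of)
  vapply(seq_len(k), function(c) {
    inc <- net$community_of == c
    sum(net$participation[inc]) + sum(net$cross_participation[!inc])
  }, numeric(1))
}

#' @export
print.ca_network <- function(x, ...) {
  cat(sprintf("<ca_network> %d clusters, %d communities (sizes: %s)\n",
              x$n_clusters, max(x$community_of),
              paste(tabulate(x$community_of), collapse = ", ")))
  cat(sprintf("  ignition %.2g /min/community, participation %.2g, cross %.2g, independent %.2g /min\n",
              mean(x$ignition_rate), mean(x$participation),
              mean(x$cross_participation), mean(x$independent_rate)))
  invisible(x)
}

#' Perturbation specification
#'
#' Describes a chemical insult applied to a cavity: a fraction of clusters
#' silenced outright, multiplicative weakening of cross-community (and
#' optionally within-community) participation, and boosting of independent
#' firing in a fraction of clusters. All-identity defaults leave a network
#' unchanged.
#'
#' @param silenced_fraction fraction of clusters set inactive, in [0,1].
#' @param weaken_factor multiplier on cross-community participation (>= 0).
#' @param within_weaken_factor multiplier on within-community participation.
#' @param boosted_fraction fraction of clusters with boosted independent rate.
#' @param boost_factor multiplier on the independent rate of boosted clusters.
#' @return an object of class `ca_perturbation`.
#' @export
perturbation_spec <- function(silenced_fraction = 0, weaken_factor = 1,
                              within_weaken_factor = 1,
                              boosted_fraction = 0, boost_factor = 1) {
  stopifnot(silenced_fraction >= 0, silenced_fraction <= 1,
            boosted_fraction >= 0, boosted_fraction <= 1,
            weaken_factor >= 0, within_weaken_factor >= 0, boost_factor >= 0)
  structure(list(silenced_fraction = silenced_fraction,
                 weaken_factor = weaken_factor,
                 within_weaken_factor = within_weaken_factor,
                 boosted_fraction = boosted_fraction,
                 boost_factor = boost_factor),
            class = "ca_perturbation")
}

#' Apply a perturbation to a network
#'
#' Returns a new network; the input is unchanged. Silenced clusters get zero
#' participation, cross-participation and independent rate; cross-community
#' participation of the remaining clusters is multiplied by `weaken_factor`
#' (within-community by `within_weaken_factor`); boosted clusters get their
#' independent rate multiplied by `boost_factor`. Cluster count, positions
#' and community labels are conserved.
#'
#' @param network a `ca_network`.
#' @param spec a `ca_perturbation` (see [perturbation_spec()]).
#' @param seed integer seed choosing which clusters are silenced/boosted.
#' @return a perturbed `ca_network`.
#' @export
apply_perturbation <- function(network, spec, seed = NULL) {
  stopifnot(inherits(network, "ca_network"), inherits(spec, "ca_perturbation"))
  with_seed(seed, {
    net <- network
    n <- net$n_clusters
    n_sil <- round(spec$silenced_fraction * n)
    n_boost <- round(spec$boosted_fraction * n)
    silenced <- if (n_sil > 0) sample.int(n, n_sil) else integer(0)
    boostable <- setdiff(seq_len(n), silenced)
    boosted <- if (n_boost > 0 && length(boostable) > 0)
      sample(boostable, min(n_boost, length(boostable))) else integer(0)
    net$participation <- net$participation * spec$within_weaken_factor
    net$cross_participation <- net$cross_participation * spec$weaken_factor
    net$independent_rate[boosted] <- net$independent_rate[boosted] * spec$boost_factor
    net$participation[silenced] <- 0
    net$cross_participation[silenced] <- 0
    net$independent_rate[silenced] <- 0
    net$silenced <- silenced
    net$boosted <- boosted
    net
  })
}

#' Simulate clustered-network activity
#'
#' Community events are drawn as homogeneous Poisson processes whose
#' effective rate is the network `ignition_rate` scaled by the community's
#' current recruitment mass relative to its unperturbed mass (so silencing
#' or weakening lowers the collective event rate). Each cluster joins an
#' event with its (cross-)participation probability and receives an
#' exponential activation delay on `delay_scale`. Independent firings are
#' added as per-cluster Poisson processes.
#'
#' @param network a `ca_network`.
#' @param duration recording duration in seconds (default 30 min).
#' @param seed integer RNG seed.
#' @return an object of class `ca_activity` with elements `onsets` (named
#'   list of sorted onset times per cluster, seconds), `events` (data frame:
#'   event id, community, ignition time, member count) and `members` (list of
#'   data frames with the ground-truth sequence membership and times),
#'   `true_partition` (community labels) and `duration`.
#' @export
#' @examples
#' net <- generate_network(36, 3, seed = 1)
#' act <- simulate_activity(net, duration = 60, seed = 2)
#' length(act$onsets)
simulate_activity <- function(network, duration = 1800, seed = NULL) {
  stopifnot(inherits(network, "ca_network"))
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  with_seed(seed, {
    n <- network$n_clusters
    k <- max(network$community_of)
    mass <- recruitment_mass(network)
    mass0 <- network$mass0 %||% mass
    rate_eff <- (network$ignition_rate / 60) * ifelse(mass0 > 0, mass / mass0, 0)
    ev_comm <- integer(0); ev_time <- numeric(0)
    for (c in seq_len(k)) {
      m <- rpois(1L, rate_eff[c] * duration)
      if (m > 0) {
        ev_comm <- c(ev_comm, rep.int(c, m))
        ev_time <- c(ev_time, sort(runif(m, 0, duration)))
      }
    }
    ord <- order(ev_time)
    ev_comm <- ev_comm[ord]; ev_time <- ev_time[ord]
    onsets <- vector("list", n)
    for (i in seq_len(n)) onsets[[i]] <- numeric(0)
    members <- vector("list", length(ev_time))
    p_join <- matrix(rep(network$cross_participation, k), nrow = n)
    for (c in seq_len(k)) {
      inc <- network$community_of == c
      p_join[inc, c] <- network$participation[inc]
    }
    for (e in seq_along(ev_time)) {
      joins <- which(runif(n) < p_join[, ev_comm[e]])
      tms <- ev_time[e] + rexp(length(joins), rate = 1 / network$delay_scale)
      keep <- tms <= duration
      joins <- joins[keep]; tms <- tms[keep]
      members[[e]] <- data.frame(cluster = joins, time = tms)
      for (i in seq_along(joins))
        onsets[[joins[i]]] <- c(onsets[[joins[i]]], tms[i])
    }
    # independent firings outside collective events
    for (i in seq_len(n)) {
      m <- rpois(1L, network$independent_rate[i] / 60 * duration)
      if (m > 0) onsets[[i]] <- c(onsets[[i]], runif(m, 0, duration))
      onsets[[i]] <- sort(onsets[[i]])
    }
    names(onsets) <- cluster_ids(n)
    structure(list(
      onsets = onsets,
      events = data.frame(event = seq_along(ev_time), community = ev_comm,
                          time = ev_time,
                          n_members = vapply(members, nrow, integer(1))),
      members = members,
      true_partition = network$community_of,
      duration = duration
    ), class = "ca_activity")
  })
}

#' @export
print.ca_activity <- function(x, ...) {
  rate <- mean(lengths(x$onsets)) / x$duration * 60
  cat(sprintf("<ca_activity> %d clusters, %.1f min, %d ground-truth events, mean rate %.2f /min\n",
              length(x$onsets), x$duration / 60, nrow(x$events), rate))
  invisible(x)
}

cluster_ids <- function(n) sprintf("c%03d", seq_len(n) - 1L)

#' Render fluorescence traces from onset trains
#'
#' Each onset contributes a calcium-like transient: linear rise over
#' `rise_ms` to `amplitude`, then exponential decay with time constant
#' `decay_ms`; transients superpose additively over a zero baseline, with
#' additive white Gaussian noise of standard deviation `noise_sd`. Defaults
#' mimic Fluo-4 kinetics at 20 ms frames.
#'
#' @param onsets named list of onset-time vectors (seconds), or a
#'   `ca_activity`.
#' @param duration recording duration in seconds; defaults to the activity
#'   duration or to max onset + 5 s.
#' @param frame_dt frame interval in seconds (default 0.02).
#' @param kernel list with `rise_ms`, `decay_ms`, `amplitude`.
#' @param noise_sd noise standard deviation (trace units).
#' @param seed integer RNG seed for the noise.
#' @return an object of class `ca_recording`: `traces` (time x ROI matrix),
#'   `time` (seconds), `frame_dt`, `roi_ids`.
#' @export
render_traces <- function(onsets, duration = NULL, frame_dt = 0.02,
                          kernel = list(rise_ms = 50, decay_ms = 1000, amplitude = 1),
                          noise_sd = 0.05, seed = NULL) {
  if (inherits(onsets, "ca_activity")) {
    duration <- duration %||% onsets$duration
    onsets <- onsets$onsets
  }
  stopifnot(is.list(onsets), frame_dt > 0)
  rise <- kernel$rise_ms / 1000; decay <- kernel$decay_ms / 1000
  amp <- kernel$amplitude %||% 1
  if (!(decay > rise && rise > 0)) stop("kernel must satisfy decay_ms > rise_ms > 0")
  duration <- duration %||% (max(c(0, unlist(onsets))) + 5)
  nt <- max(1L, floor(duration / frame_dt))
  tv <- (seq_len(nt) - 1L) * frame_dt
  # kernel sampled on the frame grid, truncated at 8 decay constants
  kt <- seq(0, rise + 8 * decay, by = frame_dt)
  kv <- ifelse(kt <= rise, amp * kt / rise, amp * exp(-(kt - rise) / decay))
  traces <- with_seed(seed, {
    tr <- matrix(0, nrow = nt, ncol = length(onsets))
    for (i in seq_along(onsets)) {
      for (t0 in onsets[[i]]) {
        f0 <- as.integer(ceiling((t0 - 1e-12) / frame_dt)) + 1L # first frame >= t0
        if (f0 > nt) next
        idx <- f0:min(nt, f0 + length(kt) - 1L)
        el <- (idx - 1L) * frame_dt - t0
        tr[idx, i] <- tr[idx, i] +
          ifelse(el <= rise, amp * el / rise, amp * exp(-(el - rise) / decay))
      }
    }
    if (noise_sd > 0) tr <- tr + matrix(rnorm(nt * length(onsets), sd = noise_sd), nt)
    tr
  })
  ids <- names(onsets) %||% cluster_ids(length(onsets))
  colnames(traces) <- ids
  structure(list(traces = traces, time = tv, frame_dt = frame_dt,
                 roi_ids = ids), class = "ca_recording")
}

#' @export
print.ca_recording <- function(x, ...) {
  cat(sprintf("<ca_recording> %d frames x %d ROIs, frame_dt %.3g s (%.1f min)\n",
              nrow(x$traces), ncol(x$traces), x$frame_dt,
              nrow(x$traces) * x$frame_dt / 60))
  invisible(x)
}
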