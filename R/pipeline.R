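#' Default experiment configuration
#'
#' A self-contained synthetic experiment emulating the standard 4-cavity
#' layout (2 x 2 PDMS grid): one control cavity plus three perturbed ones.
#' The perturbation magnitudes are free parameters (no quantitative
#' dose-effect mapping exists); the defaults grade from near-identity
#' (magnetic nanoparticles, M) through moderate (amyloid-beta) to severe
#' (the M-Abeta complex: 30% of clusters silenced and cross-community
#' participation reduced to 30%).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param duration recording duration per condition, seconds (default 30 min).
#' @param n_clusters,n_communities synthetic network size.
#' @param from_traces if `TRUE` (default) activity is rendered to
#'   fluorescence traces and onsets re-detected; if `FALSE` the ground-truth
#'   onsets are analyzed directly.
#' @param n_surrogates surrogate count for connectivity and community nulls.
#' @param out_dir optional output directory for interface files.
#' @return a config list accepted by [run_pipeline()].
#' @export
default_experiment_config <- function(seed = 1, duration = 1800,
                                      n_clusters = 36, n_communities = 3,
                                      from_traces = TRUE, n_surrogates = 500,
                                      out_dir = NULL) {
  list(
    seed = seed, duration = duration,
    n_clusters = n_clusters, n_communities = n_communities,
    frame_dt = 0.02, noise_sd = 0.05,
    kernel = list(rise_ms = 50, decay_ms = 1000, amplitude = 1),
    amp_k = 3, deriv_k = 2, refractory = 0.5,
    window = 0.2, tau = 0.2, n_surrogates = n_surrogates,
    z_threshold = 1.95, vi_step = 0.01,
    from_traces = from_traces, out_dir = out_dir,
    cavities = list(
      control = list(role = "control"),
      M = list(role = "M", silenced_fraction = 0.05, weaken_factor = 0.95),
      Abeta = list(role = "Abeta", silenced_fraction = 0.1,
                   weaken_factor = 0.7),
      `M-Abeta` = list(role = "M-Abeta", silenced_fraction = 0.3,
                       weaken_factor = 0.3)
    )
  )
}

#' Read an experiment configuration from YAML
#'
#' Fields missing from the file fall back to [default_experiment_config()]
#' values.
#'
#' @param path YAML file path.
#' @return a config list.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_experiment_config()
  base[names(cfg)] <- cfg
  base
}

derive_seed <- function(seed, i) as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)

config_hash <- function(cfg) {
  b <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the end-to-end synthetic experiment pipeline
#'
#' For each cavity: generate the ground-truth network, simulate a "before"
#' recording, apply the cavity's perturbation, simulate an "after"
#' recording, optionally render fluorescence traces and re-detect onsets,
#' then detect sequences, summarize activity, infer functional graphs,
#' detect communities and compute topology descriptors. Perturbed-cavity
#' after-quantities are drift-corrected by the control cavity. Fully
#' reproducible from the config seed.
#'
#' @param config config list (see [default_experiment_config()]) or path to
#'   a YAML config file.
#' @return object of class `ca_experiment`: per-cavity results plus the
#'   drift model and a `summary` list (ratios, skewness, moduli counts,
#'   topology ratios) ready for JSON export.
#' @export
run_pipeline <- function(config = default_experiment_config()) {
  if (is.character(config)) config <- read_config_yaml(config)
  cfg <- config
  roles <- vapply(cfg$cavities, function(c) c$role %||% "", character(1))
  if (sum(roles == "control") != 1L)
    stop("config must label exactly one cavity as control")
  if (is.null(cfg$seed)) stop("config must provide a seed")
  if (!is.numeric(cfg$duration) || cfg$duration <= 0)
    stop("config duration must be > 0")
  control_name <- names(cfg$cavities)[roles == "control"]

  cavs <- list()
  for (ci in seq_along(cfg$cavities)) {
    nm <- names(cfg$cavities)[ci]
    cavs[[nm]] <- analyze_cavity(cfg, cfg$cavities[[ci]],
                                 seed = derive_seed(cfg$seed, ci))
  }

  ctrl <- cavs[[control_name]]
  if (!(ctrl$summary_before$Phi > 0 && ctrl$summary_after$Phi > 0))
    stop("control cavity silent: drift correction impossible")

  summary <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                  cavities = list())
  drift <- NULL
  for (nm in names(cavs)) {
    cv <- cavs[[nm]]
    dc <- drift_correct(cv$summary_after, ctrl$summary_before,
                        ctrl$summary_after)
    drift <- dc$drift
    cv$summary_after_corrected <- dc$corrected
    cv$difference <- difference_summary(cv$summary_before, dc$corrected)
    cv$partition_change <- compare_partitions(cv$partition_before,
                                              cv$partition_after)
    cv$weight_diff <- weight_differences(cv$graph_after, cv$graph_before)
    cv$topology_ratios <- topology_ratios(cv$topology_after,
                                          cv$topology_before)
    cavs[[nm]] <- cv
    summary$cavities[[nm]] <- list(
      role = cv$role,
      Phi_before = cv$summary_before$Phi,
      Phi_after_corrected = dc$corrected$Phi,
      Phi_ratio = dc$corrected$Phi / cv$summary_before$Phi,
      Psi_before = cv$summary_before$Psi,
      Psi_after_corrected = dc$corrected$Psi,
      Psi_ratio = if (cv$summary_before$Psi > 0)
        dc$corrected$Psi / cv$summary_before$Psi else NA,
      gamma = cv$difference$gamma,
      mu = cv$difference$mu,
      n_moduli_before = cv$partition_before$n_moduli,
      n_moduli_after = cv$partition_after$n_moduli,
      vi_before_after = cv$partition_change$vi,
      gamma_wd = cv$weight_diff$gamma_wd,
      topology_ratios = as.list(cv$topology_ratios)
    )
  }
  summary$drift <- list(r = drift$r, r_psi = drift$r_psi)

  out <- structure(list(config = cfg, cavities = cavs, drift = drift,
                        control = control_name, summary = summary),
                   class = "ca_experiment")
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

# Full single-cavity analysis: before/after simulation + the whole chain.
analyze_cavity <- function(cfg, cavity, seed) {
  spec <- perturbation_spec(
    silenced_fraction = cavity$silenced_fraction %||% 0,
    weaken_factor = cavity$weaken_factor %||% 1,
    within_weaken_factor = cavity$within_weaken_factor %||% 1,
    boosted_fraction = cavity$boosted_fraction %||% 0,
    boost_factor = cavity$boost_factor %||% 1)
  net <- generate_network(cfg$n_clusters, cfg$n_communities,
                          seed = derive_seed(seed, 1))
  net_after <- apply_perturbation(net, spec, seed = derive_seed(seed, 2))
  res <- list(role = cavity$role %||% "unknown", network = net,
              network_after = net_after)
  for (cond in c("before", "after")) {
    thisnet <- if (cond == "before") net else net_after
    act <- simulate_activity(thisnet, duration = cfg$duration,
                             seed = derive_seed(seed, if (cond == "before") 3 else 4))
    ons <- if (isTRUE(cfg$from_traces)) {
      rec <- render_traces(act, frame_dt = cfg$frame_dt, kernel = cfg$kernel,
                           noise_sd = cfg$noise_sd,
                           seed = derive_seed(seed, if (cond == "before") 5 else 6))
      detect_onsets(rec, amp_k = cfg$amp_k, deriv_k = cfg$deriv_k,
                    refractory = cfg$refractory)
    } else {
      new_onsets(act$onsets, duration = cfg$duration)
    }
    seqs <- detect_sequences(ons, window = cfg$window)
    summ <- summarize_activity(ons, seqs, duration = cfg$duration,
                               condition = cond)
    graph <- infer_functional_graph(seqs, tau = cfg$tau,
                                    n_surrogates = cfg$n_surrogates,
                                    seed = derive_seed(seed, if (cond == "before") 7 else 8))
    graph <- significant_links(graph, z_threshold = cfg$z_threshold)
    X <- coactivation_matrix(seqs)
    part <- tryCatch({
      nd <- normalized_jaccard_distance(X, n_surrogates = cfg$n_surrogates,
                                        seed = derive_seed(seed, if (cond == "before") 9 else 10))
      dend <- build_dendrogram(nd$D_norm)
      select_threshold(dend, step = cfg$vi_step)$partition
    }, error = function(e) {
      structure(list(labels = rep(1L, length(seqs$cluster_ids)),
                     n_moduli = 1L, threshold = NA_real_),
                class = "ca_partition")
    })
    topo <- topology_descriptors(graph)
    res[[paste0("activity_", cond)]] <- act
    res[[paste0("onsets_", cond)]] <- ons
    res[[paste0("sequences_", cond)]] <- seqs
    res[[paste0("summary_", cond)]] <- summ
    res[[paste0("graph_", cond)]] <- graph
    res[[paste0("partition_", cond)]] <- part
    res[[paste0("topology_", cond)]] <- topo
  }
  res
}

#' @export
print.ca_experiment <- function(x, ...) {
  cat(sprintf("<ca_experiment> %d cavities (control: %s), drift r = %.3f\n",
              length(x$cavities), x$control, x$drift$r))
  for (nm in names(x$summary$cavities)) {
    s <- x$summary$cavities[[nm]]
    cat(sprintf("  %-8s Phi ratio %.2f, Psi ratio %.2f, gamma %+.2f, moduli %d -> %d\n",
                nm, s$Phi_ratio, s$Psi_ratio %||% NA, s$gamma,
                s$n_moduli_before, s$n_moduli_after))
  }
  invisible(x)
}

#' Write the interface files of a completed experiment
#'
#' Emits, per cavity and condition, the onsets TSV, sequences JSON,
#' coactivation CSV, graph TSV/GraphML and partition JSON, plus a global
#' `summary.json` that records the config hash and master seed.
#'
#' @param experiment a `ca_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "ca_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(experiment$cavities)) {
    cv <- experiment$cavities[[nm]]
    for (cond in c("before", "after")) {
      stem <- file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", nm), "_", cond))
      write_onsets_tsv(cv[[paste0("onsets_", cond)]], paste0(stem, "_onsets.tsv"))
      write_sequences_json(cv[[paste0("sequences_", cond)]],
                           paste0(stem, "_sequences.jsonl"))
      write_coactivation_csv(coactivation_matrix(cv[[paste0("sequences_", cond)]]),
                             paste0(stem, "_coactivation.csv"))
      write_graph_tsv(cv[[paste0("graph_", cond)]], paste0(stem, "_graph.tsv"))
      write_graphml(cv[[paste0("graph_", cond)]], paste0(stem, "_graph.graphml"))
      write_partition_json(cv[[paste0("partition_", cond)]],
                           paste0(stem, "_partition.json"))
    }
  }
  jsonlite::write_json(experiment$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
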