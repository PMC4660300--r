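#' Weighted-directed topology descriptors of a functional graph
#'
#' Computes five descriptors of the significant-link functional graph (the
#' z-scored weights above threshold). Weights are rescaled to (0, 1] by the
#' maximum weight; edge length is the inverse weight for geodesics.
#'
#' \describe{
#'   \item{strength}{per-node sum of in- plus out-going weighted links
#'     (raw significant z-weights); the scalar descriptor is the mean node
#'     strength.}
#'   \item{global_efficiency}{mean over all ordered node pairs of the
#'     inverse geodesic length (disconnected pairs contribute 0): global
#'     integration.}
#'   \item{local_efficiency}{mean, over nodes with at least two neighbors,
#'     of the global efficiency of the subgraph induced by the union of in-
#'     and out-neighbors: communication within local subgraphs.}
#'   \item{clustering}{mean directed weighted clustering coefficient
#'     (Fagiolo's triangle fraction) over nodes with >= 2 neighbors:
#'     segregation.}
#'   \item{assortativity}{Pearson correlation of total weighted degree
#'     (in-strength + out-strength) across linked node pairs; 0 when all
#'     linked nodes have equal degree, NA when there are no links.}
#' }
#'
#' @param graph a `ca_graph` with significance mask (see
#'   [significant_links()]), or a non-negative weighted adjacency matrix
#'   with zero diagonal.
#' @return object of class `ca_topology` with the five scalar descriptors
#'   plus `strength_per_node` and `n_links`.
#' @export
topology_descriptors <- function(graph) {
  A <- if (inherits(graph, "ca_graph")) {
    if (is.null(graph$sig_mask))
      stop("call significant_links() first")
    a <- graph$W
    a[!graph$sig_mask] <- 0
    a[a < 0] <- 0
    a
  } else {
    as.matrix(graph)
  }
  N <- nrow(A)
  if (N < 2) stop("graph needs >= 2 nodes")
  if (any(A < 0)) stop("weights must be non-negative")
  diag(A) <- 0
  s_in <- colSums(A); s_out <- rowSums(A)
  strength <- s_in + s_out
  if (all(A == 0)) {
    warning("empty graph: descriptors set to 0, assortativity undefined")
    return(structure(list(strength = 0, strength_per_node = strength,
                          global_efficiency = 0, local_efficiency = 0,
                          clustering = 0, assortativity = NA_real_,
                          n_links = 0L), class = "ca_topology"))
  }
  An <- A / max(A)
  ge <- global_efficiency(An)
  # local efficiency over in/out-neighbor subgraphs
  nb_list <- lapply(seq_len(N), function(v) {
    setdiff(which(An[v, ] > 0 | An[, v] > 0), v)
  })
  has_nb <- which(lengths(nb_list) >= 2L)
  le <- if (length(has_nb)) {
    mean(vapply(has_nb, function(v) {
      global_efficiency(An[nb_list[[v]], nb_list[[v]], drop = FALSE])
    }, numeric(1)))
  } else 0
  cc <- directed_clustering(An)
  cc_nodes <- lengths(nb_list) >= 2L & !is.na(cc)
  cc_mean <- if (any(cc_nodes)) mean(cc[cc_nodes]) else 0
  # assortativity over directed links
  e <- which(A > 0, arr.ind = TRUE)
  x <- strength[e[, 1]]; y <- strength[e[, 2]]
  assort <- if (nrow(e) < 2 || sd(x) == 0 || sd(y) == 0) {
    if (nrow(e) >= 1) 0 else NA_real_
  } else cor(x, y)
  structure(list(strength = mean(strength), strength_per_node = strength,
                 global_efficiency = ge, local_efficiency = le,
                 clustering = cc_mean, assortativity = assort,
                 n_links = sum(A > 0)), class = "ca_topology")
}

# Mean inverse geodesic over ordered pairs; lengths are inverse weights.
global_efficiency <- function(An) {
  N <- nrow(An)
  if (N < 2) return(0)
  if (all(An == 0)) return(0)
  g <- igraph::graph_from_adjacency_matrix(An, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, mode = "out", weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

# Fagiolo (directed weighted) clustering coefficient per node, on weights
# normalized to [0,1]. NA for nodes with fewer than two neighbors.
directed_clustering <- function(An) {
  W3 <- An^(1 / 3)
  S <- W3 + t(W3)
  num <- diag(S %*% S %*% S) / 2
  Ab <- (An > 0) * 1
  dtot <- rowSums(Ab) + colSums(Ab)
  dbi <- rowSums(Ab * t(Ab))
  Tt <- dtot * (dtot - 1) - 2 * dbi
  ifelse(Tt > 0, num / Tt, NA_real_)
}

#' @export
print.ca_topology <- function(x, ...) {
  cat(sprintf(paste0("<ca_topology> %d links; strength %.3f, E_glob %.3f, ",
                     "E_loc %.3f, clustering %.3f, assortativity %s\n"),
              x$n_links, x$strength, x$global_efficiency,
              x$local_efficiency, x$clustering,
              if (is.na(x$assortativity)) "NA" else sprintf("%.3f", x$assortativity)))
  invisible(x)
}

#' After/before ratios of topology descriptors
#'
#' Element-wise ratios of the five descriptors; a zero or missing `before`
#' value yields NA rather than an error.
#'
#' @param after,before `ca_topology` objects.
#' @return named numeric vector of five ratios.
#' @export
topology_ratios <- function(after, before) {
  stopifnot(inherits(after, "ca_topology"), inherits(before, "ca_topology"))
  keys <- c("strength", "global_efficiency", "local_efficiency",
            "clustering", "assortativity")
  vapply(keys, function(k) {
    a <- after[[k]]; b <- before[[k]]
    if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
  }, numeric(1))
}
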