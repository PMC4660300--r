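#' Write and read trace tables
#'
#' Traces are exchanged as CSV with a first column `time_s` followed by one
#' column per cluster (`c000`, `c001`, ...).
#'
#' @param recording a `ca_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(recording, path) {
  stopifnot(inherits(recording, "ca_recording"))
  df <- data.frame(time_s = recording$time, recording$traces,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param condition,cavity_role optional labels attached to the recording.
#' @export
read_traces_csv <- function(path, condition = NA_character_,
                            cavity_role = NA_character_) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be `time_s`")
  tv <- df[[1]]
  tr <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(tr)) stop("traces contain missing values")
  dt <- if (length(tv) > 1) median(diff(tv)) else 0.02
  structure(list(traces = tr, time = tv, frame_dt = dt,
                 roi_ids = colnames(tr), condition = condition,
                 cavity_role = cavity_role), class = "ca_recording")
}

#' Write and read onset trains as TSV
#'
#' One row per onset: `cluster_id<TAB>onset_time_s`, with a header line.
#'
#' @param onsets `ca_onsets` or named list of onset times.
#' @param path file path.
#' @return `path` invisibly (writer); a `ca_onsets` (reader).
#' @export
write_onsets_tsv <- function(onsets, path) {
  ids <- names(onsets) %||% cluster_ids(length(onsets))
  df <- data.frame(cluster_id = rep(ids, lengths(onsets)),
                   onset_time_s = unlist(onsets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_onsets_tsv
#' @param cluster_ids optional full label set (so silent clusters keep an
#'   empty train).
#' @param duration optional recording duration attribute (seconds).
#' @export
read_onsets_tsv <- function(path, cluster_ids = NULL, duration = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  ids <- cluster_ids %||% sort(unique(df$cluster_id))
  out <- lapply(ids, function(id) sort(df$onset_time_s[df$cluster_id == id]))
  names(out) <- ids
  new_onsets(out, duration = duration)
}

#' Write firing sequences as JSON lines
#'
#' One JSON object per line: `{"seq": j, "members": [...], "times": [...]}`.
#'
#' @param sequences a `ca_sequences`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sequences_json <- function(sequences, path) {
  stopifnot(inherits(sequences, "ca_sequences"))
  lines <- vapply(seq_along(sequences$sequences), function(j) {
    s <- sequences$sequences[[j]]
    jsonlite::toJSON(list(seq = j, members = s$members, times = s$times),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a coactivation matrix as CSV (cluster rows, sequence columns)
#' @param X binary coactivation matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_coactivation_csv <- function(X, path) {
  write.csv(as.data.frame(X), path, row.names = TRUE)
  invisible(path)
}

#' Write a functional graph as an edge-list TSV
#'
#' Columns `src`, `dst`, `w` (raw weight), `W` (z-score), `sig` (0/1).
#' Edges are all ordered pairs with non-zero raw weight or a significant
#' score.
#'
#' @param graph a `ca_graph`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "ca_graph"))
  sig <- graph$sig_mask %||% (graph$W > Inf)
  keep <- which(graph$w > 0 | sig, arr.ind = TRUE)
  df <- data.frame(src = graph$cluster_ids[keep[, 1]],
                   dst = graph$cluster_ids[keep[, 2]],
                   w = graph$w[keep], W = graph$W[keep],
                   sig = as.integer(sig[keep]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a functional graph as GraphML
#'
#' Edge attributes `w`, `W` and `sig` as in [write_graph_tsv()].
#'
#' @param graph a `ca_graph`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "ca_graph"))
  sig <- graph$sig_mask %||% (graph$W > Inf)
  keep <- which(graph$w > 0 | sig, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(graph$cluster_ids), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$cluster_ids)
  if (nrow(keep)) {
    g <- igraph::add_edges(g, rbind(keep[, 1], keep[, 2]))
    g <- igraph::set_edge_attr(g, "w", value = graph$w[keep])
    g <- igraph::set_edge_attr(g, "W", value = graph$W[keep])
    g <- igraph::set_edge_attr(g, "sig", value = as.integer(sig[keep]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a partition as JSON
#' @param partition a `ca_partition`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  stopifnot(inherits(partition, "ca_partition"))
  jsonlite::write_json(list(labels = unname(partition$labels),
                            d_th = partition$threshold,
                            n_moduli = partition$n_moduli),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a dendrogram merge table as CSV
#'
#' Columns `node`, `child1`, `child2`, `height`; negative child indices are
#' leaves (hclust convention), positive ones earlier merge nodes.
#'
#' @param dendrogram a `ca_dendrogram`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_csv <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "ca_dendrogram"))
  hc <- dendrogram$hclust
  df <- data.frame(node = seq_len(nrow(hc$merge)),
                   child1 = hc$merge[, 1], child2 = hc$merge[, 2],
                   height = hc$height)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth of a simulated recording as JSON
#'
#' `{"onsets": {...}, "partition": [...]}` as produced by
#' [simulate_activity()].
#'
#' @param activity a `ca_activity`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(activity, path) {
  stopifnot(inherits(activity, "ca_activity"))
  jsonlite::write_json(list(onsets = activity$onsets,
                            partition = activity$true_partition),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
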