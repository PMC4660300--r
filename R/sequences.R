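#' Detect firing sequences
#'
#' A firing sequence is the concatenated activation of two or more distinct
#' clusters with consecutive onsets separated by at most `window` (200 ms by
#' default); the same gap is the cut-off separating two sequences. All
#' onsets are pooled and sorted; a chain grows while the gap to the previous
#' onset is within the window. Chains involving a single cluster (clusters
#' firing independently) are discarded; if a cluster fires more than once
#' inside one chain only its first activation is kept.
#'
#' @param onsets a `ca_onsets` object or named list of onset-time vectors.
#' @param window chaining window in seconds (default 0.2).
#' @return an object of class `ca_sequences`: list with `sequences` (each a
#'   list with `members`, `times`, `start`, `end`), `cluster_ids`, `window`,
#'   `duration`.
#' @export
#' @examples
#' seqs <- detect_sequences(list(a = c(0, 5.0), b = c(0.1, 5.1)))
#' length(seqs$sequences)
detect_sequences <- function(onsets, window = 0.2) {
  if (!(is.numeric(window) && window > 0)) stop("`window` must be > 0")
  ids <- names(onsets) %||% cluster_ids(length(onsets))
  duration <- attr(onsets, "duration")
  cl <- rep(seq_along(onsets), lengths(onsets))
  tt <- unlist(onsets, use.names = FALSE)
  seqs <- list()
  if (length(tt)) {
    o <- order(tt, cl)
    tt <- tt[o]; cl <- cl[o]
    brk <- c(TRUE, diff(tt) > window)
    chain <- cumsum(brk)
    for (ch in split(seq_along(tt), chain)) {
      first <- !duplicated(cl[ch])
      mem <- cl[ch][first]
      if (length(mem) < 2L) next
      tmem <- tt[ch][first]
      seqs[[length(seqs) + 1L]] <-
        list(members = ids[mem], times = tmem,
             start = tmem[1], end = max(tt[ch]))
    }
  }
  structure(list(sequences = seqs, cluster_ids = ids, window = window,
                 duration = duration), class = "ca_sequences")
}

#' @export
print.ca_sequences <- function(x, ...) {
  ns <- length(x$sequences)
  cat(sprintf("<ca_sequences> %d sequences over %d clusters", ns,
              length(x$cluster_ids)))
  if (ns > 0) {
    sz <- vapply(x$sequences, function(s) length(s$members), integer(1))
    dur <- vapply(x$sequences, function(s) s$end - s$start, numeric(1))
    cat(sprintf("; median size %d, median span %.0f ms", median(sz),
                median(dur) * 1000))
  }
  cat("\n")
  invisible(x)
}

#' Build the binary coactivation matrix X
#'
#' `X[i, j] = 1` if cluster `i` participated in sequence `j`. Rows are the
#' activity history of each cluster; a silent cluster has an all-zero row;
#' every column has at least two ones (sequences involve >= 2 clusters).
#'
#' @param sequences a `ca_sequences` object or a list of character vectors
#'   of sequence members.
#' @param cluster_ids cluster labels defining the row order; defaults to the
#'   ids stored in `sequences`.
#' @return an N x M binary integer matrix with cluster-id rownames.
#' @export
#' @examples
#' X <- coactivation_matrix(list(c("a", "b"), c("b", "c")), c("a", "b", "c"))
coactivation_matrix <- function(sequences, cluster_ids = NULL) {
  if (inherits(sequences, "ca_sequences")) {
    cluster_ids <- cluster_ids %||% sequences$cluster_ids
    memb <- lapply(sequences$sequences, `[[`, "members")
  } else {
    memb <- sequences
    if (is.null(cluster_ids)) stop("`cluster_ids` required for a plain member list")
  }
  X <- matrix(0L, nrow = length(cluster_ids), ncol = length(memb),
              dimnames = list(cluster_ids, NULL))
  for (j in seq_along(memb)) {
    idx <- match(memb[[j]], cluster_ids)
    if (anyNA(idx))
      stop("sequence ", j, " contains clusters not in `cluster_ids`: ",
           paste(memb[[j]][is.na(idx)], collapse = ", "))
    X[idx, j] <- 1L
  }
  X
}
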