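#' Infer the directed weighted functional connectivity graph
#'
#' Two clusters are functionally linked when they co-participate in firing
#' sequences. Within each sequence, every ordered pair activating at times
#' `t_i < t_j` contributes `exp(-(t_j - t_i)/tau)` to the directed raw
#' weight `w[i, j]` (earlier activation leads); simultaneous activations
#' contribute weight 1 in both directions. Raw weights are summed over all
#' sequences. Significance and normalization come from a firings-preserving
#' null model: each cluster's sequence-participation row is independently
#' cyclically shifted across sequence slots, and each surrogate sequence
#' reassigns its slot's observed relative activation times by random
#' permutation to the new members (drawing from the pooled observed delay
#' distribution only when a surrogate sequence has more members than its
#' slot had times). The
#' z-score is `W = (w - mean_surrogate) / sd_surrogate` (pairs with zero
#' surrogate s.d. get `W = 0`).
#'
#' @param sequences a `ca_sequences` object.
#' @param n_clusters number of clusters (defaults to the ids in `sequences`).
#' @param tau decay time of the delay kernel, seconds (default 0.2, the
#'   sequence window).
#' @param n_surrogates number of surrogates for the null (default 500).
#' @param seed integer RNG seed; fixed seed reproduces `W` exactly.
#' @return object of class `ca_graph`: `w` (raw weights), `W` (z-scores),
#'   `sig_mask` (set by [significant_links()]), `n_surrogates`,
#'   `cluster_ids`, `z_threshold`.
#' @export
infer_functional_graph <- function(sequences, n_clusters = NULL, tau = 0.2,
                                   n_surrogates = 500, seed = NULL) {
  stopifnot(inherits(sequences, "ca_sequences"))
  if (!(tau > 0)) stop("`tau` must be > 0")
  if (n_surrogates < 2) stop("`n_surrogates` must be >= 2")
  ids <- sequences$cluster_ids
  if (!is.null(n_clusters)) {
    if (n_clusters < length(ids))
      stop("`n_clusters` smaller than the number of cluster labels")
    if (n_clusters > length(ids)) ids <- c(ids, cluster_ids(n_clusters)[(length(ids) + 1L):n_clusters])
  }
  N <- length(ids)
  M <- length(sequences$sequences)
  # membership and relative-time matrices (N x M)
  B <- matrix(FALSE, N, M)
  Tm <- matrix(NA_real_, N, M)
  for (j in seq_len(M)) {
    s <- sequences$sequences[[j]]
    idx <- match(s$members, ids)
    B[idx, j] <- TRUE
    Tm[idx, j] <- s$times - min(s$times)
  }
  w <- pair_weights(B, Tm, tau, N)
  if (M > 0) {
    pool <- Tm[B]
    times_of_col <- lapply(seq_len(M), function(j) Tm[B[, j], j])
    acc <- matrix(0, N, N); acc2 <- matrix(0, N, N)
    with_seed(seed, {
      for (s in seq_len(n_surrogates)) {
        off <- sample.int(M, N, replace = TRUE) - 1L
        # cyclic shift of each cluster's participation row
        cols <- outer(off, seq_len(M) - 1L, function(o, j) ((j + o) %% M) + 1L)
        Bs <- matrix(B[cbind(rep(seq_len(N), M), as.vector(cols))], N, M)
        Ts <- matrix(NA_real_, N, M)
        kj <- colSums(Bs)
        for (j in which(kj > 0L)) {
          tj <- times_of_col[[j]]
          Ts[Bs[, j], j] <- if (kj[j] <= length(tj)) sample(tj, kj[j])
          else sample(c(tj, sample(pool, kj[j] - length(tj), replace = TRUE)))
        }
        ws <- pair_weights(Bs, Ts, tau, N)
        acc <- acc + ws
        acc2 <- acc2 + ws * ws
      }
    })
    mu <- acc / n_surrogates
    va <- (acc2 - n_surrogates * mu^2) / (n_surrogates - 1)
    sdv <- sqrt(pmax(va, 0))
    W <- ifelse(sdv > 0, (w - mu) / sdv, 0)
  } else {
    W <- matrix(0, N, N)
  }
  diag(W) <- 0
  dimnames(w) <- dimnames(W) <- list(ids, ids)
  structure(list(w = w, W = W, sig_mask = NULL, n_surrogates = n_surrogates,
                 tau = tau, cluster_ids = ids, z_threshold = NA_real_),
            class = "ca_graph")
}

# Accumulate delay-kernel weights over all within-sequence ordered pairs.
# B: N x M logical membership; Tm: relative activation times (NA if absent).
pair_weights <- function(B, Tm, tau, N) {
  w <- matrix(0, N, N)
  idx <- which(B)
  if (length(idx) < 2L) return(w)
  colj <- ((idx - 1L) %/% N) + 1L
  rowi <- ((idx - 1L) %% N) + 1L
  tt <- Tm[idx]
  o <- order(colj, tt, rowi)
  colj <- colj[o]; rowi <- rowi[o]; tt <- tt[o]
  n <- length(colj)
  grp_start <- which(c(TRUE, colj[-1] != colj[-n]))
  pos <- seq_len(n) - rep(grp_start, diff(c(grp_start, n + 1L))) + 1L
  sel <- which(pos >= 2L)
  if (!length(sel)) return(w)
  nb <- pos[sel] - 1L
  ia <- sequence(nb, from = sel - nb)  # earlier member (leader)
  ib <- rep(sel, nb)                   # later member (follower)
  wv <- exp(-(tt[ib] - tt[ia]) / tau)
  src <- rowi[ia]; dst <- rowi[ib]
  tie <- tt[ib] == tt[ia]
  if (any(tie)) {  # simultaneous: weight 1 in both directions
    src <- c(src, rowi[ib][tie]); dst <- c(dst, rowi[ia][tie])
    wv <- c(wv, rep(1, sum(tie)))
  }
  li <- (dst - 1L) * N + src
  acc <- rowsum(wv, li)
  w[as.integer(rownames(acc))] <- acc
  w
}

#' Select significant functional links
#'
#' Keeps links whose z-score exceeds `z_threshold` (default 1.95, the upper
#' tail of the 95% confidence interval of the surrogate null); negative and
#' sub-threshold scores are disregarded.
#'
#' @param graph a `ca_graph` with `W` computed.
#' @param z_threshold z-score threshold (default 1.95).
#' @return the graph with `sig_mask` and `z_threshold` set.
#' @export
significant_links <- function(graph, z_threshold = 1.95) {
  stopifnot(inherits(graph, "ca_graph"))
  m <- graph$W > z_threshold
  diag(m) <- FALSE
  graph$sig_mask <- m
  graph$z_threshold <- z_threshold
  graph
}

#' @export
print.ca_graph <- function(x, ...) {
  n <- length(x$cluster_ids)
  cat(sprintf("<ca_graph> %d clusters, %d surrogates", n, x$n_surrogates))
  if (!is.null(x$sig_mask))
    cat(sprintf(", %d significant links (z > %.2f)", sum(x$sig_mask),
                x$z_threshold))
  cat("\n")
  invisible(x)
}

#' Weight differences between two conditions
#'
#' Element-wise difference of z-scored weights on the union of significant
#' links of the two graphs (a link not significant in one condition counts
#' as weight 0 there), plus the sample skewness of the differences over the
#' union links.
#'
#' @param after,before `ca_graph` objects over the same cluster set, with
#'   significance masks set (see [significant_links()]).
#' @return object of class `ca_weight_diff`: `wd` (N x N), `gamma_wd`,
#'   `union_mask`.
#' @export
weight_differences <- function(after, before) {
  stopifnot(inherits(after, "ca_graph"), inherits(before, "ca_graph"))
  if (!identical(after$cluster_ids, before$cluster_ids))
    stop("graphs cover different cluster sets")
  if (is.null(after$sig_mask) || is.null(before$sig_mask))
    stop("call significant_links() on both graphs first")
  u <- after$sig_mask | before$sig_mask
  wd <- matrix(0, nrow(u), ncol(u), dimnames = dimnames(after$W))
  wd[u] <- after$W[u] * after$sig_mask[u] - before$W[u] * before$sig_mask[u]
  structure(list(wd = wd, union_mask = u,
                 gamma_wd = if (any(u)) sample_skewness(wd[u]) else 0,
                 median_wd = if (any(u)) median(wd[u]) else 0),
            class = "ca_weight_diff")
}

#' @export
print.ca_weight_diff <- function(x, ...) {
  cat(sprintf("<ca_weight_diff> %d union links, mean wd = %.3f, gamma = %.3f\n",
              sum(x$union_mask),
              if (any(x$union_mask)) mean(x$wd[x$union_mask]) else 0,
              x$gamma_wd))
  invisible(x)
}
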