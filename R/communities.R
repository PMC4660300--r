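#' Jaccard similarity of cluster activity histories
#'
#' For any two rows A, B of the binary coactivation matrix, the Jaccard
#' similarity is the number of concurrent activations over the number of
#' occurrences where at least one of the two clusters fired:
#' `J(A, B) = |A & B| / |A | B|`. Identical histories give 1, histories with
#' no common activation give 0; a pair of silent clusters (empty union) is
#' defined as 0. The Jaccard distance is `D = 1 - J`.
#'
#' @param X binary N x M coactivation matrix (see [coactivation_matrix()]).
#' @return list with `J_S` (similarity) and `J_D` (distance), both N x N.
#' @export
#' @examples
#' X <- rbind(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0), c(0, 0, 0, 1, 1),
#'            c(0, 0, 0, 1, 1), c(1, 1, 0, 0, 0))
#' jaccard_similarity(X)$J_S[1, 5]  # 2/3
jaccard_similarity <- function(X) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1))) stop("`X` must be binary")
  storage.mode(X) <- "double"
  inter <- tcrossprod(X)
  rs <- rowSums(X)
  uni <- outer(rs, rs, "+") - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  dimnames(J) <- list(rownames(X), rownames(X))
  list(J_S = J, J_D = 1 - J)
}

#' Surrogate-normalized Jaccard distance
#'
#' Raw Jaccard distances are not comparable across recordings, so they are
#' z-scored against a null of `n_surrogates` row-reshuffled copies of `X`
#' (each surrogate independently permutes the entries within every row,
#' preserving each cluster's number of firings). With `S` the surrogate
#' distances, `Z = (mean(S) - D) / sd(S)` (positive = more similar than
#' chance) and the normalized distance is `D_norm = 1 - pnorm(Z)`, so
#' strongly coupled pairs get distances near 0. Pairs with zero surrogate
#' s.d. get `D_norm = 0.5`; silent clusters are forced to distance 1 from
#' everything, so they end up as singleton communities.
#'
#' @param X binary N x M coactivation matrix.
#' @param n_surrogates number of row-shuffled surrogates (default 500).
#' @param seed integer RNG seed.
#' @return list with `J_S`, `J_D`, `Z`, `D_norm` (all N x N).
#' @export
normalized_jaccard_distance <- function(X, n_surrogates = 500, seed = NULL) {
  if (n_surrogates < 2) stop("`n_surrogates` must be >= 2")
  base <- jaccard_similarity(X)
  D <- base$J_D
  N <- nrow(D); M <- ncol(X)
  Xd <- as.matrix(X); storage.mode(Xd) <- "double"
  acc <- matrix(0, N, N); acc2 <- matrix(0, N, N)
  with_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      Xs <- Xd
      if (M > 1) for (i in seq_len(N)) Xs[i, ] <- Xd[i, sample.int(M)]
      inter <- tcrossprod(Xs)
      rs <- rowSums(Xs)
      uni <- outer(rs, rs, "+") - inter
      S <- 1 - ifelse(uni > 0, inter / uni, 0)
      acc <- acc + S
      acc2 <- acc2 + S * S
    }
  })
  mu <- acc / n_surrogates
  va <- (acc2 - n_surrogates * mu^2) / (n_surrogates - 1)
  sdv <- sqrt(pmax(va, 0))
  Z <- ifelse(sdv > 1e-12, (mu - D) / sdv, 0)
  Dn <- 1 - pnorm(Z)
  silent <- rowSums(Xd) == 0
  Dn[silent, ] <- 1
  Dn[, silent] <- 1
  diag(Z) <- 0
  diag(Dn) <- 0
  dimnames(Z) <- dimnames(Dn) <- dimnames(D)
  c(base, list(Z = Z, D_norm = Dn))
}

#' Build an average-linkage dendrogram on a distance matrix
#'
#' @param D symmetric distance matrix with zero diagonal (raw or normalized
#'   Jaccard distance).
#' @return object of class `ca_dendrogram`: `hclust` (the stats::hclust
#'   tree, average linkage), `leaf_order` (for reordering similarity
#'   matrices in heat maps), `heights`, `labels`.
#' @export
build_dendrogram <- function(D) {
  D <- as.matrix(D)
  if (anyNA(D)) stop("distance matrix contains NA/NaN")
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(diag(D) != 0))
    stop("`D` must be symmetric with zero diagonal")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- cluster_ids(nrow(D))
  hc <- hclust(as.dist(D), method = "average")
  structure(list(hclust = hc, leaf_order = hc$order, heights = hc$height,
                 labels = rownames(D)), class = "ca_dendrogram")
}

#' @export
print.ca_dendrogram <- function(x, ...) {
  cat(sprintf("<ca_dendrogram> %d leaves, merge heights in [%.3f, %.3f] (average linkage)\n",
              length(x$labels), min(x$heights), max(x$heights)))
  invisible(x)
}

#' Cut a dendrogram at a distance threshold
#'
#' Communities are the leaves of the subtrees whose merge height exceeds
#' `d`; labels are assigned in leaf order (the community of the first leaf
#' in the tree ordering is 1, and so on).
#'
#' @param dendrogram a `ca_dendrogram`.
#' @param d cut threshold (distance units, >= 0).
#' @return object of class `ca_partition`: `labels` (integer vector, one
#'   entry per cluster), `n_moduli`, `threshold`.
#' @export
cut_dendrogram <- function(dendrogram, d) {
  stopifnot(inherits(dendrogram, "ca_dendrogram"), d >= 0)
  raw <- cutree(dendrogram$hclust, h = d)
  labs <- relabel_in_order(raw, dendrogram$leaf_order)
  structure(list(labels = labs, n_moduli = max(labs), threshold = d),
            class = "ca_partition")
}

relabel_in_order <- function(raw, leaf_order) {
  first_seen <- unique(raw[leaf_order])
  out <- match(raw, first_seen)
  names(out) <- names(raw)
  out
}

#' @export
print.ca_partition <- function(x, ...) {
  cat(sprintf("<ca_partition> %d moduli over %d clusters (sizes: %s)%s\n",
              x$n_moduli, length(x$labels),
              paste(tabulate(x$labels), collapse = ", "),
              if (is.null(x$threshold) || is.na(x$threshold)) ""
              else sprintf(", d = %.2f", x$threshold)))
  invisible(x)
}

#' Variation of Information between two partitions
#'
#' Information-theoretic partition distance `VI = H(X|Y) + H(Y|X)` computed
#' from the contingency table of community labels, in bits (base-2
#' logarithm). VI is zero iff the partitions coincide up to relabeling, is
#' symmetric, and satisfies the triangle inequality.
#'
#' @param p1,p2 `ca_partition` objects or integer label vectors over the
#'   same elements.
#' @return VI in bits (non-negative scalar).
#' @export
variation_of_information <- function(p1, p2) {
  l1 <- if (inherits(p1, "ca_partition")) p1$labels else p1
  l2 <- if (inherits(p2, "ca_partition")) p2$labels else p2
  if (length(l1) != length(l2)) stop("partitions have different lengths")
  n <- length(l1)
  if (n == 0L) return(0)
  ct <- table(l1, l2) / n
  px <- rowSums(ct); py <- colSums(ct)
  nz <- ct > 0
  hxy <- -sum(ct[nz] * log2(ct[nz]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  max(0, 2 * hxy - hx - hy)
}

#' Select the community threshold by Variation of Information
#'
#' Scans the cut threshold `d` from 0 past the top merge in steps of
#' `step`. For every threshold the mean VI (MVI) of its partition against
#' the partitions at all other thresholds is computed, and the jumps
#' `dMVI_i = MVI(d_{i+1}) - MVI(d_i)` located. Jumps in dMVI mark
#' thresholds where a small variation significantly reorganizes the
#' communities; they bound plateaus of stable structure. The selected
#' threshold is the midpoint of the plateau whose partition has minimal
#' MVI among those with at least two communities: the most representative
#' non-trivial structure (lowest mean disagreement with every other scale),
#' i.e. the minimal yet significant set of communities short of the trivial
#' single-community case.
#'
#' @param dendrogram a `ca_dendrogram`.
#' @param step threshold scan step (default 0.01).
#' @return object of class `ca_threshold_scan`: `thresholds`, `n_moduli`,
#'   `MVI`, `dMVI`, `d_th`, `partition` (the `ca_partition` at `d_th`).
#' @export
select_threshold <- function(dendrogram, step = 0.01) {
  stopifnot(inherits(dendrogram, "ca_dendrogram"), step > 0)
  hmax <- max(dendrogram$heights)
  thr <- seq(0, by = step, length.out = max(2L, floor(hmax / step) + 2L))
  parts <- lapply(thr, function(d) cut_dendrogram(dendrogram, d))
  nm <- vapply(parts, `[[`, integer(1), "n_moduli")
  if (all(nm < 2)) stop("all partitions are trivial (single community)")
  key <- vapply(parts, function(p) paste(p$labels, collapse = ","), character(1))
  uk <- unique(key)
  cnt <- as.vector(table(factor(key, levels = uk)))
  ureps <- parts[match(uk, key)]
  nu <- length(uk)
  VIu <- matrix(0, nu, nu)
  if (nu > 1) for (a in seq_len(nu - 1)) for (b in (a + 1):nu)
    VIu[a, b] <- VIu[b, a] <- variation_of_information(ureps[[a]], ureps[[b]])
  K <- length(thr)
  MVI <- (VIu %*% cnt)[match(key, uk)] / (K - 1)  # VI to self is 0
  dMVI <- diff(MVI)
  # most representative non-trivial plateau: minimal MVI among n >= 2
  elig <- which(nm >= 2L)
  best_key <- key[elig[which.min(MVI[elig])]]
  plateau <- which(key == best_key)
  i_th <- plateau[ceiling(length(plateau) / 2)]
  structure(list(thresholds = thr, n_moduli = nm, MVI = as.vector(MVI),
                 dMVI = as.vector(dMVI), d_th = thr[i_th],
                 partition = parts[[i_th]]),
            class = "ca_threshold_scan")
}

#' @export
print.ca_threshold_scan <- function(x, ...) {
  cat(sprintf("<ca_threshold_scan> %d thresholds (step %.3g), d_th = %.2f -> %d moduli\n",
              length(x$thresholds), diff(x$thresholds[1:2]), x$d_th,
              x$partition$n_moduli))
  invisible(x)
}

#' Compare community partitions before and after a perturbation
#'
#' Reports the number of moduli in each partition, the VI between them, and
#' the split/merge mapping: which before-community contributes clusters to
#' which after-communities.
#'
#' @param before,after `ca_partition` objects over the same cluster set.
#' @return object of class `ca_partition_change`: `n_before`, `n_after`,
#'   `vi`, `mapping` (data frame before/after/n_clusters), `n_splits`
#'   (before-communities mapping to > 1 after-community), `n_merges`.
#' @export
compare_partitions <- function(before, after) {
  lb <- if (inherits(before, "ca_partition")) before$labels else before
  la <- if (inherits(after, "ca_partition")) after$labels else after
  if (length(lb) != length(la)) stop("partitions cover different cluster sets")
  ct <- table(before = lb, after = la)
  map <- as.data.frame(ct, stringsAsFactors = FALSE)
  map <- map[map$Freq > 0, ]
  names(map) <- c("before_community", "after_community", "n_clusters")
  structure(list(
    n_before = length(unique(lb)), n_after = length(unique(la)),
    vi = variation_of_information(lb, la),
    mapping = map,
    n_splits = sum(rowSums(ct > 0) > 1),
    n_merges = sum(colSums(ct > 0) > 1)
  ), class = "ca_partition_change")
}

#' @export
print.ca_partition_change <- function(x, ...) {
  cat(sprintf("<ca_partition_change> %d -> %d moduli, VI = %.3f bits, %d splits, %d merges\n",
              x$n_before, x$n_after, x$vi, x$n_splits, x$n_merges))
  invisible(x)
}
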