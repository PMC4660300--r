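# Independent brute-force oracles and small fixtures used across tests.

# Toy coactivation histories: 5 clusters, 5 sequences
# ({1,2,5}, {1,2,5}, {1,2}, {3,4}, {3,4}).
toy_coactivation <- function() {
  X <- rbind(c(1, 1, 1, 0, 0),
             c(1, 1, 1, 0, 0),
             c(0, 0, 0, 1, 1),
             c(0, 0, 0, 1, 1),
             c(1, 1, 0, 0, 0))
  rownames(X) <- as.character(1:5)
  X
}

# Jaccard similarity via explicit set operations on index sets.
jaccard_bruteforce <- function(X) {
  n <- nrow(X)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- which(X[i, ] == 1); b <- which(X[j, ] == 1)
    u <- union(a, b)
    J[i, j] <- if (length(u) == 0) 0 else length(intersect(a, b)) / length(u)
  }
  J
}

# Average-linkage agglomeration recomputed from the definition: merge the
# two groups with the smallest mean pairwise distance, repeatedly.
average_linkage_bruteforce <- function(D) {
  groups <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      d <- mean(D[groups[[a]], groups[[b]]])
      if (d < bestd) { bestd <- d; best <- c(a, b) }
    }
    heights <- c(heights, bestd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  sort(heights)
}

# Exhaustive gap-rule partition of pooled onsets: a new chain starts
# exactly where the gap to the previous onset exceeds the window.
chain_bruteforce <- function(times, clusters, window) {
  o <- order(times)
  times <- times[o]; clusters <- clusters[o]
  chains <- list(); cur_t <- c(); cur_c <- c()
  for (i in seq_along(times)) {
    if (length(cur_t) && times[i] - cur_t[length(cur_t)] > window) {
      chains[[length(chains) + 1]] <- list(t = cur_t, c = cur_c)
      cur_t <- c(); cur_c <- c()
    }
    cur_t <- c(cur_t, times[i]); cur_c <- c(cur_c, clusters[i])
  }
  if (length(cur_t)) chains[[length(chains) + 1]] <- list(t = cur_t, c = cur_c)
  # keep chains with >= 2 distinct clusters, first activation per cluster
  out <- list()
  for (ch in chains) {
    keep <- !duplicated(ch$c)
    if (length(unique(ch$c)) >= 2)
      out[[length(out) + 1]] <- list(members = ch$c[keep], times = ch$t[keep])
  }
  out
}

# VI from the contingency table, written independently (natural sums).
vi_bruteforce <- function(x, y) {
  n <- length(x)
  vi <- 0
  for (cx in unique(x)) for (cy in unique(y)) {
    nxy <- sum(x == cx & y == cy)
    if (nxy == 0) next
    px <- sum(x == cx) / n; py <- sum(y == cy) / n; pxy <- nxy / n
    vi <- vi - pxy * (log2(pxy / px) + log2(pxy / py))
  }
  vi
}

# A small deterministic sequence set for connectivity tests.
two_cluster_sequences <- function(times_a = 0, times_b = 0.1) {
  detect_sequences(list(A = times_a, B = times_b), window = 0.2)
}
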