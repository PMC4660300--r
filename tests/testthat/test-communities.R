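test_that("Jaccard similarity reproduces the worked toy example", {
  X <- toy_coactivation()
  J <- jaccard_similarity(X)$J_S
  expect_equal(J["1", "2"], 1)          # identical histories
  expect_equal(J["1", "5"], 2 / 3)
  expect_equal(J["2", "5"], 2 / 3)
  expect_equal(J["1", "3"], 0)          # disjoint histories
  expect_equal(J["3", "4"], 1)
  # silent pair -> 0 by convention
  X0 <- rbind(a = c(1, 0), b = c(0, 0), c = c(0, 0))
  expect_equal(jaccard_similarity(X0)$J_S["b", "c"], 0)
  expect_error(jaccard_similarity(matrix(2, 2, 2)), "binary")
})

test_that("Jaccard equals the brute-force set computation (oracle)", {
  set.seed(4)
  for (rep in 1:10) {
    X <- matrix(rbinom(8 * 12, 1, 0.4), nrow = 8)
    expect_equal(unname(jaccard_similarity(X)$J_S), jaccard_bruteforce(X))
  }
})

test_that("surrogate-normalized distances separate coupled from null pairs", {
  # identical dense rows: more similar than any surrogate -> D_norm < 0.5
  Xd <- matrix(rep(c(1, 1, 0, 1, 0, 0, 1, 0, 1, 1), 4), nrow = 4, byrow = TRUE)
  nd <- normalized_jaccard_distance(Xd, n_surrogates = 100, seed = 1)
  off <- row(nd$D_norm) != col(nd$D_norm)
  expect_true(all(nd$D_norm[off] < 0.5))
  # independent random rows: mean off-diagonal D_norm ~ 0.5
  set.seed(2)
  Xr <- matrix(rbinom(20 * 200, 1, 0.3), nrow = 20)
  ndr <- normalized_jaccard_distance(Xr, n_surrogates = 200, seed = 3)
  offr <- row(ndr$D_norm) != col(ndr$D_norm)
  expect_equal(mean(ndr$D_norm[offr]), 0.5, tolerance = 0.1)
  # determinism
  nd2 <- normalized_jaccard_distance(Xd, n_surrogates = 100, seed = 1)
  expect_identical(nd$D_norm, nd2$D_norm)
  # silent clusters forced to distance 1
  Xs <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 0))
  nds <- normalized_jaccard_distance(Xs, n_surrogates = 50, seed = 4)
  expect_equal(nds$D_norm[3, 1], 1)
  expect_equal(nds$D_norm[3, 3], 0)
})

test_that("average-linkage dendrogram matches brute force on small cases", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2)
    D <- D + t(D)
    dend <- build_dendrogram(D)
    expect_equal(sort(dend$heights), average_linkage_bruteforce(D),
                 tolerance = 1e-10)
    expect_true(all(diff(dend$heights) >= -1e-12))  # monotone merges
  }
  Dna <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(build_dendrogram(Dna), "NA")
  expect_error(build_dendrogram(matrix(1:9, 3, 3)), "symmetric")
})

test_that("cutting the toy dendrogram at 0.75 yields the two paper moduli", {
  dend <- build_dendrogram(jaccard_similarity(toy_coactivation())$J_D)
  # {1,2} and {3,4} merge at height 0
  expect_equal(sum(dend$heights == 0), 2)
  p <- cut_dendrogram(dend, 0.75)
  expect_equal(p$n_moduli, 2L)
  expect_equal(unname(p$labels[c("1", "2", "5")]), rep(p$labels[["1"]], 3))
  expect_equal(unname(p$labels[c("3", "4")]), rep(p$labels[["3"]], 2))
  # extremes
  expect_equal(cut_dendrogram(dend, 1)$n_moduli, 1L)
  # two leaves merge at their distance
  d2 <- build_dendrogram(matrix(c(0, .4, .4, 0), 2, 2))
  expect_equal(d2$heights, 0.4)
  expect_equal(cut_dendrogram(d2, 0.3)$n_moduli, 2L)
})

test_that("moduli count is non-increasing in the cut threshold", {
  set.seed(6)
  D <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  dend <- build_dendrogram(D)
  nm <- vapply(seq(0, max(dend$heights), length.out = 30),
               function(d) cut_dendrogram(dend, d)$n_moduli, integer(1))
  expect_true(all(diff(nm) <= 0))
})

test_that("VI is a metric with the expected values", {
  expect_equal(variation_of_information(c(1, 1, 2, 2, 2), c(1, 1, 2, 2, 2)), 0)
  expect_equal(variation_of_information(c(1, 1, 2, 2, 2), c(2, 2, 1, 1, 1)), 0)
  v <- variation_of_information(c(1, 1, 2, 2, 2), c(1, 1, 1, 2, 2))
  expect_equal(v, vi_bruteforce(c(1, 1, 2, 2, 2), c(1, 1, 1, 2, 2)))
  expect_equal(v, 1.102, tolerance = 1e-3)
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    p1 <- sample(1:3, n, replace = TRUE)
    p2 <- sample(1:3, n, replace = TRUE)
    p3 <- sample(1:4, n, replace = TRUE)
    expect_equal(variation_of_information(p1, p2),
                 variation_of_information(p2, p1))
    expect_gte(variation_of_information(p1, p2) +
               variation_of_information(p2, p3) -
               variation_of_information(p1, p3), -1e-12)
  }
  expect_error(variation_of_information(c(1, 2), c(1, 2, 3)), "length")
})

test_that("threshold selection finds the toy and planted structures", {
  dend <- build_dendrogram(jaccard_similarity(toy_coactivation())$J_D)
  sel <- select_threshold(dend)
  expect_equal(sel$partition$n_moduli, 2L)
  expect_equal(variation_of_information(sel$partition$labels,
                                        c(1, 1, 2, 2, 1)), 0)
  expect_true(all(diff(sel$thresholds) > 0))
  # label invariance under leaf reordering
  perm <- c(3, 5, 1, 4, 2)
  Dp <- jaccard_similarity(toy_coactivation()[perm, ])$J_D
  selp <- select_threshold(build_dendrogram(Dp))
  expect_equal(selp$partition$n_moduli, 2L)
  # degenerate tree where every threshold yields one community
  expect_error(select_threshold(build_dendrogram(matrix(0, 2, 2))), "trivial")
})

test_that("planted two-block distances are recovered exactly", {
  set.seed(8)
  net <- generate_network(20, 2, seed = 9)
  act <- simulate_activity(net, 1200, seed = 10)
  X <- coactivation_matrix(detect_sequences(act$onsets))
  nd <- normalized_jaccard_distance(X, n_surrogates = 200, seed = 11)
  sel <- select_threshold(build_dendrogram(nd$D_norm))
  expect_equal(variation_of_information(sel$partition$labels,
                                        net$community_of), 0, tolerance = 0.1)
})

test_that("partition comparison reports splits and VI", {
  p1 <- structure(list(labels = rep(1:3, each = 5), n_moduli = 3L,
                       threshold = 0.5), class = "ca_partition")
  expect_equal(compare_partitions(p1, p1)$n_splits, 0L)
  expect_equal(compare_partitions(p1, p1)$vi, 0)
  # one 15-cluster community split into 3 of 5
  before <- rep(1L, 15)
  after <- rep(1:3, each = 5)
  ch <- compare_partitions(before, after)
  expect_equal(ch$n_before, 1L)
  expect_equal(ch$n_after, 3L)
  expect_equal(ch$n_splits, 1L)
  expect_equal(nrow(ch$mapping), 3L)
  expect_error(compare_partitions(rep(1, 3), rep(1, 4)), "cluster set")
})

test_that("partitions and dendrograms serialize", {
  dend <- build_dendrogram(jaccard_similarity(toy_coactivation())$J_D)
  p <- cut_dendrogram(dend, 0.75)
  f <- tempfile(fileext = ".json")
  write_partition_json(p, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$n_moduli, 2L)
  expect_equal(back$labels, unname(p$labels))
  f2 <- tempfile(fileext = ".csv")
  write_dendrogram_csv(dend, f2)
  tab <- read.csv(f2)
  expect_equal(nrow(tab), 4L)  # N - 1 merges
  expect_equal(tab$height, dend$heights)
  unlink(c(f, f2))
})
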