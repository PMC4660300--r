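test_that("generate_network builds valid, seed-deterministic networks", {
  net <- generate_network(36, 3, seed = 1)
  expect_s3_class(net, "ca_network")
  expect_equal(net$n_clusters, 36L)
  expect_equal(sort(unique(net$community_of)), 1:3)
  sizes <- tabulate(net$community_of)
  expect_lte(max(sizes) / min(sizes), 3)
  expect_true(all(net$participation >= 0 & net$participation <= 1))
  expect_true(all(sqrt(rowSums(net$positions^2)) <= 3.5 / 2 + 1e-9))

  expect_identical(generate_network(30, 2, seed = 7),
                   generate_network(30, 2, seed = 7))
  tiny <- generate_network(2, 2, seed = 0)
  expect_equal(sort(tabulate(tiny$community_of)), c(1L, 1L))
  expect_error(generate_network(1, 1), "n_clusters")
  expect_error(generate_network(5, 6), "n_communities")
})

test_that("communities are spatially contiguous angular sectors", {
  net <- generate_network(40, 4, seed = 3)
  ang <- atan2(net$positions[, 2] - mean(net$positions[, 2]),
               net$positions[, 1] - mean(net$positions[, 1]))
  # sorted by angle, community labels form contiguous blocks
  labs <- net$community_of[order(ang)]
  expect_equal(length(rle(labs)$lengths), 4L)
})

test_that("simulate_activity matches the prescribed event statistics", {
  net <- generate_network(36, 3, seed = 1)
  act <- simulate_activity(net, duration = 1800, seed = 2)
  expect_s3_class(act, "ca_activity")
  rate <- mean(lengths(act$onsets)) / 1800 * 60
  expect_gt(rate, 1); expect_lt(rate, 2)
  expect_true(all(unlist(act$onsets) >= 0 & unlist(act$onsets) <= 1800))
  expect_true(all(vapply(act$onsets, function(x) !is.unsorted(x), logical(1))))
  # determinism
  act2 <- simulate_activity(net, duration = 1800, seed = 2)
  expect_identical(act, act2)
  # zero participation + zero independent rate -> silence
  mute <- generate_network(10, 2, seed = 4, participation = 0,
                           cross_participation = 0, independent_rate = 0)
  expect_equal(sum(lengths(simulate_activity(mute, 600, seed = 1)$onsets)), 0L)
  expect_error(simulate_activity(net, duration = -1), "duration")
})

test_that("sequence statistics fall in the expected ranges", {
  net <- generate_network(36, 3, seed = 5)
  act <- simulate_activity(net, duration = 1800, seed = 6)
  seqs <- detect_sequences(act$onsets)
  sz <- vapply(seqs$sequences, function(s) length(s$members), integer(1))
  span <- vapply(seqs$sequences, function(s) s$end - s$start, numeric(1))
  gaps <- diff(vapply(seqs$sequences, `[[`, numeric(1), "start"))
  expect_gte(median(sz), 5); expect_lte(median(sz), 15)
  expect_lt(median(span), 0.2)   # ~100 ms scale
  expect_gt(median(gaps), 1); expect_lt(median(gaps), 10)
})

test_that("renewal event rate obeys the law of large numbers", {
  # one community, long run: empirical rate within 3 s.e. of nominal
  net <- generate_network(6, 1, seed = 2, ignition_rate = 1,
                          participation = 1, cross_participation = 0,
                          independent_rate = 0)
  dur_min <- 2000
  act <- simulate_activity(net, duration = dur_min * 60, seed = 9)
  m <- nrow(act$events)
  se <- sqrt(dur_min) # Poisson sd of count at 1/min
  expect_lt(abs(m - dur_min), 3 * se)
})

test_that("render_traces produces kernel-shaped transients", {
  # single onset: maximum within [t0, t0 + rise]
  rec <- render_traces(list(a = 1), duration = 4, noise_sd = 0, seed = 1)
  tmax <- rec$time[which.max(rec$traces[, 1])]
  expect_gte(tmax, 1); expect_lte(tmax, 1 + 0.05 + rec$frame_dt)
  expect_equal(max(rec$traces[, 1]), 1, tolerance = 0.05)
  # empty train -> all-zero trace
  rec0 <- render_traces(list(a = numeric(0)), duration = 2, noise_sd = 0)
  expect_true(all(rec0$traces == 0))
  # superposition: two onsets 5 s apart, decay 1 s -> peaks within 1%
  rec2 <- render_traces(list(a = c(1, 6)), duration = 10, noise_sd = 0)
  p1 <- max(rec2$traces[rec2$time < 5, 1])
  p2 <- max(rec2$traces[rec2$time >= 5, 1]) - exp(-5000 / 1000)
  expect_equal(p2 / p1, 1, tolerance = 0.01)
  expect_error(render_traces(list(a = 1), kernel = list(rise_ms = 100, decay_ms = 50)),
               "kernel")
})

test_that("apply_perturbation follows the spec and conserves structure", {
  net <- generate_network(20, 2, seed = 3)
  idn <- apply_perturbation(net, perturbation_spec(), seed = 1)
  expect_equal(idn$participation, net$participation)
  expect_equal(idn$independent_rate, net$independent_rate)
  expect_identical(idn$community_of, net$community_of)

  spec <- perturbation_spec(silenced_fraction = 0.3, weaken_factor = 0.3,
                            boosted_fraction = 0.1, boost_factor = 5)
  pert <- apply_perturbation(net, spec, seed = 2)
  expect_identical(pert$community_of, net$community_of)
  expect_equal(pert$n_clusters, net$n_clusters)
  expect_length(pert$silenced, 6)
  expect_equal(pert$participation[pert$silenced], rep(0, 6))
  expect_equal(pert$independent_rate[pert$silenced], rep(0, 6))
  alive <- setdiff(seq_len(20), pert$silenced)
  expect_equal(pert$cross_participation[alive],
               net$cross_participation[alive] * 0.3)
  expect_equal(pert$independent_rate[pert$boosted],
               net$independent_rate[pert$boosted] * 5)
  # input untouched
  expect_equal(net$participation, generate_network(20, 2, seed = 3)$participation)

  # full silencing -> empty onset trains
  allmute <- apply_perturbation(net, perturbation_spec(silenced_fraction = 1),
                                seed = 1)
  expect_equal(sum(lengths(simulate_activity(allmute, 300, seed = 1)$onsets)), 0L)
})

test_that("weakening lowers the sequence occurrence rate", {
  # the programmed effect (~8% fewer ignitions) needs long recordings to
  # rise above Poisson noise; average the ratio over three seed pairs
  ratios <- vapply(1:3, function(r) {
    net <- generate_network(36, 3, seed = 10 + r)
    pert <- apply_perturbation(net, perturbation_spec(weaken_factor = 0.3),
                               seed = 20 + r)
    s0 <- detect_sequences(simulate_activity(net, 7200, seed = 30 + r)$onsets)
    s1 <- detect_sequences(simulate_activity(pert, 7200, seed = 40 + r)$onsets)
    length(s1$sequences) / length(s0$sequences)
  }, numeric(1))
  expect_lt(mean(ratios), 1)
})

test_that("trace/ground-truth round-trips through the file formats", {
  net <- generate_network(6, 2, seed = 1)
  act <- simulate_activity(net, 60, seed = 2)
  rec <- render_traces(act, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_traces_csv(rec, f)
  rec2 <- read_traces_csv(f)
  expect_equal(rec2$traces, rec$traces, ignore_attr = TRUE)
  expect_equal(rec2$frame_dt, rec$frame_dt, tolerance = 1e-8)
  g <- tempfile(fileext = ".json")
  write_ground_truth_json(act, g)
  gt <- jsonlite::read_json(g, simplifyVector = TRUE)
  expect_equal(gt$partition, net$community_of)
  unlink(c(f, g))
})
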