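test_that("null edge probability is total weight over pair count", {
  # 6-node unweighted graph with 6 edges: p = 6/15
  w <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1))
  for (e in seq_len(nrow(edges)))
    w[edges[e, 1], edges[e, 2]] <- w[edges[e, 2], edges[e, 1]] <- 1
  expect_equal(null_edge_probability(corr_network(w)), 6 / 15)

  wc <- matrix(0.5, 4, 4); diag(wc) <- 0
  expect_equal(null_edge_probability(corr_network(wc)), 0.5)
  expect_equal(null_edge_probability(corr_network(matrix(0, 3, 3))), 0)
  expect_error(null_edge_probability(corr_network(matrix(0, 1, 1))),
               "size error")
})

test_that("canonicalization is label-permutation invariant and
           idempotent", {
  labels <- paste0("MP", 1:5)
  a1 <- c(MP1 = 2L, MP2 = 2L, MP3 = 7L, MP4 = 7L, MP5 = 2L)
  a2 <- c(MP1 = 1L, MP2 = 1L, MP3 = 3L, MP4 = 3L, MP5 = 1L)
  p1 <- canonical_partition(a1, labels)
  p2 <- canonical_partition(a2, labels)
  expect_identical(p1, p2)
  expect_identical(canonical_partition(p1), p1)
  expect_identical(p1[[1]], c("MP1", "MP2", "MP5"))
})

test_that("energy identities: singletons give 0; all-in-one gives 0 at
           gamma = 1 under the weight-conserving null", {
  for (seed in 1:25) {
    net <- make_random_network(sample(3:9, 1), seed = seed,
                               density = runif(1, 0.2, 1))
    p <- null_edge_probability(net)
    singletons <- canonical_partition(
      stats::setNames(seq_along(net$labels), net$labels), net$labels)
    allone <- canonical_partition(
      stats::setNames(rep(1L, length(net$labels)), net$labels),
      net$labels)
    expect_equal(rb_energy(singletons, net, p), 0)
    expect_equal(rb_energy(allone, net, p, gamma = 1), 0,
                 tolerance = 1e-12)
  }
})

test_that("two disjoint 3-cliques have the planted bipartition as the
           exhaustive global minimum at energy -3.6", {
  net <- make_clique_pair(3)
  p <- null_edge_probability(net)
  expect_equal(p, 6 / 15)
  planted <- canonical_partition(
    stats::setNames(rep(1:2, each = 3), net$labels), net$labels)
  expect_equal(rb_energy(planted, net, p), -3.6)
  bf <- brute_force_min(net, p)
  expect_equal(bf$energy, -3.6, tolerance = 1e-12)
  keys <- vapply(bf$partitions, partition_key, "")
  expect_true(partition_key(planted) %in% keys)
})

test_that("brute force handles degenerate cases: empty network ties,
           single node, size cap", {
  empty <- corr_network(matrix(0, 3, 3), c("a", "b", "c"))
  bf <- brute_force_min(empty, 0)
  expect_equal(bf$energy, 0)
  expect_equal(length(bf$partitions), 5L) # Bell(3): every partition ties

  one <- corr_network(matrix(0, 2, 2), c("a", "b"))
  expect_equal(length(brute_force_min(one, 0)$partitions), 2L)

  big <- make_random_network(13, seed = 1)
  expect_error(brute_force_min(big, 0.5), "size error")
})

test_that("annealing is deterministic given (config, seed) and never ends
           above its starting energy", {
  net <- make_random_network(8, seed = 77)
  p <- null_edge_probability(net)
  cfg <- anneal_config(master_seed = 5)
  r1 <- anneal(net, p, cfg, trial_seed = 42L)
  r2 <- anneal(net, p, cfg, trial_seed = 42L)
  expect_identical(r1$partition, r2$partition)
  expect_identical(r1$energy, r2$energy)
  for (s in 1:10) {
    r <- anneal(net, p, cfg, trial_seed = s)
    expect_lte(r$energy, r$initial_energy + 1e-12)
    expect_equal(r$energy, rb_energy(r$partition, net, p),
                 tolerance = 1e-12)
  }
})

test_that("annealing finds the exhaustive minimum on small networks", {
  for (seed in c(3, 11, 29)) {
    net <- make_random_network(sample(5:9, 1), seed = seed)
    p <- null_edge_probability(net)
    bf <- brute_force_min(net, p)
    seeds <- spawn_seeds(seed, 30)
    best <- min(vapply(seeds, function(s)
      anneal(net, p, anneal_config(), s)$energy, 0))
    expect_equal(best, bf$energy, tolerance = 1e-9)
  }
})

test_that("an unambiguous two-clique network is solved in nearly every
           trial and tallied with frequency ~1", {
  net <- make_clique_pair(3)
  p <- null_edge_probability(net)
  tab <- frequency_solutions(net, p,
                             anneal_config(trials = 100, master_seed = 9))
  expect_equal(sum(tab$count), 100L)
  expect_equal(sum(tab$frequency), 1, tolerance = 1e-12)
  expect_gte(tab$frequency[1], 0.99)
  planted <- canonical_partition(
    stats::setNames(rep(1:2, each = 3), net$labels), net$labels)
  expect_identical(partition_key(top_partition(tab)),
                   partition_key(planted))
  expect_equal(tab$mean_energy[1], -3.6, tolerance = 1e-12)
})

test_that("a single trial yields a one-entry table with frequency 1", {
  net <- make_random_network(6, seed = 2)
  tab <- frequency_solutions(net, null_edge_probability(net),
                             anneal_config(trials = 1, master_seed = 3))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$frequency, 1)
})

test_that("module reproducibility counts exact-module occurrences", {
  net <- make_clique_pair(3)
  p <- null_edge_probability(net)
  tab <- frequency_solutions(net, p,
                             anneal_config(trials = 50, master_seed = 4))
  expect_equal(module_reproducibility(tab, paste0("A", 1:3)), 1,
               tolerance = 0.02)
  # a nodeset that never occurs as an exact module
  expect_equal(module_reproducibility(tab, c("A1", "B1")), 0)
  # subsets of a module do not count (set equality, not containment)
  expect_equal(module_reproducibility(tab, c("A1", "A2")), 0)
  expect_error(module_reproducibility(tab, "Z9"), "label error")
})

test_that("a uniform complete graph is energy-degenerate: every partition
           scores 0", {
  k <- 6
  w <- matrix(0.37, k, k); diag(w) <- 0
  net <- corr_network(w)
  p <- null_edge_probability(net)
  expect_equal(p, 0.37)
  r <- anneal(net, p, anneal_config(), trial_seed = 8L)
  expect_equal(r$energy, 0, tolerance = 1e-12)
})
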