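test_that("a triangle admits no legal swap", {
  tri <- binary_network(matrix(1, 3, 3) - diag(3))
  # exhaustive: every ordered pair of distinct edges must abort
  el <- edge_list(tri, base = 1L)
  a <- unclass(tri)
  for (e1 in 1:3) {
    for (e2 in setdiff(1:3, e1)) {
      for (flip in c(FALSE, TRUE)) {
        res <- smallworldnet:::propose_swap(a, el, e1, e2, flip = flip)
        expect_false(res$success)
        expect_identical(res$a, a)
      }
    }
  }
  set.seed(1)
  out <- rewire_swap(tri)
  expect_false(out$success)
  expect_identical(unclass(out$net), unclass(tri))
})

test_that("two disjoint edges always swap into a crossed pairing", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[3, 4] <- a[4, 3] <- 1
  net <- binary_network(a)
  # the two crossed pairings are the only legal rewirings; both are proposed
  el <- edge_list(net, base = 1L)
  res_keep <- smallworldnet:::propose_swap(a, el, 1, 2, flip = FALSE)
  res_flip <- smallworldnet:::propose_swap(a, el, 1, 2, flip = TRUE)
  expect_true(res_keep$success && res_flip$success)
  expect_equal(edge_list(binary_network(res_keep$a), base = 1L),
               cbind(i = c(1, 2), j = c(4, 3)), ignore_attr = TRUE)
  expect_equal(edge_list(binary_network(res_flip$a), base = 1L),
               cbind(i = c(1, 2), j = c(3, 4)), ignore_attr = TRUE)
  set.seed(2)
  seen <- replicate(20, {
    out <- rewire_swap(net)
    expect_true(out$success)
    expect_equal(degree_sequence(out$net), degree_sequence(net))
    paste(edge_list(out$net, base = 1L), collapse = ",")
  })
  expect_equal(length(unique(seen)), 2) # both pairings occur
})

test_that("swaps conserve degrees, symmetry and simplicity", {
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(8:16, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.6))
    if (sum(a) / 2 < 2) next
    net <- binary_network(a)
    rn <- randomize_network(net, target_swaps = 10 * n_edges(net),
                            seed = 100 + rep)
    b <- unclass(rn)
    expect_equal(degree_sequence(rn), degree_sequence(net))
    expect_identical(b, t(b))
    expect_true(all(diag(b) == 0))
    expect_true(all(b %in% c(0, 1)))
  }
})

test_that("randomization scrambles the edge set but not the degrees", {
  g <- generate_benchmark_graph("erdos_renyi", n = 90, p = 0.2, seed = 4)
  rn <- randomize_network(g, target_swaps = 10 * n_edges(g), seed = 5)
  expect_equal(degree_sequence(rn), degree_sequence(g))
  inter <- sum(unclass(g) * unclass(rn)) / 2
  union <- n_edges(g) + n_edges(rn) - inter
  expect_lt(inter / union, 0.9) # Jaccard similarity well below identity
  # zero swaps is the identity
  expect_identical(unclass(randomize_network(g, 0)), unclass(g))
  # seeded determinism
  expect_identical(unclass(randomize_network(g, 500, seed = 6)),
                   unclass(randomize_network(g, 500, seed = 6)))
})

test_that("rigid graphs trigger the rigidity warning and are returned intact", {
  tri <- binary_network(matrix(1, 3, 3) - diag(3))
  expect_warning(out <- randomize_network(tri, 10, seed = 7, attempt_factor = 5),
                 "rigid")
  expect_identical(unclass(out), unclass(tri))
})

test_that("ensemble summaries store per-network values and their means", {
  g <- generate_benchmark_graph("watts_strogatz", n = 40, k = 6, p = 0.1,
                                seed = 8)
  ens <- ensemble_summary(g, n_random = 5, target_swaps_per_edge = 10, seed = 9)
  expect_equal(nrow(ens$per_network), 5)
  expect_equal(ens$C_random, mean(ens$per_network$C))
  expect_equal(ens$L_random, mean(ens$per_network$L[!is.na(ens$per_network$L)]))
  # single-network ensemble: the mean is that network's value
  e1 <- ensemble_summary(g, n_random = 1, target_swaps_per_edge = 10, seed = 10)
  expect_equal(e1$C_random, e1$per_network$C[1])
  # reproducible under the same seed
  e2 <- ensemble_summary(g, n_random = 5, target_swaps_per_edge = 10, seed = 9)
  expect_identical(ens$per_network, e2$per_network)
})

test_that("rewiring a lattice destroys its triangles", {
  rl <- generate_benchmark_graph("ring_lattice", n = 90, k = 10)
  m <- network_metrics(rl)
  ens <- ensemble_summary(rl, n_random = 5, target_swaps_per_edge = 10, seed = 11)
  expect_lt(ens$C_random, m$C_net)
})

test_that("small-world indices are the stated ratios", {
  swi <- small_world_index(0.6, 0.3, 2.0, 1.8)
  expect_equal(swi$gamma, 2.0)
  expect_equal(swi$lam, 2.0 / 1.8)
  expect_equal(swi$sigma, swi$gamma / swi$lam)
  eq <- small_world_index(0.4, 0.4, 1.7, 1.7)
  expect_equal(eq$sigma, 1)
  expect_error(small_world_index(0, 0.3, 2, 1.8), "positive")
})

test_that("an Erdos-Renyi graph is (nearly) its own null", {
  g <- generate_benchmark_graph("erdos_renyi", n = 90, p = 0.2, seed = 12)
  m <- network_metrics(g)
  ens <- ensemble_summary(g, n_random = 20, target_swaps_per_edge = 10, seed = 13)
  expect_lt(abs(m$C_net / ens$C_random - 1), 0.1)
  expect_lt(abs(m$L_net / ens$L_random - 1), 0.1)
})

test_that("modular binarized networks show small-world structure", {
  cfg <- simulation_config(n_subjects = 1, n_regions = 60, n_timepoints = 150,
                           n_modules = 6, within_r = 0.7, between_r = 0.05,
                           seed = 14)
  x <- generate_roi_timeseries(cfg, "A")$subjects[[1]]
  net <- binarize(correlation_matrix(x), 0.3)
  m <- network_metrics(net)
  ens <- ensemble_summary(net, n_random = 20, target_swaps_per_edge = 10,
                          seed = 15)
  swi <- small_world_index(m$C_net, ens$C_random, m$L_net, ens$L_random)
  expect_gt(swi$sigma, 1)
})
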