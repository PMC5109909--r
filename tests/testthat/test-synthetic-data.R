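test_that("benchmark graph generators honour their structural contracts", {
  k4 <- generate_benchmark_graph("complete", n = 4)
  expect_true(all(unclass(k4)[upper.tri(k4)] == 1))
  expect_equal(n_edges(k4), 6L)

  rl <- generate_benchmark_graph("ring_lattice", n = 90, k = 10)
  expect_true(all(rowSums(unclass(rl)) == 10))
  expect_equal(n_edges(rl), 450L)

  ws <- generate_benchmark_graph("watts_strogatz", n = 90, k = 10, p = 0.1, seed = 7)
  expect_equal(sum(rowSums(unclass(ws))), 900) # edge count of the lattice kept
  d <- shortest_paths(ws)
  expect_true(all(is.finite(d)))

  st <- generate_benchmark_graph("star", n = 5)
  expect_equal(unname(sort(rowSums(unclass(st)))), c(1, 1, 1, 1, 4))
  cy <- generate_benchmark_graph("cycle", n = 6)
  expect_true(all(rowSums(unclass(cy)) == 2))

  expect_error(generate_benchmark_graph("ring_lattice", n = 10, k = 3),
               "even")
  expect_error(generate_benchmark_graph("complete", n = 2), "n must be")
})

test_that("seeded generators are bit-identical across calls", {
  for (kind in c("watts_strogatz", "erdos_renyi")) {
    g1 <- generate_benchmark_graph(kind, n = 40, k = 6, p = 0.2, seed = 11)
    g2 <- generate_benchmark_graph(kind, n = 40, k = 6, p = 0.2, seed = 11)
    expect_identical(unclass(g1), unclass(g2))
  }
  cfg <- simulation_config(n_subjects = 2, n_regions = 12, n_timepoints = 30,
                           n_modules = 3, seed = 5)
  s1 <- generate_roi_timeseries(cfg, "A")
  s2 <- generate_roi_timeseries(cfg, "A")
  expect_identical(s1$subjects, s2$subjects)
})

test_that("simulation config validates correlation targets and PSD", {
  expect_error(simulation_config(within_r = 0.2, between_r = 0.5),
               "smaller than within_r")
  expect_error(simulation_config(within_r = 1.2, between_r = 0.1),
               "inside \\(-1, 1\\)")
  expect_error(simulation_config(within_r = 0.95, group_effect = 0.1,
                                 between_r = 0.1), "group B")
  # strongly negative between-module correlation breaks positive definiteness
  expect_error(simulation_config(n_regions = 30, n_modules = 3,
                                 within_r = 0.2, between_r = -0.9),
               "positive semi-definite")
})

test_that("generated series recover the target block correlations", {
  cfg <- simulation_config(n_subjects = 1, n_regions = 12, n_timepoints = 5000,
                           n_modules = 3, within_r = 0.6, between_r = 0.1,
                           seed = 42)
  x <- generate_roi_timeseries(cfg, "A")$subjects[[1]]
  r <- cor(t(x))
  mod <- rep(1:3, each = 4)
  within <- r[outer(mod, mod, "==") & upper.tri(r)]
  between <- r[outer(mod, mod, "!=") & upper.tri(r)]
  expect_lt(abs(mean(within) - 0.6), 0.05)
  expect_lt(abs(mean(between) - 0.1), 0.05)
})

test_that("null configuration yields near-zero empirical correlations", {
  cfg <- simulation_config(n_subjects = 1, n_regions = 15, n_timepoints = 1000,
                           n_modules = 3, within_r = 1e-12, between_r = 0,
                           seed = 3)
  x <- generate_roi_timeseries(cfg, "A")$subjects[[1]]
  r <- cor(t(x))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)
})

test_that("AR(1) option preserves the lag-0 correlation targets", {
  cfg <- simulation_config(n_subjects = 1, n_regions = 12, n_timepoints = 5000,
                           n_modules = 3, within_r = 0.6, between_r = 0.1,
                           ar1 = 0.4, seed = 42)
  x <- generate_roi_timeseries(cfg, "A")$subjects[[1]]
  r <- cor(t(x))
  mod <- rep(1:3, each = 4)
  within <- r[outer(mod, mod, "==") & upper.tri(r)]
  expect_lt(abs(mean(within) - 0.6), 0.05)
  # and the series really are autocorrelated
  ac <- mean(apply(x, 1, function(v) cor(v[-1], v[-length(v)])))
  expect_gt(ac, 0.25)
})

test_that("two-group generator induces the intended density difference", {
  cfg <- simulation_config(n_subjects = 10, n_regions = 45, n_timepoints = 150,
                           n_modules = 3, within_r = 0.5, between_r = 0.1,
                           group_effect = 0.1, seed = 9)
  ds <- generate_two_group_dataset(cfg, labels = c("right", "left"))
  expect_identical(names(ds), c("right", "left"))
  k_mean <- vapply(ds, function(set) {
    mean(vapply(set$subjects, function(x) {
      net <- binarize(correlation_matrix(x), 0.3)
      mean(rowSums(unclass(net)))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(k_mean[["left"]], k_mean[["right"]])
})

test_that("module sizes differ by at most one region", {
  for (n in c(90, 91, 47)) {
    cfg <- simulation_config(n_regions = n, n_modules = 6, n_subjects = 1)
    sigma <- block_correlation(n, 6, cfg$within_r, cfg$between_r)
    expect_equal(nrow(sigma), n)
  }
  sizes <- table(smallworldnet:::module_assignment(47, 6))
  expect_lte(diff(range(sizes)), 1)
})

test_that("scan arithmetic and volume dropping behave as stated", {
  expect_identical(scan_volumes(310, 2), 155L)
  x <- matrix(rnorm(10 * 20), 10, 20)
  expect_equal(dim(drop_initial_volumes(x, 5)), c(10, 15))
  expect_equal(drop_initial_volumes(x, 5), x[, 6:20])
})
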