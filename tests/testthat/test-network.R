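test_that("edge probability endpoints behave: complete graph and empty graph", {
  net <- generate_network(3, z = 2, k = 2, theta = 0, rng_seed = 1)
  expect_equal(nrow(net$edges), 3L)
  expect_false(any(net$antagonist))

  net0 <- generate_network(100, z = 0, k = 2, theta = 0, rng_seed = 1)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(length(giant_component(net0)), 1L)
  expect_equal(giant_component(net0), 1L)  # tie-break: smallest index

  # z >= n - 1 clamps to the complete graph
  netc <- generate_network(20, z = 100, k = 2, theta = 0, rng_seed = 1)
  expect_equal(nrow(netc$edges), choose(20, 2))
  expect_equal(giant_component(netc), 1:20)
})

test_that("generation is reproducible and validates its arguments", {
  a <- generate_network(200, 4, 2, 0.5, rng_seed = 42)
  b <- generate_network(200, 4, 2, 0.5, rng_seed = 42)
  expect_identical(a, b)
  d <- generate_network(200, 4, 2, 0.5, rng_seed = 43)
  expect_false(identical(a$edges, d$edges))

  expect_error(generate_network(5, 2, k = 6), "k")
  expect_error(generate_network(10, 2, theta = 1.5), "theta")
  expect_error(generate_network(10, -1), "nonnegative")
})

test_that("thresholds, seeds and antagonist counts match the construction", {
  net <- generate_network(1000, 4, k = 3, theta = 1 / 3, rng_seed = 9)
  expect_true(all(net$thresholds > 0 & net$thresholds < 1))
  expect_length(net$seeds, 3L)
  expect_false(anyDuplicated(net$seeds) > 0)
  expect_equal(sum(net$antagonist), round((1000 - 3) / 3))
  expect_false(any(net$antagonist[net$seeds]))
})

test_that("sample mean degree matches the target within 3 standard errors", {
  degs <- vapply(1:30, function(s) {
    net <- generate_network(2000, 4, 2, 0, rng_seed = s)
    2 * nrow(net$edges) / net$n
  }, numeric(1))
  se <- sd(degs) / sqrt(length(degs))
  expect_lt(abs(mean(degs) - 4), 3 * se)
})

test_that("gcc_fraction_theoretical solves the self-consistency relation", {
  expect_equal(gcc_fraction_theoretical(0.5), 0)
  expect_equal(gcc_fraction_theoretical(1), 0)
  # frozen from an independent uniroot solve of v = 1 - exp(-z v)
  expect_equal(gcc_fraction_theoretical(2), 0.796812130020, tolerance = 1e-9)
  expect_equal(gcc_fraction_theoretical(4), 0.980172598718, tolerance = 1e-9)
  expect_equal(gcc_fraction_theoretical(8), 0.999663633449, tolerance = 1e-9)
  v <- gcc_fraction_theoretical(4)
  expect_lt(abs(v - (1 - exp(-4 * v))), 1e-10)
  expect_error(gcc_fraction_theoretical(-1), "nonnegative")
})

test_that("gcc fraction is nondecreasing in z and approaches 1", {
  zs <- c(0, 0.5, 1, 1.5, 2, 4, 8, 50, 500)
  vs <- gcc_fraction_theoretical(zs)
  expect_true(all(diff(vs) >= 0))
  expect_true(all(vs[zs <= 1] == 0))
  expect_gt(vs[length(vs)], 1 - 1e-10)
})

test_that("empirical giant components agree with percolation theory", {
  for (z in c(2, 4)) {
    fr <- vapply(1:40, function(s) {
      net <- generate_network(3000, z, 2, 0, rng_seed = 1000 + s)
      length(giant_component(net)) / net$n
    }, numeric(1))
    se <- sd(fr) / sqrt(length(fr))
    expect_lt(abs(mean(fr) - gcc_fraction_theoretical(z)), 3 * se)
  }
})

test_that("clustering estimate equals z/(n-1) and matches simulation", {
  expect_equal(clustering_estimate(10000, 10), 10 / 9999)
  expect_equal(clustering_estimate(2, 1), 1)
  cc <- vapply(1:15, function(s) {
    net <- generate_network(2000, 10, 2, 0, rng_seed = s)
    igraph::transitivity(as_igraph(net), type = "global")
  }, numeric(1))
  se <- sd(cc) / sqrt(length(cc))
  expect_lt(abs(mean(cc) - clustering_estimate(2000, 10)), 3 * se)
})

test_that("edge-list round trip preserves the network exactly", {
  net <- generate_network(80, 3, 2, 0.25, rng_seed = 5)
  path <- file.path(tempdir(), "net.edges")
  write_edgelist(net, path)
  back <- read_edgelist(path)
  expect_equal(back$edges, net$edges)
  expect_equal(back$thresholds, net$thresholds, tolerance = 1e-12)
  expect_equal(back$antagonist, net$antagonist)
  expect_equal(back$seeds, net$seeds)
})

test_that("malformed edge lists are rejected with a line number", {
  path <- file.path(tempdir(), "bad.edges")
  sidecar <- paste0(path, ".meta.yaml")
  yaml::write_yaml(list(n = 3, k = 1, seed_nodes = 0L,
                        thresholds = c(.5, .5, .5),
                        antagonist_flags = c(0L, 0L, 0L)), sidecar)
  writeLines(c("0 1", "0 0"), path)
  expect_error(read_edgelist(path), "self-loop at line 2")
  writeLines(c("0 1", "oops"), path)
  expect_error(read_edgelist(path), "line 2")
  writeLines(character(0), path)
  empty <- read_edgelist(path)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(empty$n, 3L)
})

test_that("hand-built networks reject invariant violations", {
  expect_error(threshold_network(3, rbind(c(1, 1)), rep(.5, 3), 1), "self-loop")
  expect_error(threshold_network(3, rbind(c(1, 2), c(2, 1)), rep(.5, 3), 1),
               "duplicate")
  expect_error(threshold_network(3, rbind(c(1, 2)), c(.5, .5, 1.2), 1),
               "thresholds")
  expect_error(threshold_network(3, rbind(c(1, 2)), rep(.5, 3), c(1, 1)),
               "seed")
})
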