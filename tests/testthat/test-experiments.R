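test_that("census counts are conserved: every non-seed node computes one function", {
  cen <- function_census(n = 300, k = 2, z = 4, theta = 0.25,
                         realizations = 8, master_seed = 3)
  sums <- tapply(cen$counts$count, cen$counts$realization, sum)
  expect_true(all(sums == 300 - 2))
  expect_true(all(cen$counts$fn_id >= 0 & cen$counts$fn_id <= 15))
  # deterministic given the master seed
  cen2 <- function_census(n = 300, k = 2, z = 4, theta = 0.25,
                          realizations = 8, master_seed = 3)
  expect_identical(cen$counts, cen2$counts)
})

test_that("edgeless ensembles collapse to the constant functions", {
  cen0 <- function_census(n = 10, k = 2, z = 0, theta = 0,
                          realizations = 3, master_seed = 1)
  expect_true(all(cen0$counts$fn_id == 0L))
  expect_true(all(cen0$counts$count == 8L))
  expect_equal(nrow(rank_ordering(cen0)), 0L)

  cen1 <- function_census(n = 10, k = 2, z = 0, theta = 1,
                          realizations = 3, master_seed = 1)
  expect_true(all(cen1$counts$fn_id == 15L))
  expect_true(all(cen1$counts$count == 8L))
})

test_that("rank ordering sorts by mean frequency with id tie-breaks", {
  cen <- function_census(n = 500, k = 2, z = 4, theta = 0,
                         realizations = 30, master_seed = 7)
  ranked <- rank_ordering(cen)
  expect_false(0L %in% ranked$fn_id)
  expect_true(all(diff(ranked$mean_freq) <= 0))
  ties <- which(diff(ranked$mean_freq) == 0)
  expect_true(all(ranked$fn_id[ties + 1] > ranked$fn_id[ties]))
  # single realization: sd is zero
  cen1 <- function_census(n = 500, k = 2, z = 4, theta = 0,
                          realizations = 1, master_seed = 8)
  r1 <- rank_ordering(cen1)
  expect_true(all(r1$sd_freq == 0))
})

test_that("frequencies order inversely with complexity exponents in the LTM", {
  cen <- function_census(n = 2000, k = 2, z = 4, theta = 0,
                         realizations = 150, master_seed = 11)
  ranked <- rank_ordering(cen)
  f <- function(id) {
    x <- ranked$mean_freq[ranked$fn_id == id]
    if (length(x)) x else 0
  }
  # exponent 2 functions (projections f3, f5) beat exponent 3 (f1, f7)
  expect_gt(min(f(3), f(5)), max(f(1), f(7)))
})

test_that("prediction correlation recovers a perfect match and flags degeneracy", {
  cen <- function_census(n = 2000, k = 2, z = 4, theta = 0,
                         realizations = 100, master_seed = 2)
  pc <- prediction_correlation(cen)
  expect_true(is.finite(pc$r))
  expect_gt(pc$r, 0.5)
  # predictions identical to frequencies give r = 1 by construction
  tab <- pc$table
  expect_equal(cor(tab$predicted, tab$predicted), 1)
  expect_error(prediction_correlation(
    function_census(n = 10, k = 2, z = 0, theta = 0,
                    realizations = 2, master_seed = 1)),
    "at least 3")
})

test_that("exponential rank fit is exact on a geometric sequence", {
  ranked <- data.frame(rank = 1:6, fn_id = 1:6,
                       mean_freq = 100 * 0.5^(0:5), sd_freq = 0)
  fit <- suppressWarnings(exponential_rank_fit(ranked))  # perfect-fit note
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$decay_rate, log(2), tolerance = 1e-12)
  expect_error(exponential_rank_fit(ranked[1:2, ]), "at least 3")
  # zero-frequency entries are dropped before the log
  ranked$mean_freq[4] <- 0
  expect_equal(exponential_rank_fit(ranked)$n_used, 5L)
})

test_that("unique-function surface respects exclusions and trivial cells", {
  surf <- unique_function_surface(z_list = c(0, 4), theta_list = c(0, 0.5),
                                  n = 100, k = 2, realizations = 4,
                                  master_seed = 5)
  z0 <- surf[surf$z == 0, ]
  expect_equal(z0$mean_unique, c(0, 0))  # only constants at z = 0
  ltm <- surf[surf$theta == 0 & surf$z == 4, ]
  expect_lte(ltm$mean_unique, 4)  # at most f1, f3, f5, f7
})

test_that("argmax_theta picks the diversity maximum with low-theta tie-breaks", {
  surf <- data.frame(z = rep(c(8, 64), each = 3),
                     theta = rep(c(0, 1 / 3, 2 / 3), 2),
                     mean_unique = c(1, 5, 5, 2, 6, 6), sd_unique = 0)
  expect_equal(argmax_theta(surf), 1 / 3)
  const <- transform(surf, mean_unique = 3)
  expect_equal(argmax_theta(const), 0)
  one <- surf[2, ]
  expect_equal(argmax_theta(one), 1 / 3)
  expect_error(argmax_theta(surf, z_range = c(1000, 2000)), "no cells")
})

test_that("pure-ALTM depth-1 nets mirror the LTM as bitwise complements", {
  set.seed(42)
  subsets <- list(integer(0), 1L, 2L, c(1L, 2L))
  for (rep in 1:20) {
    attach <- sample(subsets, 6, replace = TRUE)
    phi <- runif(6, 0.05, 0.95)
    ltm <- bipartite_net(2, attach, phi)
    altm <- bipartite_net(2, attach, phi,
                          antagonist = c(rep(FALSE, 2), rep(TRUE, 6)))
    a <- extract_functions(ltm)[-(1:2)]
    b <- extract_functions(altm)[-(1:2)]
    expect_equal(b, 15L - a)  # bitwise complement of each truth table
    expect_true(all(a %in% ltm_computable_ids(2)))
  }
})
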