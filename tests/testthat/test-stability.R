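test_that("edge bootstrap is reproducible and CI-consistent", {
  net <- mk_net5()
  d <- sample_ising(net, 300, seed = 40)
  b1 <- bootstrap_edges(d, B = 30, seed = 41)
  b2 <- bootstrap_edges(d, B = 30, seed = 41)
  expect_identical(b1$edge_estimates, b2$edge_estimates)
  expect_identical(b1$edge_ci, b2$edge_ci)
  expect_identical(b1$edge_diff_significant, b2$edge_diff_significant)

  expect_true(all(b1$edge_ci[, "lower"] <= b1$edge_ci[, "upper"]))
  expect_identical(dim(b1$edge_estimates), c(30L, 10L))
  # difference matrices are symmetric with a FALSE diagonal
  expect_identical(b1$edge_diff_significant, t(b1$edge_diff_significant))
  expect_false(any(diag(b1$edge_diff_significant)))
  expect_identical(b1$centrality_diff_significant$ei,
                   t(b1$centrality_diff_significant$ei))

  # an edge absent from every replicate has CI (0, 0): on independence data
  # at n = 2000 most edges are never selected in any resample
  set.seed(48)
  v0 <- matrix(rbinom(2000 * 4, 1, 0.5), 2000, 4,
               dimnames = list(NULL, paste0("V", 1:4)))
  b0 <- bootstrap_edges(binary_dataset(v0, two_comm(colnames(v0), 2)),
                        B = 30, seed = 49)
  never <- colSums(b0$edge_estimates != 0) == 0
  expect_gt(sum(never), 0)
  expect_true(all(b0$edge_ci[never, ] == 0))
})

test_that("bootstrap CIs tighten with sample size", {
  net <- mk_net5()
  d_small <- sample_ising(net, 400, seed = 42)
  d_large <- sample_ising(net, 4000, seed = 43)
  b_small <- bootstrap_edges(d_small, B = 60, seed = 44)
  b_large <- bootstrap_edges(d_large, B = 60, seed = 45)
  w_small <- mean(b_small$edge_ci[, "upper"] - b_small$edge_ci[, "lower"])
  w_large <- mean(b_large$edge_ci[, "upper"] - b_large$edge_ci[, "lower"])
  expect_lt(w_large, w_small)
})

test_that("paired difference test reads the percentile interval", {
  x <- rnorm(100)
  expect_false(difference_test(x, x))
  expect_true(difference_test(x + 1e-3 + abs(rnorm(100)), x))
  expect_error(difference_test(x[1:10], x[1:10]), "20")
  expect_error(difference_test(x, x[1:50]), "equal length")

  # symmetric in significance, whichever way the arguments go
  set.seed(46)
  for (i in 1:10) {
    a <- rnorm(50, sample(c(0, 0.5, 2), 1), 1)
    b <- rnorm(50)
    expect_identical(difference_test(a, b), difference_test(b, a))
  }

  # paired replicates share resampling noise: a 2-SD gap with common noise
  set.seed(47)
  u <- rnorm(1000)
  a <- 2 + u + rnorm(1000, 0, 0.3)
  b <- u + rnorm(1000, 0, 0.3)
  expect_true(difference_test(a, b))
})

test_that("case-dropping bootstrap is reproducible and near 1 at small drops", {
  net <- mk_strong10(seed = 3)
  d <- sample_ising(net, 1000, seed = 50)
  cd1 <- case_dropping_bootstrap(d, "EI", drop_grid = c(0.05, 0.3), B = 10,
                                 seed = 51)
  cd2 <- case_dropping_bootstrap(d, "EI", drop_grid = c(0.05, 0.3), B = 10,
                                 seed = 51)
  expect_identical(cd1$correlations, cd2$correlations)
  expect_true(all(cd1$correlations >= -1 & cd1$correlations <= 1, na.rm = TRUE))
  # continuity: dropping almost nothing leaves the statistic almost unchanged
  expect_gt(mean(cd1$correlations[1, ]), 0.95)

  expect_error(case_dropping_bootstrap(d, "EI", drop_grid = c(0.1, 0.8)),
               "0.75")
})

test_that("CS coefficient enforces the monotone qualifying-rung rule", {
  grid <- seq(0.05, 0.75, by = 0.05)
  mk_result <- function(corr) {
    structure(list(drop_proportions = grid, correlations = corr,
                   statistic = "EI", full_statistic = 1:3, B = ncol(corr),
                   seed = 1, n_redrawn = 0L, gamma = 0.25, rule = "AND"),
              class = "case_drop_result")
  }
  # all correlations 1 -> the grid maximum
  expect_equal(cs_coefficient(mk_result(matrix(1, 15, 40))), 0.75)
  # only the first rung qualifies
  corr <- matrix(0.2, 15, 40); corr[1, ] <- 0.9
  expect_equal(cs_coefficient(mk_result(corr)), 0.05)
  # nothing qualifies
  expect_equal(cs_coefficient(mk_result(matrix(0.2, 15, 40))), 0)
  # a dip at rung 4 caps CS below it, whatever happens later
  corr2 <- matrix(0.95, 15, 40); corr2[4, ] <- 0.1
  expect_equal(cs_coefficient(mk_result(corr2)), 0.15)
  # NA correlations (degenerate replicates) count as failures
  corr3 <- matrix(1, 15, 40); corr3[2, 1:4] <- NA
  expect_equal(cs_coefficient(mk_result(corr3)), 0.05)
  # constant statistic plus vanishing noise -> grid maximum
  set.seed(52)
  corr4 <- matrix(1 - abs(rnorm(15 * 40, 0, 1e-6)), 15, 40)
  expect_equal(cs_coefficient(mk_result(corr4)), 0.75)
})

test_that("bootstrap CIs track the estimator's sampling distribution", {
  # Percentile CIs centre on the l1-shrunken estimate, which sits ~0.8 SE
  # below the generating weight at every tractable n, so they undercover
  # the *true* weights by construction (~0.83 observed). The properties
  # that do hold, checked over 200 scaled-down trials: near-nominal
  # coverage of the estimator's own expected value, and a floor on
  # true-weight coverage consistent with that bias.
  net <- mk_net5()
  res <- vapply(1:200, function(tr) {
    d <- sample_ising(net, 800, seed = 7000 + tr)
    b <- suppressMessages(bootstrap_edges(d, B = 50, seed = tr))
    wt <- net$weights[cbind(b$edge_index$i, b$edge_index$j)]
    nz <- wt != 0
    est <- apply(b$edge_estimates, 2, stats::median)[nz]
    rbind(b$edge_ci[nz, "lower"], b$edge_ci[nz, "upper"], est)
  }, matrix(0, 3, 5))
  # nonzero edges in pair order: (1,2) (1,5) (2,3) (3,4) (4,5)
  truth <- net$weights[cbind(c(1, 1, 2, 3, 4), c(2, 5, 3, 4, 5))]
  mc_mean <- rowMeans(res[3, , ])          # per-edge mean estimate
  cover_mean <- sapply(1:5, function(e)
    mean(res[1, e, ] <= mc_mean[e] & mc_mean[e] <= res[2, e, ]))
  cover_truth <- sapply(1:5, function(e)
    mean(res[1, e, ] <= truth[e] & truth[e] <= res[2, e, ]))
  expect_gte(mean(cover_mean), 0.85)
  expect_gte(mean(cover_truth), 0.75)
  # and the bias those numbers reflect is downward shrinkage, not noise
  expect_true(all(mc_mean < truth))
})
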