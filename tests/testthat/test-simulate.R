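test_that("enumeration matches closed forms and normalizes exactly", {
  # tau = 0, w = 0: uniform over 2^p states
  items <- paste0("V", 1:3)
  W0 <- matrix(0, 3, 3, dimnames = list(items, items))
  en <- enumerate_ising(balanced_net(W0))
  expect_equal(en$prob, rep(1 / 8, 8))

  # single node, tau = 1: P(x = 1) = logistic(1)
  net1 <- ising_network(c(V1 = 1), matrix(0, 1, 1))
  en1 <- enumerate_ising(net1)
  expect_equal(en1$prob[en1$states[, 1] == 1], plogis(1), tolerance = 1e-12)

  # p = 2, tau = 0, w12 = 1: hand-computed partition function 3 + e
  W2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  en2 <- enumerate_ising(ising_network(c(a = 0, b = 0), W2))
  expect_equal(en2$prob[rowSums(en2$states) == 2], exp(1) / (3 + exp(1)),
               tolerance = 1e-12)
  expect_equal(round(en2$prob[rowSums(en2$states) == 2], 4), 0.4754)

  # random networks normalize to machine precision
  for (s in 1:5) {
    gt <- make_true_network(3, 3, within_density = 0.8, cross_density = 0.5,
                            weight_range = c(-1, 2), tau_range = c(-2, 1),
                            seed = s)
    expect_lt(abs(sum(enumerate_ising(gt$network)$prob) - 1), 1e-12)
  }

  big <- make_true_network(11, 10, seed = 1)
  expect_error(enumerate_ising(big$network), "gibbs")
})

test_that("gibbs conditionals equal enumerated probability ratios", {
  gt <- make_true_network(2, 2, within_density = 1, cross_density = 0.5,
                          weight_range = c(-0.5, 1.5), tau_range = c(-1, 1),
                          seed = 9)
  net <- gt$network
  en <- enumerate_ising(net)
  for (k in seq_len(nrow(en$states))) {
    x <- en$states[k, ]
    for (i in 1:4) {
      x1 <- replace(x, i, 1); x0 <- replace(x, i, 0)
      k1 <- which(colSums(abs(t(en$states) - x1)) == 0)
      k0 <- which(colSums(abs(t(en$states) - x0)) == 0)
      cond <- plogis(net$thresholds[i] + sum(net$weights[i, ] * x))
      ratio <- en$prob[k1] / (en$prob[k1] + en$prob[k0])
      expect_equal(unname(cond), ratio, tolerance = 1e-12)
    }
  }
})

test_that("exact sampler frequencies match the enumerated distribution", {
  gt <- make_true_network(2, 2, within_density = 1, cross_density = 0.5,
                          weight_range = c(0.3, 1), tau_range = c(-1, 0.5),
                          seed = 5)
  d1 <- sample_ising(gt$network, 500, seed = 6)
  d2 <- sample_ising(gt$network, 500, seed = 6)
  expect_identical(d1$values, d2$values)
  g1 <- sample_ising(gt$network, 200, method = "gibbs", seed = 7,
                     burnin = 50, thin = 2)
  g2 <- sample_ising(gt$network, 200, method = "gibbs", seed = 7,
                     burnin = 50, thin = 2)
  expect_identical(g1$values, g2$values)

  en <- enumerate_ising(gt$network)
  de <- sample_ising(gt$network, 100000, seed = 8)
  key <- de$values %*% 2^(0:3)
  freq <- tabulate(key + 1, 16) / 100000
  pe <- en$prob[order(en$states %*% 2^(0:3))]
  mc_sd <- sqrt(pe * (1 - pe) / 100000)
  expect_true(all(abs(freq - pe) <= 3 * mc_sd))

  expect_error(sample_ising(gt$network, 0), "positive")
})

test_that("ground-truth generator honours densities and communities", {
  gt0 <- make_true_network(4, 4, cross_density = 0, within_density = 0.6,
                           seed = 12)
  expect_true(all(bridge_expected_influence(gt0$network) == 0))

  gt1 <- make_true_network(4, 4, cross_density = 1, within_density = 1,
                           seed = 13)
  expect_equal(network_summary(gt1$network)$density, 1)

  # edge count is binomial: mean over 500 seeds within 2 SE of expectation
  wd <- 0.4; cd <- 0.25
  counts <- vapply(1:500, function(s)
    network_summary(make_true_network(9, 7, within_density = wd,
                                      cross_density = cd,
                                      seed = s)$network)$n_edges,
    numeric(1))
  n_within <- choose(9, 2) + choose(7, 2)
  mu <- wd * n_within + cd * 63
  se <- sqrt(wd * (1 - wd) * n_within + cd * (1 - cd) * 63) / sqrt(500)
  expect_lt(abs(mean(counts) - mu), 2 * se)
})

test_that("questionnaire generator reproduces its orthant probabilities", {
  # cut-points far in the upper tail: everything is 0
  comm3 <- two_comm(paste0("V", 1:3), 2)
  r0 <- ordinal_recipe(diag(3), matrix(c(4, 5, 6), 3, 3, byrow = TRUE),
                       comm3, n = 50, seed = 1)
  expect_true(all(generate_questionnaire(r0)$values == 0))

  # reference-calibrated marginals at n = 10,000: presence and all category
  # probabilities within 3 binomial SEs (PHQ1 presence target 0.73)
  rec <- paperlike_recipe(n = 10000, seed = 2)
  q <- generate_questionnaire(rec)
  p1 <- pnorm(rec$thresholds[, 1], lower.tail = FALSE)
  expect_equal(unname(p1[1]), 4535 / 6183, tolerance = 1e-12)
  presence <- colMeans(q$values > 0)
  expect_true(all(abs(presence - p1) <= 3 * sqrt(p1 * (1 - p1) / 10000)))
  for (k in 2:3) {
    pk <- pnorm(rec$thresholds[, k], lower.tail = FALSE)
    ok <- abs(colMeans(q$values >= k) - pk) <= 3 * sqrt(pk * (1 - pk) / 10000)
    expect_true(all(ok))
  }
  # positive skew throughout
  skew <- apply(q$values, 2, function(v) mean((v - mean(v))^3) / sd(v)^3)
  expect_true(all(skew > 0))

  # identity latent correlation: observed item correlations near zero
  ri <- ordinal_recipe(diag(3), matrix(c(0, 0.8, 1.6), 3, 3, byrow = TRUE),
                       comm3, n = 10000, seed = 3)
  qi <- generate_questionnaire(ri)
  cors <- cor(qi$values)[upper.tri(diag(3))]
  expect_true(all(abs(cors) < 3 / sqrt(10000)))

  # non-positive-definite correlation is rejected
  Rbad <- matrix(0.99, 3, 3); Rbad[1, 2] <- Rbad[2, 1] <- -0.99; diag(Rbad) <- 1
  expect_error(generate_questionnaire(
    ordinal_recipe(Rbad, matrix(c(0, 1, 2), 3, 3, byrow = TRUE), comm3,
                   n = 10, seed = 1)), "positive definite")
})

test_that("recovery report grades estimates against the truth", {
  net <- mk_recovery_net(1)
  expect_equal(recovery_report(net, net),
               list(sensitivity = 1, specificity = 1, weight_correlation = 1,
                    sign_accuracy = 1, n_true_edges = 12L,
                    n_estimated_edges = 12L),
               tolerance = 1e-12)

  empty <- balanced_net(net$weights * 0, net$community)
  r <- recovery_report(net, empty)
  expect_equal(r$sensitivity, 0)
  expect_equal(r$specificity, 1)
})

test_that("estimation converges to the truth as n grows", {
  net <- mk_recovery_net(2)
  wcor <- vapply(c(500, 2000, 8000), function(n) {
    d <- sample_ising(net, n, seed = 60 + n)
    recovery_report(net, estimate_network(d))$weight_correlation
  }, numeric(1))
  expect_true(all(diff(wcor) >= -1e-12))
  expect_gt(wcor[3], 0.9)
})
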