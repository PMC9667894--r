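test_that("read_responses parses valid CSVs and rejects malformed ones", {
  comm <- phq_gad_communities()
  path <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(0L, 3, 16, dimnames = list(NULL, names(comm)))
  write.csv(m, path, row.names = FALSE)
  x <- read_responses(path, comm)
  expect_s3_class(x, "item_responses")
  expect_identical(dim(x$values), c(3L, 16L))
  expect_true(all(x$values == 0))
  expect_identical(x$item_ids, names(comm))

  # missing declared column
  write.csv(m[, -16], path, row.names = FALSE)
  expect_error(read_responses(path, comm), "GAD7")

  # out-of-range cell names row and item
  m2 <- m; m2[2, 3] <- 4L
  write.csv(m2, path, row.names = FALSE)
  expect_error(read_responses(path, comm), "row 2.*PHQ3")

  # non-integer cell
  m3 <- matrix("a", 2, 16, dimnames = list(NULL, names(comm)))
  write.csv(m3, path, row.names = FALSE)
  expect_error(read_responses(path, comm), "PHQ1")
})

test_that("SD screening rule excludes items and is scale invariant", {
  # zero-variance item always fails the rule
  expect_identical(screen_low_informative(c(a = 1, b = 1, c = 1, d = 0)), "d")
  # hand arithmetic: mean SD 0.825, threshold 0.825 / 2.5 = 0.33 > 0.3
  expect_identical(screen_low_informative(c(a = 1, b = 1, c = 1, d = 0.3)), "d")
  expect_identical(screen_low_informative(c(a = 1, b = 1, c = 1, d = 0.34)),
                   character(0))
  expect_error(screen_low_informative(c(1, 1, -0.1)), "non-negative")
  expect_error(screen_low_informative(c(1, 1), factor = -1), "positive")

  # multiplying all SDs by c > 0 never changes the exclusion set
  set.seed(42)
  for (i in 1:20) {
    sds <- stats::setNames(runif(8, 0, 2), letters[1:8])
    cc <- runif(1, 0.01, 50)
    expect_identical(screen_low_informative(sds * cc),
                     screen_low_informative(sds))
  }

  # alternative reading: against the item's own mean
  expect_identical(
    screen_low_informative(c(a = 0.3, b = 0.8), mode = "item_mean",
                           item_means = c(1.0, 1.0)),
    "a")
})

test_that("redundancy screen flags duplicates and respects its gates", {
  set.seed(7)
  v <- matrix(sample(0:3, 200 * 5, replace = TRUE), 200, 5)
  v[, 2] <- v[, 1]  # exact duplicate
  x <- mk_responses(v)
  red <- detect_redundant_pairs(x)
  expect_identical(nrow(red), 1L)
  expect_setequal(c(red$item_a, red$item_b), c("V1", "V2"))
  expect_equal(red$correlation, 1)
  expect_equal(red$prop_significant, 0)

  # mutually independent items never reach the correlation gate
  set.seed(8)
  v2 <- matrix(sample(0:3, 2000 * 16, replace = TRUE), 2000, 16)
  expect_identical(nrow(detect_redundant_pairs(mk_responses(v2))), 0L)

  # a pair below cor_min is never flagged however similar its profile
  set.seed(9)
  z <- rnorm(500)
  v3 <- cbind(V1 = as.integer(cut(z + rnorm(500, 0, 1.2), c(-Inf, -0.5, 0.5, 1.2, Inf))) - 1L,
              V2 = as.integer(cut(z + rnorm(500, 0, 1.2), c(-Inf, -0.5, 0.5, 1.2, Inf))) - 1L,
              V3 = sample(0:3, 500, TRUE))
  x3 <- mk_responses(v3)
  r12 <- cor(v3[, 1], v3[, 2])
  expect_lt(r12, 0.5)
  expect_identical(nrow(detect_redundant_pairs(x3)), 0L)

  # guard rails
  v4 <- v[1:30, ]; v4[, 3] <- 2L
  expect_error(detect_redundant_pairs(mk_responses(v4)), "zero-variance.*V3")
  expect_error(detect_redundant_pairs(mk_responses(v[1:10, ])), "n >= 20")
})

test_that("binarize maps 0 -> 0 and 1,2,3 -> 1 and is idempotent", {
  v <- rbind(c(0, 1, 2, 3), c(3, 0, 1, 2))
  b <- binarize(mk_responses(v))
  expect_identical(unname(b$values), rbind(c(0L, 1L, 1L, 1L), c(1L, 0L, 1L, 1L)))
  expect_identical(binarize(b), b)

  z <- binarize(mk_responses(matrix(0, 4, 3)))
  expect_true(all(z$values == 0))

  # presence proportion equals the nonzero fraction: P(x > 0) = 0.73 design
  set.seed(10)
  v2 <- matrix(sample(0:3, 10000 * 3, TRUE, prob = c(0.27, 0.3, 0.28, 0.15)),
               10000, 3)
  b2 <- binarize(mk_responses(v2))
  expect_true(all(abs(colMeans(b2$values) - 0.73) < 3 * sqrt(0.73 * 0.27 / 10000)))
})

test_that("scale screening applies the cutoff on raw totals", {
  # one respondent per boundary case: total 5 positive, total 4 negative
  v <- rbind(c(1, 1, 1, 1, 1, 0, 0, 0, 0, rep(0, 7)),
             c(1, 1, 1, 1, 0, 0, 0, 0, 0, rep(0, 7)),
             c(0, 0, 0, 0, 0, 0, 0, 0, 0, rep(1, 7)))
  colnames(v) <- names(phq_gad_communities())
  x <- item_responses(v, phq_gad_communities())
  sc <- scale_screen(x, cutoff = 5)
  expect_identical(unname(sc$totals[, "depression"]), c(5, 4, 0))
  expect_identical(unname(sc$positive[, "depression"]), c(TRUE, FALSE, FALSE))
  expect_identical(unname(sc$positive[, "anxiety"]), c(FALSE, FALSE, TRUE))
  expect_equal(unname(sc$prevalence["depression"]), 1 / 3)
})

test_that("cronbach_alpha matches its covariance-matrix formulation", {
  # k identical columns -> alpha exactly 1
  set.seed(11)
  col <- sample(0:3, 50, TRUE)
  x <- mk_responses(matrix(col, 50, 4))
  expect_equal(cronbach_alpha(x, "depression"), 1)

  # two independent items -> alpha near 0
  set.seed(12)
  v <- cbind(sample(0:3, 10000, TRUE), sample(0:3, 10000, TRUE),
             sample(0:3, 10000, TRUE))
  expect_lt(abs(cronbach_alpha(mk_responses(v, n_dep = 2), "depression")), 0.05)

  # hand matrix against the independent covariance identity
  # alpha = k/(k-1) * (1 - tr(C)/sum(C)) with C the item covariance matrix
  v2 <- rbind(c(0, 1, 2), c(1, 1, 3), c(2, 0, 1), c(3, 2, 2))
  x2 <- mk_responses(v2, n_dep = 3)
  C <- cov(v2)
  oracle <- 3 / 2 * (1 - sum(diag(C)) / sum(C))
  expect_equal(cronbach_alpha(x2, "depression"), oracle, tolerance = 1e-12)

  # invariant to adding a constant to one item (stay within 0-3)
  v3 <- v2; v3[, 2] <- v3[, 2] + 1
  expect_equal(cronbach_alpha(mk_responses(v3, n_dep = 3), "depression"),
               cronbach_alpha(x2, "depression"), tolerance = 1e-12)

  expect_error(cronbach_alpha(mk_responses(matrix(2, 5, 3), n_dep = 3),
                              "depression"), "variance")
})

test_that("full screening chain keeps all items on reference-matched data", {
  q <- generate_questionnaire(paperlike_recipe(n = 2000, seed = 31))
  rep <- screen_items(q)
  expect_identical(rep$excluded_low_sd, character(0))
  expect_identical(nrow(rep$redundant_pairs), 0L)
})
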