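# Edge accuracy and centrality stability: non-parametric bootstrap,
# paired difference tests, case-dropping bootstrap, CS coefficient.

#' Non-parametric bootstrap of edge weights
#'
#' Resamples respondents with replacement \code{B} times, re-estimates the
#' network with identical settings on each resample, and records all
#' \eqn{p(p-1)/2} edge weights. Percentile 95% confidence intervals
#' (2.5th/97.5th) are attached per edge, together with pairwise paired
#' difference tests between edges and between node centralities (EI, BEI)
#' computed from the same resamples. A resample with a constant column is
#' re-drawn (and counted); if more than 10% of draws need re-drawing the run
#' aborts, since the data are then too sparse to bootstrap honestly.
#'
#' @param data a [binary_dataset].
#' @param B number of bootstrap samples (default 1000).
#' @param gamma,rule estimation settings, as [estimate_network].
#' @param seed master seed; replicate r uses a deterministic child seed so
#'   results do not depend on execution order.
#' @param max_redraw_rate redraw budget as a fraction of \code{B}.
#' @return object of class \code{bootstrap_result}: \code{edge_estimates}
#'   (B x E matrix, columns named "a--b"), \code{edge_ci} (E x 2),
#'   \code{edge_diff_significant} (E x E logical),
#'   \code{centrality_diff_significant} (list of p x p logicals for
#'   \code{ei} and \code{bei}), \code{n_redrawn}, \code{B}, \code{seed}.
#' @export
bootstrap_edges <- function(data, B = 1000L, gamma = 0.25, rule = "AND",
                            seed = 1L, max_redraw_rate = 0.1) {
  stopifnot(inherits(data, "binary_dataset"), B >= 2L)
  v <- data$values
  n <- nrow(v)
  pairs <- upper_pairs(data$item_ids)
  E <- nrow(pairs)
  edge_names <- paste(pairs$item_a, pairs$item_b, sep = "--")
  seeds <- child_seeds(seed, 2L * B)  # spares for redraws
  est <- matrix(NA_real_, B, E, dimnames = list(NULL, edge_names))
  n_redrawn <- 0L
  next_seed <- B
  for (b in seq_len(B)) {
    s <- seeds[b]
    repeat {
      idx <- local_seed(s, sample.int(n, n, replace = TRUE))
      vb <- v[idx, , drop = FALSE]
      if (!any(colMeans(vb) %in% c(0, 1))) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_redraw_rate * B)
        stop("more than ", round(100 * max_redraw_rate),
             "% of bootstrap resamples had constant columns; ",
             "data too sparse for this bootstrap")
      next_seed <- next_seed + 1L
      s <- seeds[next_seed]
    }
    net_b <- estimate_network(binary_dataset(vb, data$community),
                              gamma = gamma, rule = rule)
    est[b, ] <- net_b$weights[cbind(pairs$i, pairs$j)]
  }
  if (n_redrawn > 0)
    message("bootstrap_edges: re-drew ", n_redrawn, " degenerate resample(s)")
  ci <- t(apply(est, 2, stats::quantile, probs = c(0.025, 0.975), type = 7))
  colnames(ci) <- c("lower", "upper")
  structure(list(
    edge_estimates = est,
    edge_index = pairs,
    edge_ci = ci,
    edge_diff_significant = pairwise_difference_matrix(est),
    centrality_diff_significant = list(
      ei = pairwise_difference_matrix(replicate_centrality(est, pairs,
                                                           data$item_ids,
                                                           cross = NULL)),
      bei = if (!is.null(data$community))
        pairwise_difference_matrix(replicate_centrality(est, pairs,
                                                        data$item_ids,
                                                        cross = data$community))
      else NULL),
    n_redrawn = n_redrawn, B = B, seed = seed,
    gamma = gamma, rule = rule), class = "bootstrap_result")
}

# Per-replicate node centralities reconstructed from bootstrapped edge
# weights: EI (cross = NULL) or BEI (cross = community labels).
replicate_centrality <- function(est, pairs, item_ids, cross = NULL) {
  p <- length(item_ids)
  keep <- if (is.null(cross)) rep(TRUE, nrow(pairs)) else
    cross[pairs$item_a] != cross[pairs$item_b]
  out <- matrix(0, nrow(est), p, dimnames = list(NULL, item_ids))
  for (e in which(keep)) {
    out[, pairs$i[e]] <- out[, pairs$i[e]] + est[, e]
    out[, pairs$j[e]] <- out[, pairs$j[e]] + est[, e]
  }
  out
}

pairwise_difference_matrix <- function(samples, conf = 0.95) {
  k <- ncol(samples)
  m <- matrix(FALSE, k, k, dimnames = list(colnames(samples), colnames(samples)))
  for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k)) {
    m[a, b] <- m[b, a] <- difference_test(samples[, a], samples[, b],
                                          conf = conf)
  }
  m
}

#' Paired bootstrap difference test
#'
#' Two bootstrapped quantities (computed on the same resamples) differ
#' significantly when the percentile \code{conf} interval of their paired
#' differences excludes zero.
#'
#' @param samples_a,samples_b equal-length vectors of paired bootstrap
#'   replicates.
#' @param conf confidence level (default 0.95).
#' @return logical scalar.
#' @export
difference_test <- function(samples_a, samples_b, conf = 0.95) {
  if (length(samples_a) != length(samples_b))
    stop("paired samples must have equal length")
  if (length(samples_a) < 20L)
    stop("need at least 20 bootstrap samples for a meaningful percentile CI")
  d <- samples_a - samples_b
  q <- stats::quantile(d, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE, type = 7)
  q[1] > 0 || q[2] < 0
}

#' Case-dropping bootstrap of a centrality statistic
#'
#' For each drop proportion q in \code{drop_grid}, draws \code{B} subsamples
#' of size \code{round((1-q) n)} without replacement, re-estimates the
#' network on each, and records the product-moment correlation between the
#' subsample statistic vector (EI or BEI) and the full-sample one. A
#' subsample whose network cannot be estimated (constant column) is re-drawn
#' and counted, with the same 10% budget as [bootstrap_edges]. A replicate
#' whose statistic vector is constant (e.g. an empty re-estimated network)
#' has no defined correlation and is recorded as \code{NA}; such replicates
#' count against the stability criterion in [cs_coefficient].
#'
#' @param data a [binary_dataset].
#' @param statistic \code{"EI"} or \code{"BEI"}.
#' @param drop_grid increasing drop proportions in (0, 0.75].
#' @param B subsamples per proportion (default 1000).
#' @param gamma,rule estimation settings.
#' @param seed master seed (deterministic child seeds per replicate).
#' @param max_redraw_rate redraw budget as a fraction of total replicates.
#' @return object of class \code{case_drop_result}: \code{drop_proportions},
#'   \code{correlations} (grid x B matrix), \code{statistic},
#'   \code{full_statistic}, \code{B}, \code{seed}, \code{n_redrawn}.
#' @export
case_dropping_bootstrap <- function(data, statistic = c("EI", "BEI"),
                                    drop_grid = seq(0.05, 0.75, by = 0.05),
                                    B = 1000L, gamma = 0.25, rule = "AND",
                                    seed = 1L, max_redraw_rate = 0.1) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(data, "binary_dataset"), B >= 2L)
  if (any(drop_grid <= 0) || any(drop_grid > 0.75))
    stop("`drop_grid` must lie in (0, 0.75]")
  if (is.unsorted(drop_grid, strictly = TRUE))
    stop("`drop_grid` must be strictly increasing")
  stat_fun <- function(net) switch(statistic,
    EI = expected_influence(net, 1),
    BEI = bridge_expected_influence(net))
  full_net <- estimate_network(data, gamma = gamma, rule = rule)
  full_stat <- stat_fun(full_net)
  if (stats::sd(full_stat) == 0)
    message("full-sample ", statistic, " vector is constant (e.g. an empty ",
            "network); all stability correlations are undefined and the CS ",
            "coefficient will be 0")
  v <- data$values
  n <- nrow(v)
  total <- length(drop_grid) * B
  seeds <- child_seeds(seed, 2L * total)
  corr <- matrix(NA_real_, length(drop_grid), B)
  n_redrawn <- 0L
  next_seed <- total
  for (g in seq_along(drop_grid)) {
    m <- round((1 - drop_grid[g]) * n)
    if (m < 2L) stop("drop proportion ", drop_grid[g], " leaves < 2 cases")
    for (b in seq_len(B)) {
      s <- seeds[(g - 1L) * B + b]
      repeat {
        idx <- local_seed(s, sample.int(n, m, replace = FALSE))
        vb <- v[idx, , drop = FALSE]
        if (!any(colMeans(vb) %in% c(0, 1))) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraw_rate * total)
          stop("more than ", round(100 * max_redraw_rate),
               "% of case-dropping subsamples had constant columns")
        next_seed <- next_seed + 1L
        s <- seeds[next_seed]
      }
      net_b <- estimate_network(binary_dataset(vb, data$community),
                                gamma = gamma, rule = rule)
      sb <- stat_fun(net_b)
      corr[g, b] <- if (stats::sd(sb) == 0 || stats::sd(full_stat) == 0)
        NA_real_ else stats::cor(sb, full_stat)
    }
  }
  if (n_redrawn > 0)
    message("case_dropping_bootstrap: re-drew ", n_redrawn,
            " degenerate subsample(s)")
  structure(list(drop_proportions = drop_grid, correlations = corr,
                 statistic = statistic, full_statistic = full_stat,
                 B = B, seed = seed, n_redrawn = n_redrawn,
                 gamma = gamma, rule = rule),
            class = "case_drop_result")
}

#' Correlation-stability coefficient
#'
#' The CS coefficient is the largest drop proportion q such that, at q and at
#' every smaller proportion in the grid, at least \code{prob} of the
#' case-dropping correlations are >= \code{cor_threshold}; it is 0 when even
#' the smallest proportion fails. Values above 0.5 are conventionally read
#' as good stability, above 0.25 as acceptable. \code{NA} correlations
#' (degenerate replicate statistics) count as failures.
#'
#' @param result a [case_dropping_bootstrap] result.
#' @param cor_threshold correlation criterion (default 0.7).
#' @param prob required fraction of replicates meeting it (default 0.95).
#' @return a single number: 0 or one of the grid proportions.
#' @export
cs_coefficient <- function(result, cor_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(result, "case_drop_result"))
  ok <- apply(result$correlations, 1,
              function(r) mean(!is.na(r) & r >= cor_threshold) >= prob)
  ok <- cumprod(ok) > 0  # every smaller proportion must qualify too
  if (!any(ok)) 0 else max(result$drop_proportions[ok])
}

#' @export
print.bootstrap_result <- function(x, ...) {
  w <- x$edge_ci[, "upper"] - x$edge_ci[, "lower"]
  cat(sprintf("<bootstrap_result> B = %d, %d edges, mean 95%% CI width %.3f (seed %d)\n",
              x$B, nrow(x$edge_ci), mean(w), x$seed))
  invisible(x)
}

#' @export
print.case_drop_result <- function(x, ...) {
  cat(sprintf("<case_drop_result> %s, B = %d, drop grid %.2f-%.2f, CS = %.2f\n",
              x$statistic, x$B, min(x$drop_proportions),
              max(x$drop_proportions), cs_coefficient(x)))
  invisible(x)
}
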