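# Fixture builders and independent oracles shared across test files.
# All networks use balanced thresholds tau = -rowSums(W)/2 so every symptom
# sits near 50% presence, keeping nodewise estimation well conditioned.

two_comm <- function(items, n_dep) {
  stats::setNames(rep(c("depression", "anxiety"),
                      c(n_dep, length(items) - n_dep)), items)
}

balanced_net <- function(W, community = NULL) {
  ising_network(stats::setNames(-rowSums(W) / 2, colnames(W)), W,
                community = community)
}

# 4-node chain V1-V2-V3-V4 with equal weights; strong enough that nodewise
# selection is unambiguous at n = 200.
mk_chain4 <- function(w = 2) {
  items <- paste0("V", 1:4)
  W <- matrix(0, 4, 4, dimnames = list(items, items))
  W[1, 2] <- W[2, 3] <- W[3, 4] <- w
  W <- W + t(W)
  balanced_net(W, two_comm(items, 2))
}

# 5-node ring network with heterogeneous, solidly detectable weights, for
# bootstrap tests (weights below ~0.8 leave percentile CIs visibly biased by
# l1 shrinkage at the sample sizes used here).
mk_net5 <- function() {
  items <- paste0("V", 1:5)
  W <- matrix(0, 5, 5, dimnames = list(items, items))
  W[1, 2] <- 0.9; W[2, 3] <- 1.0; W[3, 4] <- 0.8; W[4, 5] <- 1.1
  W[1, 5] <- 0.85
  W <- W + t(W)
  balanced_net(W, two_comm(items, 3))
}

# Strongly determined 10-node two-community network: dense, strong positive
# couplings, balanced margins. Subsamples reproduce its centrality ordering.
mk_strong10 <- function(seed = 3) {
  gt <- make_true_network(6, 4, within_density = 0.5, cross_density = 0.25,
                          weight_range = c(0.8, 1.2), seed = seed)
  balanced_net(gt$network$weights, gt$network$community)
}

# 10-node two-community network with exactly 12 positive edges in
# [0.5, 1.5]: the parameter-recovery ground truth.
mk_recovery_net <- function(seed) {
  items <- c(paste0("D", 1:5), paste0("A", 1:5))
  idx <- which(upper.tri(matrix(0, 10, 10)), arr.ind = TRUE)
  W <- matrix(0, 10, 10, dimnames = list(items, items))
  set.seed(seed)
  sel <- sample(nrow(idx), 12)
  W[idx[sel, , drop = FALSE]] <- stats::runif(12, 0.5, 1.5)
  W <- W + t(W)
  balanced_net(W, two_comm(items, 5))
}

# Random symmetric weight matrix (possibly negative weights) for
# centrality oracles.
rand_weights <- function(p, seed, density = 0.6) {
  set.seed(seed)
  items <- paste0("V", seq_len(p))
  W <- matrix(0, p, p, dimnames = list(items, items))
  up <- which(upper.tri(W))
  on <- stats::runif(length(up)) < density
  W[up[on]] <- stats::runif(sum(on), -1, 1)
  W + t(W)
}

# Exhaustive best-subset logistic EBIC selection: the brute-force oracle
# for nodewise model selection (all 2^k predictor subsets).
best_subset_ebic <- function(y, X, gamma = 0.25) {
  pc <- ncol(X)
  best <- NULL; best_e <- Inf; best_k <- Inf
  for (m in 0:(2^pc - 1)) {
    S <- which(bitwAnd(m, 2^(0:(pc - 1))) > 0)
    f <- if (length(S))
      suppressWarnings(stats::glm.fit(cbind(1, X[, S, drop = FALSE]), y,
                                      family = stats::binomial()))
    else stats::glm.fit(matrix(1, length(y)), y, family = stats::binomial())
    ll <- sum(y * log(f$fitted.values) + (1 - y) * log(1 - f$fitted.values))
    e <- ebic(ll, length(S), length(y), pc, gamma)
    if (e < best_e - 1e-10 || (e < best_e + 1e-10 && length(S) < best_k)) {
      best <- S; best_e <- e; best_k <- length(S)
    }
  }
  best
}

# Ordinal test matrix with every item passing validation.
mk_responses <- function(vals, n_dep = NULL) {
  vals <- as.matrix(vals)
  if (is.null(colnames(vals)))
    colnames(vals) <- paste0("V", seq_len(ncol(vals)))
  n_dep <- n_dep %||% ceiling(ncol(vals) / 2)
  item_responses(vals, two_comm(colnames(vals), n_dep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
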