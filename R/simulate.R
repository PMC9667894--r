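# Synthetic-data generation: exact enumeration and sampling of Ising
# networks, a Gibbs sampler for larger graphs, random two-community ground
# truths, and a parameter-recovery harness.

#' Enumerate the exact Ising distribution
#'
#' Computes \eqn{P(x) \propto \exp(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j)}
#' over all \eqn{2^p} binary states, normalized with log-sum-exp for
#' stability. Exact oracle for the samplers and estimators; refuses p > 20
#' (use the Gibbs sampler there).
#'
#' @param net an [ising_network] with p <= 20 nodes.
#' @return list with \code{states} (2^p x p 0/1 matrix), \code{log_prob} and
#'   \code{prob}.
#' @export
enumerate_ising <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  p <- length(net$item_ids)
  if (p > 20L)
    stop("enumeration is limited to p <= 20; use sample_ising(method = 'gibbs')")
  states <- as.matrix(expand.grid(rep(list(0:1), p), KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- net$item_ids
  # sum_{i<j} w_ij x_i x_j = x' W x / 2 for symmetric zero-diagonal W
  logw <- drop(states %*% net$thresholds) +
    rowSums((states %*% net$weights) * states) / 2
  logz <- logsumexp(logw)
  list(states = states, log_prob = logw - logz, prob = exp(logw - logz))
}

#' Sample binary data from an Ising network
#'
#' \code{method = "exact"} draws i.i.d. states from the enumerated
#' distribution (p <= 20). \code{method = "gibbs"} runs one Markov chain per
#' requested draw, updated site by site with the conditional
#' \eqn{P(x_i = 1 \mid x_{-i}) = \mathrm{logistic}(\tau_i + \sum_j w_{ij} x_j)};
#' every chain is burned in for \code{burnin} full sweeps and its state is
#' recorded after \code{thin} further sweeps, so draws are independent
#' across rows. All chains update in lockstep (vectorized across rows).
#'
#' @param net an [ising_network].
#' @param n number of draws.
#' @param method \code{"exact"} (default for p <= 20) or \code{"gibbs"}.
#' @param seed RNG seed.
#' @param burnin,thin Gibbs controls (full sweeps).
#' @return a [binary_dataset] with the network's items and communities.
#' @export
sample_ising <- function(net, n, method = c("exact", "gibbs"), seed = NULL,
                         burnin = 1000L, thin = 10L) {
  method <- match.arg(method)
  stopifnot(inherits(net, "ising_network"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer")
  p <- length(net$item_ids)
  vals <- local_seed(seed, {
    if (method == "exact") {
      enum <- enumerate_ising(net)
      idx <- sample.int(nrow(enum$states), n, replace = TRUE,
                        prob = enum$prob)
      enum$states[idx, , drop = FALSE]
    } else {
      X <- matrix(sample(0:1, n * p, replace = TRUE), n, p)
      for (sweep in seq_len(burnin + thin)) {
        for (i in seq_len(p)) {
          pr <- stats::plogis(net$thresholds[i] + X %*% net$weights[, i])
          X[, i] <- as.integer(stats::runif(n) < pr)
        }
      }
      colnames(X) <- net$item_ids
      X
    }
  })
  rownames(vals) <- NULL
  binary_dataset(vals, community = net$community)
}

#' Generate a random two-community ground-truth network
#'
#' Draws a sparse Ising network over two symptom communities
#' ("depression", items D1..Dp; "anxiety", items A1..Aq): each within- or
#' cross-community pair receives an edge independently at the corresponding
#' density, edge weights are uniform on \code{weight_range} (positive by
#' default, the typical sign structure of symptom networks) and thresholds
#' uniform on \code{tau_range} (negative, so symptoms are present in a
#' minority-to-majority of cases). Fully determined by \code{seed}.
#'
#' @param p_dep,p_anx community sizes (defaults 9 and 7, the PHQ-9/GAD-7
#'   layout).
#' @param within_density,cross_density edge probabilities within and across
#'   communities.
#' @param weight_range,tau_range uniform ranges for weights and thresholds.
#' @param seed RNG seed.
#' @return list of class \code{ground_truth}: \code{network}
#'   (an [ising_network]) and \code{recipe}.
#' @export
make_true_network <- function(p_dep = 9L, p_anx = 7L,
                              within_density = 0.5, cross_density = 0.3,
                              weight_range = c(0.2, 1.0),
                              tau_range = c(-2, 0), seed = NULL) {
  if (any(c(within_density, cross_density) < 0) ||
      any(c(within_density, cross_density) > 1))
    stop("densities must lie in [0, 1]")
  if (weight_range[1] > weight_range[2]) stop("invalid `weight_range`")
  items <- c(if (p_dep > 0) paste0("D", seq_len(p_dep)),
             if (p_anx > 0) paste0("A", seq_len(p_anx)))
  community <- stats::setNames(rep(c("depression", "anxiety"),
                                   c(p_dep, p_anx)), items)
  p <- p_dep + p_anx
  pairs <- upper_pairs(items)
  cross <- community[pairs$item_a] != community[pairs$item_b]
  dens <- ifelse(cross, cross_density, within_density)
  net <- local_seed(seed, {
    present <- stats::runif(nrow(pairs)) < dens
    w <- ifelse(present,
                stats::runif(nrow(pairs), weight_range[1], weight_range[2]),
                0)
    W <- matrix(0, p, p, dimnames = list(items, items))
    W[cbind(pairs$i, pairs$j)] <- w
    W <- W + t(W)
    tau <- stats::setNames(stats::runif(p, tau_range[1], tau_range[2]), items)
    ising_network(tau, W, community = community)
  })
  structure(list(network = net,
                 recipe = list(p_dep = p_dep, p_anx = p_anx,
                               within_density = within_density,
                               cross_density = cross_density,
                               weight_range = weight_range,
                               tau_range = tau_range, seed = seed)),
            class = "ground_truth")
}

#' Recipe for a latent-Gaussian ordinal questionnaire generator
#'
#' @param latent_correlation p x p positive-definite correlation matrix of
#'   the latent normal.
#' @param thresholds p x 3 matrix of strictly increasing cut-points (latent
#'   SD units); crossing cut-point k moves the response to category k.
#' @param community named community labels for the p items (names give the
#'   item ids and order).
#' @param n number of respondents.
#' @param seed RNG seed.
#' @return list of class \code{ordinal_recipe}.
#' @export
ordinal_recipe <- function(latent_correlation, thresholds, community, n,
                           seed = NULL) {
  p <- length(community)
  latent_correlation <- as.matrix(latent_correlation)
  thresholds <- as.matrix(thresholds)
  if (!all(dim(latent_correlation) == p))
    stop("`latent_correlation` must be p x p")
  if (max(abs(latent_correlation - t(latent_correlation))) > 1e-12 ||
      any(abs(diag(latent_correlation) - 1) > 1e-12))
    stop("`latent_correlation` must be symmetric with unit diagonal")
  if (!all(dim(thresholds) == c(p, 3L)))
    stop("`thresholds` must be p x 3")
  if (any(thresholds[, 1] >= thresholds[, 2]) ||
      any(thresholds[, 2] >= thresholds[, 3]))
    stop("cut-points must be strictly increasing per item")
  structure(list(latent_correlation = latent_correlation,
                 thresholds = thresholds, community = community,
                 n = n, seed = seed),
            class = "ordinal_recipe")
}

#' Generate ordinal questionnaire responses from a recipe
#'
#' Draws a latent multivariate normal with the recipe's correlation and
#' discretizes each coordinate by its three cut-points into \{0,1,2,3\}, so
#' the marginal category probabilities are the normal orthant probabilities
#' of the cut-points. With high first cut-points (most mass below) this
#' reproduces the positively skewed item distributions typical of symptom
#' questionnaires.
#'
#' @param recipe an [ordinal_recipe].
#' @return an [item_responses] object.
#' @export
generate_questionnaire <- function(recipe) {
  stopifnot(inherits(recipe, "ordinal_recipe"))
  p <- length(recipe$community)
  L <- tryCatch(chol(recipe$latent_correlation),
                error = function(e) stop("latent correlation matrix is not positive definite"))
  vals <- local_seed(recipe$seed, {
    Z <- matrix(stats::rnorm(recipe$n * p), recipe$n, p) %*% L
    X <- (Z > matrix(recipe$thresholds[, 1], recipe$n, p, byrow = TRUE)) +
         (Z > matrix(recipe$thresholds[, 2], recipe$n, p, byrow = TRUE)) +
         (Z > matrix(recipe$thresholds[, 3], recipe$n, p, byrow = TRUE))
    colnames(X) <- names(recipe$community)
    X
  })
  item_responses(vals, recipe$community)
}

#' Parameter-recovery report
#'
#' Compares an estimated network against the generating ground truth:
#' sensitivity (recovered true edges / true edges), specificity (correctly
#' absent / truly absent), product-moment correlation between true and
#' estimated weights over the true-edge positions, and sign accuracy over
#' the recovered edges.
#'
#' @param truth a \code{ground_truth} or [ising_network].
#' @param estimate an [ising_network] over the same items.
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{weight_correlation}, \code{sign_accuracy}, \code{n_true_edges},
#'   \code{n_estimated_edges}.
#' @export
recovery_report <- function(truth, estimate) {
  if (inherits(truth, "ground_truth")) truth <- truth$network
  stopifnot(inherits(truth, "ising_network"),
            inherits(estimate, "ising_network"))
  if (!setequal(truth$item_ids, estimate$item_ids))
    stop("truth and estimate must share the same items")
  pairs <- upper_pairs(truth$item_ids)
  wt <- truth$weights[cbind(pairs$i, pairs$j)]
  we <- estimate$weights[truth$item_ids, truth$item_ids][cbind(pairs$i, pairs$j)]
  true_e <- wt != 0
  est_e <- we != 0
  sens <- if (any(true_e)) mean(est_e[true_e]) else NA_real_
  spec <- if (any(!true_e)) mean(!est_e[!true_e]) else NA_real_
  wcor <- if (sum(true_e) >= 2L) {
    if (stats::sd(wt[true_e]) == 0 || stats::sd(we[true_e]) == 0) {
      if (max(abs(wt[true_e] - we[true_e])) < 1e-12) 1 else NA_real_
    } else stats::cor(wt[true_e], we[true_e])
  } else NA_real_
  both <- true_e & est_e
  sign_acc <- if (any(both)) mean(sign(wt[both]) == sign(we[both])) else NA_real_
  list(sensitivity = sens, specificity = spec, weight_correlation = wcor,
       sign_accuracy = sign_acc, n_true_edges = sum(true_e),
       n_estimated_edges = sum(est_e))
}
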