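# Ising network estimation: eLasso (nodewise l1-penalized logistic
# regression with extended-BIC selection, rule-based symmetrization).

#' Regularization path for one nodewise logistic regression
#'
#' Fits the l1-penalized logistic regression of one binary item on the
#' remaining items over a decreasing lambda grid:
#' \deqn{\max_\beta \; \ell(\beta_0, \beta) - \lambda \|\beta\|_1}
#' with an unpenalized intercept, where \eqn{\ell} is the Bernoulli
#' log-likelihood scaled by 1/n. Solved by coordinate descent via
#' \pkg{glmnet} (convergence threshold \code{thresh}); predictors are left
#' on their common \{0,1\} scale, not standardized.
#'
#' The default grid has 100 log-spaced values from \eqn{\lambda_{max}}
#' (the null-model stationarity bound
#' \eqn{\max_j |\sum_i x_{ij}(y_i - \bar y)| / n}, above which all slopes are
#' zero) down to \eqn{0.01\,\lambda_{max}}; the unpenalized endpoint is never
#' included, which keeps estimates finite under quasi-separation.
#'
#' @param y binary response vector (both classes must be present).
#' @param X n x (p-1) binary predictor matrix with column names; no column
#'   may be constant.
#' @param lambda optional decreasing lambda grid; computed from the data when
#'   \code{NULL}.
#' @param nlambda,lambda_min_ratio grid size and lower endpoint ratio used
#'   when \code{lambda} is \code{NULL}.
#' @param thresh coordinate-descent convergence threshold (default 1e-7,
#'   the solver's own default;
#'   tighten when comparing against unpenalized ML fits).
#' @param node optional node label used in error messages.
#' @return An object of class \code{nodewise_fit}: \code{lambda},
#'   \code{intercepts}, \code{coefficients} ((p-1) x L matrix),
#'   \code{loglik} (unpenalized log-likelihood at each solution), \code{df},
#'   \code{n}, \code{p_candidates}.
#' @export
fit_penalized_logistic_path <- function(y, X, lambda = NULL, nlambda = 100L,
                                        lambda_min_ratio = 0.01,
                                        thresh = 1e-7, node = "response") {
  X <- as.matrix(X)
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("`y` must be binary 0/1")
  if (any(is.na(X)) || !all(X %in% c(0, 1)))
    stop("predictors must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("node '", node, "' has a single response class; cannot estimate")
  cmeans <- colMeans(X)
  if (any(cmeans %in% c(0, 1)))
    stop("constant predictor column(s): ",
         paste(colnames(X)[cmeans %in% c(0, 1)], collapse = ", "))
  n <- nrow(X)
  if (is.null(lambda)) {
    lmax <- max(abs(crossprod(X, y - mean(y)))) / n
    lmax <- max(lmax, 1e-6)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  if (is.unsorted(rev(lambda), strictly = TRUE))
    stop("`lambda` must be strictly decreasing")
  fit <- glmnet::glmnet(X, y, family = "binomial", lambda = lambda,
                        standardize = FALSE, thresh = thresh, maxit = 1e6)
  beta <- as.matrix(fit$beta)
  a0 <- fit$a0
  # Bernoulli deviance = -2 * loglik (saturated loglik is 0), so the
  # unpenalized log-likelihood at each solution comes with the fit
  loglik <- -(1 - fit$dev.ratio) * fit$nulldev / 2
  structure(list(node = node, lambda = fit$lambda, intercepts = unname(a0),
                 coefficients = beta, loglik = unname(loglik),
                 df = unname(colSums(beta != 0)), n = n,
                 p_candidates = ncol(X)),
            class = "nodewise_fit")
}

#' Extended Bayesian information criterion
#'
#' \deqn{EBIC = -2\ell + k \ln n + 2\gamma k \ln p}
#' where \eqn{\ell} is the (unpenalized) log-likelihood of the fitted model,
#' \eqn{k} the number of selected predictors, \eqn{n} the sample size and
#' \eqn{p} the number of candidate predictors. \code{gamma = 0} reduces to
#' the ordinary BIC; larger \code{gamma} penalizes dense models harder.
#'
#' @param loglik log-likelihood value(s).
#' @param k number of nonzero coefficients (vectorized with \code{loglik}).
#' @param n sample size.
#' @param p_candidates number of candidate predictors.
#' @param gamma extra-sparsity weight, >= 0.
#' @return numeric EBIC value(s).
#' @export
ebic <- function(loglik, k, n, p_candidates, gamma) {
  if (any(gamma < 0)) stop("`gamma` must be non-negative")
  if (n < 1 || p_candidates < 1) stop("`n` and `p_candidates` must be positive")
  if (any(k < 0) || any(k > p_candidates))
    stop("`k` must lie in [0, p_candidates]")
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p_candidates)
}

#' EBIC model selection along a nodewise path
#'
#' Adds EBIC values to a [fit_penalized_logistic_path] result and marks the
#' selected lambda. Ties are broken toward the sparser model (the largest
#' lambda among the minimizers).
#'
#' @param fit a \code{nodewise_fit}.
#' @param gamma EBIC gamma.
#' @return The fit with elements \code{ebic}, \code{gamma} and
#'   \code{selected_index} added.
#' @export
select_ebic <- function(fit, gamma = 0.25) {
  stopifnot(inherits(fit, "nodewise_fit"))
  fit$ebic <- ebic(fit$loglik, fit$df, fit$n, fit$p_candidates, gamma)
  fit$gamma <- gamma
  fit$selected_index <- which(fit$ebic <= min(fit$ebic) + 1e-10)[1L]
  fit
}

#' Estimate an Ising network from binary data (eLasso)
#'
#' Runs an EBIC-selected l1-penalized logistic regression of every item on
#' all others, then symmetrizes: under the \code{"AND"} rule an edge i--j is
#' retained only when each node's selected model includes the other; under
#' \code{"OR"} when either does. The retained weight is the mean of the two
#' directed coefficients (a coefficient absent from one selected model
#' counts as zero under \code{"OR"}). Node thresholds are the selected
#' intercepts. Row order of the input is irrelevant.
#'
#' @param data a [binary_dataset] (or 0/1 matrix with column names); every
#'   column must contain both 0s and 1s.
#' @param gamma EBIC gamma (default 0.25, favouring sparsity over the plain
#'   BIC).
#' @param rule edge retention rule, \code{"AND"} (default) or \code{"OR"}.
#' @param nlambda,lambda_min_ratio lambda grid controls, per node.
#' @return An [ising_network] with estimation provenance in \code{gamma} and
#'   \code{rule}; per-node fits attached as attribute \code{"fits"}.
#' @export
estimate_network <- function(data, gamma = 0.25, rule = c("AND", "OR"),
                             nlambda = 100L, lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  if (is.matrix(data)) data <- binary_dataset(data)
  stopifnot(inherits(data, "binary_dataset"))
  v <- data$values
  p <- ncol(v)
  if (p < 3L) stop("network estimation needs at least 3 items")
  cm <- colMeans(v)
  if (any(cm %in% c(0, 1)))
    stop("constant column(s), cannot estimate: ",
         paste(data$item_ids[cm %in% c(0, 1)], collapse = ", "))
  directed <- matrix(0, p, p, dimnames = list(data$item_ids, data$item_ids))
  thresholds <- numeric(p)
  fits <- vector("list", p)
  for (i in seq_len(p)) {
    fit <- fit_penalized_logistic_path(v[, i], v[, -i, drop = FALSE],
                                       nlambda = nlambda,
                                       lambda_min_ratio = lambda_min_ratio,
                                       node = data$item_ids[i])
    fit <- select_ebic(fit, gamma = gamma)
    s <- fit$selected_index
    directed[i, -i] <- fit$coefficients[, s]
    thresholds[i] <- fit$intercepts[s]
    fits[[i]] <- fit
  }
  present <- directed != 0
  adj <- if (rule == "AND") present & t(present) else present | t(present)
  weights <- (directed + t(directed)) / 2 * adj
  net <- ising_network(stats::setNames(thresholds, data$item_ids), weights,
                       community = data$community, gamma = gamma, rule = rule)
  attr(net, "fits") <- fits
  net
}

#' Summarize an Ising network
#'
#' Edge count, density, mean weight over the nonzero edges, and a ranking of
#' edges by absolute weight (ties broken lexicographically by item pair).
#' An empty network reports \code{mean_weight = 0} with \code{empty = TRUE}.
#'
#' @param net an [ising_network].
#' @return list with \code{n_nodes}, \code{n_edges}, \code{n_possible},
#'   \code{density}, \code{mean_weight}, \code{empty},
#'   \code{strongest_edges} (data.frame item_a, item_b, weight).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  pairs <- upper_pairs(net$item_ids)
  w <- net$weights[cbind(pairs$i, pairs$j)]
  nz <- w != 0
  n_possible <- nrow(pairs)
  edges <- pairs[nz, c("item_a", "item_b"), drop = FALSE]
  edges$weight <- w[nz]
  ord <- order(-abs(edges$weight), edges$item_a, edges$item_b)
  list(n_nodes = length(net$item_ids),
       n_edges = sum(nz),
       n_possible = n_possible,
       density = sum(nz) / n_possible,
       mean_weight = if (any(nz)) mean(w[nz]) else 0,
       empty = !any(nz),
       strongest_edges = edges[ord, , drop = FALSE])
}
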