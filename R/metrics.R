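# Node-level importance: expected influence, bridge expected influence,
# percentile-based bridge selection, predictability.

#' Expected influence centrality
#'
#' One-step expected influence is the signed sum of a node's edge weights,
#' \eqn{EI_1(i) = \sum_j w_{ij}}; the two-step variant additionally
#' propagates through the neighbours' own influence,
#' \eqn{EI_2(i) = EI_1(i) + \sum_j w_{ij} EI_1(j)}. Unlike strength
#' centrality, negative edges subtract, so EI ranks how strongly activating
#' a node is for the rest of the network.
#'
#' @param net an [ising_network].
#' @param step 1 (default) or 2.
#' @return named numeric vector in item order.
#' @export
expected_influence <- function(net, step = 1) {
  stopifnot(inherits(net, "ising_network"), step %in% c(1, 2))
  ei1 <- rowSums(net$weights)
  if (step == 1) return(ei1)
  ei1 + drop(net$weights %*% ei1)
}

#' Bridge expected influence centrality
#'
#' Signed sum of a node's edges that cross to a different community:
#' \eqn{BEI_1(i) = \sum_{j: c(j) \neq c(i)} w_{ij}}. High-BEI nodes are
#' candidate bridge symptoms connecting the disorders. Within-community
#' edges are ignored for the sum but the network is otherwise untouched.
#'
#' @param net an [ising_network].
#' @param communities optional named community labels; defaults to the
#'   network's own. Every node must be labelled and at least two communities
#'   must be present.
#' @return named numeric vector in item order.
#' @export
bridge_expected_influence <- function(net, communities = NULL) {
  stopifnot(inherits(net, "ising_network"))
  communities <- communities %||% net$community
  if (is.null(communities)) stop("community labels are required")
  if (!all(net$item_ids %in% names(communities)))
    stop("unlabelled node(s): ",
         paste(setdiff(net$item_ids, names(communities)), collapse = ", "))
  cm <- communities[net$item_ids]
  if (length(unique(cm)) < 2L) stop("need at least two communities")
  cross <- outer(cm, cm, "!=")
  rowSums(net$weights * cross)
}

#' Select bridge symptoms by BEI percentile
#'
#' Flags nodes whose BEI is strictly greater than the empirical
#' \code{percentile}-th percentile of all BEI values
#' (linear-interpolation quantile); values tied with the threshold are not
#' flagged, so a constant BEI vector flags nothing.
#'
#' @param bei named numeric vector of bridge expected influence values.
#' @param percentile percentile threshold, default 80.
#' @return character vector of flagged item ids.
#' @export
select_bridge_symptoms <- function(bei, percentile = 80) {
  if (length(bei) < 2L) stop("need at least 2 nodes")
  thr <- stats::quantile(bei, percentile / 100, names = FALSE, type = 7)
  ids <- names(bei) %||% as.character(seq_along(bei))
  ids[bei > thr]
}

#' Node predictability
#'
#' How well each symptom is predicted by its network neighbours. For node i
#' an (unpenalized) logistic regression of the item on its neighbours in
#' \code{net} is fitted; with in-sample correct classification rate CC at
#' probability threshold 0.5 and majority-class rate CC0, the default metric
#' is the normalized correct classification
#' \deqn{nCC = (CC - CC0) / (1 - CC0),}
#' which is 0 when the neighbours add nothing over the marginal and 1 for
#' perfect classification. Isolated nodes have nCC = 0 by definition.
#' \code{type = "CC"} returns the raw accuracy instead.
#'
#' @param data the [binary_dataset] the network was estimated from.
#' @param net an [ising_network] over the same items.
#' @param type \code{"nCC"} (default) or \code{"CC"} (raw accuracy).
#' @return named numeric vector in item order.
#' @export
predictability <- function(data, net, type = c("nCC", "CC")) {
  type <- match.arg(type)
  stopifnot(inherits(data, "binary_dataset"), inherits(net, "ising_network"))
  if (!identical(data$item_ids, net$item_ids))
    stop("data and network must share the same items in the same order")
  v <- data$values
  out <- numeric(ncol(v))
  names(out) <- net$item_ids
  for (i in seq_along(out)) {
    y <- v[, i]
    cc0 <- max(mean(y), 1 - mean(y))
    if (cc0 == 1)
      stop("item '", net$item_ids[i], "' is constant; predictability undefined")
    nb <- which(net$weights[i, ] != 0)
    if (length(nb) == 0L) {
      cc <- cc0
    } else {
      Xn <- v[, nb, drop = FALSE]
      # saturation (e.g. a copy neighbour) triggers harmless separation
      # warnings from glm; intended behaviour here
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, Xn), y, family = stats::binomial()))
      cc <- mean((fit$fitted.values > 0.5) == y)
    }
    out[i] <- if (type == "CC") cc else (cc - cc0) / (1 - cc0)
  }
  out
}

#' Assemble the centrality table
#'
#' One row per node: expected influence (1- and 2-step), bridge expected
#' influence, predictability, the bridge flag from the percentile rule, and
#' z-scored EI/BEI columns for plotting. Rows are in item order; the
#' \code{ei_rank} column gives the descending-EI rank (central symptoms
#' first).
#'
#' @param net an [ising_network] with community labels.
#' @param data optional [binary_dataset] for predictability (NA otherwise).
#' @param bridge_percentile percentile for [select_bridge_symptoms].
#' @return data.frame of class \code{centrality_table}.
#' @export
summarize_centrality <- function(net, data = NULL, bridge_percentile = 80) {
  stopifnot(inherits(net, "ising_network"))
  ei1 <- expected_influence(net, 1)
  ei2 <- expected_influence(net, 2)
  bei1 <- bridge_expected_influence(net)
  bridges <- select_bridge_symptoms(bei1, bridge_percentile)
  pred <- if (!is.null(data)) predictability(data, net) else
    stats::setNames(rep(NA_real_, length(ei1)), names(ei1))
  zs <- function(x) if (stats::sd(x) == 0) x * 0 else as.numeric(scale(x))
  out <- data.frame(item = net$item_ids,
                    community = unname(net$community[net$item_ids]),
                    ei1 = unname(ei1), ei2 = unname(ei2), bei1 = unname(bei1),
                    predictability = unname(pred),
                    is_bridge = net$item_ids %in% bridges,
                    ei1_z = zs(unname(ei1)), bei1_z = zs(unname(bei1)),
                    ei_rank = rank(-ei1, ties.method = "first"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}
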