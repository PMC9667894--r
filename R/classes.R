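#' Construct an item-response matrix
#'
#' Container for ordinal questionnaire responses: an n x p matrix of integer
#' Likert frequency ratings in 0--3 (0 = not at all ... 3 = almost every day),
#' with an a-priori community label per item (e.g. \code{"depression"} for
#' PHQ-9 items, \code{"anxiety"} for GAD-7 items). Responses must be complete;
#' missing cells are rejected rather than imputed.
#'
#' @param values integer matrix, respondents in rows, items in columns. Column
#'   names must match \code{names(community)}; columns are reordered to the
#'   order declared in \code{community}.
#' @param community named character vector mapping each item id to its
#'   community label.
#' @param respondent_ids optional character vector of row ids.
#' @return An object of class \code{item_responses} with elements
#'   \code{values}, \code{item_ids}, \code{community}, \code{respondent_ids}.
#' @export
item_responses <- function(values, community, respondent_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(names(community)) || anyDuplicated(names(community)))
    stop("`community` must be a named vector with unique item ids")
  item_ids <- names(community)
  if (length(item_ids) < 3L) stop("at least 3 items are required")
  if (is.null(colnames(values)))
    stop("`values` must have column names matching the item ids")
  missing_items <- setdiff(item_ids, colnames(values))
  if (length(missing_items))
    stop("missing item column(s): ", paste(missing_items, collapse = ", "))
  values <- values[, item_ids, drop = FALSE]
  if (nrow(values) < 1L) stop("at least one respondent is required")
  check_cells_ordinal(values)
  if (is.null(respondent_ids)) respondent_ids <- as.character(seq_len(nrow(values)))
  storage.mode(values) <- "integer"
  rownames(values) <- respondent_ids
  structure(
    list(values = values, item_ids = item_ids,
         community = community[item_ids], respondent_ids = respondent_ids),
    class = "item_responses")
}

check_cells_ordinal <- function(values) {
  bad <- which(is.na(values) | values != round(values) | values < 0 | values > 3,
               arr.ind = TRUE)
  if (nrow(bad)) {
    r <- bad[1L, 1L]; c <- bad[1L, 2L]
    stop(sprintf(
      "invalid response at row %d, item '%s': %s (must be an integer in 0-3)",
      r, colnames(values)[c], format(values[r, c])))
  }
  invisible(TRUE)
}

#' @export
print.item_responses <- function(x, ...) {
  cat(sprintf("<item_responses> %d respondents x %d items (%s)\n",
              nrow(x$values), length(x$item_ids),
              paste(sprintf("%s: %d", names(table(x$community)),
                            as.integer(table(x$community))), collapse = ", ")))
  invisible(x)
}

#' Construct a binary presence/absence dataset
#'
#' @param values matrix in \{0,1\} with item column names.
#' @param community named character vector of community labels (same ids).
#' @return An object of class \code{binary_dataset}.
#' @export
binary_dataset <- function(values, community = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("`values` must have item column names")
  if (any(is.na(values)) || !all(values %in% c(0, 1)))
    stop("binary dataset cells must all be 0 or 1")
  if (!is.null(community)) {
    missing_items <- setdiff(colnames(values), names(community))
    if (length(missing_items))
      stop("no community label for: ", paste(missing_items, collapse = ", "))
    community <- community[colnames(values)]
  }
  storage.mode(values) <- "integer"
  structure(list(values = values, item_ids = colnames(values),
                 community = community),
            class = "binary_dataset")
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf("<binary_dataset> %d respondents x %d items; presence %.2f-%.2f\n",
              nrow(x$values), ncol(x$values),
              min(colMeans(x$values)), max(colMeans(x$values))))
  invisible(x)
}

#' Construct an Ising network
#'
#' A pairwise Markov random field over binary symptom indicators:
#' \deqn{P(x) \propto \exp(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j)}
#' with node thresholds \eqn{\tau_i} (log-odds units) and a symmetric,
#' zero-diagonal weight matrix \eqn{w}.
#'
#' @param thresholds numeric vector of node thresholds, named by item id.
#' @param weights symmetric p x p numeric matrix with zero diagonal.
#' @param community optional named character vector of community labels.
#' @param gamma,rule optional estimation provenance (EBIC gamma, edge rule).
#' @return An object of class \code{ising_network}.
#' @export
ising_network <- function(thresholds, weights, community = NULL,
                          gamma = NULL, rule = NULL) {
  weights <- as.matrix(weights)
  p <- length(thresholds)
  item_ids <- names(thresholds) %||% colnames(weights)
  if (is.null(item_ids)) stop("item ids required (name `thresholds` or `weights`)")
  if (!all(dim(weights) == p)) stop("`weights` must be p x p")
  if (!all(is.finite(thresholds)) || !all(is.finite(weights)))
    stop("network parameters must be finite")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 0)) &&
      max(abs(weights - t(weights))) > 0)
    stop("`weights` must be exactly symmetric")
  if (any(diag(weights) != 0)) stop("`weights` diagonal must be exactly zero")
  names(thresholds) <- item_ids
  dimnames(weights) <- list(item_ids, item_ids)
  if (!is.null(community)) {
    if (!all(item_ids %in% names(community)))
      stop("every item needs a community label")
    community <- community[item_ids]
  }
  structure(list(thresholds = thresholds, weights = weights,
                 item_ids = item_ids, community = community,
                 gamma = gamma, rule = rule),
            class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("<ising_network> %d nodes, %d edges (density %.3f, mean weight %.3f)\n",
              length(x$item_ids), s$n_edges, s$density, s$mean_weight))
  invisible(x)
}
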