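#' Read ordinal questionnaire responses from CSV
#'
#' Reads a respondent-by-item CSV (header row, one respondent per row) and
#' validates it against the declared item set. Every declared item must be
#' present as a column and every cell must be an integer in 0--3; anything
#' else is an error naming the offending column or cell.
#'
#' @param path path to a CSV file with a header row.
#' @param community named character vector mapping item ids to community
#'   labels; also fixes the item order of the result.
#' @return An [item_responses] object.
#' @export
read_responses <- function(path, community) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing_items <- setdiff(names(community), names(df))
  if (length(missing_items))
    stop("input is missing item column(s): ",
         paste(missing_items, collapse = ", "))
  vals <- as.matrix(df[, names(community), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- names(which(!vapply(df[, names(community), drop = FALSE],
                               is.numeric, logical(1))))
    stop("non-numeric values in column(s): ", paste(bad, collapse = ", "))
  }
  item_responses(vals, community)
}

#' Per-item descriptive statistics
#'
#' Means and standard deviations (sample convention) of the raw 0--3 item
#' scores, the inputs to the low-informativeness screen.
#'
#' @param x an [item_responses] object.
#' @return data.frame with columns \code{item}, \code{community},
#'   \code{mean}, \code{sd}, \code{presence} (proportion of nonzero
#'   responses).
#' @export
item_descriptives <- function(x) {
  stopifnot(inherits(x, "item_responses"))
  v <- x$values
  data.frame(item = x$item_ids,
             community = unname(x$community),
             mean = colMeans(v),
             sd = apply(v, 2, stats::sd),
             presence = colMeans(v > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen out low-informative items by standard deviation
#'
#' An item is flagged as uninformative when its standard deviation is more
#' than \code{factor} times lower than a reference value: item i is excluded
#' iff \code{sd[i] * factor < reference}. The default reference
#' (\code{mode = "mean_sd"}) is the mean SD across all items; the alternative
#' reading (\code{mode = "item_mean"}, reference = the item's own mean score)
#' is exposed because the verbal rule is ambiguous.
#'
#' @param item_sds named numeric vector of item standard deviations.
#' @param factor positive multiplier (default 2.5).
#' @param mode reference for the comparison, see Details.
#' @param item_means item means, required for \code{mode = "item_mean"}.
#' @return character vector of excluded item ids (possibly empty).
#' @export
screen_low_informative <- function(item_sds, factor = 2.5,
                                   mode = c("mean_sd", "item_mean"),
                                   item_means = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("`factor` must be a single positive number")
  if (any(is.na(item_sds)) || any(item_sds < 0))
    stop("item SDs must be non-negative")
  if (length(item_sds) < 2L) stop("need at least 2 items")
  ids <- names(item_sds) %||% as.character(seq_along(item_sds))
  ref <- switch(mode,
    mean_sd = rep(mean(item_sds), length(item_sds)),
    item_mean = {
      if (is.null(item_means) || length(item_means) != length(item_sds))
        stop("`item_means` required (same length as `item_sds`) for mode 'item_mean'")
      as.numeric(item_means)
    })
  ids[item_sds * factor < ref]
}

#' Flag redundant item pairs (goldbricker-style screen)
#'
#' For every item pair whose zero-order product-moment correlation is at
#' least \code{cor_min}, the two items' correlations with each remaining item
#' are compared with the dependent overlapping-correlations z test
#' (Hittner-Steiger, back-transformed-average variant). A pair is flagged as
#' potentially redundant when fewer than \code{prop_threshold} of those
#' comparisons differ significantly at \code{alpha} -- i.e. the two items
#' relate to the rest of the network almost interchangeably.
#'
#' Correlations are computed on the raw ordinal scores. Flagged pairs are
#' reported, not dropped; dropping is an explicit analyst decision.
#'
#' @param x an [item_responses] object (n >= 20 respondents).
#' @param cor_min minimum zero-order correlation to consider a pair.
#' @param alpha significance level of each dependent-correlation test.
#' @param prop_threshold pairs with a proportion of significant comparisons
#'   strictly below this are flagged.
#' @return data.frame with columns \code{item_a}, \code{item_b},
#'   \code{correlation}, \code{prop_significant}; zero rows when nothing is
#'   flagged.
#' @export
detect_redundant_pairs <- function(x, cor_min = 0.5, alpha = 0.05,
                                   prop_threshold = 0.25) {
  stopifnot(inherits(x, "item_responses"))
  v <- x$values
  n <- nrow(v); p <- ncol(v)
  if (n < 20L) stop("redundancy screening needs n >= 20 respondents; got ", n,
                    " (collect a larger sample)")
  if (p < 3L) stop("redundancy screening needs at least 3 items")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ",
         paste(x$item_ids[sds == 0], collapse = ", "))
  R <- stats::cor(v)
  out <- data.frame(item_a = character(), item_b = character(),
                    correlation = numeric(), prop_significant = numeric(),
                    stringsAsFactors = FALSE)
  for (a in seq_len(p - 1L)) for (b in seq((a + 1L), p)) {
    if (R[a, b] < cor_min) next
    others <- setdiff(seq_len(p), c(a, b))
    pvals <- vapply(others, function(cc)
      dependent_cor_test(R[a, cc], R[b, cc], R[a, b], n), numeric(1))
    prop_sig <- mean(pvals < alpha)
    if (prop_sig < prop_threshold)
      out <- rbind(out, data.frame(item_a = x$item_ids[a],
                                   item_b = x$item_ids[b],
                                   correlation = R[a, b],
                                   prop_significant = prop_sig,
                                   stringsAsFactors = FALSE))
  }
  out
}

# Two-sided p-value for H0: rho(a,c) = rho(b,c) with a, b, c measured on the
# same sample (overlapping dependent correlations). Hittner-Steiger z using
# the back-transformed average correlation in the covariance term.
dependent_cor_test <- function(r_ac, r_bc, r_ab, n) {
  z1 <- atanh(r_ac); z2 <- atanh(r_bc)
  if (abs(z1 - z2) < 1e-15) return(1)
  rm_ <- tanh((z1 + z2) / 2)
  cov_ <- (r_ab * (1 - 2 * rm_^2) - 0.5 * rm_^2 * (1 - 2 * rm_^2 - r_ab^2)) /
    (1 - rm_^2)^2
  cov_ <- min(cov_, 1 - 1e-12)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_))
  2 * stats::pnorm(-abs(z))
}

#' Binarize ordinal responses to presence/absence
#'
#' Maps a rating of 0 (symptom not present) to 0 and any rating of 1, 2 or 3
#' to 1. Idempotent: applying it to an already binary dataset is the
#' identity.
#'
#' @param x an [item_responses] or [binary_dataset] object.
#' @return A [binary_dataset] with the same items and order.
#' @export
binarize <- function(x) {
  if (inherits(x, "binary_dataset")) return(x)
  stopifnot(inherits(x, "item_responses"))
  binary_dataset((x$values > 0) + 0L, community = x$community)
}

#' Scale totals, positive screens and prevalence
#'
#' Sums the raw 0--3 item scores within each community (scale) per
#' respondent and applies the screening cutoff: a respondent screens
#' positive on a scale when the total is at least \code{cutoff}.
#'
#' @param x an [item_responses] object.
#' @param cutoff screening cutoff on the scale total (default 5).
#' @return list with \code{totals} (n x communities matrix),
#'   \code{positive} (logical matrix), \code{n_positive} and
#'   \code{prevalence} (named numeric, proportion screening positive).
#' @export
scale_screen <- function(x, cutoff = 5) {
  stopifnot(inherits(x, "item_responses"))
  comms <- unique(unname(x$community))
  totals <- sapply(comms, function(cm)
    rowSums(x$values[, x$community == cm, drop = FALSE]))
  totals <- matrix(totals, nrow = nrow(x$values),
                   dimnames = list(x$respondent_ids, comms))
  positive <- totals >= cutoff
  list(totals = totals, positive = positive, cutoff = cutoff,
       n_positive = colSums(positive),
       prevalence = colMeans(positive))
}

#' Cronbach's alpha for one scale
#'
#' Internal-consistency reliability of the raw ordinal items of one
#' community: \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' with \eqn{k} items, item variances \eqn{s_i^2} and total-score variance
#' \eqn{s_T^2}, all with the sample (n-1) convention.
#'
#' @param x an [item_responses] object.
#' @param scale community label of the scale to score.
#' @return alpha as a single number.
#' @export
cronbach_alpha <- function(x, scale) {
  stopifnot(inherits(x, "item_responses"))
  v <- x$values[, x$community == scale, drop = FALSE]
  k <- ncol(v)
  if (k < 2L) stop("scale '", scale, "' has fewer than 2 items")
  tot_var <- stats::var(rowSums(v))
  if (tot_var == 0) stop("total-score variance is zero for scale '", scale,
                         "'; alpha is undefined")
  k / (k - 1) * (1 - sum(apply(v, 2, stats::var)) / tot_var)
}

#' Run the full item-screening chain
#'
#' Descriptives, SD-based low-informativeness screen, and redundancy screen,
#' assembled into one report.
#'
#' @param x an [item_responses] object.
#' @param sd_factor factor for [screen_low_informative].
#' @param cor_min,alpha,prop_threshold passed to [detect_redundant_pairs].
#' @param run_redundancy set \code{FALSE} to skip the redundancy screen
#'   (recorded in the report).
#' @return list of class \code{screening_report}: \code{descriptives},
#'   \code{excluded_low_sd}, \code{redundant_pairs},
#'   \code{redundancy_screened}.
#' @export
screen_items <- function(x, sd_factor = 2.5, cor_min = 0.5, alpha = 0.05,
                         prop_threshold = 0.25, run_redundancy = TRUE) {
  desc <- item_descriptives(x)
  sds <- stats::setNames(desc$sd, desc$item)
  excluded <- screen_low_informative(sds, factor = sd_factor)
  red <- if (run_redundancy)
    detect_redundant_pairs(x, cor_min = cor_min, alpha = alpha,
                           prop_threshold = prop_threshold)
  else NULL
  structure(list(descriptives = desc, excluded_low_sd = excluded,
                 redundant_pairs = red, redundancy_screened = run_redundancy,
                 sd_factor = sd_factor),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d items; %d excluded by SD rule; %s\n",
              nrow(x$descriptives), length(x$excluded_low_sd),
              if (!x$redundancy_screened) "redundancy screen skipped"
              else sprintf("%d redundant pair(s) flagged",
                           nrow(x$redundant_pairs))))
  invisible(x)
}
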