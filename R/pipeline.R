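# End-to-end orchestration: config, the full analysis flow, report
# serialization and comparison.

#' Analysis configuration
#'
#' Bundles every tunable of the analysis flow; a config plus a seed fully
#' determines every number in the resulting report. Configs round-trip
#' through YAML/JSON unchanged ([read_config], [write_config]).
#'
#' @param input path to the input CSV (optional when data are passed to
#'   [run_full_analysis] directly).
#' @param community named character vector: item id -> community label.
#' @param gamma EBIC gamma (default 0.25).
#' @param rule edge rule, "AND" or "OR".
#' @param cutoff scale screening cutoff (default 5).
#' @param sd_factor low-informativeness SD factor (default 2.5).
#' @param cor_min,alpha,prop_threshold redundancy-screen settings.
#' @param run_redundancy skip flag for the redundancy screen (recorded in
#'   provenance).
#' @param bootstrap_B edge-bootstrap replicates (default 1000; 0 skips).
#' @param case_drop_B case-dropping replicates per proportion (default
#'   1000; 0 skips).
#' @param drop_grid case-dropping proportions.
#' @param bridge_percentile BEI percentile for bridge selection.
#' @param seed master seed.
#' @param output_dir optional directory for exported artifacts.
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(input = NULL, community = phq_gad_communities(),
                            gamma = 0.25, rule = "AND", cutoff = 5,
                            sd_factor = 2.5, cor_min = 0.5, alpha = 0.05,
                            prop_threshold = 0.25, run_redundancy = TRUE,
                            bootstrap_B = 1000L, case_drop_B = 1000L,
                            drop_grid = seq(0.05, 0.75, by = 0.05),
                            bridge_percentile = 80, seed = 1L,
                            output_dir = NULL) {
  stopifnot(gamma >= 0, rule %in% c("AND", "OR"), cutoff >= 0,
            sd_factor > 0, cor_min >= 0, cor_min <= 1,
            alpha > 0, alpha < 1, prop_threshold >= 0, prop_threshold <= 1,
            bootstrap_B >= 0, case_drop_B >= 0,
            all(drop_grid > 0), all(drop_grid <= 0.75),
            bridge_percentile > 0, bridge_percentile < 100)
  structure(list(input = input, community = community, gamma = gamma,
                 rule = rule, cutoff = cutoff, sd_factor = sd_factor,
                 cor_min = cor_min, alpha = alpha,
                 prop_threshold = prop_threshold,
                 run_redundancy = run_redundancy,
                 bootstrap_B = as.integer(bootstrap_B),
                 case_drop_B = as.integer(case_drop_B),
                 drop_grid = drop_grid,
                 bridge_percentile = bridge_percentile,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path file path ending in .yaml/.yml or .json.
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  lst$community <- unlist(lst$community)
  if (!is.null(lst$drop_grid)) lst$drop_grid <- as.numeric(unlist(lst$drop_grid))
  do.call(analysis_config, lst)
}

#' @rdname analysis_config
#' @param config an \code{analysis_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  lst <- unclass(config)
  lst$community <- as.list(lst$community)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML configs requires the 'yaml' package")
    yaml::write_yaml(lst, path)
  } else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE)
  invisible(path)
}

stage_log <- function(stage, t0, detail = "") {
  message(sprintf("[%s] %.2fs %s", stage,
                  as.numeric(Sys.time() - t0, units = "secs"), detail))
}

#' Run the full symptom-network analysis
#'
#' Executes the complete flow on ordinal questionnaire data: read and
#' validate, descriptives and Cronbach's alpha per scale, scale screening
#' prevalence, SD-based item exclusion, redundancy screen, binarization,
#' Ising estimation (eLasso, EBIC gamma from the config), network summary,
#' EI/BEI/predictability, percentile bridge selection, edge bootstrap and
#' case-dropping bootstraps with CS coefficients. Identical config + seed
#' give an identical report. Items failing the SD screen are dropped before
#' estimation; an item constant after binarization aborts the run naming the
#' item.
#'
#' @param config an [analysis_config].
#' @param data optional [item_responses]; when \code{NULL}, read from
#'   \code{config$input}.
#' @return list of class \code{analysis_report}.
#' @export
run_full_analysis <- function(config, data = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  if (is.null(data)) {
    if (is.null(config$input)) stop("no input: set config$input or pass `data`")
    data <- read_responses(config$input, config$community)
  }
  stage_log("read", t0, sprintf("%d x %d", nrow(data$values),
                                length(data$item_ids)))

  t0 <- Sys.time()
  screening <- screen_items(data, sd_factor = config$sd_factor,
                            cor_min = config$cor_min, alpha = config$alpha,
                            prop_threshold = config$prop_threshold,
                            run_redundancy = config$run_redundancy)
  reliability <- vapply(unique(unname(data$community)),
                        function(s) cronbach_alpha(data, s), numeric(1))
  screen <- scale_screen(data, cutoff = config$cutoff)
  stage_log("screen", t0, sprintf("%d item(s) excluded by SD rule",
                                  length(screening$excluded_low_sd)))

  kept <- setdiff(data$item_ids, screening$excluded_low_sd)
  if (length(kept) < 3L)
    stop("screening left fewer than 3 items; aborting at stage 'screen'")
  data_kept <- item_responses(data$values[, kept, drop = FALSE],
                              data$community[kept], data$respondent_ids)

  t0 <- Sys.time()
  bin <- binarize(data_kept)
  bad <- colMeans(bin$values) %in% c(0, 1)
  if (any(bad))
    stop("item(s) constant after binarization: ",
         paste(bin$item_ids[bad], collapse = ", "),
         "; aborting at stage 'binarize'")
  net <- estimate_network(bin, gamma = config$gamma, rule = config$rule)
  summ <- network_summary(net)
  stage_log("estimate", t0, sprintf("%d edges, density %.3f",
                                    summ$n_edges, summ$density))

  t0 <- Sys.time()
  centrality <- summarize_centrality(net, bin,
                                     bridge_percentile = config$bridge_percentile)
  central <- centrality$item[order(centrality$ei_rank)]
  bridges <- centrality$item[centrality$is_bridge]
  stage_log("centrality", t0,
            sprintf("bridges: %s", paste(bridges, collapse = ", ")))

  boot <- NULL; cs <- c(EI = NA_real_, BEI = NA_real_); case_drops <- NULL
  if (config$bootstrap_B > 0) {
    t0 <- Sys.time()
    boot <- bootstrap_edges(bin, B = config$bootstrap_B,
                            gamma = config$gamma, rule = config$rule,
                            seed = config$seed)
    stage_log("bootstrap", t0, sprintf("B = %d", config$bootstrap_B))
  }
  if (config$case_drop_B > 0) {
    t0 <- Sys.time()
    case_drops <- lapply(c(EI = "EI", BEI = "BEI"), function(st)
      case_dropping_bootstrap(bin, statistic = st,
                              drop_grid = config$drop_grid,
                              B = config$case_drop_B, gamma = config$gamma,
                              rule = config$rule, seed = config$seed + 1L))
    cs <- vapply(case_drops, cs_coefficient, numeric(1))
    stage_log("stability", t0, sprintf("CS(EI) = %.2f, CS(BEI) = %.2f",
                                       cs[["EI"]], cs[["BEI"]]))
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  structure(list(
    screening = screening,
    reliability = reliability,
    prevalence = screen$prevalence,
    n_positive = screen$n_positive,
    network = net,
    summary = summ,
    centrality = centrality,
    central_symptoms = central,
    bridge_symptoms = bridges,
    bootstrap = boot,
    case_drops = case_drops,
    cs_coefficients = cs,
    provenance = list(config = config,
                      config_hash = fnv1a(as.character(cfg_json)),
                      seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("symptomnet")))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  items: %d | edges: %d (density %.2f, mean weight %.3f)\n",
              x$summary$n_nodes, x$summary$n_edges, x$summary$density,
              x$summary$mean_weight))
  cat(sprintf("  prevalence: %s\n",
              paste(sprintf("%s %.0f%%", names(x$prevalence),
                            100 * x$prevalence), collapse = ", ")))
  cat(sprintf("  alpha: %s\n",
              paste(sprintf("%s %.3f", names(x$reliability),
                            x$reliability), collapse = ", ")))
  cat(sprintf("  central: %s\n",
              paste(utils::head(x$central_symptoms, 3), collapse = ", ")))
  cat(sprintf("  bridges: %s\n", paste(x$bridge_symptoms, collapse = ", ")))
  if (!all(is.na(x$cs_coefficients)))
    cat(sprintf("  CS: EI %.2f, BEI %.2f\n",
                x$cs_coefficients[["EI"]], x$cs_coefficients[["BEI"]]))
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Full-precision JSON of the report's numeric content (weights, centrality
#' table, stability summaries, provenance); presentation rounding is left to
#' the caller.
#'
#' @param report an \code{analysis_report}.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  lst <- list(
    reliability = as.list(report$reliability),
    prevalence = as.list(report$prevalence),
    excluded_low_sd = report$screening$excluded_low_sd,
    redundant_pairs = report$screening$redundant_pairs,
    network = list(items = report$network$item_ids,
                   community = as.list(report$network$community),
                   thresholds = unname(report$network$thresholds),
                   weights = report$network$weights,
                   gamma = report$network$gamma,
                   rule = report$network$rule),
    summary = report$summary[c("n_nodes", "n_edges", "density", "mean_weight")],
    centrality = report$centrality,
    central_symptoms = report$central_symptoms,
    bridge_symptoms = report$bridge_symptoms,
    cs_coefficients = as.list(report$cs_coefficients),
    provenance = list(config_hash = report$provenance$config_hash,
                      seed = report$provenance$seed,
                      package_version = report$provenance$package_version))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Compare two analysis reports
#'
#' Structured diff of the deterministic and stochastic quantities of two
#' reports over the same item set: per-edge weight deltas, edge-set changes
#' (added/removed/sign-flipped), EI/BEI deltas and CS-coefficient deltas.
#' Differences below \code{tol} are ignored.
#'
#' @param a,b \code{analysis_report} objects over the same items.
#' @param tol absolute tolerance below which a delta counts as zero.
#' @return list of class \code{report_diff} with \code{edges} (data.frame of
#'   changed edges with columns delta/status), \code{ei}, \code{bei},
#'   \code{cs}, and \code{is_empty}.
#' @export
compare_reports <- function(a, b, tol = 1e-12) {
  stopifnot(inherits(a, "analysis_report"), inherits(b, "analysis_report"))
  if (!setequal(a$network$item_ids, b$network$item_ids))
    stop("reports cover different item sets")
  items <- a$network$item_ids
  wa <- a$network$weights
  wb <- b$network$weights[items, items]
  pairs <- upper_pairs(items)
  va <- wa[cbind(pairs$i, pairs$j)]
  vb <- wb[cbind(pairs$i, pairs$j)]
  delta <- vb - va
  status <- rep("changed", length(delta))
  status[va == 0 & vb != 0] <- "added"
  status[va != 0 & vb == 0] <- "removed"
  status[va * vb < 0] <- "sign_flip"
  changed <- abs(delta) > tol
  edges <- data.frame(item_a = pairs$item_a[changed],
                      item_b = pairs$item_b[changed],
                      weight_a = va[changed], weight_b = vb[changed],
                      delta = delta[changed], status = status[changed],
                      stringsAsFactors = FALSE)
  eia <- stats::setNames(a$centrality$ei1, a$centrality$item)[items]
  eib <- stats::setNames(b$centrality$ei1, b$centrality$item)[items]
  beia <- stats::setNames(a$centrality$bei1, a$centrality$item)[items]
  beib <- stats::setNames(b$centrality$bei1, b$centrality$item)[items]
  dei <- (eib - eia)[abs(eib - eia) > tol]
  dbei <- (beib - beia)[abs(beib - beia) > tol]
  dcs <- b$cs_coefficients - a$cs_coefficients
  dcs <- dcs[!is.na(dcs) & abs(dcs) > tol]
  structure(list(edges = edges, ei = dei, bei = dbei, cs = dcs,
                 is_empty = nrow(edges) == 0 && length(dei) == 0 &&
                   length(dbei) == 0 && length(dcs) == 0),
            class = "report_diff")
}

#' @export
print.report_diff <- function(x, ...) {
  if (x$is_empty) cat("<report_diff> no differences\n")
  else cat(sprintf(
    "<report_diff> %d edge change(s) (%s), %d EI, %d BEI, %d CS delta(s)\n",
    nrow(x$edges), paste(names(table(x$edges$status)), collapse = "/"),
    length(x$ei), length(x$bei), length(x$cs)))
  invisible(x)
}
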