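# Network export/import: weighted edge list + node table CSV, GraphML,
# JSON bundle. All formats round-trip weights at full double precision.

fmt_num <- function(x) sprintf("%.17g", x)

#' Export an estimated network
#'
#' Writes an [ising_network] (or the network inside an analysis report) in
#' one of three lossless formats:
#' \describe{
#'   \item{\code{edgelist_csv}}{\code{<path>} with columns
#'     \code{item_a,item_b,weight} (nonzero upper-triangle edges) plus a
#'     sibling node table \code{<path minus .csv>_nodes.csv} with
#'     \code{item,threshold,community}, so isolated nodes survive the round
#'     trip.}
#'   \item{\code{graphml}}{a GraphML document with node attributes
#'     \code{community}, \code{threshold} and edge attribute \code{weight}.}
#'   \item{\code{json}}{a JSON bundle with items, communities, thresholds,
#'     the full weight matrix and estimation provenance (gamma, rule).}
#' }
#' Numbers are written with 17 significant digits, so
#' \code{import_network(export_network(net, f, p), f)} reproduces the weight
#' matrix exactly.
#'
#' @param net an [ising_network] or \code{analysis_report}.
#' @param format one of \code{"edgelist_csv"}, \code{"graphml"},
#'   \code{"json"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, format = c("edgelist_csv", "graphml", "json"),
                           path) {
  if (inherits(net, "analysis_report")) net <- net$network
  stopifnot(inherits(net, "ising_network"))
  format <- match.arg(format)
  s <- network_summary(net)
  edges <- s$strongest_edges
  switch(format,
    edgelist_csv = {
      out <- edges
      out$weight <- fmt_num(out$weight)
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
      nodes <- data.frame(item = net$item_ids,
                          threshold = fmt_num(net$thresholds),
                          community = if (is.null(net$community)) ""
                                      else unname(net$community),
                          stringsAsFactors = FALSE)
      utils::write.csv(nodes, nodes_path(path), row.names = FALSE,
                       quote = FALSE)
    },
    graphml = write_graphml(net, edges, path),
    json = jsonlite::write_json(
      list(items = net$item_ids,
           community = if (is.null(net$community)) NULL
                       else as.list(net$community),
           thresholds = unname(net$thresholds),
           weights = unname(net$weights),
           gamma = net$gamma, rule = net$rule),
      path, auto_unbox = TRUE, digits = I(17), null = "null"))
  invisible(path)
}

nodes_path <- function(path) sub("(\\.csv)?$", "_nodes.csv", path)

write_graphml <- function(net, edges, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<graphml xmlns="http://graphml.graphdrawing.org/xmlns" ',
           'xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" ',
           'xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns ',
           'http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">'),
    '  <key id="d0" for="node" attr.name="community" attr.type="string"/>',
    '  <key id="d1" for="node" attr.name="threshold" attr.type="double"/>',
    '  <key id="d2" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    vapply(seq_along(net$item_ids), function(i) paste0(
      '    <node id="', esc(net$item_ids[i]), '">',
      '<data key="d0">',
      esc(if (is.null(net$community)) "" else net$community[[i]]),
      '</data>',
      '<data key="d1">', fmt_num(net$thresholds[i]), '</data>',
      '</node>'), character(1)),
    if (nrow(edges)) vapply(seq_len(nrow(edges)), function(e) paste0(
      '    <edge source="', esc(edges$item_a[e]), '" target="',
      esc(edges$item_b[e]), '">',
      '<data key="d2">', fmt_num(edges$weight[e]), '</data></edge>'),
      character(1)),
    '  </graph>',
    '</graphml>')
  writeLines(lines, path)
}

#' Import a previously exported network
#'
#' Inverse of [export_network]; reconstructs the [ising_network] exactly.
#'
#' @param path file written by [export_network].
#' @param format the format it was written in.
#' @return an [ising_network].
#' @export
import_network <- function(path,
                           format = c("edgelist_csv", "graphml", "json")) {
  format <- match.arg(format)
  switch(format,
    edgelist_csv = {
      nodes <- utils::read.csv(nodes_path(path),
                               colClasses = c("character", "character",
                                              "character"))
      edges <- utils::read.csv(path,
                               colClasses = c("character", "character",
                                              "character"))
      items <- nodes$item
      W <- matrix(0, length(items), length(items),
                  dimnames = list(items, items))
      if (nrow(edges)) {
        W[cbind(edges$item_a, edges$item_b)] <- as.numeric(edges$weight)
        W[cbind(edges$item_b, edges$item_a)] <- as.numeric(edges$weight)
      }
      comm <- if (all(nodes$community == "")) NULL else
        stats::setNames(nodes$community, items)
      ising_network(stats::setNames(as.numeric(nodes$threshold), items), W,
                    community = comm)
    },
    graphml = {
      if (!requireNamespace("xml2", quietly = TRUE))
        stop("reading GraphML requires the 'xml2' package")
      doc <- xml2::read_xml(path)
      ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
      nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
      items <- xml2::xml_attr(nodes, "id")
      get_data <- function(node, key)
        xml2::xml_text(xml2::xml_find_first(
          node, sprintf(".//g:data[@key='%s']", key), ns))
      comm <- vapply(nodes, get_data, character(1), key = "d0")
      tau <- as.numeric(vapply(nodes, get_data, character(1), key = "d1"))
      W <- matrix(0, length(items), length(items),
                  dimnames = list(items, items))
      e_nodes <- xml2::xml_find_all(doc, ".//g:edge", ns)
      if (length(e_nodes)) {
        src <- xml2::xml_attr(e_nodes, "source")
        tgt <- xml2::xml_attr(e_nodes, "target")
        w <- as.numeric(vapply(e_nodes, get_data, character(1), key = "d2"))
        W[cbind(src, tgt)] <- w
        W[cbind(tgt, src)] <- w
      }
      cm <- if (all(comm == "")) NULL else stats::setNames(comm, items)
      ising_network(stats::setNames(tau, items), W, community = cm)
    },
    json = {
      lst <- jsonlite::read_json(path, simplifyVector = TRUE)
      items <- lst$items
      W <- as.matrix(lst$weights)
      dimnames(W) <- list(items, items)
      comm <- if (is.null(lst$community)) NULL else
        stats::setNames(unlist(lst$community), names(lst$community))
      ising_network(stats::setNames(lst$thresholds, items), W,
                    community = comm, gamma = lst$gamma, rule = lst$rule)
    })
}
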