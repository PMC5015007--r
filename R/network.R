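#' High-confidence interaction network by posterior thresholding
#'
#' Keeps pairs whose posterior interaction probability strictly exceeds
#' `tau` (default 0.8) and builds an undirected simple graph weighted by
#' the posterior. Proteins left without any confident partner are dropped
#' unless `keep_isolated = TRUE` and `universe` is supplied.
#'
#' @param scores data frame with columns `protein_a`, `protein_b`,
#'   `posterior` (e.g. the `posterior` element of a [ppi_fit()]).
#' @param tau confidence threshold in `[0, 1]`; strict inequality.
#' @param keep_isolated retain proteins from `universe` that have no
#'   confident edge.
#' @param universe optional character vector of protein ids (required when
#'   `keep_isolated = TRUE`).
#' @return An [igraph::graph][igraph] object with edge attribute `weight`
#'   (the posterior).
#' @export
#' @examples
#' sc <- data.frame(protein_a = c("a", "a"), protein_b = c("b", "c"),
#'                  posterior = c(0.9, 0.5))
#' g <- threshold_network(sc, tau = 0.8)
#' igraph::ecount(g)  # 1
threshold_network <- function(scores, tau = 0.8, keep_isolated = FALSE,
                              universe = NULL) {
  stopifnot(tau >= 0, tau <= 1,
            all(c("protein_a", "protein_b", "posterior") %in% names(scores)))
  keep <- scores$posterior > tau
  el <- scores[keep, c("protein_a", "protein_b", "posterior"), drop = FALSE]
  names(el)[3] <- "weight"
  verts <- if (keep_isolated) {
    if (is.null(universe))
      stop("keep_isolated = TRUE requires a universe of protein ids")
    data.frame(name = universe, stringsAsFactors = FALSE)
  } else NULL
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Degree of a protein in the confidence network
#'
#' Number of incident edges (unweighted), used e.g. for hub calling.
#'
#' @param network an igraph network (e.g. from [threshold_network()]).
#' @param protein protein identifier(s).
#' @return Integer degree(s).
#' @export
node_degree <- function(network, protein) {
  missing <- setdiff(protein, igraph::V(network)$name)
  if (length(missing))
    stop("protein(s) not in network: ", paste(missing, collapse = ", "))
  deg <- igraph::degree(network)
  unname(deg[protein])
}

#' Write / read a weighted edge list
#'
#' Plain-TSV serialization (`protein_a`, `protein_b`, `posterior`) of a
#' confidence network; `read_network_tsv()` restores the graph exactly.
#' `write_network_graphml()` exports GraphML for visualization tools.
#'
#' @param network an igraph network with a `weight` edge attribute.
#' @param path output file path.
#' @return The path, invisibly; `read_network_tsv()` returns an igraph
#'   object.
#' @export
write_network_tsv <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  out <- data.frame(protein_a = pmin(el$from, el$to),
                    protein_b = pmax(el$from, el$to),
                    posterior = el$weight, stringsAsFactors = FALSE)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cl in c("protein_a", "protein_b")) d[[cl]] <- as.character(d[[cl]])
  names(d)[3] <- "weight"
  igraph::graph_from_data_frame(d, directed = FALSE)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
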