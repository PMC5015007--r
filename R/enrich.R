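#' Disorder annotation
#'
#' Flags intrinsically disordered proteins (IDPs): a protein is an IDP when
#' its longest continuous intrinsically disordered region is strictly
#' longer than `threshold` amino acids (default 40).
#'
#' @param annotation data frame with columns `protein_id` and
#'   `disorder_length` (longest continuous disordered region, in amino
#'   acids).
#' @param threshold IDP length cutoff (strict).
#' @return The annotation with a logical `is_idp` column added.
#' @export
#' @examples
#' disorder_annotation(data.frame(protein_id = c("a", "b"),
#'                                disorder_length = c(41, 40)))$is_idp
disorder_annotation <- function(annotation, threshold = 40) {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "disorder_length") %in% names(annotation)))
  if (any(annotation$disorder_length < 0))
    stop("disorder lengths must be non-negative")
  annotation$is_idp <- annotation$disorder_length > threshold
  annotation
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail hypergeometric probability of seeing `m` or more successes in
#' `n` draws without replacement from a population of `N` containing `M`
#' successes:
#' `p = sum_{i = m}^{min(n, M)} C(M, i) C(N - M, n - i) / C(N, n)`,
#' evaluated in log space via [stats::phyper()].
#'
#' @param N population size.
#' @param M number of successes in the population.
#' @param n draws (module size).
#' @param m observed successes in the draw.
#' @return The p-value in `(0, 1]`; `m = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeom_pvalue(10, 5, 4, 4)  # 5 / 210
hypergeom_pvalue <- function(N, M, n, m) {
  if (any(m < 0 | n < 0 | M < 0 | N < 0) || any(m > n) || any(n > N) ||
      any(M > N))
    stop("require 0 <= m <= n <= N and 0 <= M <= N")
  exp(stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE, log.p = TRUE))
}

#' IDP enrichment of network modules
#'
#' Tests every module of a SCAN partition for over-representation of
#' intrinsically disordered proteins with the hypergeometric tail
#' probability, taking the clustered network (all proteins carrying a
#' partition entry) as the population. Clustered proteins missing from
#' the annotation are treated as non-IDPs with a warning. No multiplicity
#' correction is applied by default; Benjamini-Hochberg is available via
#' `correction = "BH"`.
#'
#' @param partition a [scan_cluster()] result.
#' @param annotation a [disorder_annotation()] result (or a raw annotation
#'   data frame, annotated on the fly).
#' @param alpha significance level for the `significant` flag.
#' @param correction `"none"` (default) or `"BH"`.
#' @return Data frame with one row per module: `module`, `n` (size), `m`
#'   (IDP count), `p_value`, `significant`.
#' @export
test_modules <- function(partition, annotation, alpha = 0.05,
                         correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (!"is_idp" %in% names(annotation))
    annotation <- disorder_annotation(annotation)
  idp <- stats::setNames(annotation$is_idp, annotation$protein_id)
  unknown <- setdiff(partition$protein, annotation$protein_id)
  if (length(unknown)) {
    warning(length(unknown),
            " clustered protein(s) lack disorder annotation; treated as",
            " non-IDP")
    idp[unknown] <- FALSE
  }
  N <- nrow(partition)
  Mv <- sum(idp[partition$protein])
  labs <- setdiff(unique(partition$type), c("HUB", "OUTLIER"))
  labs <- labs[order(as.integer(labs))]
  res <- do.call(rbind, lapply(labs, function(s) {
    prots <- partition$protein[partition$type == s]
    m <- sum(idp[prots])
    data.frame(module = s, n = length(prots), m = m,
               p_value = hypergeom_pvalue(N, Mv, length(prots), m),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(module = character(), n = integer(), m = integer(),
                      p_value = numeric(), significant = logical()))
  p_adj <- if (correction == "BH") stats::p.adjust(res$p_value, "BH") else
    res$p_value
  res$significant <- p_adj < alpha
  res
}

#' IDP fraction among a module's hub nodes
#'
#' Hubs of a module are the nodes whose degree in the module-induced
#' subgraph exceeds `hub_degree` (default 5). Returns the fraction of hubs
#' that are IDPs; errors when the module has no hubs. Set
#' `induced = FALSE` to call hubs by whole-network degree instead.
#'
#' @param network an igraph network.
#' @param module_nodes character vector of module member ids (must be in
#'   the network).
#' @param annotation a [disorder_annotation()] result.
#' @param hub_degree degree cutoff (strict).
#' @param induced use the module-induced subgraph for degrees (default).
#' @return Fraction of hub nodes annotated as IDPs.
#' @export
hub_idp_fraction <- function(network, module_nodes, annotation,
                             hub_degree = 5, induced = TRUE) {
  miss <- setdiff(module_nodes, igraph::V(network)$name)
  if (length(miss))
    stop("module node(s) not in network: ", paste(miss, collapse = ", "))
  if (!"is_idp" %in% names(annotation))
    annotation <- disorder_annotation(annotation)
  g <- if (induced) igraph::induced_subgraph(network, module_nodes) else
    network
  deg <- igraph::degree(g)[module_nodes]
  hubs <- module_nodes[deg > hub_degree]
  if (!length(hubs)) stop("no hubs: no module node exceeds degree ",
                          hub_degree)
  idp <- stats::setNames(annotation$is_idp, annotation$protein_id)
  mean(idp[hubs] %in% TRUE)
}

#' Write module enrichment results
#'
#' @param enrichment a [test_modules()] result.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
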