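#' Structural similarity of two vertices
#'
#' SCAN's similarity between adjacent vertices: the normalized overlap of
#' closed neighbourhoods,
#' `sigma(u, v) = |G(u) n G(v)| / sqrt(|G(u)| * |G(v)|)` with
#' `G(x) = {x} + neighbours(x)`. Clustering is purely topological: edge
#' weights are deliberately ignored.
#'
#' @param network an igraph network.
#' @param u,v vertex names.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' structural_similarity(g, "a", "b")  # 2 / sqrt(6)
structural_similarity <- function(network, u, v) {
  miss <- setdiff(c(u, v), igraph::V(network)$name)
  if (length(miss))
    stop("vertex not in network: ", paste(miss, collapse = ", "))
  gu <- c(u, igraph::neighbors(network, u)$name)
  gv <- c(v, igraph::neighbors(network, v)$name)
  length(intersect(gu, gv)) / sqrt(length(gu) * length(gv))
}

# similarity for every edge of the graph at once; returns a data frame
# (from, to, sigma) aligned with igraph's edge order
edge_similarities <- function(network) {
  el <- igraph::as_data_frame(network, what = "edges")[, c("from", "to")]
  if (!nrow(el)) return(cbind(el, sigma = numeric()))
  adj <- igraph::adjacent_vertices(network, igraph::V(network))
  closed <- lapply(seq_along(adj), function(i)
    c(igraph::V(network)$name[i], adj[[i]]$name))
  names(closed) <- igraph::V(network)$name
  sz <- lengths(closed)
  el$sigma <- vapply(seq_len(nrow(el)), function(k) {
    a <- el$from[k]; b <- el$to[k]
    length(intersect(closed[[a]], closed[[b]])) / sqrt(sz[[a]] * sz[[b]])
  }, numeric(1))
  el
}

#' SCAN structural clustering
#'
#' Clusters the network with the SCAN algorithm: a vertex is a *core* if at
#' least `mu` of its neighbours have structural similarity `>= epsilon`;
#' clusters are grown from cores through structure-reachability (a core
#' attaches every neighbour with similarity `>= epsilon`), and the
#' remaining unclustered vertices are classified as *hubs* when adjacent to
#' two or more clusters and *outliers* otherwise. Vertices are processed
#' in sorted name order, so the labelling is deterministic and independent
#' of edge order.
#'
#' @param network an igraph network.
#' @param epsilon similarity threshold in `(0, 1]`.
#' @param mu minimum number of similar neighbours for a core (default 2).
#' @return An object of class `ppi_modules`: data frame with columns
#'   `protein` and `type` (`"1"`, `"2"`, ... for module labels, `"HUB"`,
#'   `"OUTLIER"`), with attributes `epsilon`, `mu` and `n_modules`.
#' @references Xu, Yuruk, Feng & Schweiger (2007) SCAN: a structural
#'   clustering algorithm for networks. KDD '07.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
#' scan_cluster(g, epsilon = 0.5)  # two triangle modules
scan_cluster <- function(network, epsilon, mu = 2) {
  stopifnot(epsilon > 0, mu >= 2)
  vs <- sort(igraph::V(network)$name)
  n <- length(vs)
  es <- edge_similarities(network)
  # epsilon-neighbourhood (excluding self) per vertex
  nbr <- stats::setNames(vector("list", n), vs)
  ok <- es$sigma >= epsilon
  for (k in which(ok)) {
    nbr[[es$from[k]]] <- c(nbr[[es$from[k]]], es$to[k])
    nbr[[es$to[k]]] <- c(nbr[[es$to[k]]], es$from[k])
  }
  is_core <- vapply(vs, function(v) length(nbr[[v]]) >= mu, logical(1))
  label <- stats::setNames(rep(NA_integer_, n), vs)
  nclust <- 0L
  for (v in vs) {
    if (!is_core[[v]] || !is.na(label[[v]])) next
    nclust <- nclust + 1L
    queue <- v
    label[[v]] <- nclust
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is_core[[u]]) next
      for (w in sort(nbr[[u]])) {
        if (is.na(label[[w]])) {
          label[[w]] <- nclust
          if (is_core[[w]]) queue <- c(queue, w)
        }
      }
    }
  }
  type <- as.character(label)
  un <- which(is.na(label))
  if (length(un)) {
    adj <- igraph::adjacent_vertices(network, vs[un])
    for (t in seq_along(un)) {
      touching <- unique(stats::na.omit(label[adj[[t]]$name]))
      type[un[t]] <- if (length(touching) >= 2) "HUB" else "OUTLIER"
    }
  }
  structure(data.frame(protein = vs, type = type, stringsAsFactors = FALSE),
            epsilon = epsilon, mu = mu, n_modules = nclust,
            class = c("ppi_modules", "data.frame"))
}

#' @export
print.ppi_modules <- function(x, ...) {
  cat(sprintf(paste0("SCAN partition (epsilon = %.3g, mu = %d): ",
                     "%d modules, %d hubs, %d outliers over %d proteins\n"),
              attr(x, "epsilon"), attr(x, "mu"), attr(x, "n_modules"),
              sum(x$type == "HUB"), sum(x$type == "OUTLIER"), nrow(x)))
  invisible(x)
}

# membership vector for modularity: module labels with hubs/outliers as
# singleton communities
partition_membership <- function(network, partition) {
  type <- stats::setNames(partition$type, partition$protein)
  vs <- igraph::V(network)$name
  memb <- type[vs]
  extra <- which(!memb %in% as.character(seq_len(attr(partition, "n_modules"))))
  nm <- attr(partition, "n_modules")
  memb[extra] <- nm + seq_along(extra)
  as.integer(memb)
}

#' Newman modularity of a partition
#'
#' `Q_N = sum_s [ l_s / L - (d_s / (2L))^2 ]` over modules `s`, with `L`
#' the total edge count, `l_s` the within-module edge count and `d_s` the
#' total degree of module `s`. Hubs and outliers enter as singleton
#' modules so that the partition covers the network.
#'
#' @param network an igraph network with at least one edge.
#' @param partition a [scan_cluster()] result (or any `ppi_modules`).
#' @return The modularity score.
#' @export
modularity_QN <- function(network, partition) {
  L <- igraph::ecount(network)
  if (L == 0) stop("modularity is undefined for an empty network")
  memb <- partition_membership(network, partition)
  el <- igraph::as_data_frame(network, what = "edges")
  vs <- igraph::V(network)$name
  m_of <- stats::setNames(memb, vs)
  within <- m_of[el$from] == m_of[el$to]
  # within-module edge counts per module
  ls <- table(factor(m_of[el$from][within], levels = unique(memb)))
  ds <- tapply(igraph::degree(network), memb, sum)
  q <- 0
  for (s in names(ds)) {
    l_s <- if (s %in% names(ls)) ls[[s]] else 0
    q <- q + l_s / L - (ds[[s]] / (2 * L))^2
  }
  unname(q)
}

#' Similarity-based modularity of a partition
#'
#' The similarity-weighted analogue of [modularity_QN()]: with each edge
#' weighted by its structural similarity `sigma(u, v)`,
#' `Q_S = sum_s [ IS_s / TS - (DS_s / (2 TS))^2 ]` where `TS` is the total
#' similarity over all edges, `IS_s` the similarity of within-module edges
#' and `DS_s` the similarity-weighted degree of module `s`. When all edge
#' similarities are equal, `Q_S` coincides with `Q_N`.
#'
#' @inheritParams modularity_QN
#' @return The similarity-based modularity score.
#' @export
modularity_QS <- function(network, partition) {
  if (igraph::ecount(network) == 0)
    stop("modularity is undefined for an empty network")
  es <- edge_similarities(network)
  TS <- sum(es$sigma)
  memb <- partition_membership(network, partition)
  vs <- igraph::V(network)$name
  m_of <- stats::setNames(memb, vs)
  mods <- unique(memb)
  # similarity-weighted degree per vertex
  wdeg <- stats::setNames(numeric(length(vs)), vs)
  for (k in seq_len(nrow(es))) {
    wdeg[[es$from[k]]] <- wdeg[[es$from[k]]] + es$sigma[k]
    wdeg[[es$to[k]]] <- wdeg[[es$to[k]]] + es$sigma[k]
  }
  q <- 0
  for (s in mods) {
    inmod <- m_of[es$from] == s & m_of[es$to] == s
    IS <- sum(es$sigma[inmod])
    DS <- sum(wdeg[vs[m_of == s]])
    q <- q + IS / TS - (DS / (2 * TS))^2
  }
  q
}

#' Select the SCAN threshold by maximizing similarity-based modularity
#'
#' Clusters the network at every epsilon on a grid, computes both
#' modularity metrics, and returns the epsilon maximizing `Q_S` (ties
#' resolved toward the smallest epsilon), together with the full metric
#' curves for plotting.
#'
#' @param network an igraph network.
#' @param grid epsilon values to sweep (default 0.05 to 0.95 by 0.01).
#' @param mu SCAN core size.
#' @return A list with `epsilon` (the selected value), `partition` (the
#'   [scan_cluster()] result at that value), and `curve` (data frame of
#'   `epsilon`, `Q_N`, `Q_S`, `n_modules`).
#' @export
select_epsilon <- function(network, grid = seq(0.05, 0.95, by = 0.01),
                           mu = 2) {
  stopifnot(length(grid) >= 1, all(grid > 0), all(grid < 1))
  grid <- sort(grid)
  parts <- lapply(grid, function(e) scan_cluster(network, e, mu))
  qn <- vapply(parts, function(p) modularity_QN(network, p), numeric(1))
  qs <- vapply(parts, function(p) modularity_QS(network, p), numeric(1))
  best <- which.max(qs)  # which.max takes the first (smallest) maximizer
  list(epsilon = grid[best], partition = parts[[best]],
       curve = data.frame(epsilon = grid, Q_N = qn, Q_S = qs,
                          n_modules = vapply(parts, attr, integer(1),
                                             "n_modules")))
}

#' Write a module partition and metric curves
#'
#' `modules.tsv` holds one row per protein (`protein`,
#' `module`: a label or `HUB`/`OUTLIER`); `metrics.tsv` holds the epsilon
#' sweep (`epsilon`, `Q_N`, `Q_S`).
#'
#' @param partition a [scan_cluster()] result.
#' @param curve the `curve` element of [select_epsilon()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_modules_tsv <- function(partition, path) {
  out <- data.frame(protein = partition$protein, module = partition$type,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules_tsv
#' @export
write_metrics_tsv <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
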