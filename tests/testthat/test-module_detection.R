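# SCAN clustering, both modularity metrics, and epsilon selection.

test_that("structural similarity matches hand calculations", {
  g <- igraph::make_graph(~ a - b, b - c)
  expect_equal(structural_similarity(g, "a", "b"), 2 / sqrt(6))
  expect_equal(structural_similarity(g, "a", "b"),
               structural_similarity(g, "b", "a"))
  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  expect_equal(structural_similarity(tri, "a", "b"), 1)
  expect_error(structural_similarity(g, "a", "zz"), "not in network")
})

test_that("SCAN recovers two disjoint triangles as two modules", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  p <- scan_cluster(g, epsilon = 0.5, mu = 2)
  expect_equal(attr(p, "n_modules"), 2L)
  expect_false(any(p$type %in% c("HUB", "OUTLIER")))
  lab <- stats::setNames(p$type, p$protein)
  expect_length(unique(lab[c("a", "b", "c")]), 1L)
  expect_length(unique(lab[c("d", "e", "f")]), 1L)
  expect_false(lab[["a"]] == lab[["d"]])
})

test_that("epsilon above 1 makes every node an outlier", {
  g <- two_triangle_graph()
  p <- scan_cluster(g, epsilon = 1.0001, mu = 2)
  expect_true(all(p$type == "OUTLIER"))
})

test_that("a node bridging two triangles is classified as a hub", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d,
                          g - a, g - d)
  p <- scan_cluster(g, epsilon = 0.8, mu = 2)
  lab <- stats::setNames(p$type, p$protein)
  expect_equal(lab[["g"]], "HUB")
  expect_equal(attr(p, "n_modules"), 2L)
})

test_that("SCAN labels are invariant to edge input order", {
  el <- rbind(c("a", "b"), c("b", "c"), c("c", "a"),
              c("d", "e"), c("e", "f"), c("f", "d"), c("c", "d"))
  g1 <- igraph::graph_from_edgelist(el, directed = FALSE)
  g2 <- igraph::graph_from_edgelist(el[sample(7), c(2, 1)],
                                    directed = FALSE)
  p1 <- scan_cluster(g1, 0.6)
  p2 <- scan_cluster(g2, 0.6)
  expect_identical(p1$type[order(p1$protein)], p2$type[order(p2$protein)])
})

test_that("Newman modularity matches hand arithmetic and igraph", {
  g <- two_triangle_graph()
  p <- two_triangle_partition(g)
  expect_equal(modularity_QN(g, p), 2 * (3 / 7 - (7 / 14)^2),
               tolerance = 1e-12)
  # independent oracle: igraph's modularity on the same membership
  memb <- ppibayes:::partition_membership(g, p)
  expect_equal(modularity_QN(g, p),
               igraph::modularity(g, membership = memb))
  # single module covering the graph scores zero
  p1 <- structure(data.frame(protein = letters[1:6], type = "1",
                             stringsAsFactors = FALSE),
                  epsilon = 0.5, mu = 2, n_modules = 1L,
                  class = c("ppi_modules", "data.frame"))
  expect_equal(modularity_QN(g, p1), 0)
  # all-singletons partition is negative on any graph with edges
  ps <- structure(data.frame(protein = letters[1:6],
                             type = as.character(1:6),
                             stringsAsFactors = FALSE),
                  epsilon = 0.5, mu = 2, n_modules = 6L,
                  class = c("ppi_modules", "data.frame"))
  expect_lt(modularity_QN(g, ps), 0)
})

test_that("Q_N stays within its theoretical range on random partitions", {
  set.seed(42)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(12, 0.35)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("n", 1:12)
    k <- sample(2:4, 1)
    p <- structure(data.frame(protein = paste0("n", 1:12),
                              type = as.character(sample(k, 12, TRUE)),
                              stringsAsFactors = FALSE),
                   epsilon = 0.5, mu = 2, n_modules = as.integer(k),
                   class = c("ppi_modules", "data.frame"))
    q <- modularity_QN(g, p)
    expect_gte(q, -0.5); expect_lt(q, 1)
  }
})

test_that("splitting a clique lowers Newman modularity", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- letters[1:6]
  whole <- structure(data.frame(protein = letters[1:6], type = "1",
                                stringsAsFactors = FALSE),
                     epsilon = 0.5, mu = 2, n_modules = 1L,
                     class = c("ppi_modules", "data.frame"))
  split <- structure(data.frame(protein = letters[1:6],
                                type = as.character(rep(1:2, each = 3)),
                                stringsAsFactors = FALSE),
                     epsilon = 0.5, mu = 2, n_modules = 2L,
                     class = c("ppi_modules", "data.frame"))
  expect_lt(modularity_QN(g, split), modularity_QN(g, whole))
})

test_that("similarity-based modularity generalizes Newman modularity", {
  # all structural similarities equal (vertex-transitive cycle): Q_S = Q_N
  g <- igraph::make_ring(8)
  igraph::V(g)$name <- paste0("r", 1:8)
  p <- structure(data.frame(protein = paste0("r", 1:8),
                            type = as.character(rep(1:2, each = 4)),
                            stringsAsFactors = FALSE),
                 epsilon = 0.5, mu = 2, n_modules = 2L,
                 class = c("ppi_modules", "data.frame"))
  expect_equal(modularity_QS(g, p), modularity_QN(g, p), tolerance = 1e-12)
  # general graph: agrees with igraph's weighted modularity at sigma weights
  g2 <- two_triangle_graph()
  p2 <- two_triangle_partition(g2)
  es <- ppibayes:::edge_similarities(g2)
  memb <- ppibayes:::partition_membership(g2, p2)
  expect_equal(modularity_QS(g2, p2),
               igraph::modularity(g2, membership = memb,
                                  weights = es$sigma))
  # whole-graph module scores zero
  p1 <- structure(data.frame(protein = letters[1:6], type = "1",
                             stringsAsFactors = FALSE),
                  epsilon = 0.5, mu = 2, n_modules = 1L,
                  class = c("ppi_modules", "data.frame"))
  expect_equal(modularity_QS(g2, p1), 0)
})

test_that("epsilon selection maximizes Q_S and recovers planted structure", {
  sel1 <- select_epsilon(two_triangle_graph(), grid = 0.5)
  expect_equal(sel1$epsilon, 0.5)
  # planted partition: two dense communities, sparse between
  set.seed(3)
  pref <- matrix(c(0.9, 0.03, 0.03, 0.9), 2)
  g <- igraph::sample_sbm(30, pref, block.sizes = c(15, 15))
  igraph::V(g)$name <- sprintf("v%02d", 1:30)
  sel <- select_epsilon(g, grid = seq(0.1, 0.9, by = 0.05))
  expect_gt(max(sel$curve$Q_S), 0)
  expect_true(all(sel$curve$Q_S[sel$curve$epsilon == sel$epsilon] >=
                    sel$curve$Q_S - 1e-12))
  part <- sel$partition
  lab <- stats::setNames(part$type, part$protein)
  b1 <- lab[sprintf("v%02d", 1:15)]
  b2 <- lab[sprintf("v%02d", 16:30)]
  mode1 <- names(sort(table(b1), decreasing = TRUE))[1]
  mode2 <- names(sort(table(b2), decreasing = TRUE))[1]
  expect_false(mode1 == mode2)
  expect_gt(mean(b1 == mode1), 0.8)
  expect_gt(mean(b2 == mode2), 0.8)
})

test_that("module tables and metric curves write to TSV", {
  g <- two_triangle_graph()
  sel <- select_epsilon(g, grid = c(0.3, 0.5, 0.7))
  dir <- withr::local_tempdir()
  write_modules_tsv(sel$partition, file.path(dir, "modules.tsv"))
  write_metrics_tsv(sel$curve, file.path(dir, "metrics.tsv"))
  m <- utils::read.delim(file.path(dir, "modules.tsv"))
  expect_equal(nrow(m), 6L)
  k <- utils::read.delim(file.path(dir, "metrics.tsv"))
  expect_equal(k$epsilon, c(0.3, 0.5, 0.7))
})
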