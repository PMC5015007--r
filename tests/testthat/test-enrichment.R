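# Hypergeometric module enrichment and hub composition.

test_that("hypergeometric tail matches hand-computed sums", {
  expect_equal(hypergeom_pvalue(10, 5, 4, 4), 5 / 210)
  expect_equal(hypergeom_pvalue(6, 3, 3, 2), 0.5)  # (9 + 1) / 20
  expect_equal(hypergeom_pvalue(20, 8, 5, 0), 1)
  expect_error(hypergeom_pvalue(10, 11, 4, 2), "require")
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "require")
})

test_that("hypergeometric tail is non-increasing in m and normalized", {
  p <- vapply(0:5, function(m) hypergeom_pvalue(12, 6, 5, m), numeric(1))
  expect_true(all(diff(p) <= 1e-12))
  # point masses sum to one across the support
  for (N in c(8, 15)) for (M in c(3, 7)) for (n in c(4, 6)) {
    lo <- max(0, n - (N - M)); hi <- min(n, M)
    mass <- sum(choose(M, lo:hi) * choose(N - M, n - lo:hi) / choose(N, n))
    expect_equal(mass, 1)
  }
})

test_that("hypergeometric tail agrees with a rational-arithmetic oracle", {
  # exact integer arithmetic: all binomials for N <= 30 are exact doubles
  oracle <- function(N, M, n, m) {
    if (m > min(n, M)) return(0)  # empty sum: no feasible outcome
    i <- seq(m, min(n, M))
    sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
  }
  set.seed(99)
  for (rep in 1:200) {
    N <- sample(1:30, 1); M <- sample(0:N, 1); n <- sample(0:N, 1)
    m <- sample(0:n, 1)
    expect_equal(hypergeom_pvalue(N, M, n, m), oracle(N, M, n, m),
                 tolerance = 1e-12)
  }
})

test_that("disorder annotation applies the strict 40-residue cutoff", {
  ann <- disorder_annotation(data.frame(
    protein_id = c("a", "b", "c"), disorder_length = c(41L, 40L, 0L)))
  expect_identical(ann$is_idp, c(TRUE, FALSE, FALSE))
  expect_error(disorder_annotation(data.frame(
    protein_id = "a", disorder_length = -1)), "non-negative")
})

test_that("module testing delegates to the hypergeometric tail", {
  part <- structure(data.frame(
    protein = paste0("p", 1:20),
    type = c(rep("1", 5), rep("2", 5), rep("OUTLIER", 10)),
    stringsAsFactors = FALSE),
    epsilon = 0.5, mu = 2, n_modules = 2L,
    class = c("ppi_modules", "data.frame"))
  # half the network is IDP; module 1 is all-IDP, module 2 has none
  ann <- data.frame(protein_id = paste0("p", 1:20),
                    disorder_length = c(rep(100L, 5), rep(0L, 5),
                                        rep(c(100L, 0L), 5)))
  res <- test_modules(part, ann)
  expect_equal(res$n, c(5L, 5L))
  expect_equal(res$m[1], 5L)
  expect_equal(res$p_value[1], hypergeom_pvalue(20, 10, 5, 5))
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  # zero IDPs anywhere: every module p-value is exactly 1
  ann0 <- data.frame(protein_id = paste0("p", 1:20), disorder_length = 0L)
  expect_true(all(test_modules(part, ann0)$p_value == 1))
  # unannotated proteins are warned about and treated as non-IDP
  expect_warning(test_modules(part, ann[1:15, ]), "lack disorder")
  # Benjamini-Hochberg flag weakens borderline calls
  resbh <- test_modules(part, ann, correction = "BH")
  expect_equal(resbh$p_value, res$p_value)
})

test_that("hub IDP fraction counts induced-subgraph hubs", {
  g <- igraph::make_star(7, mode = "undirected", center = 1)
  igraph::V(g)$name <- paste0("s", 1:7)
  ann_idp <- data.frame(protein_id = paste0("s", 1:7),
                        disorder_length = c(90L, rep(0L, 6)))
  expect_equal(hub_idp_fraction(g, paste0("s", 1:7), ann_idp), 1.0)
  ann_no <- data.frame(protein_id = paste0("s", 1:7), disorder_length = 0L)
  expect_equal(hub_idp_fraction(g, paste0("s", 1:7), ann_no), 0.0)
  # two degree-6 hubs, one an IDP
  g2 <- igraph::make_full_bipartite_graph(2, 8)
  igraph::V(g2)$name <- c("h1", "h2", paste0("t", 1:8))
  ann2 <- data.frame(protein_id = igraph::V(g2)$name,
                     disorder_length = c(100L, 0L, rep(0L, 8)))
  expect_equal(hub_idp_fraction(g2, igraph::V(g2)$name, ann2), 0.5)
  # degree cutoff is strict and absence of hubs is an error
  expect_error(hub_idp_fraction(g, paste0("s", 2:7), ann_idp), "no hubs")
  # induced = FALSE uses whole-network degrees
  expect_equal(hub_idp_fraction(g, paste0("s", 1:7), ann_idp,
                                induced = FALSE), 1.0)
})

test_that("the planted IDP-rich community is flagged significant", {
  cfg <- ppi_sim_config(n_proteins = 80, seed = 17,
                        communities = c(15, 15), p_within = 0.5,
                        idp_rates = c(0.9, 0.1), idp_background = 0.1,
                        n_homolog_organisms = 0, n_baits = 5)
  truth <- sample_ground_truth(cfg)
  ann <- disorder_annotation(sample_disorder(truth, cfg))
  # cluster the true graph directly (clustering is tested elsewhere)
  Z <- truth$state$Z$human
  g <- igraph::graph_from_adjacency_matrix(Z, mode = "undirected")
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  sel <- select_epsilon(g, grid = seq(0.2, 0.8, by = 0.05))
  res <- test_modules(sel$partition, ann)
  lab <- stats::setNames(sel$partition$type, sel$partition$protein)
  planted <- names(truth$communities)[truth$communities %in% 1]
  planted_mod <- names(sort(table(lab[planted]), decreasing = TRUE))[1]
  expect_true(res$significant[res$module == planted_mod])
})
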