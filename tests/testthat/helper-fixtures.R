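# Shared fixtures: all built in code, deterministic under fixed seeds.

# a small evidence set exercising all four evidence types at once
tiny_full_evidence <- function() {
  ppi_evidence(
    y2h = rbind(
      data.frame(protein_a = c("A", "A", "B"), protein_b = c("B", "C", "C"),
                 source_id = "y2h_h", replicate = 1L,
                 observed = c(1L, 0L, 1L), organism = "human"),
      data.frame(protein_a = "A*", protein_b = "B*", source_id = "y2h_s",
                 replicate = 1L, observed = 1L, organism = "org1")),
    complexes = data.frame(bait = "A", members = "B", experiment_id = "e1",
                           organism = "human"),
    literature = data.frame(protein_a = c("A", "A"), protein_b = c("B", "B"),
                            channel = c("H", "L"), observed = c(1L, 0L)),
    homology = data.frame(human_protein = c("A", "B"),
                          ortholog = c("A*", "B*"), organism = "org1",
                          identity = c(0.9, 0.7)))
}

tiny_theta <- function(...) {
  ppi_params(rho = 0.05, r = 0.1, alpha_I = 0.8, alpha_S = 0.3,
             alpha_U = 0.01, psi1 = 0.8, psi2 = 0.4,
             gamma1 = 0.8, gamma0 = 0.05, beta1 = 0.6, beta0 = 0.02,
             phi1 = 0.7, phi0 = 0.05, lambda1 = 0.7, lambda0 = 0.02, ...)
}

# random small instance with all evidence types, for oracle-agreement tests
random_tiny_instance <- function(seed, n_prot = 3, n_star = 2) {
  set.seed(seed)
  ids <- LETTERS[seq_len(n_prot)]
  prs <- t(utils::combn(ids, 2))
  y2h <- data.frame(protein_a = prs[, 1], protein_b = prs[, 2],
                    source_id = "y", replicate = 1L,
                    observed = stats::rbinom(nrow(prs), 1, 0.4),
                    organism = "human", stringsAsFactors = FALSE)
  lit_keep <- stats::runif(nrow(prs)) < 0.7
  lit <- if (any(lit_keep))
    data.frame(protein_a = prs[lit_keep, 1], protein_b = prs[lit_keep, 2],
               channel = sample(c("H", "L"), sum(lit_keep), replace = TRUE),
               observed = stats::rbinom(sum(lit_keep), 1, 0.4),
               stringsAsFactors = FALSE) else NULL
  bait <- sample(ids, 1)
  members <- sample(setdiff(ids, bait), stats::rbinom(1, n_prot - 1, 0.5))
  cx <- data.frame(bait = bait, members = paste(members, collapse = ","),
                   experiment_id = "e", organism = "human",
                   stringsAsFactors = FALSE)
  mapped <- sample(ids, n_star)
  hom <- data.frame(human_protein = mapped,
                    ortholog = paste0(mapped, "*"), organism = "org1",
                    identity = stats::runif(n_star, 0.4, 1),
                    stringsAsFactors = FALSE)
  star_y2h <- if (n_star >= 2) {
    sp <- t(utils::combn(paste0(mapped, "*"), 2))
    data.frame(protein_a = sp[, 1], protein_b = sp[, 2], source_id = "ys",
               replicate = 1L, observed = stats::rbinom(nrow(sp), 1, 0.4),
               organism = "org1", stringsAsFactors = FALSE)
  } else NULL
  ppi_evidence(y2h = rbind(y2h, star_y2h), complexes = cx,
               literature = lit, homology = hom)
}

# two triangles joined by a single edge (7 edges); the canonical
# modularity example
two_triangle_graph <- function() {
  igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d, c - d)
}

two_triangle_partition <- function(g) {
  structure(data.frame(protein = letters[1:6],
                       type = as.character(rep(1:2, each = 3)),
                       stringsAsFactors = FALSE),
            epsilon = 0.5, mu = 2, n_modules = 2L,
            class = c("ppi_modules", "data.frame"))
}

# cached medium simulation + fit shared by the acceptance blocks
.accept_cache <- new.env(parent = emptyenv())

recovery_sim <- function() {
  if (is.null(.accept_cache$sim))
    .accept_cache$sim <- ppi_simulate(ppi_sim_config(seed = 11))
  .accept_cache$sim
}

recovery_fit <- function() {
  if (is.null(.accept_cache$fit))
    .accept_cache$fit <- ppi_fit(recovery_sim()$evidence, seed = 2,
                                 verbose = FALSE)
  .accept_cache$fit
}
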