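#' Simulation configuration
#'
#' Describes a synthetic study: the size of the human proteome slice, the
#' true parameter vector, the coverage and replication of each evidence
#' type, the homolog landscape, and (optionally) planted communities with
#' elevated intrinsically-disordered-protein (IDP) frequency that give the
#' clustering and enrichment stages a known positive control.
#'
#' Defaults emulate a desk-scale version of a genome-wide evidence
#' landscape: two Y2H replicates over all pairs, pull-downs for 100 baits,
#' complete literature indicator coverage on both channels, and one other
#' organism in which 60% of proteins have an ortholog with sequence
#' identity uniform on `[0.3, 1]`.
#'
#' @param n_proteins number of human proteins.
#' @param theta_true a [ppi_params()] object; the generative parameters.
#' @param n_y2h_replicates Y2H replicates per screened pair.
#' @param y2h_coverage fraction of pairs screened by Y2H.
#' @param n_baits number of human pull-down baits; other organisms get half.
#' @param n_homolog_organisms number of other organisms.
#' @param ortholog_fraction fraction of human proteins with an ortholog in
#'   each other organism.
#' @param identity_distribution range `c(lo, hi)` of the uniform sequence
#'   identity distribution.
#' @param lit_coverage named vector `c(H = , L = )` of literature indicator
#'   coverage fractions per channel.
#' @param communities optional integer vector of planted community sizes
#'   (assigned to the first `sum(communities)` proteins); within-community
#'   pairs interact with probability `p_within` instead of `rho`.
#' @param p_within within-community interaction probability.
#' @param idp_rates optional per-community IDP frequencies (recycled);
#'   proteins outside communities use `idp_background`.
#' @param idp_background background IDP frequency.
#' @param seed integer seed; all sampling is reproducible from it.
#'
#' @return An object of class `ppi_sim_config` (a list).
#' @export
ppi_sim_config <- function(n_proteins = 500,
                           theta_true = ppi_params(
                             rho = 0.01, r = 0.02,
                             alpha_I = 0.9, alpha_S = 0.4, alpha_U = 0.005,
                             psi1 = 0.8, psi2 = 0.4,
                             gamma1 = 0.8, gamma0 = 0.01,
                             beta1 = 0.6, beta0 = 0.005,
                             phi1 = 0.7, phi0 = 0.01,
                             lambda1 = 0.7, lambda0 = 0.001),
                           n_y2h_replicates = 2,
                           y2h_coverage = 1.0,
                           n_baits = 100,
                           n_homolog_organisms = 1,
                           ortholog_fraction = 0.6,
                           identity_distribution = c(0.3, 1.0),
                           lit_coverage = c(H = 1.0, L = 1.0),
                           communities = NULL,
                           p_within = 0.35,
                           idp_rates = NULL,
                           idp_background = 0.12,
                           seed = 1L) {
  stopifnot(n_proteins >= 2, n_y2h_replicates >= 1,
            y2h_coverage >= 0, y2h_coverage <= 1,
            n_baits >= 0, n_homolog_organisms >= 0,
            ortholog_fraction >= 0, ortholog_fraction <= 1,
            length(identity_distribution) == 2,
            all(lit_coverage >= 0), all(lit_coverage <= 1))
  if (!is.null(communities) && sum(communities) > n_proteins)
    stop("planted communities exceed the proteome size")
  structure(list(n_proteins = as.integer(n_proteins), theta_true = theta_true,
                 n_y2h_replicates = as.integer(n_y2h_replicates),
                 y2h_coverage = y2h_coverage, n_baits = as.integer(n_baits),
                 n_homolog_organisms = as.integer(n_homolog_organisms),
                 ortholog_fraction = ortholog_fraction,
                 identity_distribution = identity_distribution,
                 lit_coverage = lit_coverage,
                 communities = communities, p_within = p_within,
                 idp_rates = idp_rates, idp_background = idp_background,
                 seed = as.integer(seed)),
            class = "ppi_sim_config")
}

sim_protein_ids <- function(n) sprintf("P%0*d", nchar(n), seq_len(n))
sim_star_ids <- function(human_ids, g) paste0(human_ids, "*", g)

# upper-triangle pair enumeration (i < j), by column-major upper.tri order
all_pairs <- function(n) {
  j <- rep(2:n, 1:(n - 1))
  i <- sequence(1:(n - 1))
  cbind(i, j)
}

#' Sample a ground-truth latent state
#'
#' Forward-samples the latent state of the generative model: human
#' interactions `Z ~ Bernoulli(rho)` (or `p_within` inside planted
#' communities), self-activations `X ~ Bernoulli(r)`, and, for each other
#' organism, ortholog assignments with uniform sequence identities and
#' starred states drawn through the homology-transfer factors.
#'
#' @param config a [ppi_sim_config()] object.
#' @return An object of class `ppi_truth`: list with elements `state`
#'   ([ppi_state()]), `universe`, `homology`, `communities` (integer label
#'   per human protein, `NA` outside communities), and `config`.
#' @export
sample_ground_truth <- function(config) {
  stopifnot(inherits(config, "ppi_sim_config"))
  set.seed(config$seed)
  th <- config$theta_true
  n <- config$n_proteins
  ids <- sim_protein_ids(n)

  comm <- rep(NA_integer_, n)
  if (!is.null(config$communities)) {
    comm[seq_len(sum(config$communities))] <-
      rep(seq_along(config$communities), config$communities)
  }

  prs <- all_pairs(n)
  p_edge <- rep(th$rho, nrow(prs))
  if (!is.null(config$communities)) {
    same <- !is.na(comm[prs[, 1]]) & !is.na(comm[prs[, 2]]) &
      comm[prs[, 1]] == comm[prs[, 2]]
    p_edge[same] <- config$p_within
  }
  zvec <- stats::rbinom(nrow(prs), 1L, p_edge)
  Z <- matrix(0L, n, n, dimnames = list(ids, ids))
  Z[prs[zvec == 1L, , drop = FALSE]] <- 1L
  Z <- Z + t(Z)
  X <- stats::setNames(stats::rbinom(n, 1L, th$r), ids)

  uni <- data.frame(protein = ids, organism = "human",
                    stringsAsFactors = FALSE)
  hom <- data.frame(human_protein = character(), ortholog = character(),
                    organism = character(), identity = numeric(),
                    stringsAsFactors = FALSE)
  state <- structure(list(Z = list(human = Z),
                          X = list(human = as.integer(X))), class = "ppi_state")
  names(state$X$human) <- ids

  for (g in seq_len(config$n_homolog_organisms)) {
    org <- paste0("org", g)
    k <- round(config$ortholog_fraction * n)
    mapped <- sort(sample.int(n, k))
    hids <- ids[mapped]
    sids <- sim_star_ids(hids, g)
    idv <- stats::runif(k, config$identity_distribution[1],
                        config$identity_distribution[2])
    hom <- rbind(hom, data.frame(human_protein = hids, ortholog = sids,
                                 organism = org, identity = idv,
                                 stringsAsFactors = FALSE))
    uni <- rbind(uni, data.frame(protein = sids, organism = org,
                                 stringsAsFactors = FALSE))
    # starred state via transfer
    if (k >= 2) {
      sprs <- all_pairs(k)
      zh <- Z[cbind(mapped[sprs[, 1]], mapped[sprs[, 2]])]
      J <- joint_identity(idv[sprs[, 1]], idv[sprs[, 2]])
      p1 <- transfer_prob(zh, J, "interaction", th)
      zs <- stats::rbinom(nrow(sprs), 1L, p1)
      Zs <- matrix(0L, k, k, dimnames = list(sids, sids))
      Zs[sprs[zs == 1L, , drop = FALSE]] <- 1L
      Zs <- Zs + t(Zs)
    } else Zs <- matrix(0L, k, k, dimnames = list(sids, sids))
    p1x <- transfer_prob(X[mapped], idv, "self_activation", th)
    Xs <- stats::setNames(stats::rbinom(k, 1L, p1x), sids)
    state$Z[[org]] <- Zs
    state$X[[org]] <- Xs
  }

  structure(list(state = state, universe = uni, homology = hom,
                 communities = stats::setNames(comm, ids), config = config),
            class = "ppi_truth")
}

#' @export
print.ppi_truth <- function(x, ...) {
  cat("Simulated ground truth (seed ", x$config$seed, ")\n", sep = "")
  print(x$state)
  if (any(!is.na(x$communities)))
    cat("  planted communities:",
        paste(table(x$communities), collapse = ", "), "\n")
  invisible(x)
}

sim_y2h_block <- function(Z, X, ids, coverage, n_rep, theta, source_id,
                          organism) {
  n <- length(ids)
  if (n < 2 || coverage <= 0 || n_rep < 1)
    return(NULL)
  prs <- all_pairs(n)
  if (coverage < 1) {
    keep <- sample.int(nrow(prs), round(coverage * nrow(prs)))
    prs <- prs[sort(keep), , drop = FALSE]
  }
  if (!nrow(prs)) return(NULL)
  z <- Z[prs]
  p <- y2h_response_prob(z, X[prs[, 1]], X[prs[, 2]], theta)
  m <- nrow(prs)
  obs <- stats::rbinom(m * n_rep, 1L, rep(p, each = n_rep))
  data.frame(protein_a = rep(ids[prs[, 1]], each = n_rep),
             protein_b = rep(ids[prs[, 2]], each = n_rep),
             source_id = source_id,
             replicate = rep(seq_len(n_rep), m),
             observed = obs, organism = organism,
             stringsAsFactors = FALSE)
}

sim_complex_block <- function(Z, ids, n_baits, theta, organism) {
  if (n_baits < 1) return(NULL)
  deg <- rowSums(Z)
  eligible <- which(deg > 0)
  if (!length(eligible)) return(NULL)
  baits <- sample(eligible, n_baits, replace = length(eligible) < n_baits)
  rows <- vector("list", n_baits)
  for (b in seq_len(n_baits)) {
    k <- baits[b]
    n1 <- which(Z[k, ] == 1L)
    nbr2 <- which(colSums(Z[n1, , drop = FALSE]) > 0)
    n2 <- setdiff(nbr2, c(n1, k))
    far <- setdiff(seq_along(ids), c(n1, n2, k))
    cap1 <- n1[stats::runif(length(n1)) < theta$psi1]
    cap2 <- n2[stats::runif(length(n2)) < theta$psi2]
    nfar <- stats::rbinom(1L, length(far), theta$psi_bg)
    capf <- if (nfar > 0) sample(far, nfar) else integer()
    members <- ids[sort(c(cap1, cap2, capf))]
    rows[[b]] <- data.frame(bait = ids[k],
                            members = paste(members, collapse = ","),
                            experiment_id = sprintf("mpc_%s_%03d", organism, b),
                            organism = organism, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Sample an evidence set from a ground truth
#'
#' Forward-samples all four evidence types from a [sample_ground_truth()]
#' draw under the generative model: Y2H replicates per
#' [y2h_response_prob()], one pull-down complex per bait (baits drawn
#' uniformly from proteins with at least one true neighbour; 1-/2-step
#' neighbours captured with `psi1`/`psi2`, distant proteins with `psi_bg`),
#' literature indicators for both channels, and the same again inside each
#' other organism. Sampling is reproducible from `config$seed`.
#'
#' @param truth a `ppi_truth` object.
#' @param config a [ppi_sim_config()] object (defaults to the one stored in
#'   `truth`).
#' @return A [ppi_evidence()] object.
#' @export
sample_evidence <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ppi_truth"))
  set.seed(config$seed + 1L)
  th <- config$theta_true
  st <- truth$state
  ids <- rownames(st$Z$human)

  y2h <- sim_y2h_block(st$Z$human, st$X$human, ids, config$y2h_coverage,
                       config$n_y2h_replicates, th, "y2h_human", "human")
  cplx <- sim_complex_block(st$Z$human, ids, config$n_baits, th, "human")

  lit <- NULL
  n <- length(ids)
  prs <- all_pairs(n)
  for (ch in c("H", "L")) {
    cov <- unname(config$lit_coverage[ch])
    if (is.na(cov) || cov <= 0) next
    keep <- if (cov < 1)
      sort(sample.int(nrow(prs), round(cov * nrow(prs)))) else
        seq_len(nrow(prs))
    sub <- prs[keep, , drop = FALSE]
    z <- st$Z$human[sub]
    rates <- if (ch == "H") c(th$gamma1, th$gamma0) else c(th$beta1, th$beta0)
    p1 <- rates[1]^z * rates[2]^(1 - z)
    lit <- rbind(lit, data.frame(protein_a = ids[sub[, 1]],
                                 protein_b = ids[sub[, 2]],
                                 channel = ch,
                                 observed = stats::rbinom(nrow(sub), 1L, p1),
                                 stringsAsFactors = FALSE))
  }

  for (org in setdiff(names(st$Z), "human")) {
    sids <- rownames(st$Z[[org]])
    y2h <- rbind(y2h, sim_y2h_block(st$Z[[org]], st$X[[org]], sids,
                                    config$y2h_coverage,
                                    config$n_y2h_replicates, th,
                                    paste0("y2h_", org), org))
    cplx <- rbind(cplx, sim_complex_block(st$Z[[org]], sids,
                                          max(1L, config$n_baits %/% 2L),
                                          th, org))
  }

  ppi_evidence(y2h = y2h, complexes = cplx, literature = lit,
               homology = truth$homology, universe = truth$universe)
}

#' Sample disorder annotations with planted module enrichment
#'
#' Assigns each human protein a longest-continuous-disordered-region length.
#' Proteins are IDPs (length > 40 aa) with frequency `idp_rates[c]` inside
#' planted community `c` and `idp_background` elsewhere; IDP lengths are
#' uniform on 41–300 aa, non-IDP lengths uniform on 0–40 aa.
#'
#' @inheritParams sample_evidence
#' @return A data frame with columns `protein_id`, `disorder_length`.
#' @export
sample_disorder <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ppi_truth"))
  set.seed(config$seed + 2L)
  ids <- names(truth$communities)
  rate <- rep(config$idp_background, length(ids))
  if (!is.null(config$idp_rates)) {
    cc <- truth$communities
    planted <- !is.na(cc)
    rates <- rep_len(config$idp_rates, max(cc, na.rm = TRUE))
    rate[planted] <- rates[cc[planted]]
  }
  is_idp <- stats::runif(length(ids)) < rate
  len <- ifelse(is_idp, sample(41:300, length(ids), replace = TRUE),
                sample(0:40, length(ids), replace = TRUE))
  data.frame(protein_id = ids, disorder_length = as.integer(len),
             stringsAsFactors = FALSE)
}

#' Run a full forward simulation
#'
#' Convenience wrapper: [sample_ground_truth()], [sample_evidence()] and
#' [sample_disorder()] from one configuration.
#'
#' @param config a [ppi_sim_config()] object.
#' @return A list of class `ppi_sim` with elements `truth`, `evidence`,
#'   `disorder` and `config`.
#' @export
ppi_simulate <- function(config = ppi_sim_config()) {
  truth <- sample_ground_truth(config)
  evidence <- sample_evidence(truth, config)
  disorder <- sample_disorder(truth, config)
  structure(list(truth = truth, evidence = evidence, disorder = disorder,
                 config = config), class = "ppi_sim")
}

#' Write simulation outputs to a directory
#'
#' Writes the evidence TSVs (see [write_evidence()]) plus
#' `ground_truth_edges.tsv`, `ground_truth_params.tsv`, `disorder.tsv` and
#' a `manifest.tsv` recording the seed and configuration scalars.
#'
#' @param sim a [ppi_simulate()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ppi_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_evidence(sim$evidence, dir)
  utils::write.table(state_edges(sim$truth$state, "human"),
                     file.path(dir, "ground_truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  th <- sim$config$theta_true
  utils::write.table(data.frame(component = .learnable,
                                value = unlist(th[.learnable])),
                     file.path(dir, "ground_truth_params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$disorder, file.path(dir, "disorder.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  scalars <- c(seed = cfg$seed, n_proteins = cfg$n_proteins,
               n_y2h_replicates = cfg$n_y2h_replicates,
               y2h_coverage = cfg$y2h_coverage, n_baits = cfg$n_baits,
               n_homolog_organisms = cfg$n_homolog_organisms,
               ortholog_fraction = cfg$ortholog_fraction)
  utils::write.table(data.frame(key = names(scalars), value = unname(scalars)),
                     file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
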