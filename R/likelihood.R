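#' Probability that a Y2H replicate reports positive
#'
#' A single yeast two-hybrid replicate on pair (i, j) reports positive if at
#' least one of three mechanisms fires: a true interaction (probability
#' `alpha_I`, available only when `z = 1`), self-activation (probability
#' `alpha_S` per self-activating partner), or an unknown background process
#' (probability `alpha_U`). The response probability is
#' `1 - (1 - alpha_I)^z * (1 - alpha_S)^(x_i + x_j) * (1 - alpha_U)`.
#'
#' With `selfact_mode = "indicator"` on `theta`, the self-activation
#' exponent is `min(x_i + x_j, 1)` instead: the mechanism fires at most once
#' per pair regardless of how many partners self-activate.
#'
#' @param z 0/1, true interaction status of the pair.
#' @param x_i,x_j 0/1, self-activation status of the two partners.
#' @param theta a [ppi_params()] object.
#' @return Probability of a positive replicate (vectorized over `z`,
#'   `x_i`, `x_j`).
#' @export
#' @examples
#' th <- ppi_params(alpha_I = 0.933, alpha_U = 0.007)
#' y2h_response_prob(1, 0, 0, th)
y2h_response_prob <- function(z, x_i, x_j, theta) {
  s <- x_i + x_j
  if (identical(attr(theta, "selfact_mode"), "indicator")) s <- pmin(s, 1)
  1 - (1 - theta$alpha_I)^z * (1 - theta$alpha_S)^s * (1 - theta$alpha_U)
}

# graph-distance classes of all proteins relative to a bait, from a
# symmetric 0/1 matrix: 1 = direct neighbour, 2 = two steps, 3 = farther
bait_neighbourhoods <- function(Z, bait) {
  n1 <- which(Z[bait, ] == 1L)
  nbr2 <- if (length(n1)) which(colSums(Z[n1, , drop = FALSE]) > 0) else integer()
  bi <- match(bait, rownames(Z))
  n2 <- setdiff(nbr2, c(n1, bi))
  list(n1 = rownames(Z)[n1], n2 = rownames(Z)[n2])
}

#' Log-likelihood of one observed pull-down complex
#'
#' A bait's pull-down captures each of its 1-step neighbours (under the
#' latent interaction graph) independently with probability `psi1`, each
#' 2-step neighbour with probability `psi2`, and — occasionally — proteins
#' at distance three or more with a small fixed background probability
#' `psi_bg`. Missed 1- and 2-step neighbours contribute `(1 - psi)` factors;
#' no factor is charged for distant proteins that were not observed.
#'
#' @param bait protein identifier of the bait.
#' @param observed character vector of complex members (bait excluded).
#' @param state a [ppi_state()] object supplying the interaction graph.
#' @param theta a [ppi_params()] object (components `psi1`, `psi2`,
#'   `psi_bg`).
#' @param organism organism whose latent graph the bait lives in.
#' @return The log-probability of observing exactly this member set.
#' @export
#' @examples
#' uni <- data.frame(protein = c("K", "A", "B", "C"), organism = "human")
#' st <- ppi_state(uni, edges = data.frame(protein_a = c("K", "K", "A"),
#'                                         protein_b = c("A", "B", "C")))
#' th <- ppi_params(psi1 = 0.8, psi2 = 0.6)
#' complex_log_likelihood("K", c("A", "C"), st, th)  # log(0.8 * 0.2 * 0.6)
complex_log_likelihood <- function(bait, observed, state, theta,
                                   organism = "human") {
  Z <- state$Z[[organism]]
  if (is.null(Z) || !(bait %in% rownames(Z)))
    stop("bait '", bait, "' is not in the universe of organism '",
         organism, "'")
  observed <- setdiff(as.character(observed), bait)
  nb <- bait_neighbourhoods(Z, bait)
  n_far <- length(setdiff(observed, c(nb$n1, nb$n2)))
  a1 <- length(intersect(nb$n1, observed))
  b1 <- length(nb$n1) - a1
  a2 <- length(intersect(nb$n2, observed))
  b2 <- length(nb$n2) - a2
  a1 * log(theta$psi1) + b1 * log1p(-theta$psi1) +
    a2 * log(theta$psi2) + b2 * log1p(-theta$psi2) +
    n_far * log(theta$psi_bg)
}

#' Log-probability of a literature report indicator
#'
#' A literature channel reports an interaction with probability `rate_pos`
#' when the pair truly interacts and `rate_neg` (the false positive rate)
#' when it does not: `Pr[report = 1 | z] = rate_pos^z * rate_neg^(1 - z)`.
#' Channel H uses rates `(gamma1, gamma0)`, channel L `(beta1, beta0)`.
#'
#' @param observed 0/1 report indicator.
#' @param z 0/1 latent interaction status.
#' @param rate_pos,rate_neg report probabilities given `z = 1` / `z = 0`.
#' @return Log-probability of the observed indicator (vectorized).
#' @export
#' @examples
#' literature_log_prob(1, 1, 0.8, 0.01)  # log(0.8)
literature_log_prob <- function(observed, z, rate_pos, rate_neg) {
  p1 <- rate_pos^z * rate_neg^(1 - z)
  ifelse(observed == 1, log(p1), log1p(-p1))
}

#' Homology transfer probability
#'
#' Probability that the latent status of a homologous pair (or protein) in
#' another organism is 1, given the human status. In the default
#' `"constant"` parameterization the transfer rates are the bare parameters
#' (`phi1`/`phi0` for interactions, `lambda1`/`lambda0` for
#' self-activation) and the sequence identity is ignored. In the
#' `"logistic"` parameterization (set on `theta`, see [ppi_params()]) each
#' rate is `plogis(a + b * identity)` with `b >= 0`, so transfer becomes
#' monotonically more faithful with sequence identity. For interacting
#' pairs the identity argument is the joint identity
#' `J = sqrt(I_ii' * I_jj')` of the two aligned protein pairs.
#'
#' @param z 0/1 human latent status (vectorized).
#' @param identity joint (pairs) or single (proteins) sequence identity in
#'   `[0, 1]`; unused in constant mode.
#' @param mode `"interaction"` or `"self_activation"`.
#' @param theta a [ppi_params()] object.
#' @return `Pr[starred status = 1 | z]`.
#' @export
#' @examples
#' transfer_prob(1, 0.9, "interaction", ppi_params(phi1 = 0.7))  # 0.7
transfer_prob <- function(z, identity,
                          mode = c("interaction", "self_activation"), theta) {
  mode <- match.arg(mode)
  tm <- attr(theta, "transfer_mode")
  if (identical(tm, "logistic")) {
    cf <- attr(theta, "logistic_coef")
    key <- if (mode == "interaction") c("phi1", "phi0") else
      c("lambda1", "lambda0")
    d1 <- stats::plogis(cf[[key[1]]][1] + cf[[key[1]]][2] * identity)
    d0 <- stats::plogis(cf[[key[2]]][1] + cf[[key[2]]][2] * identity)
  } else {
    if (mode == "interaction") { d1 <- theta$phi1; d0 <- theta$phi0 }
    else { d1 <- theta$lambda1; d0 <- theta$lambda0 }
  }
  d1^z * d0^(1 - z)
}

# joint sequence identity of a homologous pair of pairs
joint_identity <- function(I_a, I_b) sqrt(I_a * I_b)

#' Log prior of the human latent state
#'
#' Independent Bernoulli priors: each unordered human pair interacts with
#' probability `rho` and each human protein self-activates with probability
#' `r`. Starred states are not included here — their prior is the homology
#' transfer factor, handled by [complete_log_likelihood()].
#'
#' @param state a [ppi_state()] object.
#' @param theta a [ppi_params()] object.
#' @return Log prior probability of the human `(Z, X)`.
#' @export
prior_log_prob <- function(state, theta) {
  Z <- state$Z$human; X <- state$X$human
  n_edge <- sum(Z[upper.tri(Z)])
  n_pair <- length(Z[upper.tri(Z)])
  n_x <- sum(X)
  xlogy <- function(k, p) if (k == 0) 0 else k * log(p)
  xlogy(n_edge, theta$rho) + xlogy(n_pair - n_edge, 1 - theta$rho) +
    xlogy(n_x, theta$r) + xlogy(length(X) - n_x, 1 - theta$r)
}

# homology lookup tables for one organism: ortholog and identity indexed
# by human protein, plus the reverse map
homology_tables <- function(ev, organism) {
  h <- ev$homology[ev$homology$organism == organism, , drop = FALSE]
  if (anyDuplicated(h$human_protein) || anyDuplicated(h$ortholog)) {
    warning("duplicate homolog mapping(s) for organism '", organism,
            "'; keeping the first")
    h <- h[!duplicated(h$human_protein), , drop = FALSE]
    h <- h[!duplicated(h$ortholog), , drop = FALSE]
  }
  list(ortholog = stats::setNames(h$ortholog, h$human_protein),
       identity = stats::setNames(h$identity, h$human_protein),
       human = stats::setNames(h$human_protein, h$ortholog))
}

#' Complete log-likelihood of the hierarchical model
#'
#' Sum of the log factors of the full generative model at a given latent
#' state: Y2H replicate factors (human and other organisms), pull-down
#' complex factors, literature channels H and L, homology-transfer factors
#' tying starred states to the human state, and the Bernoulli priors on the
#' human state. Starred pairs or proteins without a homolog mapping fall
#' back to the `rho` / `r` priors.
#'
#' Per-source parameter overrides on `theta` (see [ppi_params()]) are keyed
#' by `source_id` for Y2H records, `experiment_id` for complexes and the
#' channel (`"H"`/`"L"`) for literature records.
#'
#' @param state a [ppi_state()] covering the evidence universe.
#' @param evidence a [ppi_evidence()] object.
#' @param theta a [ppi_params()] object.
#' @return The complete log-likelihood (a scalar).
#' @export
complete_log_likelihood <- function(state, evidence, theta) {
  uni <- evidence$universe
  for (o in unique(uni$organism)) {
    prots <- uni$protein[uni$organism == o]
    if (is.null(state$Z[[o]]) || !all(prots %in% rownames(state$Z[[o]])))
      stop("state does not cover the evidence universe for organism '", o, "'")
  }
  ll <- prior_log_prob(state, theta)

  # Y2H replicates, any organism
  y <- evidence$y2h
  if (nrow(y)) {
    for (k in seq_len(nrow(y))) {
      o <- y$organism[k]
      th <- theta_for_source(theta, y$source_id[k])
      z <- state$Z[[o]][y$protein_a[k], y$protein_b[k]]
      p <- y2h_response_prob(z, state$X[[o]][y$protein_a[k]],
                             state$X[[o]][y$protein_b[k]], th)
      ll <- ll + if (y$observed[k] == 1) log(p) else log1p(-p)
    }
  }

  # pull-down complexes, any organism
  cx <- evidence$complexes
  if (nrow(cx)) {
    mem <- parse_members(cx$members)
    for (k in seq_len(nrow(cx))) {
      th <- theta_for_source(theta, cx$experiment_id[k])
      ll <- ll + complex_log_likelihood(cx$bait[k], mem[[k]], state, th,
                                        organism = cx$organism[k])
    }
  }

  # literature channels (human pairs)
  lit <- evidence$literature
  if (nrow(lit)) {
    for (k in seq_len(nrow(lit))) {
      th <- theta_for_source(theta, lit$channel[k])
      rates <- if (lit$channel[k] == "H") c(th$gamma1, th$gamma0) else
        c(th$beta1, th$beta0)
      z <- state$Z$human[lit$protein_a[k], lit$protein_b[k]]
      ll <- ll + literature_log_prob(lit$observed[k], z, rates[1], rates[2])
    }
  }

  # homology transfer: starred states given the human state
  for (o in setdiff(names(state$Z), "human")) {
    tab <- homology_tables(evidence, o)
    Zs <- state$Z[[o]]; Xs <- state$X[[o]]
    prots <- rownames(Zs)
    mapped <- prots[prots %in% names(tab$human)]
    # proteins
    for (a in prots) {
      if (a %in% names(tab$human)) {
        h <- tab$human[[a]]
        p1 <- transfer_prob(state$X$human[h], tab$identity[[h]],
                            "self_activation", theta)
      } else p1 <- theta$r
      ll <- ll + if (Xs[a] == 1) log(p1) else log1p(-p1)
    }
    # pairs
    if (length(prots) > 1) {
      for (ai in seq_len(length(prots) - 1)) {
        for (bi in (ai + 1):length(prots)) {
          a <- prots[ai]; b <- prots[bi]
          if (a %in% mapped && b %in% mapped) {
            ha <- tab$human[[a]]; hb <- tab$human[[b]]
            J <- joint_identity(tab$identity[[ha]], tab$identity[[hb]])
            p1 <- transfer_prob(state$Z$human[ha, hb], J, "interaction", theta)
          } else p1 <- theta$rho
          ll <- ll + if (Zs[a, b] == 1) log(p1) else log1p(-p1)
        }
      }
    }
  }
  unname(ll)
}
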