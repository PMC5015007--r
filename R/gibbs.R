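#' Monte Carlo E-step: Gibbs sampling of the latent state
#'
#' Runs the compiled Gibbs sampler at fixed parameters: `n_burnin` discarded
#' sweeps followed by `n_samples` retained sweeps, each sweep resampling
#' every latent variable (human and starred `Z` and `X`) once from its full
#' conditional in a deterministic scan order. Returns Monte Carlo estimates
#' of the expected sufficient statistics consumed by [m_step()].
#'
#' @param evidence a [ppi_evidence()] object.
#' @param theta a [ppi_params()] object (clipped to the open unit interval
#'   internally so every conditional is proper).
#' @param n_burnin,n_samples positive sweep counts.
#' @param seed integer seed; fixed seed gives identical statistics.
#' @param index prebuilt internal evidence index (for repeated calls).
#' @param init warm-start latent state (the `final` element of a previous
#'   result); defaults to the all-zero state.
#'
#' @return An object of class `ppi_estats`: list with per-pair posterior
#'   mean `zmean`, per-protein `xmean`, the Y2H outcome count table
#'   `y2h_tab` (group x z x (x_i + x_j) x outcome), literature and
#'   pull-down capture count matrices, homology-transfer count vectors,
#'   and the final latent state for warm starts.
#' @seealso [m_step()], [score_posteriors()], [ppi_fit()]
#' @export
e_step <- function(evidence, theta, n_burnin = 50, n_samples = 100,
                   seed = 1, index = NULL, init = NULL) {
  stopifnot(n_burnin >= 0, n_samples >= 1)
  if (is.null(index)) index <- evidence_index(evidence, theta)
  pd <- assemble_pd(index, theta, init)
  set.seed(seed)
  res <- gibbs_run_cpp(pd, as.integer(n_burnin), as.integer(n_samples))
  nG <- length(index$y2h_keys)
  structure(list(
    zmean = res$zsum / n_samples,
    xmean = stats::setNames(res$xsum / n_samples, index$proteins$human),
    y2h_tab = array(res$y2h_tab, dim = c(2, 3, 2, nG),
                    dimnames = list(y = 0:1, s = 0:2, z = 0:1,
                                    group = index$y2h_keys)),
    lit = matrix(res$lit, ncol = 4, byrow = TRUE,
                 dimnames = list(index$lit_keys,
                                 c("z", "z_obs", "nz", "nz_obs"))),
    mpc = matrix(res$mpc, ncol = 4, byrow = TRUE,
                 dimnames = list(index$mpc_keys,
                                 c("cap1", "miss1", "cap2", "miss2"))),
    tr_pair = stats::setNames(res$tr_pair, c("z", "z_zs", "nz", "nz_zs")),
    tr_x = stats::setNames(res$tr_x, c("x", "x_xs", "nx", "nx_xs")),
    n_samples = n_samples,
    final = res$final_state,
    index = index), class = "ppi_estats")
}

#' Posterior interaction probabilities by Gibbs sampling
#'
#' Estimates `Pr[Z_ij = 1 | all evidence]` for every unordered human
#' protein pair as the mean of sampled `Z_ij` over retained Gibbs sweeps at
#' fixed parameters.
#'
#' @inheritParams e_step
#' @return A data frame with columns `protein_a`, `protein_b`, `posterior`,
#'   covering all human pairs, in canonical pair order.
#' @export
#' @examples
#' ev <- ppi_evidence(
#'   y2h = data.frame(protein_a = "P1", protein_b = "P2",
#'                    source_id = "s", replicate = 1, observed = 1))
#' th <- ppi_params(rho = 0.01, alpha_I = 0.9, alpha_S = 0, alpha_U = 0.005,
#'                  r = 1e-6)
#' sc <- score_posteriors(ev, th, n_samples = 2000, seed = 1)
#' sc$posterior  # close to 0.645
score_posteriors <- function(evidence, theta, n_burnin = 50,
                             n_samples = 500, seed = 1, index = NULL) {
  if (is.null(index)) index <- evidence_index(evidence, theta)
  st <- e_step(evidence, theta, n_burnin, n_samples, seed, index = index)
  ids <- index$proteins$human
  gi <- pair_grid(length(ids))
  data.frame(protein_a = ids[gi[, 1L]], protein_b = ids[gi[, 2L]],
             posterior = st$zmean, stringsAsFactors = FALSE)
}

#' Exact posterior by exhaustive enumeration
#'
#' Brute-force oracle: enumerates every configuration of the latent binary
#' variables (all human pair and self-activation indicators plus starred
#' counterparts), accumulates the complete likelihood of each, and returns
#' the exact marginal `Pr[Z_ij = 1 | evidence]` per human pair. Only
#' feasible for at most 20 latent variables; intended for tests and
#' validation of the Gibbs sampler.
#'
#' @inheritParams e_step
#' @return A data frame with columns `protein_a`, `protein_b`, `posterior`.
#' @export
exact_posterior <- function(evidence, theta) {
  uni <- evidence$universe
  orgs <- evidence_organisms(evidence)
  prot <- lapply(orgs, function(o) organism_proteins(evidence, o))
  names(prot) <- orgs
  nvec <- vapply(prot, length, integer(1))
  # latent variable layout: per organism, pair bits then protein bits
  nbits <- sum(nvec * (nvec - 1) / 2) + sum(nvec)
  if (nbits > 20)
    stop("instance has ", nbits,
         " latent variables; exact enumeration is capped at 20")
  offs <- list(); pos <- 0L
  for (o in orgs) {
    n <- length(prot[[o]])
    P <- n * (n - 1) / 2
    offs[[o]] <- list(z = pos + seq_len(P), x = pos + P + seq_len(n))
    pos <- pos + P + n
  }
  M <- 2^nbits
  cfg <- 0:(M - 1)
  B <- vapply(seq_len(nbits), function(k) bitwAnd(cfg, 2^(k - 1)) > 0,
              logical(M))
  if (nbits == 1L) B <- matrix(B, ncol = 1L)
  ll <- numeric(M)

  # priors: human pairs and proteins; starred handled via transfer below
  h <- offs$human
  lr1 <- log(clip_prob(theta$rho)); lr0 <- log1p(-clip_prob(theta$rho))
  for (p in h$z) ll <- ll + ifelse(B[, p], lr1, lr0)
  lx1 <- log(clip_prob(theta$r)); lx0 <- log1p(-clip_prob(theta$r))
  for (p in h$x) ll <- ll + ifelse(B[, p], lx1, lx0)

  pmapl <- lapply(prot, function(p) stats::setNames(seq_along(p), p))
  pidx1 <- function(o, a, b) {
    i <- pmapl[[o]][[a]]; j <- pmapl[[o]][[b]]
    offs[[o]]$z[pair_index(min(i, j), max(i, j), nvec[[o]])]
  }

  # Y2H records
  y <- evidence$y2h
  for (k in seq_len(nrow(y))) {
    o <- y$organism[k]
    th <- theta_for_source(theta, y$source_id[k])
    zb <- pidx1(o, y$protein_a[k], y$protein_b[k])
    xa <- offs[[o]]$x[pmapl[[o]][[y$protein_a[k]]]]
    xb <- offs[[o]]$x[pmapl[[o]][[y$protein_b[k]]]]
    combos <- expand.grid(z = 0:1, xi = 0:1, xj = 0:1)
    pr <- clip_prob(y2h_response_prob(combos$z, combos$xi, combos$xj, th))
    lp <- if (y$observed[k] == 1) log(pr) else log1p(-pr)
    idx <- 1L + B[, zb] + 2L * B[, xa] + 4L * B[, xb]
    ll <- ll + lp[idx]
  }

  # literature records (human)
  lit <- evidence$literature
  for (k in seq_len(nrow(lit))) {
    th <- theta_for_source(theta, lit$channel[k])
    rts <- clip_prob(if (lit$channel[k] == "H") c(th$gamma1, th$gamma0)
                     else c(th$beta1, th$beta0))
    zb <- pidx1("human", lit$protein_a[k], lit$protein_b[k])
    lp <- literature_log_prob(rep(lit$observed[k], 2), 0:1, rts[1], rts[2])
    ll <- ll + lp[1L + B[, zb]]
  }

  # complexes: tabulate each organism's graph configurations once
  cx <- evidence$complexes
  for (o in unique(cx$organism)) {
    rows <- which(cx$organism == o)
    zb <- offs[[o]]$z
    nP <- length(zb)
    ids <- prot[[o]]
    gi <- pair_grid(length(ids))
    cll <- numeric(2^nP)
    mem <- parse_members(cx$members[rows])
    for (cfg_o in 0:(2^nP - 1)) {
      bits <- bitwAnd(cfg_o, 2^(seq_len(nP) - 1)) > 0
      Zm <- matrix(0L, length(ids), length(ids),
                   dimnames = list(ids, ids))
      if (any(bits)) {
        on <- gi[bits, , drop = FALSE]
        Zm[on] <- 1L; Zm[on[, 2:1, drop = FALSE]] <- 1L
      }
      stt <- structure(list(Z = stats::setNames(list(Zm), o)), class = "ppi_state")
      v <- 0
      for (t in seq_along(rows)) {
        th <- theta_for_source(theta, cx$experiment_id[rows[t]])
        th[c("psi1", "psi2", "psi_bg")] <-
          lapply(th[c("psi1", "psi2", "psi_bg")], clip_prob)
        v <- v + complex_log_likelihood(cx$bait[rows[t]], mem[[t]],
                                        stt, th, organism = o)
      }
      cll[cfg_o + 1] <- v
    }
    if (nP > 0) {
      idx <- as.vector(B[, zb, drop = FALSE] %*% 2^(seq_len(nP) - 1))
      ll <- ll + cll[idx + 1]
    } else ll <- ll + cll[1]
  }

  # homology transfer (and prior fallback for unmapped starred variables)
  for (o in setdiff(orgs, "human")) {
    tab <- homology_tables(evidence, o)
    sids <- prot[[o]]
    for (ii in seq_along(sids)) {
      sb <- offs[[o]]$x[ii]
      a <- sids[ii]
      if (a %in% names(tab$human)) {
        hh <- tab$human[[a]]
        hb <- offs$human$x[pmapl$human[[hh]]]
        p1 <- clip_prob(transfer_prob(0:1, tab$identity[[hh]],
                                      "self_activation", theta))
        ll <- ll + ifelse(B[, sb], log(p1)[1L + B[, hb]],
                          log1p(-p1)[1L + B[, hb]])
      } else {
        ll <- ll + ifelse(B[, sb], lx1, lx0)
      }
    }
    if (length(sids) >= 2) {
      gi <- pair_grid(length(sids))
      for (t in seq_len(nrow(gi))) {
        a <- sids[gi[t, 1]]; b <- sids[gi[t, 2]]
        sb <- offs[[o]]$z[t]
        if (a %in% names(tab$human) && b %in% names(tab$human)) {
          ha <- tab$human[[a]]; hb2 <- tab$human[[b]]
          J <- joint_identity(tab$identity[[ha]], tab$identity[[hb2]])
          p1 <- clip_prob(transfer_prob(0:1, J, "interaction", theta))
          zb <- pidx1("human", ha, hb2)
          ll <- ll + ifelse(B[, sb], log(p1)[1L + B[, zb]],
                            log1p(-p1)[1L + B[, zb]])
        } else {
          ll <- ll + ifelse(B[, sb], lr1, lr0)
        }
      }
    }
  }

  w <- exp(ll - max(ll))
  ids <- prot$human
  gi <- pair_grid(length(ids))
  post <- vapply(seq_len(nrow(gi)), function(t) {
    p <- offs$human$z[t]
    sum(w[B[, p]]) / sum(w)
  }, numeric(1))
  data.frame(protein_a = ids[gi[, 1L]], protein_b = ids[gi[, 2L]],
             posterior = post, stringsAsFactors = FALSE)
}
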