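# Internal translation of a ppi_evidence object into the flat, 0-based
# arrays consumed by the compiled Gibbs sweep.  The structure (protein
# indices, CSR evidence layouts, homology links) is built once per fit by
# evidence_index(); the numeric parameter tables are rebuilt from theta at
# every E-step by pack_theta().

# 1-based index of unordered pair (i, j), i < j, among n proteins, in
# row-major order (1,2), (1,3), ..., (1,n), (2,3), ...
pair_index <- function(i, j, n) (i - 1) * (2 * n - i) / 2 + (j - i)

# pairs (i, j), i < j, in pair_index order
pair_grid <- function(n) {
  if (n < 2) return(cbind(i = integer(), j = integer()))
  cbind(i = rep(seq_len(n - 1), times = (n - 1):1),
        j = sequence((n - 1):1, from = 2:n))
}

# CSR pointer (0-based, length nbins + 1) for entries sorted by bin
csr_ptr <- function(bins, nbins) c(0L, cumsum(tabulate(bins, nbins)))

evidence_index <- function(ev, theta) {
  orgs <- evidence_organisms(ev)
  prot <- lapply(orgs, function(o) organism_proteins(ev, o))
  names(prot) <- orgs
  pmap <- lapply(prot, function(p) stats::setNames(seq_along(p), p))
  nvec <- vapply(prot, length, integer(1))
  Pvec <- nvec * (nvec - 1) / 2

  ov <- attr(theta, "overrides")
  ov_sources <- if (is.null(ov)) character() else unique(ov$source_id)
  y2h_keys <- c(".shared", intersect(ov_sources, unique(ev$y2h$source_id)))
  mpc_keys <- c(".shared", intersect(ov_sources,
                                     unique(ev$complexes$experiment_id)))
  lit_keys <- c("H", "L")

  org_data <- vector("list", length(orgs))
  for (oi in seq_along(orgs)) {
    o <- orgs[oi]
    n <- nvec[oi]; P <- Pvec[oi]
    d <- list(n = as.integer(n),
              z = integer(P), x = integer(n),
              y2h_ptr = integer(P + 1), y2h_grp = integer(),
              y2h_npos = integer(), y2h_nneg = integer(),
              xy_ptr = integer(n + 1), xy_partner = integer(),
              xy_grp = integer(), xy_npos = integer(), xy_nneg = integer(),
              lit_ptr = integer(P + 1), lit_grp = integer(),
              lit_obs = integer(),
              cx_bait = integer(), cx_grp = integer(),
              cx_ptr = 0L, cx_mem = integer(),
              pb_ptr = integer(n + 1), pb_cx = integer(),
              sp_link = rep(-1L, P), sx_link = rep(-1L, n))

    y <- ev$y2h[ev$y2h$organism == o, , drop = FALSE]
    if (nrow(y)) {
      ia <- unname(pmap[[o]][y$protein_a]); ib <- unname(pmap[[o]][y$protein_b])
      ii <- pmin(ia, ib); jj <- pmax(ia, ib)
      p <- pair_index(ii, jj, n)
      g <- match(y$source_id, y2h_keys, nomatch = 1L)  # 1 = shared
      key <- (p - 1) * length(y2h_keys) + g
      agg <- rowsum(cbind(pos = y$observed, tot = 1L), key)
      k <- as.numeric(rownames(agg))
      pair <- (k - 1) %/% length(y2h_keys) + 1
      grp <- (k - 1) %% length(y2h_keys) + 1
      ordp <- order(pair)
      pair <- as.integer(pair[ordp]); grp <- as.integer(grp[ordp])
      npos <- as.integer(agg[ordp, "pos"])
      nneg <- as.integer(agg[ordp, "tot"] - agg[ordp, "pos"])
      d$y2h_ptr <- csr_ptr(pair, P)
      d$y2h_grp <- grp - 1L; d$y2h_npos <- npos; d$y2h_nneg <- nneg
      # per-protein view
      gi <- pair_grid(n)
      ei <- gi[pair, 1L]; ej <- gi[pair, 2L]
      who <- c(ei, ej); partner <- c(ej, ei)
      ordw <- order(who)
      d$xy_ptr <- csr_ptr(who[ordw], n)
      d$xy_partner <- partner[ordw] - 1L
      d$xy_grp <- rep(grp - 1L, 2L)[ordw]
      d$xy_npos <- rep(npos, 2L)[ordw]
      d$xy_nneg <- rep(nneg, 2L)[ordw]
    }

    if (o == "human" && nrow(ev$literature)) {
      lit <- ev$literature
      ia <- unname(pmap[[o]][lit$protein_a])
      ib <- unname(pmap[[o]][lit$protein_b])
      p <- pair_index(pmin(ia, ib), pmax(ia, ib), n)
      g <- match(lit$channel, lit_keys)
      ordp <- order(p)
      d$lit_ptr <- csr_ptr(p[ordp], P)
      d$lit_grp <- as.integer(g[ordp] - 1L)
      d$lit_obs <- as.integer(lit$observed[ordp])
    }

    cx <- ev$complexes[ev$complexes$organism == o, , drop = FALSE]
    if (nrow(cx)) {
      mem <- parse_members(cx$members)
      bait <- unname(pmap[[o]][cx$bait])
      ordb <- order(bait)
      cx <- cx[ordb, , drop = FALSE]; mem <- mem[ordb]; bait <- bait[ordb]
      d$cx_bait <- as.integer(bait - 1L)
      d$cx_grp <- match(cx$experiment_id, mpc_keys, nomatch = 1L) - 1L
      lens <- lengths(mem)
      d$cx_ptr <- c(0L, cumsum(lens))
      d$cx_mem <- if (sum(lens)) as.integer(unname(
        pmap[[o]][unlist(mem)]) - 1L) else integer()
      d$pb_ptr <- csr_ptr(bait, n)
      d$pb_cx <- as.integer(seq_along(bait) - 1L)
    }
    org_data[[oi]] <- d
  }

  # homology links
  pl <- list(hpair = integer(), org = integer(), spair = integer(),
             J = numeric())
  xl <- list(h = integer(), org = integer(), star = integer(), I = numeric())
  for (oi in seq_along(orgs)[-1]) {
    o <- orgs[oi]
    tab <- homology_tables(ev, o)
    hs <- names(tab$ortholog)
    keep <- hs %in% names(pmap$human) & tab$ortholog %in% names(pmap[[o]])
    hs <- hs[keep]
    if (!length(hs)) next
    hidx <- unname(pmap$human[hs])
    sidx <- unname(pmap[[o]][tab$ortholog[hs]])
    idv <- unname(tab$identity[hs])
    nl0 <- length(xl$h)
    xl$h <- c(xl$h, hidx - 1L)
    xl$org <- c(xl$org, rep(oi - 1L, length(hs)))
    xl$star <- c(xl$star, sidx - 1L)
    xl$I <- c(xl$I, idv)
    org_data[[oi]]$sx_link[sidx] <- nl0 + seq_along(hs) - 1L
    if (length(hs) >= 2) {
      cmb <- pair_grid(length(hs))
      ha <- hidx[cmb[, 1]]; hb <- hidx[cmb[, 2]]
      sa <- sidx[cmb[, 1]]; sb <- sidx[cmb[, 2]]
      hp <- pair_index(pmin(ha, hb), pmax(ha, hb), nvec[1])
      sp <- pair_index(pmin(sa, sb), pmax(sa, sb), nvec[oi])
      np0 <- length(pl$hpair)
      pl$hpair <- c(pl$hpair, as.integer(hp - 1L))
      pl$org <- c(pl$org, rep(oi - 1L, length(hp)))
      pl$spair <- c(pl$spair, as.integer(sp - 1L))
      pl$J <- c(pl$J, joint_identity(idv[cmb[, 1]], idv[cmb[, 2]]))
      org_data[[oi]]$sp_link[sp] <- np0 + seq_along(hp) - 1L
    }
  }
  # CSR from human pairs / proteins to links
  P0 <- Pvec[1]; n0 <- nvec[1]
  if (length(pl$hpair)) {
    ordl <- order(pl$hpair)
    # reorder links and remap references
    remap <- integer(length(ordl)); remap[ordl] <- seq_along(ordl) - 1L
    for (oi in seq_along(orgs)[-1]) {
      sl <- org_data[[oi]]$sp_link
      org_data[[oi]]$sp_link <-
        as.integer(ifelse(sl >= 0, remap[sl + 1L], -1L))
    }
    pl <- lapply(pl, function(v) v[ordl])
    pl$hp_ptr <- csr_ptr(pl$hpair + 1L, P0)
    pl$hp_link <- as.integer(seq_along(pl$hpair) - 1L)
  } else {
    pl$hp_ptr <- integer(P0 + 1); pl$hp_link <- integer()
  }
  if (length(xl$h)) {
    ordl <- order(xl$h)
    remap <- integer(length(ordl)); remap[ordl] <- seq_along(ordl) - 1L
    for (oi in seq_along(orgs)[-1]) {
      sl <- org_data[[oi]]$sx_link
      org_data[[oi]]$sx_link <-
        as.integer(ifelse(sl >= 0, remap[sl + 1L], -1L))
    }
    xl <- lapply(xl, function(v) v[ordl])
    xl$xh_ptr <- csr_ptr(xl$h + 1L, n0)
    xl$xh_link <- as.integer(seq_along(xl$h) - 1L)
  } else {
    xl$xh_ptr <- integer(n0 + 1); xl$xh_link <- integer()
  }

  list(orgs = orgs, proteins = prot, pmap = pmap, n = nvec, P = Pvec,
       y2h_keys = y2h_keys, mpc_keys = mpc_keys, lit_keys = lit_keys,
       org_data = org_data, links_pair = pl, links_x = xl)
}

# numeric parameter tables for the sampler, from a ppi_params object
pack_theta <- function(index, theta) {
  nG <- length(index$y2h_keys)
  logp <- numeric(nG * 12)
  for (g in seq_len(nG)) {
    key <- index$y2h_keys[g]
    th <- if (key == ".shared") theta else theta_for_source(theta, key)
    for (z in 0:1) for (s in 0:2) {
      p <- clip_prob(y2h_response_prob(z, s, 0, th))
      base <- (((g - 1) * 2 + z) * 3 + s) * 2
      logp[base + 1] <- log1p(-p)  # y = 0
      logp[base + 2] <- log(p)     # y = 1
    }
  }
  llr1 <- llr0 <- numeric(length(index$lit_keys))
  for (g in seq_along(index$lit_keys)) {
    key <- index$lit_keys[g]
    th <- theta_for_source(theta, key)
    rts <- if (key == "H") c(th$gamma1, th$gamma0) else c(th$beta1, th$beta0)
    rts <- clip_prob(rts)
    llr1[g] <- log(rts[1] / rts[2])
    llr0[g] <- log((1 - rts[1]) / (1 - rts[2]))
  }
  mpc <- matrix(0, length(index$mpc_keys), 5)
  for (g in seq_along(index$mpc_keys)) {
    key <- index$mpc_keys[g]
    th <- if (key == ".shared") theta else theta_for_source(theta, key)
    p1 <- clip_prob(th$psi1); p2 <- clip_prob(th$psi2)
    pb <- clip_prob(th$psi_bg)
    mpc[g, ] <- c(log(p1), log1p(-p1), log(p2), log1p(-p2), log(pb))
  }
  pl <- index$links_pair
  d1 <- rep_len(clip_prob(transfer_prob(1, pl$J, "interaction", theta)),
                length(pl$J))
  d0 <- rep_len(clip_prob(transfer_prob(0, pl$J, "interaction", theta)),
                length(pl$J))
  links_pair <- c(pl[c("hpair", "org", "spair", "hp_ptr", "hp_link")],
                  list(lr_z = log(d1 / d0), lr_c = log((1 - d1) / (1 - d0)),
                       lo1 = stats::qlogis(d1), lo0 = stats::qlogis(d0)))
  xlk <- index$links_x
  o1 <- rep_len(clip_prob(transfer_prob(1, xlk$I, "self_activation", theta)),
                length(xlk$I))
  o0 <- rep_len(clip_prob(transfer_prob(0, xlk$I, "self_activation", theta)),
                length(xlk$I))
  links_x <- c(xlk[c("h", "org", "star", "xh_ptr", "xh_link")],
               list(lr_x = log(o1 / o0), lr_c = log((1 - o1) / (1 - o0)),
                    lo1 = stats::qlogis(o1), lo0 = stats::qlogis(o0)))
  list(links_pair = links_pair, links_x = links_x,
       y2h_logp = logp, n_y2h_groups = as.integer(nG),
       lit_llr1 = llr1, lit_llr0 = llr0, mpc_logs = mpc,
       logit_rho = stats::qlogis(clip_prob(theta$rho)),
       logit_r = stats::qlogis(clip_prob(theta$r)))
}

assemble_pd <- function(index, theta, init = NULL) {
  od <- index$org_data
  if (!is.null(init)) {
    for (o in seq_along(od)) {
      od[[o]]$z <- init[[o]]$z
      od[[o]]$x <- init[[o]]$x
    }
  }
  c(list(orgs = od), pack_theta(index, theta))
}
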