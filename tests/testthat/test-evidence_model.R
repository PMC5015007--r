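# Domain types and per-source probability functions of the generative model.

test_that("parameter vector validates and applies per-source overrides", {
  th <- ppi_params(rho = 0.01)
  expect_s3_class(th, "ppi_params")
  expect_error(ppi_params(rho = 1.2), "probability")
  expect_error(ppi_params(alpha_I = -0.1), "probability")
  ov <- data.frame(source_id = "screen2", parameter = "alpha_I",
                   value = 0.3)
  th2 <- ppi_params(alpha_I = 0.9, overrides = ov)
  expect_equal(ppibayes:::theta_for_source(th2, "screen2")$alpha_I, 0.3)
  expect_equal(ppibayes:::theta_for_source(th2, "screen1")$alpha_I, 0.9)
  expect_error(ppi_params(overrides = data.frame(
    source_id = "s", parameter = "nope", value = 0.5)), "unknown parameter")
})

test_that("evidence constructor canonicalizes pairs and drops self-pairs", {
  expect_warning(
    ev <- ppi_evidence(y2h = data.frame(
      protein_a = c("B", "C"), protein_b = c("A", "C"), source_id = "s",
      replicate = 1L, observed = 1L)),
    "self-pair")
  expect_equal(nrow(ev$y2h), 1L)
  expect_equal(ev$y2h$protein_a, "A")
  expect_equal(ev$y2h$protein_b, "B")
  # replicate contiguity enforced
  expect_error(ppi_evidence(y2h = data.frame(
    protein_a = "A", protein_b = "B", source_id = "s",
    replicate = c(1L, 3L), observed = c(1L, 0L))), "contiguous")
  # unknown proteins rejected against an explicit universe
  expect_error(ppi_evidence(
    y2h = data.frame(protein_a = "A", protein_b = "Z", source_id = "s",
                     replicate = 1L, observed = 1L),
    universe = data.frame(protein = c("A", "B"), organism = "human")),
    "absent from the universe")
})

test_that("evidence sets round-trip through the TSV writers losslessly", {
  ev <- tiny_full_evidence()
  dir <- withr::local_tempdir()
  write_evidence(ev, dir)
  ev2 <- read_evidence(dir)
  expect_equal(ev2$y2h, ev$y2h)
  expect_equal(ev2$complexes, ev$complexes)
  expect_equal(ev2$literature, ev$literature)
  expect_equal(ev2$homology, ev$homology, tolerance = 1e-12)
  expect_equal(ev2$universe, ev$universe)
})

test_that("malformed evidence TSV is rejected with file and line", {
  dir <- withr::local_tempdir()
  write_evidence(tiny_full_evidence(), dir)
  lines <- readLines(file.path(dir, "y2h.tsv"))
  lines[3] <- "A\tB\tbroken"
  writeLines(lines, file.path(dir, "y2h.tsv"))
  expect_error(read_evidence(dir), "y2h.tsv.*line 3")
})

test_that("Y2H response probability follows the three-mechanism model", {
  # background only: alpha_U straight through
  th <- ppi_params(alpha_I = 0.933, alpha_S = 0.852, alpha_U = 0.007)
  expect_equal(y2h_response_prob(0, 0, 0, th), 0.007)
  # true interaction plus background
  expect_equal(y2h_response_prob(1, 0, 0, th), 1 - 0.067 * 0.993)
  # no mechanism can fire
  th0 <- ppi_params(alpha_I = 0, alpha_S = 0, alpha_U = 0)
  expect_equal(y2h_response_prob(1, 1, 1, th0), 0)
  # each self-activating partner contributes one exponent factor
  ths <- ppi_params(alpha_I = 0, alpha_S = 0.3, alpha_U = 0)
  expect_equal(y2h_response_prob(0, 1, 1, ths), 1 - 0.7^2)
  # indicator variant fires at most once per pair
  thi <- ppi_params(alpha_I = 0, alpha_S = 0.3, alpha_U = 0,
                    selfact_mode = "indicator")
  expect_equal(y2h_response_prob(0, 1, 1, thi), 0.3)
})

test_that("Y2H response probabilities are normalized over the outcome", {
  th <- tiny_theta()
  for (z in 0:1) for (xi in 0:1) for (xj in 0:1) {
    p <- y2h_response_prob(z, xi, xj, th)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("complex likelihood multiplies capture factors over 1- and 2-step neighbours", {
  uni <- data.frame(protein = c("K", "A", "B", "C"), organism = "human")
  st <- ppi_state(uni, edges = data.frame(protein_a = c("K", "K", "A"),
                                          protein_b = c("A", "B", "C")))
  th <- ppi_params(psi1 = 0.8, psi2 = 0.6)
  # n1 = {A, B}, n2 = {C}; observed {A, C}
  expect_equal(complex_log_likelihood("K", c("A", "C"), st, th),
               log(0.8 * 0.2 * 0.6))
  # everything observed: no miss factors
  expect_equal(complex_log_likelihood("K", c("A", "B", "C"), st, th),
               2 * log(0.8) + log(0.6))
  # single missed direct neighbour at the printed estimate
  uni2 <- data.frame(protein = c("K", "A"), organism = "human")
  st2 <- ppi_state(uni2, edges = data.frame(protein_a = "K", protein_b = "A"))
  th2 <- ppi_params(psi1 = 0.809)
  expect_equal(complex_log_likelihood("K", character(), st2, th2),
               log(1 - 0.809))
  # distant observed members get the background capture factor
  st3 <- ppi_state(uni)  # empty graph: everything is distant
  expect_equal(complex_log_likelihood("K", "A", st3, th),
               log(th$psi_bg))
  expect_error(complex_log_likelihood("Zz", "A", st, th), "universe")
})

test_that("complex likelihood ignores edits outside the bait neighbourhood", {
  uni <- data.frame(protein = c("K", "A", "B", "C", "D"), organism = "human")
  th <- ppi_params(psi1 = 0.8, psi2 = 0.6)
  st <- ppi_state(uni, edges = data.frame(protein_a = c("K", "A"),
                                          protein_b = c("A", "B")))
  base <- complex_log_likelihood("K", c("A", "B"), st, th)
  # C-D is at distance >= 3 from K: toggling it cannot matter
  st2 <- ppi_state(uni, edges = data.frame(protein_a = c("K", "A", "C"),
                                           protein_b = c("A", "B", "D")))
  expect_equal(complex_log_likelihood("K", c("A", "B"), st2, th), base)
})

test_that("literature factor uses channel rates and complements", {
  expect_equal(literature_log_prob(1, 1, 0.8, 0.01), log(0.8))
  expect_equal(literature_log_prob(1, 0, 0.8, 0.01), log(0.01))
  expect_equal(literature_log_prob(0, 1, 0.8, 0.01), log(0.2))
  # normalization over the observed indicator
  for (z in 0:1)
    expect_equal(exp(literature_log_prob(1, z, 0.7, 0.1)) +
                   exp(literature_log_prob(0, z, 0.7, 0.1)), 1)
})

test_that("transfer probability honours mode and parameterization", {
  th <- tiny_theta()
  expect_equal(transfer_prob(1, 0.5, "interaction", th), 0.7)
  expect_equal(transfer_prob(0, 0.5, "interaction", th), 0.05)
  expect_equal(transfer_prob(1, 0.5, "self_activation", th), 0.7)
  expect_error(transfer_prob(1, 0.5, "nonsense", th))
  thl <- ppi_params(transfer_mode = "logistic")
  expect_gt(transfer_prob(1, 0.9, "interaction", thl),
            transfer_prob(1, 0.3, "interaction", thl))
})

test_that("prior log-probability sums Bernoulli factors", {
  uni <- data.frame(protein = c("A", "B", "C"), organism = "human")
  th <- ppi_params(rho = 0.5, r = 0.5)
  expect_equal(prior_log_prob(ppi_state(uni), th), 6 * log(0.5))
  th2 <- ppi_params(rho = 0.01, r = 0.5)
  st <- ppi_state(uni, edges = data.frame(protein_a = "A", protein_b = "B"))
  expect_equal(prior_log_prob(st, th2),
               log(0.01) + 2 * log(0.99) + 3 * log(0.5))
  # degenerate prior: impossible configuration has zero probability
  th3 <- ppi_params(rho = 1, r = 0.5)
  expect_equal(prior_log_prob(ppi_state(uni), th3), -Inf)
})

test_that("complete log-likelihood is additive over factors", {
  th <- tiny_theta()
  uni <- data.frame(protein = c("A", "B"), organism = "human")
  ev0 <- ppi_evidence(universe = uni)
  st <- ppi_state(uni)
  expect_equal(complete_log_likelihood(st, ev0, th), prior_log_prob(st, th))
  ev1 <- ppi_evidence(y2h = data.frame(
    protein_a = "A", protein_b = "B", source_id = "s", replicate = 1L,
    observed = 1L))
  expect_equal(complete_log_likelihood(st, ev1, th),
               prior_log_prob(st, th) +
                 log(y2h_response_prob(0, 0, 0, th)))
  expect_error(complete_log_likelihood(
    ppi_state(uni), tiny_full_evidence(), th), "does not cover")
})

test_that("complete log-likelihood equals the sum of independent factor logs", {
  ev <- tiny_full_evidence()
  th <- tiny_theta()
  st <- ppi_state(ev, edges = data.frame(protein_a = c("A", "A*"),
                                         protein_b = c("B", "B*")),
                  selfact = "C")
  ll <- complete_log_likelihood(st, ev, th)
  manual <- prior_log_prob(st, th) +
    log(y2h_response_prob(1, 0, 0, th)) +        # A-B human, observed 1
    log(1 - y2h_response_prob(0, 0, 1, th)) +    # A-C, x_C = 1, observed 0
    log(y2h_response_prob(0, 1, 0, th)) +        # B-C, observed 1
    log(y2h_response_prob(1, 0, 0, th)) +        # A*-B* starred, observed 1
    complex_log_likelihood("A", "B", st, th) +
    literature_log_prob(1, 1, th$gamma1, th$gamma0) +
    literature_log_prob(0, 1, th$beta1, th$beta0) +
    log(transfer_prob(1, sqrt(0.9 * 0.7), "interaction", th)) +
    log(1 - transfer_prob(0, 0.9, "self_activation", th)) +
    log(1 - transfer_prob(0, 0.7, "self_activation", th))
  expect_equal(ll, manual)
})

test_that("complete log-likelihood is invariant to protein relabelling", {
  th <- tiny_theta()
  ev <- tiny_full_evidence()
  st <- ppi_state(ev, edges = data.frame(protein_a = "A", protein_b = "C"),
                  selfact = "B")
  base <- complete_log_likelihood(st, ev, th)
  relab <- c(A = "P3", B = "P1", C = "P2", `A*` = "Q2", `B*` = "Q1")
  rl <- function(x) ifelse(x %in% names(relab), relab[x], x)
  ev2 <- ppi_evidence(
    y2h = transform(ev$y2h, protein_a = rl(protein_a),
                    protein_b = rl(protein_b)),
    complexes = transform(ev$complexes, bait = rl(bait),
                          members = rl(members)),
    literature = transform(ev$literature, protein_a = rl(protein_a),
                           protein_b = rl(protein_b)),
    homology = transform(ev$homology, human_protein = rl(human_protein),
                         ortholog = rl(ortholog)))
  st2 <- ppi_state(ev2, edges = data.frame(protein_a = "P3",
                                           protein_b = "P2"),
                   selfact = "P1")
  expect_equal(complete_log_likelihood(st2, ev2, th), base)
})
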