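# Gibbs E-step, M-step and the Monte Carlo EM driver.

test_that("pair with no evidence scores at the prior", {
  uni <- data.frame(protein = c("A", "B"), organism = "human")
  ev <- ppi_evidence(universe = uni)
  th <- ppi_params(rho = 0.3, r = 1e-6)
  expect_equal(exact_posterior(ev, th)$posterior, 0.3)
  sc <- score_posteriors(ev, th, n_samples = 4000, seed = 1)
  expect_lt(abs(sc$posterior - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
})

test_that("single-pair Y2H posterior matches the closed form", {
  ev <- ppi_evidence(y2h = data.frame(
    protein_a = "P1", protein_b = "P2", source_id = "s", replicate = 1L,
    observed = 1L))
  th <- ppi_params(rho = 0.01, alpha_I = 0.9, alpha_S = 0,
                   alpha_U = 0.005, r = 1e-6)
  # Bayes rule by hand: rho p1 / (rho p1 + (1 - rho) p0)
  p1 <- 1 - (1 - 0.9) * (1 - 0.005)
  expected <- 0.01 * p1 / (0.01 * p1 + 0.99 * 0.005)
  expect_equal(expected, 0.6452884, tolerance = 1e-6)
  expect_equal(exact_posterior(ev, th)$posterior, expected)
  sc <- score_posteriors(ev, th, n_samples = 5000, seed = 2)
  expect_lt(abs(sc$posterior - expected), 0.02)
})

test_that("uninformative factors cancel from the conditional", {
  # literature with rate_pos = rate_neg carries no information
  uni <- data.frame(protein = c("A", "B"), organism = "human")
  th <- ppi_params(rho = 0.2, gamma1 = 0.5, gamma0 = 0.5, r = 1e-6)
  ev <- ppi_evidence(literature = data.frame(
    protein_a = "A", protein_b = "B", channel = "H", observed = 1L),
    universe = uni)
  expect_equal(exact_posterior(ev, th)$posterior, 0.2)
  # alpha_I = alpha_S = 0: Y2H carries no information about z
  th2 <- ppi_params(rho = 0.2, alpha_I = 0, alpha_S = 0, alpha_U = 0.05,
                    r = 1e-6)
  ev2 <- ppi_evidence(y2h = data.frame(
    protein_a = "A", protein_b = "B", source_id = "s", replicate = 1L,
    observed = 1L))
  expect_equal(exact_posterior(ev2, th2)$posterior, 0.2)
})

test_that("conclusive literature evidence saturates the posterior", {
  th <- ppi_params(rho = 0.05, gamma1 = 1 - 1e-9, gamma0 = 1e-9, r = 1e-6)
  ev <- ppi_evidence(literature = data.frame(
    protein_a = "A", protein_b = "B", channel = "H", observed = 1L))
  sc <- score_posteriors(ev, th, n_samples = 500, seed = 3)
  expect_equal(sc$posterior, 1)
})

test_that("E-step is deterministic given the seed", {
  ev <- random_tiny_instance(42)
  th <- tiny_theta()
  s1 <- e_step(ev, th, n_burnin = 10, n_samples = 50, seed = 7)
  s2 <- e_step(ev, th, n_burnin = 10, n_samples = 50, seed = 7)
  expect_identical(s1$zmean, s2$zmean)
  expect_identical(s1$y2h_tab, s2$y2h_tab)
  s3 <- e_step(ev, th, n_burnin = 10, n_samples = 50, seed = 8)
  expect_false(identical(s1$zmean, s3$zmean))
})

test_that("Gibbs agrees with exact enumeration on tiny full instances", {
  th <- tiny_theta()
  err <- vapply(1:6, function(s) {
    ev <- random_tiny_instance(100 + s)
    ex <- exact_posterior(ev, th)
    gb <- score_posteriors(ev, th, n_burnin = 100, n_samples = 5000,
                           seed = s)
    mean(abs(ex$posterior - gb$posterior))
  }, numeric(1))
  expect_lt(mean(err), 0.02)
})

test_that("exact posterior enforces the enumeration cap", {
  sim <- ppi_simulate(ppi_sim_config(n_proteins = 10, n_baits = 2,
                                     seed = 1, n_homolog_organisms = 0))
  expect_error(exact_posterior(sim$evidence, tiny_theta()), "capped at 20")
})

test_that("chains from independent seeds agree within Monte Carlo error", {
  ev <- random_tiny_instance(77)
  th <- tiny_theta()
  n <- 4000
  a <- score_posteriors(ev, th, n_samples = n, seed = 1)$posterior
  b <- score_posteriors(ev, th, n_samples = n, seed = 2)$posterior
  # generous iid bound on the MC standard error, doubled for autocorrelation
  se <- sqrt(pmax(a * (1 - a), 0.25) / n) * 2
  expect_true(all(abs(a - b) <= 3 * (2 * se + 1e-3)))
})

test_that("M-step closed forms and constraints behave", {
  ev <- random_tiny_instance(5)
  th <- tiny_theta()
  st <- e_step(ev, th, n_burnin = 20, n_samples = 200, seed = 1)
  th2 <- m_step(st, th)
  # rho update is the mean sampled edge density
  expect_equal(th2$rho, ppibayes:::clip_prob(mean(st$zmean)))
  expect_equal(th2$r, ppibayes:::clip_prob(mean(st$xmean)))
  # rate ordering enforced after estimation
  expect_gt(th2$gamma1, th2$gamma0)
  expect_gt(th2$beta1, th2$beta0)
  for (nm in ppibayes:::.learnable) {
    expect_gte(th2[[nm]], 1e-6); expect_lte(th2[[nm]], 1 - 1e-6)
  }
})

test_that("degenerate literature statistics clip to the boundary", {
  ev <- random_tiny_instance(5)
  th <- tiny_theta()
  st <- e_step(ev, th, n_burnin = 10, n_samples = 50, seed = 1)
  st$lit["H", ] <- c(z = 10, z_obs = 10, nz = 5, nz_obs = 0)
  th2 <- m_step(st, th)
  expect_equal(th2$gamma1, 1 - 1e-6)
  expect_equal(th2$gamma0, 1e-6)
})

test_that("one M-step from the truth does not decrease the Q-function", {
  cfg <- ppi_sim_config(n_proteins = 60, n_baits = 15, seed = 21)
  sim <- ppi_simulate(cfg)
  th_star <- cfg$theta_true
  st <- e_step(sim$evidence, th_star, n_burnin = 30, n_samples = 300,
               seed = 4)
  th_new <- m_step(st, th_star)
  expect_gte(ppibayes:::q_value(st, th_new),
             ppibayes:::q_value(st, th_star) - 1e-8)
})

test_that("fit contract: max_iter = 0, determinism, trace shape", {
  ev <- random_tiny_instance(9)
  th0 <- ppi_params_init()
  f0 <- ppi_fit(ev, theta_init = th0, max_iter = 0, score_samples = 50,
                verbose = FALSE)
  expect_false(f0$converged)
  expect_identical(coef(f0), unlist(th0[ppibayes:::.learnable]))
  f1 <- ppi_fit(ev, max_iter = 3, samples_base = 30, n_burnin = 10,
                score_samples = 50, seed = 5, verbose = FALSE)
  f2 <- ppi_fit(ev, max_iter = 3, samples_base = 30, n_burnin = 10,
                score_samples = 50, seed = 5, verbose = FALSE)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$posterior, f2$posterior)
  expect_true(all(f1$trace$diff >= 0))
  expect_true(all(f1$posterior$posterior >= 0 &
                    f1$posterior$posterior <= 1))
})

test_that("fit methods print, summarize, predict and simulate", {
  ev <- random_tiny_instance(13)
  f <- ppi_fit(ev, max_iter = 2, samples_base = 20, n_burnin = 10,
               score_samples = 50, seed = 3, verbose = FALSE)
  expect_output(print(f), "Monte Carlo EM")
  expect_output(print(summary(f)), "Confident pairs")
  expect_identical(predict(f), f$posterior)
  pr <- predict(f, newdata = restrict_evidence(ev, "y2h"),
                n_samples = 20)
  expect_true(all(pr$posterior >= 0 & pr$posterior <= 1))
  ss <- simulate(f, nsim = 1, n_proteins = 15)
  expect_s3_class(ss[[1]]$evidence, "ppi_evidence")
})

test_that("adding concordant evidence moves true pairs toward 1", {
  # a truly interacting pair: Y2H alone vs Y2H + confirming literature
  th <- ppi_params(rho = 0.01, alpha_I = 0.9, alpha_S = 0,
                   alpha_U = 0.005, gamma1 = 0.8, gamma0 = 0.01, r = 1e-6)
  y <- data.frame(protein_a = "P1", protein_b = "P2", source_id = "s",
                  replicate = 1L, observed = 1L)
  base <- exact_posterior(ppi_evidence(y2h = y), th)$posterior
  both <- exact_posterior(ppi_evidence(
    y2h = y, literature = data.frame(protein_a = "P1", protein_b = "P2",
                                     channel = "H", observed = 1L)),
    th)$posterior
  expect_gt(both, base)
  expect_gt(base, th$rho)
})
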