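# Monte Carlo Q-function: expected complete log-likelihood terms that
# depend on the learnable shared parameters, evaluated from E-step
# sufficient statistics.  Conjugate families (priors, literature, transfer)
# have closed-form maximizers; the Y2H mechanism probabilities and the
# capture probabilities are maximized by greedy coordinate ascent on this
# function.
q_value <- function(stats, theta) {
  xlogy <- function(k, p) sum(k[k > 0] * log(p[k > 0]))
  q <- 0
  # priors
  P0 <- length(stats$zmean); n0 <- length(stats$xmean)
  ez <- sum(stats$zmean); ex <- sum(stats$xmean)
  rho <- clip_prob(theta$rho); r <- clip_prob(theta$r)
  q <- q + ez * log(rho) + (P0 - ez) * log1p(-rho) +
    ex * log(r) + (n0 - ex) * log1p(-r)
  # Y2H (shared group only)
  tab <- stats$y2h_tab[, , , ".shared", drop = FALSE]
  for (z in 0:1) for (s in 0:2) {
    p <- clip_prob(y2h_response_prob(z, s, 0, theta))
    q <- q + tab[2, s + 1, z + 1, 1] * log(p) +
      tab[1, s + 1, z + 1, 1] * log1p(-p)
  }
  # literature channels
  for (ch in c("H", "L")) {
    if (!ch %in% rownames(stats$lit)) next
    st <- stats$lit[ch, ]
    rts <- clip_prob(if (ch == "H") c(theta$gamma1, theta$gamma0)
                     else c(theta$beta1, theta$beta0))
    q <- q + st["z_obs"] * log(rts[1]) +
      (st["z"] - st["z_obs"]) * log1p(-rts[1]) +
      st["nz_obs"] * log(rts[2]) +
      (st["nz"] - st["nz_obs"]) * log1p(-rts[2])
  }
  # pull-down captures (shared group only)
  mp <- stats$mpc[".shared", ]
  p1 <- clip_prob(theta$psi1); p2 <- clip_prob(theta$psi2)
  q <- q + mp["cap1"] * log(p1) + mp["miss1"] * log1p(-p1) +
    mp["cap2"] * log(p2) + mp["miss2"] * log1p(-p2)
  # homology transfer (constant parameterization)
  if (identical(attr(theta, "transfer_mode"), "constant")) {
    tp <- stats$tr_pair; tx <- stats$tr_x
    f1 <- clip_prob(theta$phi1); f0 <- clip_prob(theta$phi0)
    l1 <- clip_prob(theta$lambda1); l0 <- clip_prob(theta$lambda0)
    q <- q + tp["z_zs"] * log(f1) + (tp["z"] - tp["z_zs"]) * log1p(-f1) +
      tp["nz_zs"] * log(f0) + (tp["nz"] - tp["nz_zs"]) * log1p(-f0) +
      tx["x_xs"] * log(l1) + (tx["x"] - tx["x_xs"]) * log1p(-l1) +
      tx["nx_xs"] * log(l0) + (tx["nx"] - tx["nx_xs"]) * log1p(-l0)
  }
  unname(q)
}

# greedy coordinate ascent with step halving, restricted to [eps, 1 - eps]
hill_climb <- function(par, f, step_init = 0.1, step_min = 1e-4,
                       eps = 1e-6) {
  best <- f(par)
  step <- step_init
  while (step >= step_min) {
    repeat {
      improved <- FALSE
      for (k in seq_along(par)) {
        for (dir in c(1, -1)) {
          cand <- par
          cand[k] <- min(max(par[k] + dir * step, eps), 1 - eps)
          if (cand[k] == par[k]) next
          v <- f(cand)
          if (v > best) {
            best <- v; par <- cand; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    step <- step / 2
  }
  par
}

ratio_update <- function(num, den, old) {
  if (!is.finite(den) || den <= 0) return(unname(old))
  clip_prob(unname(num / den))
}

#' M-step: maximize the Monte Carlo Q-function
#'
#' Updates the shared model parameters given E-step sufficient statistics.
#' Conjugate Bernoulli components (`rho`, `r`, `gamma1`, `gamma0`, `beta1`,
#' `beta0`, `phi1`, `phi0`, `lambda1`, `lambda0`) use closed-form Monte
#' Carlo ratio estimators; the entangled Y2H mechanism probabilities
#' (`alpha_I`, `alpha_S`, `alpha_U`) are maximized jointly and the capture
#' probabilities (`psi1`, `psi2`) coordinate-wise by greedy hill climbing
#' with step halving from 0.1 down to 1e-4, accepting only improving moves.
#' After updating, every rate pair is re-ordered (`rate_pos > rate_neg`)
#' to resolve label switching, and all components are clipped to
#' `[1e-6, 1 - 1e-6]`. Components whose statistics carry no information
#' (zero denominators) keep their previous values; `psi_bg` and any
#' per-source overrides are never updated.
#'
#' @param stats an [e_step()] result.
#' @param theta_old the current [ppi_params()].
#' @return The updated `ppi_params` object.
#' @export
m_step <- function(stats, theta_old) {
  stopifnot(inherits(stats, "ppi_estats"))
  if (any(stats$zmean < -1e-9 | stats$zmean > 1 + 1e-9) ||
      any(stats$xmean < -1e-9 | stats$xmean > 1 + 1e-9))
    stop("sufficient statistics outside feasible range")
  th <- theta_old
  th$rho <- clip_prob(mean(stats$zmean))
  th$r <- clip_prob(mean(stats$xmean))
  ov <- attr(theta_old, "overrides")
  learn_lit <- function(ch) is.null(ov) || !(ch %in% ov$source_id)
  if ("H" %in% rownames(stats$lit) && learn_lit("H")) {
    st <- stats$lit["H", ]
    th$gamma1 <- ratio_update(st["z_obs"], st["z"], th$gamma1)
    th$gamma0 <- ratio_update(st["nz_obs"], st["nz"], th$gamma0)
  }
  if ("L" %in% rownames(stats$lit) && learn_lit("L")) {
    st <- stats$lit["L", ]
    th$beta1 <- ratio_update(st["z_obs"], st["z"], th$beta1)
    th$beta0 <- ratio_update(st["nz_obs"], st["nz"], th$beta0)
  }
  if (identical(attr(theta_old, "transfer_mode"), "constant")) {
    tp <- stats$tr_pair; tx <- stats$tr_x
    th$phi1 <- ratio_update(tp["z_zs"], tp["z"], th$phi1)
    th$phi0 <- ratio_update(tp["nz_zs"], tp["nz"], th$phi0)
    th$lambda1 <- ratio_update(tx["x_xs"], tx["x"], th$lambda1)
    th$lambda0 <- ratio_update(tx["nx_xs"], tx["nx"], th$lambda0)
  }
  # Y2H mechanisms: joint hill climb on the Q-function
  tab <- stats$y2h_tab[, , , ".shared", drop = FALSE]
  if (sum(tab) > 0) {
    qy <- function(a) {
      v <- 0
      for (z in 0:1) for (s in 0:2) {
        p <- clip_prob(1 - (1 - a[1])^z * (1 - a[2])^s_eff(s, th) *
                         (1 - a[3]))
        v <- v + tab[2, s + 1, z + 1, 1] * log(p) +
          tab[1, s + 1, z + 1, 1] * log1p(-p)
      }
      v
    }
    a <- hill_climb(c(th$alpha_I, th$alpha_S, th$alpha_U), qy)
    th$alpha_I <- a[1]; th$alpha_S <- a[2]; th$alpha_U <- a[3]
  }
  # capture probabilities: coordinate-wise hill climb
  mp <- stats$mpc[".shared", ]
  if (mp["cap1"] + mp["miss1"] > 0) {
    th$psi1 <- hill_climb(th$psi1, function(p)
      mp["cap1"] * log(p) + mp["miss1"] * log1p(-p))
  }
  if (mp["cap2"] + mp["miss2"] > 0) {
    th$psi2 <- hill_climb(th$psi2, function(p)
      mp["cap2"] * log(p) + mp["miss2"] * log1p(-p))
  }
  # identifiability: keep rate_pos above rate_neg
  for (pr in list(c("gamma1", "gamma0"), c("beta1", "beta0"),
                  c("phi1", "phi0"), c("lambda1", "lambda0"))) {
    if (th[[pr[1]]] < th[[pr[2]]]) {
      tmp <- th[[pr[1]]]; th[[pr[1]]] <- th[[pr[2]]]; th[[pr[2]]] <- tmp
    }
  }
  for (nm in .learnable) th[[nm]] <- clip_prob(th[[nm]])
  th
}

# effective self-activation exponent under the configured mode
s_eff <- function(s, theta) {
  if (identical(attr(theta, "selfact_mode"), "indicator")) pmin(s, 1) else s
}

#' Fit the hierarchical evidence-integration model by Monte Carlo EM
#'
#' Alternates Gibbs-sampling E-steps ([e_step()]) with M-steps ([m_step()])
#' until the maximum absolute change in the parameter vector falls below
#' `tol` or `max_iter` iterations are reached. The number of retained
#' sweeps per E-step grows with the iteration (default
#' `samples_base * (1 + iteration)`), the standard increasing-precision
#' schedule for Monte Carlo EM; chains are warm-started between
#' iterations. After convergence the per-pair posterior interaction
#' probabilities are recomputed at the final parameters with
#' [score_posteriors()].
#'
#' @param evidence a [ppi_evidence()] object.
#' @param theta_init starting [ppi_params()]; defaults to
#'   [ppi_params_init()].
#' @param tol convergence tolerance on the maximum absolute componentwise
#'   parameter change.
#' @param max_iter maximum EM iterations; `0` returns `theta_init`
#'   unchanged with `converged = FALSE`.
#' @param n_burnin burn-in sweeps per E-step.
#' @param samples_base base retained-sweep count; iteration `t` uses
#'   `schedule(t)` sweeps.
#' @param schedule function mapping the iteration number (1-based) to the
#'   retained sweep count.
#' @param score_burnin,score_samples sweep counts for the final posterior
#'   scoring pass.
#' @param seed integer seed controlling all Gibbs randomness.
#' @param verbose print per-iteration diagnostics (diff and Monte Carlo
#'   Q-value) to stderr.
#'
#' @return An object of class `ppi_fit` with elements `theta` (the
#'   estimate), `posterior` (data frame of per-pair posterior
#'   probabilities), `trace` (per-iteration parameter values, `diff` and
#'   Q-value), `converged`, `n_iter`, `seed` and `call`. Methods:
#'   [print.ppi_fit()], [summary.ppi_fit()], [coef.ppi_fit()],
#'   [predict.ppi_fit()], [plot.ppi_fit()], [simulate.ppi_fit()].
#' @export
#' @examples
#' sim <- ppi_simulate(ppi_sim_config(n_proteins = 30, n_baits = 5,
#'                                    seed = 7))
#' fit <- ppi_fit(sim$evidence, max_iter = 2, samples_base = 20,
#'                n_burnin = 10, score_samples = 50, verbose = FALSE)
#' coef(fit)["alpha_I"]
ppi_fit <- function(evidence, theta_init = ppi_params_init(), tol = 0.01,
                    max_iter = 50, n_burnin = 50, samples_base = 100,
                    schedule = function(iter) samples_base * (1 + iter),
                    score_burnin = 50, score_samples = 500,
                    seed = 1, verbose = TRUE) {
  stopifnot(inherits(evidence, "ppi_evidence"), tol > 0, max_iter >= 0)
  cl <- match.call()
  index <- evidence_index(evidence, theta_init)
  theta <- theta_init
  trace <- list()
  converged <- FALSE
  init <- NULL
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    ns <- schedule(iter)
    stats <- e_step(evidence, theta, n_burnin = n_burnin, n_samples = ns,
                    seed = seed + iter, index = index, init = init)
    init <- stats$final
    theta_new <- m_step(stats, theta)
    diff <- max(abs(unlist(theta_new[.learnable]) -
                      unlist(theta[.learnable])))
    qv <- q_value(stats, theta_new)
    trace[[iter]] <- c(iteration = iter, unlist(theta_new[.learnable]),
                       diff = diff, q = qv, n_samples = ns)
    if (verbose)
      message(sprintf("MCEM iter %d: diff = %.5f, Q = %.2f (%d sweeps)",
                      iter, diff, qv, ns))
    theta <- theta_new
    if (diff < tol) { converged <- TRUE; break }
  }
  posterior <- score_posteriors(evidence, theta, n_burnin = score_burnin,
                                n_samples = score_samples,
                                seed = seed + max_iter + 1, index = index)
  trace <- if (length(trace)) as.data.frame(do.call(rbind, trace)) else
    data.frame()
  structure(list(theta = theta, posterior = posterior, trace = trace,
                 converged = converged, n_iter = iter, tol = tol,
                 seed = seed, evidence_summary = c(
                   proteins = nrow(evidence$universe),
                   y2h = nrow(evidence$y2h),
                   complexes = nrow(evidence$complexes),
                   literature = nrow(evidence$literature),
                   homologs = nrow(evidence$homology)),
                 call = cl), class = "ppi_fit")
}

#' @export
print.ppi_fit <- function(x, ...) {
  cat("Hierarchical Bayesian PPI evidence integration (Monte Carlo EM)\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%s after %d iteration(s) (tol %.3g)\n",
              if (x$converged) "Converged" else "Did NOT converge",
              x$n_iter, x$tol))
  cat("Parameter estimates:\n")
  print(round(unlist(x$theta[.learnable]), 4))
  invisible(x)
}

#' @describeIn ppi_fit parameter estimates as a named numeric vector.
#' @param object,x a `ppi_fit` object.
#' @param ... unused.
#' @export
coef.ppi_fit <- function(object, ...) unlist(object$theta[.learnable])

#' @describeIn ppi_fit fit overview: estimates, convergence, posterior
#'   summary and the count of confident pairs at a threshold.
#' @param tau posterior threshold used in the summary edge count.
#' @export
summary.ppi_fit <- function(object, tau = 0.8, ...) {
  out <- list(theta = coef(object), converged = object$converged,
              n_iter = object$n_iter,
              evidence = object$evidence_summary,
              n_pairs = nrow(object$posterior),
              n_confident = sum(object$posterior$posterior > tau),
              tau = tau,
              posterior_quartiles = stats::quantile(
                object$posterior$posterior, c(0, .25, .5, .75, 1)))
  class(out) <- "summary.ppi_fit"
  out
}

#' @export
print.summary.ppi_fit <- function(x, ...) {
  cat("Monte Carlo EM fit:",
      if (x$converged) "converged" else "not converged",
      "after", x$n_iter, "iteration(s)\n")
  cat("Evidence: ", paste(names(x$evidence), x$evidence, sep = " = ",
                          collapse = ", "), "\n")
  cat("Parameter estimates:\n"); print(round(x$theta, 4))
  cat("Posterior interaction probabilities over", x$n_pairs, "pairs:\n")
  print(round(x$posterior_quartiles, 4))
  cat(sprintf("Confident pairs (posterior > %.2f): %d\n",
              x$tau, x$n_confident))
  invisible(x)
}

#' @describeIn ppi_fit posterior scores for the fitted evidence (default)
#'   or for a new evidence set, computed at the fitted parameters.
#' @param newdata optional [ppi_evidence()] to score at the fitted
#'   parameters.
#' @param n_burnin,n_samples,seed Gibbs settings for scoring `newdata`.
#' @export
predict.ppi_fit <- function(object, newdata = NULL, n_burnin = 50,
                            n_samples = 500, seed = object$seed, ...) {
  if (is.null(newdata)) return(object$posterior)
  score_posteriors(newdata, object$theta, n_burnin = n_burnin,
                   n_samples = n_samples, seed = seed)
}

#' @describeIn ppi_fit trace plots of the parameter estimates and the
#'   convergence criterion across EM iterations.
#' @param which subset of parameter names to plot.
#' @export
plot.ppi_fit <- function(x, which = c("rho", "alpha_I", "alpha_U",
                                      "psi1", "psi2", "gamma1", "gamma0"),
                         ...) {
  if (!nrow(x$trace)) {
    warning("no iterations to plot")
    return(invisible(x))
  }
  which <- intersect(which, names(x$trace))
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  it <- x$trace$iteration
  graphics::matplot(it, x$trace[, which, drop = FALSE], type = "b",
                    pch = 1, lty = 1, xlab = "EM iteration",
                    ylab = "estimate", main = "Parameter trace", ...)
  graphics::legend("topright", legend = which, col = seq_along(which),
                   lty = 1, cex = 0.7, bty = "n")
  graphics::plot(it, x$trace$diff, type = "b", log = "y",
                 xlab = "EM iteration", ylab = "max |change|",
                 main = "Convergence criterion")
  graphics::abline(h = x$tol, lty = 2)
  invisible(x)
}

#' @describeIn ppi_fit forward-simulate evidence sets from the fitted
#'   parameters (a parametric-bootstrap generator) on a universe of
#'   `n_proteins`.
#' @param nsim number of simulated evidence sets.
#' @param n_proteins universe size for the simulated studies.
#' @export
simulate.ppi_fit <- function(object, nsim = 1, seed = object$seed,
                             n_proteins = 100, ...) {
  lapply(seq_len(nsim), function(k) {
    cfg <- ppi_sim_config(n_proteins = n_proteins,
                          theta_true = object$theta,
                          seed = seed + k, ...)
    ppi_simulate(cfg)
  })
}
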