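#' Model parameter vector
#'
#' Container for the parameters of the hierarchical evidence-integration
#' model. Every component is a probability:
#'
#' * `rho`: prior probability that a random protein pair interacts.
#' * `r`: prior probability that a protein is a self-activator in Y2H.
#' * `alpha_I`, `alpha_S`, `alpha_U`: probabilities that a Y2H replicate
#'   reports positive through a true interaction, a self-activation event
#'   (per self-activating partner), or an unknown process.
#' * `psi1`, `psi2`: probabilities that a pull-down bait captures a 1-step
#'   (direct) or 2-step neighbour into its complex; `psi_bg` is a small,
#'   fixed background capture probability for proteins at distance three or
#'   more from the bait (kept out of estimation).
#' * `gamma1`, `gamma0`: literature channel H true/false positive report
#'   rates; `beta1`, `beta0`: the same for channel L.
#' * `phi1`, `phi0`: probability that an interaction (respectively
#'   non-interaction) between human proteins transfers to the homologous
#'   pair in another organism; `lambda1`, `lambda0` play the same role for
#'   self-activation status.
#'
#' Rate pairs are ordered (`gamma1 > gamma0` etc.) to fix the labelling of
#' the latent classes; [m_step()] re-imposes the ordering after estimation.
#' `psi2 <= psi1` is deliberately not enforced.
#'
#' @param rho,r,alpha_I,alpha_S,alpha_U,psi1,psi2,psi_bg,gamma1,gamma0,beta1,beta0,phi1,phi0,lambda1,lambda0
#'   numeric scalars in `[0, 1]` (see above).
#' @param transfer_mode `"constant"` (homology transfer rates do not depend
#'   on sequence identity, the default) or `"logistic"` (rates increase with
#'   identity; see [transfer_prob()]).
#' @param logistic_coef when `transfer_mode = "logistic"`, a named list with
#'   elements `phi1`, `phi0`, `lambda1`, `lambda0`, each `c(a, b)` with
#'   `b >= 0`, giving the rate `plogis(a + b * identity)`.
#' @param selfact_mode `"exponent"` (each self-activating partner
#'   independently triggers the self-activation mechanism, the default) or
#'   `"indicator"` (the mechanism fires at most once per pair).
#' @param overrides optional data frame with columns `source_id`,
#'   `parameter`, `value`: fixed per-source parameter values keyed by the
#'   evidence `source_id`. Overridden sources use these values and are
#'   excluded from shared-parameter estimation.
#'
#' @return An object of class `ppi_params` (a named list).
#' @seealso [ppi_fit()], [y2h_response_prob()], [transfer_prob()]
#' @export
#' @examples
#' theta <- ppi_params(rho = 0.01, alpha_I = 0.9)
#' theta$alpha_I
ppi_params <- function(rho = 0.005, r = 1e-4,
                       alpha_I = 0.5, alpha_S = 0.3, alpha_U = 0.01,
                       psi1 = 0.7, psi2 = 0.3, psi_bg = 1e-3,
                       gamma1 = 0.7, gamma0 = 0.05,
                       beta1 = 0.7, beta0 = 0.05,
                       phi1 = 0.7, phi0 = 0.05,
                       lambda1 = 0.7, lambda0 = 0.05,
                       transfer_mode = c("constant", "logistic"),
                       logistic_coef = NULL,
                       selfact_mode = c("exponent", "indicator"),
                       overrides = NULL) {
  transfer_mode <- match.arg(transfer_mode)
  selfact_mode <- match.arg(selfact_mode)
  theta <- list(rho = rho, r = r,
                alpha_I = alpha_I, alpha_S = alpha_S, alpha_U = alpha_U,
                psi1 = psi1, psi2 = psi2, psi_bg = psi_bg,
                gamma1 = gamma1, gamma0 = gamma0,
                beta1 = beta1, beta0 = beta0,
                phi1 = phi1, phi0 = phi0,
                lambda1 = lambda1, lambda0 = lambda0)
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("parameter '", nm, "' must be a scalar probability in [0, 1]")
  }
  if (transfer_mode == "logistic") {
    if (is.null(logistic_coef))
      logistic_coef <- list(phi1 = c(0, 3), phi0 = c(-4, 2),
                            lambda1 = c(0, 3), lambda0 = c(-4, 2))
    stopifnot(all(c("phi1", "phi0", "lambda1", "lambda0") %in%
                    names(logistic_coef)))
    for (nm in c("phi1", "phi0", "lambda1", "lambda0")) {
      cf <- logistic_coef[[nm]]
      if (length(cf) != 2L || cf[2L] < 0)
        stop("logistic_coef$", nm, " must be c(a, b) with b >= 0")
    }
  }
  if (!is.null(overrides)) {
    overrides <- as.data.frame(overrides, stringsAsFactors = FALSE)
    stopifnot(all(c("source_id", "parameter", "value") %in% names(overrides)))
    bad <- setdiff(overrides$parameter, names(theta))
    if (length(bad))
      stop("unknown parameter(s) in overrides: ", paste(bad, collapse = ", "))
    if (any(overrides$value < 0 | overrides$value > 1))
      stop("override values must lie in [0, 1]")
  }
  structure(theta,
            transfer_mode = transfer_mode,
            logistic_coef = logistic_coef,
            selfact_mode = selfact_mode,
            overrides = overrides,
            class = "ppi_params")
}

#' Default initial parameter values for model fitting
#'
#' Weakly informative interior starting point for [ppi_fit()].
#'
#' @inheritParams ppi_params
#' @param ... passed on to [ppi_params()].
#' @return A `ppi_params` object.
#' @export
ppi_params_init <- function(...) {
  ppi_params(rho = 0.005, r = 1e-4, alpha_I = 0.5, alpha_S = 0.3,
             alpha_U = 0.01, psi1 = 0.7, psi2 = 0.3,
             gamma1 = 0.7, gamma0 = 0.05, beta1 = 0.7, beta0 = 0.05,
             phi1 = 0.7, phi0 = 0.05, lambda1 = 0.7, lambda0 = 0.05, ...)
}

# Components updated by the M-step (psi_bg stays fixed).
.learnable <- c("rho", "r", "alpha_I", "alpha_S", "alpha_U", "psi1", "psi2",
                "gamma1", "gamma0", "beta1", "beta0",
                "phi1", "phi0", "lambda1", "lambda0")

# Effective parameters for one evidence source: shared values with any
# per-source overrides applied.
theta_for_source <- function(theta, source_id) {
  ov <- attr(theta, "overrides")
  if (is.null(ov)) return(theta)
  hit <- ov[ov$source_id == source_id, , drop = FALSE]
  if (!nrow(hit)) return(theta)
  for (k in seq_len(nrow(hit))) theta[[hit$parameter[k]]] <- hit$value[k]
  theta
}

# TRUE for sources whose parameters are fixed by an override (excluded from
# shared-parameter sufficient statistics).
source_is_overridden <- function(theta, source_id) {
  ov <- attr(theta, "overrides")
  !is.null(ov) && source_id %in% ov$source_id
}

clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' @export
print.ppi_params <- function(x, ...) {
  cat("Evidence-integration model parameters\n")
  v <- unlist(x[.learnable])
  print(round(v, 6))
  cat("psi_bg (fixed):", format(x$psi_bg), "\n")
  cat("transfer mode:", attr(x, "transfer_mode"),
      "| self-activation mode:", attr(x, "selfact_mode"), "\n")
  ov <- attr(x, "overrides")
  if (!is.null(ov) && nrow(ov))
    cat("per-source overrides:", nrow(ov), "entries for source(s) ",
        paste(unique(ov$source_id), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.numeric.ppi_params <- function(x, ...) unlist(x[.learnable])
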