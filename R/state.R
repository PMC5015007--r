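#' Latent interaction state
#'
#' The unobserved quantities of the model: for each organism, a symmetric
#' binary interaction matrix `Z` (no self-pairs) and a binary
#' self-activation vector `X`. The human state is the target of inference;
#' states of other organisms ("starred" states) are tied to it through the
#' homology-transfer factors.
#'
#' @param universe data frame with columns `protein`, `organism` (as in
#'   [ppi_evidence()]), or a `ppi_evidence` object.
#' @param edges optional data frame with columns `protein_a`, `protein_b`
#'   listing interacting pairs (each within one organism).
#' @param selfact optional character vector of self-activating proteins.
#'
#' @return An object of class `ppi_state`: a list with named lists `Z`
#'   (organism -> symmetric 0/1 matrix) and `X` (organism -> named 0/1
#'   vector).
#' @export
#' @examples
#' uni <- data.frame(protein = c("A", "B", "C"), organism = "human")
#' st <- ppi_state(uni, edges = data.frame(protein_a = "A", protein_b = "B"))
#' st$Z$human["A", "B"]
ppi_state <- function(universe, edges = NULL, selfact = NULL) {
  if (inherits(universe, "ppi_evidence")) universe <- universe$universe
  stopifnot(all(c("protein", "organism") %in% names(universe)))
  if (anyDuplicated(universe$protein))
    stop("universe protein identifiers must be unique")
  orgs <- unique(c("human", universe$organism))
  Z <- list(); X <- list()
  for (o in orgs) {
    prots <- universe$protein[universe$organism == o]
    m <- matrix(0L, length(prots), length(prots),
                dimnames = list(prots, prots))
    Z[[o]] <- m
    X[[o]] <- stats::setNames(integer(length(prots)), prots)
  }
  st <- structure(list(Z = Z, X = X), class = "ppi_state")
  if (!is.null(edges) && nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- as.character(edges$protein_a[k]); b <- as.character(edges$protein_b[k])
      o <- universe$organism[match(a, universe$protein)]
      ob <- universe$organism[match(b, universe$protein)]
      if (is.na(o) || is.na(ob) || o != ob)
        stop("edge (", a, ", ", b, ") does not join two proteins of one organism")
      if (a == b) stop("self-pair (", a, ") not allowed in the latent state")
      st$Z[[o]][a, b] <- 1L
      st$Z[[o]][b, a] <- 1L
    }
  }
  if (!is.null(selfact) && length(selfact)) {
    for (a in as.character(selfact)) {
      o <- universe$organism[match(a, universe$protein)]
      if (is.na(o)) stop("unknown protein in selfact: ", a)
      st$X[[o]][a] <- 1L
    }
  }
  st
}

#' @export
print.ppi_state <- function(x, ...) {
  cat("Latent PPI state\n")
  for (o in names(x$Z)) {
    n <- nrow(x$Z[[o]])
    cat(sprintf("  %s: %d proteins, %d interactions, %d self-activators\n",
                o, n, sum(x$Z[[o]]) / 2L, sum(x$X[[o]])))
  }
  invisible(x)
}

# edge list (canonical order) of one organism's latent graph
state_edges <- function(state, organism = "human") {
  m <- state$Z[[organism]]
  idx <- which(upper.tri(m) & m == 1L, arr.ind = TRUE)
  data.frame(protein_a = rownames(m)[idx[, 1L]],
             protein_b = colnames(m)[idx[, 2L]],
             stringsAsFactors = FALSE)
}
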