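#' Restrict an evidence set to selected source types
#'
#' Builds the single-source restrictions of the model used to quantify the
#' value of evidence integration: `"y2h"` keeps human Y2H records only,
#' `"mpc"` human complexes only, `"literature"` literature indicators only,
#' `"homology"` the cross-organism block (homolog map plus the other
#' organisms' Y2H and complex records). The protein universe is preserved
#' so posterior scores stay comparable across restrictions.
#'
#' @param ev a [ppi_evidence()] object.
#' @param sources subset of `c("y2h", "mpc", "literature", "homology")`.
#' @return A restricted `ppi_evidence` object on the same universe.
#' @export
restrict_evidence <- function(ev, sources) {
  sources <- match.arg(sources, c("y2h", "mpc", "literature", "homology"),
                       several.ok = TRUE)
  human_y2h <- ev$y2h[ev$y2h$organism == "human", , drop = FALSE]
  star_y2h <- ev$y2h[ev$y2h$organism != "human", , drop = FALSE]
  human_cx <- ev$complexes[ev$complexes$organism == "human", , drop = FALSE]
  star_cx <- ev$complexes[ev$complexes$organism != "human", , drop = FALSE]
  y2h <- NULL; cx <- NULL; lit <- NULL; hom <- NULL
  if ("y2h" %in% sources) y2h <- human_y2h
  if ("mpc" %in% sources) cx <- human_cx
  if ("literature" %in% sources) lit <- ev$literature
  if ("homology" %in% sources) {
    hom <- ev$homology
    y2h <- rbind(y2h, star_y2h)
    cx <- rbind(cx, star_cx)
  }
  uni <- ev$universe
  if (!"homology" %in% sources)
    uni <- uni[uni$organism == "human", , drop = FALSE]
  ppi_evidence(y2h = y2h, complexes = cx, literature = lit, homology = hom,
               universe = uni)
}

#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) AUROC of scores against binary labels, with ties
#' handled by midranks. Used to compare posterior rankings against
#' ground-truth interaction status in simulations.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 (or logical) ground truth.
#' @return The AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels %in% c(1, TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative labels")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ground-truth labels aligned with a posterior score data frame
truth_labels <- function(scores, truth) {
  Z <- truth$state$Z$human
  as.integer(Z[cbind(scores$protein_a, scores$protein_b)])
}
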