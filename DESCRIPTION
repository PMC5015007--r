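Package: ppibayes
Title: Hierarchical Bayesian Integration of Protein-Protein Interaction Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous protein-protein interaction evidence
    (yeast two-hybrid screens with self-activation artifacts, mass-spectrometry
    pull-down complexes, literature reports, and cross-organism homolog
    transfer) into per-pair posterior interaction confidences under a
    hierarchical Bayesian latent-variable model fitted by Monte Carlo EM with
    Gibbs sampling. Includes a forward simulator for the full generative
    model, construction of the high-confidence weighted interaction network by
    posterior thresholding, SCAN structural clustering with epsilon selected
    by similarity-based modularity, and hypergeometric enrichment of
    intrinsically disordered proteins in network modules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
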