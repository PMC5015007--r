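---
title: "Integrating heterogeneous protein-protein interaction evidence"
author: "ppibayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating heterogeneous protein-protein interaction evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppibayes)
```

## The problem

High-throughput protein–protein interaction (PPI) assays disagree with one
another and with themselves. Yeast two-hybrid (Y2H) screens report
reporter-gene activation that can be triggered by a real binary
interaction, by a self-activating bait, or by an unknown background
process. Mass-spectrometry pull-downs (MPC) return whole co-purifying
complexes, in which most member pairs do not touch each other directly.
Literature-curated databases carry their own false positive and false
negative rates, and much of what we believe about human interactions is
transferred from orthologous pairs in yeast or other model organisms.

`ppibayes` treats the true binary interaction status `Z[ij]` of every
unordered human protein pair — and the self-activation status `X[i]` of
every protein — as latent variables, models each evidence type with its
own error process conditional on the latent state, and reports the
posterior probability `Pr[Z[ij] = 1 | all evidence]` as the confidence of
each candidate interaction. Downstream, pairs above a confidence threshold
form a weighted network that is clustered into functional modules and
tested for enrichment of intrinsically disordered proteins (IDPs).

## The hierarchical model

**Priors.** `Z[ij] ~ Bernoulli(rho)` independently over pairs and
`X[i] ~ Bernoulli(r)` over proteins.

**Y2H.** A replicate on pair (i, j) reports positive with probability

    Pr[Y = 1 | Z, X] = 1 - (1 - alpha_I)^Z[ij] (1 - alpha_S)^(X[i] + X[j]) (1 - alpha_U)

i.e. at least one of three independent mechanisms fires: a true
interaction (`alpha_I`), self-activation (`alpha_S`, once per
self-activating partner), or background (`alpha_U`). The literal exponent
`X[i] + X[j]` means two self-activating partners double-dip the
self-activation mechanism; a configuration switch
(`selfact_mode = "indicator"` in `ppi_params()`) collapses it to an
at-most-once indicator for users who prefer the conditioning-based
reading. We default to the exponent form because it is the form the
complete likelihood factorizes over.

**MPC.** For a bait k, each 1-step neighbour (direct interactor under `Z`)
enters the pulled complex with probability `psi1`, each 2-step neighbour
with `psi2`, and missed neighbours contribute `(1 - psi)` factors. The
model as stated assigns probability zero to observed members at distance
three or more, yet distant proteins are occasionally pulled down in
practice, so we add a small fixed background capture probability
(`psi_bg`, default `1e-3`, never estimated) for each distant observed
member and charge no factor for the astronomically many distant proteins
that were not observed. This keeps the likelihood finite and local without
a product over the whole proteome. `psi2 <= psi1` is deliberately not
enforced: estimated capture rates for 2-step neighbours can legitimately
exceed the direct rate in some data sets.

**Literature.** Channel H reports a pair with probability `gamma1` when it
truly interacts and `gamma0` when it does not; channel L uses `(beta1,
beta0)`. With both rates free, the labels of the two latent classes can
switch, so after every M-step the rate pairs are re-ordered to keep
`rate_pos > rate_neg`.

**Cross-organism transfer.** Starred latent states `(Z*, X*)` in other
organisms are tied to the human state by transfer probabilities:
`Pr[Z* = 1 | Z] = Delta_1^Z Delta_0^(1-Z)`, and analogously for `X*` with
`(lambda1, lambda0)`. Two parameterizations are available. The default
`"constant"` mode uses the bare rates `phi1`/`phi0`, which is the form the
complete likelihood uses and the only mode whose rates are re-estimated.
The `"logistic"` mode makes the rates increase with sequence identity,
`plogis(a + b * I)` with `b >= 0`; its coefficients are taken as given.
The joint identity of a pair of aligned pairs is not prescribed by the
model, so we use the geometric mean `J = sqrt(I[ii'] * I[jj'])`: it is
symmetric, lives in `[0, 1]`, and vanishes if either alignment does.

Starred pairs whose endpoints lack a homolog mapping fall back to the
`rho`/`r` priors.

## Monte Carlo EM

The posterior over roughly `n^2 / 2` coupled binary variables is
intractable, so parameters are estimated by Monte Carlo EM:

* **E-step** — systematic-scan Gibbs sampling of every latent variable
  from its full conditional. The conditional of `Z[ij]` multiplies the
  prior (or transfer) odds with the Y2H, literature and transfer factors
  on that pair, plus the pull-down factors of nearby baits. Toggling one
  edge can only re-classify its own endpoints (and, when the bait is an
  endpoint, the opposite endpoint's neighbours), so the complex-factor
  update touches only baits within graph distance 2 — this locality is
  what makes sweeps over a few hundred thousand pairs affordable; the
  sweep kernel is compiled (Rcpp).
* **M-step** — conjugate Bernoulli components (`rho`, `r`, the literature
  and transfer rates) have closed-form Monte Carlo ratio maximizers. The
  Y2H mechanism probabilities are entangled through the product form and
  are maximized jointly by greedy coordinate ascent with step halving
  (0.1 down to `1e-4`, accepting only improving moves); the capture
  probabilities are maximized the same way coordinate-wise. Both routes
  maximize the same Monte Carlo Q-function, so the EM ascent property is
  preserved (and is checked numerically in the test suite).

Iteration stops when the maximum absolute parameter change falls below
`tol` (default 0.01). Burn-in (50 sweeps), the growing retained-sample
schedule (`100 * (1 + iteration)`), and the cap of 50 iterations follow
standard increasing-precision MCEM practice; chains warm-start from the
previous iteration's final state. All parameters are clipped to
`[1e-6, 1 - 1e-6]` after every update so that no full conditional ever
degenerates. All Gibbs randomness flows through R's RNG, making every fit
exactly reproducible from its seed.

`exact_posterior()` provides a brute-force enumeration oracle (capped at
20 latent bits) against which the sampler is validated on small instances;
the two are independent code paths sharing only the per-factor probability
primitives.

## What the simulator emulates — and what it does not

`ppi_sim_config()` forward-samples the full generative model: ground truth
from the priors, Y2H replicates, per-bait complexes (baits drawn uniformly
among proteins with at least one true neighbour), literature indicators
for both channels, orthologs with uniform sequence identities on
`[0.3, 1]`, and starred evidence inside each homolog organism. Literature
coverage defaults to complete — an explicit 0/1 indicator per pair —
which treats the absence of a report as evidence, the same reading the
likelihood uses.

Default generative parameters are `rho = 0.01`, `alpha_I = 0.9`,
`alpha_S = 0.4`, `alpha_U = 0.005`, `psi1 = 0.8`, `psi2 = 0.4`,
`gamma1 = 0.8`, `gamma0 = 0.01`, with 2 Y2H replicates at full coverage,
100 baits per 500 proteins and one homolog organism covering 60% of
proteins. The self-activation frequency is `r = 0.02`: real screens put
the frequency of self-activating baits orders of magnitude lower, but at
desk scale such a rate would produce zero self-activators and leave the
self-activation machinery untested, so we chose a small value that
exercises it.

Two deliberate departures from biological realism: edges are otherwise
independent (no degree heterogeneity, no hub structure), and planted
communities — blocks of proteins with elevated within-block interaction
probability `p_within = 0.35` and, optionally, elevated IDP frequency —
are a device to give the clustering and enrichment stages a known positive
control, not a model of real module topology. Passing tests on these
simulations demonstrates that the inference machinery recovers the model
it assumes; it cannot certify performance on real screens whose error
processes deviate from that model.

Disorder annotations assign each protein a longest-disordered-region
length: uniform on 41–300 aa for planted IDPs, 0–40 aa otherwise, around
the field's 40-residue IDP convention.

## Network, modules, enrichment

Pairs with posterior strictly above `tau = 0.8` form the high-confidence
network, weighted by the posterior; proteins with no confident partner are
dropped (a flag retains them). Clustering uses SCAN on the topology alone
— edge weights are not used, keeping module discovery a function of the
network structure. Structural similarity is the standard normalized
closed-neighbourhood overlap; a vertex is a core when at least `mu = 2`
of its neighbours are `epsilon`-similar (the canonical SCAN core size —
the clustering itself supplies no natural default), clusters grow by
structure-reachability in sorted-vertex order (deterministic, edge-order
independent), and leftover vertices become hubs (adjacent to two or more
clusters) or outliers.

`epsilon` is chosen by sweeping a grid (default 0.05–0.95 by 0.01) and
maximizing the similarity-based modularity `Q_S`; ties go to the smallest
`epsilon`. `Q_S` is the similarity-weighted analogue of Newman modularity
`Q_N` — within-module similarity mass minus its degree-expectation, with
the normalization `(DS_s / (2 TS))^2` chosen so that `Q_S` reduces exactly
to `Q_N` when all edge similarities are equal. Hubs and outliers enter
both metrics as singleton modules, since the formulas require a full
partition. Plain `Q_N` typically decreases monotonically over the grid on
these networks, which is precisely why the similarity-based variant is
the selection criterion.

Module enrichment uses the upper-tail hypergeometric probability with the
clustered network as the population (modules are drawn from it, so it is
the exchangeable reference set; the full universe would be an
anti-conservative alternative). A protein counts as an IDP when its
longest continuous disordered region is strictly longer than 40 aa. No
multiple-testing correction is applied by default — the module count at
desk scale is small and the raw-`alpha` convention keeps the flagged set
interpretable — but Benjamini–Hochberg is available behind
`correction = "BH"`. Hub composition (`hub_idp_fraction()`) calls hubs at
induced-subgraph degree strictly above 5.

## Numerical choices and edge cases

* Probabilities are clipped to `[1e-6, 1 - 1e-6]` wherever a log or a
  logit is taken; a user-supplied boundary value (e.g. `gamma1 = 1`) is
  honoured exactly in `exact_posterior()` arithmetic but clipped inside
  the sampler.
* Self-pairs carry no information under the model and are dropped from
  evidence with a warning; homodimers are out of scope.
* Evidence on a pair from several sources aggregates per parameter
  group before sampling, so per-source overrides (fixed parameter values
  keyed by `source_id`) coexist with shared learnable parameters;
  overridden sources are excluded from the shared sufficient statistics.
* A zero denominator in any ratio update (an evidence channel that never
  touched a sampled state) leaves that component at its previous value.
* `exact_posterior()` refuses instances above 20 latent bits rather than
  silently thrashing.

## Problem sizes

The package's own validation runs at deliberately modest scale: parameter
recovery on 500 proteins (about 125,000 latent pair variables, four
evidence types, one homolog organism), oracle agreement on 3–4 protein
instances, and the full pipeline on 200 proteins with eleven planted
communities. A recovery fit at 500 proteins completes in a few minutes on
one core.

## Known limitations

* Single-site Gibbs mixes slowly when a complex factor couples several
  pairs tightly; posterior scores on such pairs carry more Monte Carlo
  error than independent-pair arithmetic suggests. Block updates or
  tempering are natural extensions.
* Per-source parameters are supported as fixed overrides only; they are
  not learned.
* The logistic transfer mode is scored but its coefficients are not
  estimated (the constant mode is the estimating mode).
* `rho` is estimated from human pairs only; starred pairs without a
  homolog mapping use `rho` in their prior but do not inform its update —
  immaterial in the shipped simulator, where every starred protein is an
  ortholog by construction.
* The enumeration oracle scales as `2^bits` and is a test instrument, not
  an inference path.
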