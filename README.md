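# ppibayes

Confidence-scored human protein–protein interaction (PPI) networks from
heterogeneous, error-prone evidence.

High-throughput interaction screens disagree: yeast two-hybrid (Y2H)
reporters fire on self-activating baits and background processes,
mass-spectrometry pull-downs (MPC) return whole complexes rather than
binary contacts, literature curation has its own false positive and false
negative rates, and much of the human interactome is inferred from
orthologs in other organisms. `ppibayes` integrates all four evidence
types in one hierarchical Bayesian model and reports, for every protein
pair, the posterior probability that the pair truly interacts. It is
aimed at systems-biology analysts who want calibrated interaction
confidences — and uncertainty-aware downstream network analysis — rather
than a hard union or intersection of databases.

## The model

The true interaction status Z<sub>ij</sub> ∈ {0,1} of each unordered pair
and the self-activation status X<sub>i</sub> of each protein are latent,
with priors Z<sub>ij</sub> ~ Bern(ρ), X<sub>i</sub> ~ Bern(r). Each
evidence type has its own observation model:

* **Y2H**: Pr[Y=1 | Z,X] = 1 − (1−α<sub>I</sub>)<sup>Z<sub>ij</sub></sup>
  (1−α<sub>S</sub>)<sup>X<sub>i</sub>+X<sub>j</sub></sup> (1−α<sub>U</sub>)
  — a replicate fires through a true interaction, self-activation, or an
  unknown process.
* **MPC**: a bait captures 1-step neighbours with probability ψ₁, 2-step
  neighbours with ψ₂ (plus a tiny fixed background rate for distant
  proteins), with (1−ψ) factors for missed neighbours.
* **Literature**: channel-specific true/false positive report rates
  (γ₁, γ₀) and (β₁, β₀).
* **Homology transfer**: starred states (Z\*, X\*) in other organisms
  follow the human state with transfer rates (φ₁, φ₀) and (λ₁, λ₀).

Parameters θ are estimated by Monte Carlo EM: a compiled Gibbs sampler
draws the latent state in the E-step and closed-form ratio estimators plus
greedy hill climbing maximize the Monte Carlo Q-function in the M-step.
Pairs with posterior Pr[Z<sub>ij</sub>=1 | evidence] > 0.8 form the
high-confidence weighted network, which is clustered with SCAN (ε chosen
by maximizing similarity-based modularity Q<sub>S</sub>) and tested
module-by-module for enrichment of intrinsically disordered proteins
(IDPs, disordered region > 40 aa) with the hypergeometric tail
probability.

See the methods vignette (`vignettes/evidence-integration.Rmd`) for
modelling details, defaults and limitations.

## Worked example

```r
library(ppibayes)

# forward-simulate a 120-protein study from the generative model
sim <- ppi_simulate(ppi_sim_config(n_proteins = 120, n_baits = 30,
                                   seed = 5))
fit <- ppi_fit(sim$evidence, seed = 2)
#> MCEM iter 1: diff = 0.24609, Q = -379082.65 (200 sweeps)
#> MCEM iter 2: diff = 0.09219, Q = -525687.41 (300 sweeps)
#> MCEM iter 3: diff = 0.03027, Q = -692371.81 (400 sweeps)
#> MCEM iter 4: diff = 0.00898, Q = -862624.70 (500 sweeps)

round(coef(fit)[c("rho", "alpha_I", "alpha_U", "psi1", "gamma1")], 4)
#>    rho alpha_I alpha_U    psi1  gamma1
#> 0.0092  0.8775  0.0051  0.8799  0.7717
```

The fit converged in four EM iterations (`diff` is the largest parameter
change per iteration; iteration stops below 0.01). The estimates sit near
the generative values (ρ = 0.01, α_I = 0.9, α_U = 0.005, ψ₁ = 0.8,
γ₁ = 0.8): the interaction prior, the Y2H true-interaction and background
rates, the bait capture rate and the literature true positive rate are all
recovered from the noisy evidence alone. Ranking every pair by posterior
against the simulated ground truth separates true from false pairs
perfectly at this small scale (AUROC = 1.0; at 500 proteins it is about
0.999).

Downstream:

```r
net <- threshold_network(fit$posterior, tau = 0.8)  # confident pairs only
sel <- select_epsilon(net)                          # SCAN + Q_S sweep
res <- test_modules(sel$partition, disorder_annotation(sim$disorder))
```

`res` lists each module's size, IDP count and hypergeometric p-value; on
simulations with a planted IDP-rich community the planted module is the
one flagged at α = 0.05.

A command-line front end covering the same pipeline (simulate / fit /
score / cluster / enrich stages exchanging TSV files) is installed as
`inst/scripts/ppibayes`.

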