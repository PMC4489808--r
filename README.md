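# snbda — Bayesian spatial network-based diffusion analysis

`snbda` infers **social transmission of behaviour** from diffusion data
when the only structural information available is *where individuals
live*: the coordinates of their nests or home bases. It is aimed at
behavioural ecologists studying territorial populations for which
direct association or interaction data cannot be collected, but
spatially structured data (increasingly available through bio-logging
and remote sensing) can.

## The model

Each individual occupies a circular **zone of influence** of
interaction radius *r* around its home base. The association of *j*
with *i* is the normalised overlap of their zones,

    a_ij = |Z_i ∩ Z_j| / |Z_i|,

the proportion of *i*'s zone shared with *j* (receiver normalisation;
the sender variant is a switch). Given the association matrix *A*, the
rate at which a naive individual *i* first performs the behaviour is
the NBDA hazard in its time-of-acquisition (TADA) form,

    λ_i(t) = (1 − z_i(t)) ( s′ Σ_{j≠i} a_ij z_j(t) + λ0 exp(β c_i) ),

with `z_j(t)` the informed indicator, `λ0` the baseline asocial rate,
`s′` the social transmission rate per unit association with informed
individuals, and `β` the effect of a normalised environmental covariate
`c_i`. Three nested models — {λ0}, {λ0, s′}, {λ0, s′, β} — are fitted
in a Bayesian framework (Uniform(−10, 10) priors on log parameters,
uniform random-walk Metropolis) and discriminated by reversible-jump
MCMC, with posterior model probabilities given by visit fractions and
Bayes factors by their ratios.

Around that core the package provides:

* exact lens-formula and Monte Carlo zone-overlap areas, and
  association-matrix construction (`disc_overlap_area`,
  `association_matrix`);
* exploratory point-pattern statistics for choosing the interaction
  radius: Ripley's K, a kernel pair-correlation estimate with
  reliability flags, CSR simulation envelopes, and an automatic radius
  suggestion (`ripley_k`, `pair_correlation`, `csr_envelope`,
  `suggest_interaction_radius`), plus the union-of-discs term of the
  area-interaction point-process density;
* an exact Gillespie simulator of diffusions on the spatial network and
  a full synthetic-study generator (`simulate_diffusion_gillespie`,
  `simulate_study`);
* the classical wave-of-advance regression baseline
  (`wave_of_advance`);
* CSV I/O, a one-call pipeline (`run_pipeline`), and a command-line
  wrapper (`inst/scripts/snbda.R`).

## Worked example

Simulate a clustered 26-individual-scale study (ten diffusions with a
strong social effect), choose the interaction radius from the pair
correlation function, and run the three-model analysis:

```r
library(snbda)
st <- simulate_study("clustered", seed = 1)
st$pattern
#> Point pattern: 17 points in [0, 1] x [0, 1]
#>   interaction radius: 0.05

pcf <- pair_correlation(st$pattern, n_sim = 99, seed = 2)
sug <- suggest_interaction_radius(pcf)
sug$radius      # 0.04  (type "clustered")

A <- association_matrix(st$pattern, radius = sug$radius)
rj <- rjmcmc_sample(1:3, st$diffusions, A, covariates = st$covariates,
                    n_iter = 20000, burn_in = 2000, seed = 3)
s <- posterior_summary(rj)
round(s$model_probabilities, 3)
#>     1     2     3
#> 0.000 0.718 0.282
s$parameters
#>   model   parameter      mean     low   high     n
#> 1     2 log_lambda0 -1.492338 -1.7503 -1.244 12924
#> 2     2 log_s_prime  1.105775  0.8838  1.303 12924
#> 3     3 log_lambda0 -1.492305 -1.7444 -1.249  5076
#> 4     3 log_s_prime  1.109402  0.8869  1.311  5076
#> 5     3        beta  0.000943 -0.0975  0.107  5076
bayes_factor(rj, 2, 3)   # 2.55

wave_of_advance(st$pattern, st$diffusions[[1]])
#> Wave of advance (distance_on_time, n = 16): slope 0.07159
#>   (SE 0.02235, p = 0.00639), R^2 = 0.423
```

Reading the output: the null (asocial) model receives essentially zero
posterior support, the social model dominates, and the Bayes factor of
about 2.5 says the environmental covariate adds little (its posterior
is centred on zero — the data were generated without an environmental
effect). The posterior means are on the natural-log scale: a baseline
rate around e^−1.5 ≈ 0.22 and a social rate per unit association
around e^1.1 ≈ 3. The wave-of-advance regression on the same data
explains less than half the variance even in this easy single-origin
case, and far less on typical replicates — distance from one origin is
a poor summary of network-structured spread.

The same workflow runs from the shell:

```sh
Rscript inst/scripts/snbda.R simulate --outdir demo --seed 1
Rscript inst/scripts/snbda.R explore  --population demo/population.csv --outdir demo
Rscript inst/scripts/snbda.R rjmcmc   --population demo/population.csv \
    --diffusion demo/diffusion_01.csv --radius 0.05 --outdir demo
```

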