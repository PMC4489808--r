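---
title: "Methods: Bayesian spatial network-based diffusion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian spatial network-based diffusion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Network-based diffusion analysis (NBDA) detects and quantifies social
transmission by asking whether the times at which individuals first
perform a novel behaviour follow a social network: individuals strongly
associated with already-informed individuals should acquire the trait
sooner. When no direct association data exist but the spatial locations
of individuals' nests or home bases are known, the network itself can be
derived from space. `snbda` implements this spatial variant end to end:
association matrices from zone-of-influence overlap, exploratory
point-pattern statistics to choose the interaction radius, Bayesian
fitting of nested hazard models with reversible-jump model
discrimination, a Gillespie simulator to generate diffusions under the
same model, and the classical wave-of-advance regression as a baseline
for comparison.

# Spatially derived associations

Each individual $i$ occupies a disc $Z_i$ of radius $r$ (the
*interaction radius*) centred at its home base, within which its
influence is assumed constant. The association $a_{ij}$ — the influence
of $j$ on $i$ — is the overlap area normalised by a zone area:

$$a_{ij} = \frac{|Z_i \cap Z_j|}{|Z_i|}.$$

Normalising by the *receiver*'s zone (the default) makes $a_{ij}$ the
proportion of $i$'s own zone shared with $j$, i.e. the proportion of
time $i$ spends under $j$'s influence; with unequal radii the matrix is
asymmetric, the smaller-radius individual receiving the larger
proportional influence. The literature is not unanimous on whether the
sender's or receiver's zone should be the denominator, so
`association_matrix(normalise = "sender")` provides the alternative
(which is simply the transpose).

Overlap areas are computed with the closed-form circle–circle lens
formula rather than by Monte Carlo integration; an unbiased hit-or-miss
estimator (`disc_overlap_area_mc()`) is retained as an independent
cross-check and the two are tested against each other. Zones are *not*
clipped at the observation window: the window bounds the points, not
the discs. This is a modelling assumption, reasonable when home bases
are interior to the study area.

# Choosing the interaction radius

The interaction radius should reflect the scale at which individuals
actually interact. The package follows standard exploratory
point-pattern practice:

* `ripley_k()` estimates $K(r) = \xi^{-1}\,
  \mathbb{E}[\#\text{ points within } r \text{ of a typical point}]$
  with translation edge correction (unbiased on rectangular windows;
  the choice of correction is a numerical detail the estimand does not
  depend on).
* `pair_correlation()` estimates $g(r) = K'(r)/(2\pi r)$ by Epanechnikov
  kernel smoothing of the pairwise distances. The default bandwidth is
  Stoyan's rule of thumb $h = 0.15/\sqrt{\hat\xi}$. Values are flagged
  unreliable where fewer than 5 pairwise distances fall within one
  bandwidth of $r$, and at $r < h$, where the kernel window extends
  below zero distance and the $1/(2\pi r)$ factor inflates the
  estimate; such scales must not be used as interaction radii.
* `csr_envelope()` builds a pointwise min/max envelope of $g$ over
  `n_sim` binomial (CSR) patterns with the same $n$ and window. The
  default is 99 simulations — enough for a pointwise test at roughly
  the 2% level while keeping envelopes cheap to recompute; the count is
  configurable for users who prefer the more common 999.
* `suggest_interaction_radius()` returns the $r$ at which $g$ most
  exceeds the upper envelope (clustering), falling back to the
  strongest deficit below the lower envelope (regularity, flagged), and
  an explicit CSR flag when the curve never leaves the envelope. Ties
  break toward smaller $r$: associations act locally and large spatial
  scales should be avoided. Because the departure is measured only at
  reliable distances, the suggestion cannot land in the inflated
  small-$r$ region.

For a formal summary of the overall interaction, the area-interaction
point-process density
$f(\nu) \propto \xi^{n(\nu)}\gamma^{-|U_{\nu,r}|}\beta^{c}$ is supported
through its geometric term $|U_{\nu,r}|$ (the union-of-discs area,
computed on a grid clipped to the window, default resolution
$512^2$ cells) and the unnormalised log density
`area_interaction_logdensity()`. Fitting this model (e.g. by maximum
pseudolikelihood) is intentionally out of scope.

# The hazard model

With $z_j(t)$ the informed indicator and $c_i$ a normalised
environmental covariate, the acquisition hazard of a naive individual
is

$$\lambda_i(t) = (1 - z_i(t))\Big(s'\sum_{j \ne i} a_{ij} z_j(t)
  + \lambda_0 e^{\beta c_i}\Big),$$

the time-of-acquisition (TADA) form of NBDA with the $s' = \lambda_0 s$
reparameterisation that makes prior specification intuitive: $s'$ is
the social transmission rate per unit association with informed
individuals and $\lambda_0$ the baseline asocial rate. Three nested
models are considered: model 1 $\{\lambda_0\}$, model 2
$\{\lambda_0, s'\}$, model 3 $\{\lambda_0, s', \beta\}$.

## Likelihood

Because the network and covariates are static, hazards are piecewise
constant between acquisition events, and the event-history
log-likelihood is a finite sum,

$$\ell = \sum_{\text{events } k} \log \lambda_{\ell_k}(t_k^-)
  - \sum_i \int_0^{\min(t_i, T)} \lambda_i(u)\, du,$$

with censored individuals contributing only the survival integral.
The implementation precomputes, per diffusion, the learners' social
association sums at their events, each individual's naive exposure
time, and the integrated social exposure, after which a likelihood
evaluation is $O(n)$ — this is what makes replicate simulation studies
with tens of thousands of MCMC iterations cheap. The likelihood is
verified in the test suite against an independent oracle that walks
the hazard paths interval by interval through the exported `hazard()`
operation, and against the closed-form exponential special case
($s' = 0$, $\beta = 0$, MLE $\hat\lambda_0 = n/\sum t_i$).

Exactly tied event times are rejected by default (they have probability
zero under the continuous-time model and usually indicate discretised
data); `ties = "jitter"` separates them by $10^{-9} \cdot \max t$ with
a warning. The innovator's acquisition is modelled like any other
asocial event unless `innovator_seeded = TRUE`, which conditions on it
(informed from $t = 0$, no event or survival contribution).

## Priors and the sign of the environmental effect

All rate parameters carry Uniform$(-10, 10)$ priors on the natural-log
scale (closed interval at the boundary). A log-scale uniform prior
cannot produce a negative environmental effect, yet negative effects
are scientifically meaningful (and occur in practice), so the default
parameterisation treats $\beta$ as a signed quantity: Uniform$(-10,10)$
on $\log|\beta|$ with an even prior on the sign. Users who prefer a
flat prior on the effect itself can set `beta_prior = "uniform"`
(Uniform$(-10, 10)$ on $\beta$). Posterior summaries always report the
signed $\beta$.

# Sampling

`mh_sample()` performs component-wise uniform random-walk Metropolis:
each parameter $\alpha$ receives a proposal from
$U[\alpha - \varepsilon, \alpha + \varepsilon]$. Default tuning widths
are $\varepsilon = 1$ for the log-rates and $\varepsilon = 3$ for the
environmental parameter — values that give healthy acceptance rates
(roughly 0.2–0.5) at the problem sizes the package targets; both are
configurable and acceptance rates are reported on the trace. The sign
of $\beta$ (signed-log parameterisation) is updated by an independent
fresh-sign proposal, symmetric under the even sign prior. The default
iteration budget is 20,000 with 2,000 discarded as burn-in.

`rjmcmc_sample()` adds a between-model move, attempted with probability
0.5 after each within-model sweep: a different model is proposed
uniformly, shared parameters are carried over, and parameters absent
from the current model are drawn fresh from their priors. Prior-draw
proposals have Jacobian 1 and their proposal density cancels the prior
of the birthed parameters, so the acceptance probability reduces to the
likelihood ratio. This simple jump is adequate for nested models of
dimension at most three; no attempt is made at mode-matching proposals.
Under a uniform model prior the posterior model probabilities are the
retained-visit fractions, and `bayes_factor()` is their ratio.

Both samplers are exactly reproducible from their seed, and both are
validated by prior-recovery checks: with the likelihood switched off,
the MH marginals must return Uniform$(-10,10)$ and the RJ model
probabilities must return uniform. Kolmogorov–Smirnov diagnostics
assume independent draws, so those checks run with wide proposals and
thinning (`thin`) to make retained draws nearly independent — a
property of the diagnostic, not a requirement for ordinary use.

Credible intervals are symmetric 95% intervals (2.5% and 97.5%
quantiles) computed by linear interpolation of order statistics (R's
default quantile type 7), reported with posterior means on the log
scale for rates.

A parameter whose posterior 95% interval covers most of the prior's
central 95% interval $[-9.5, 9.5]$ has learned nothing from the data —
"the prior has been returned". The package's checks use coverage of at
least half that interval as the operational diagnostic.

# The synthetic-data generator

`simulate_study()` reproduces the structure of the validation studies:

* **Clustered condition** (the positive case): a Matérn cluster pattern
  in the unit square — parent intensity $\kappa = 6$, mean offspring
  $\mu = 26/6$, cluster radius $0.05$, giving 26 individuals on
  average, matching a small territorial population with a handful of
  spatial clusters; an environmental field $E(x, y) = 3x - 2y$,
  z-scored across the individuals; associations at interaction radius
  $0.05$; and ten replicate diffusions simulated by the exact Gillespie
  algorithm with $\log\lambda_0 = -1.6$, $\log s' = 0.84$, $\beta = 0$.
  The rates are chosen to be consistent with posterior estimates
  reported for analyses of this design, and imply a strong social
  effect ($s = s'/\lambda_0 \approx 11.5$).
* **CSR asocial condition** (the negative control): 26 uniformly
  placed individuals, an *empty* association structure, and purely
  asocial diffusions ($s' = 0$). With no inherent associations the
  social rate is unidentifiable and its posterior must return the
  prior. The empty matrix is used directly rather than computing
  near-zero overlaps from a sparse pattern, so the control is exact.

A master seed spawns per-diffusion streams deterministically; every
generator setting and sub-seed is returned in a manifest. The generator
emulates the *structure* of field data — clustered home bases, a smooth
environmental gradient, diffusion in continuous time — but not its
messiness: no observation error in event times, no movement of home
bases, no unobserved individuals, and the generating model is exactly
the fitted model. Passing the package's recovery checks therefore
demonstrates correctness of the machinery, not robustness to model
misspecification in real data.

# Numerical choices and problem sizes

* Lens areas clamp the `acos` arguments to $[-1, 1]$ against roundoff;
  tangency counts as disjoint.
* The union-of-discs grid uses cell centres; resolution 512 keeps the
  discretisation error of typical radii well under 1%.
* The Monte Carlo overlap estimator samples the intersection of the two
  discs' bounding boxes and is exactly 0 for disjoint boxes.
* Matérn parents are drawn on the window dilated by the cluster radius
  so edge clusters are not lost; rare realisations with fewer than 5
  points are redrawn by the study generator.
* Likelihood evaluations that overflow (e.g. $e^{\beta c}$ at extreme
  prior draws) are treated as log-likelihood $-\infty$; sampler starts
  are redrawn from the prior until the likelihood is finite.
* Validation problem sizes were chosen so the whole suite runs in
  minutes on one core: replicate recovery studies use 50 studies of
  ~26 individuals with ten diffusions each and 4,000 MH iterations;
  calibration checks use 99-simulation envelopes; the headline analysis
  uses the full 20,000-iteration budget. All sizes scale up by argument.

# Limitations

* Influence is constant within the zone; distance-decaying influence is
  not implemented.
* The baseline rate $\lambda_0$ is constant in time; order-of-
  acquisition (OADA) analysis, time-varying home bases, marked
  patterns, and random effects are out of scope.
* Area-interaction model *fitting* is not provided — only the geometric
  term and unnormalised density needed to reason about it.
* The wave-of-advance regression is reported in the field's two
  orientations (`distance ~ time` by default); slope sign and
  interpretation depend on the orientation, and the single-origin
  assumption it embodies is precisely what the network model relaxes.
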