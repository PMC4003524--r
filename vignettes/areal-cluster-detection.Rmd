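---
title: "Focused cluster detection for areal disease counts: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focused cluster detection for areal disease counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealclust)
```

## The problem

Given one observed case count per administrative region, together with an
expected count summarizing the region's population structure, a *focused*
cluster-detection procedure asks: which sets of regions show excess risk
beyond what chance allows?  This package implements four such procedures
on a common data substrate, so their answers can be compared region by
region:

* the **circular spatial scan statistic** (CSS), which slides
  nearest-neighbour discs over the map and tests the disc with the
  largest Poisson likelihood ratio;
* the **flexible spatial scan statistic** (FSS), which replaces discs by
  arbitrary connected region sets inside each disc of J nearest
  neighbours, capturing irregularly shaped clusters;
* **Bayesian disease mapping** with a proper conditional autoregressive
  (CAR) prior, which smooths per-region relative risks and calls a
  cluster when a credible interval clears a threshold;
* a **data-cloning maximum-likelihood** analysis of the same hierarchical
  model, which delivers the MLE with asymptotic standard errors through
  MCMC alone, plus frequentist prediction intervals for the latent
  relative risks.

All four consume `counts_data` (observed `C_i`, expected `E_i`) on a
`region_map` (centroids + adjacency).  A synthetic-data module emulates a
67-district provincial design so the full pipeline runs, and is tested,
without any confidential registry data.

## Expected counts

`expected_counts()` performs internal indirect standardization over
year x age-group x sex strata: the rate in stratum *s* is pooled over all
regions, `rate_s = sum_i cases_{i,s} / sum_i pop_{i,s}`, and
`E_i = sum_s pop_{i,s} rate_s`.  Because the rates come from the data
itself, `sum(E) = sum(C)` holds identically; every run asserts it.  This
conservation matters downstream: the scan statistic's final term
`N log(N / E_total)` vanishes, and the multinomial Monte Carlo null for
the scan conditions on exactly the observed total.  Whether reference
rates should instead come from an external standard population is a
design choice; external rates would break the conservation and are out
of scope here.

## The scan statistics

For a window S with observed `C_in` and expected `E_in` cases, the
statistic is the log likelihood ratio

    C_in log(C_in/E_in) + (N - C_in) log((N - C_in)/(E_total - E_in))

(minus `N log(N/E_total)` when totals differ), set to zero unless
`C_in > E_in`, with `0 log 0 := 0`.  A unit test pins this to an
independent evaluation built from Poisson densities at the fitted inside
and outside rates.

**Windows.**  Circular windows are the prefixes of each region's
nearest-neighbour ordering (ties in centroid distance break by ascending
region id, so windows are reproducible across platforms).  Flexible
windows are every connected subset of the anchor's J-nearest-neighbour
set that contains the anchor.  Enumeration grows rooted connected
subgraphs with a canonical frontier ordering, which emits each subset
exactly once; its correctness is defined — and tested, exactly — against
brute-force power-set enumeration filtered by connectivity on maps with
up to 12 regions.  Because the number of connected subsets grows
exponentially in J on well-connected graphs, `scan_config(max_windows=)`
guards the enumeration, and analyses on lattice-like maps use J = 10 for
the flexible statistic where the circular one uses the conventional
J = 15.

**Inference.**  The null distribution of the maximum statistic is
simulated by redistributing the N observed cases over regions
multinomially with probabilities `E_i / sum(E)`; the p-value is
`(1 + #{null max >= observed}) / (1 + n_monte_carlo)` with 999 replicates
by default.  An asymptotic chi-squared reference for the scanned maximum
is sometimes quoted in the applied literature but is not a correct null
for a maximum over thousands of correlated windows; Monte Carlo
conditioning on N is the standard and is what the calibration study
verifies (rejection rate 5% at nominal 5% over 500 null datasets).
Secondary clusters are reported greedily in decreasing statistic order,
skipping any window that overlaps a higher-ranked reported one, and their
p-values are measured against the same null distribution of the maximum
— the usual convention, which makes secondary p-values conservative.

## The disease-mapping model

Counts follow `C_i ~ Poisson(theta_i E_i)` with
`log(theta_i) = mu + eta_i`.  The spatial effects have the proper CAR
joint distribution

    eta ~ N(0, Sigma),   Sigma = sigma2 (I - lambda D)^{-1} P,

with `P = diag(1/E_i)` and `D_ij = sqrt(E_j/E_i)` on adjacent pairs.  Two
identities drive the implementation: `D` is similar to the 0/1 adjacency
matrix `A` (conjugation by `P^{1/2}`), so the admissible interval for
`lambda` is `(1/min eig A, 1/max eig A)`, which always brackets zero; and
the precision is `(diag(E) - lambda B)/sigma2` with
`B_ij = sqrt(E_i E_j)` on edges, so density evaluations cost
O(m + edges) and `log det Sigma` follows from the eigenvalues of `A`
computed once.  Positive definiteness exactly inside the interval (and
failure outside) is verified spectrally on random maps.

Note the scaling this model implies: the prior variance of `eta_i` is
roughly `sigma2 / E_i`, so `sigma2` is the dispersion of
`sqrt(E_i) eta_i`, not of the log relative risks themselves.  Two
consequences recur below: realistic values of `sigma2` depend strongly on
the size of the expected counts, and the per-region information about
`sigma2` is governed by `sigma2 * theta` alone — it cannot be improved by
making regions larger.

**Sampler.**  `fit_bym()` runs a bespoke Metropolis-within-Gibbs chain:
single-site random walks on each `eta_i`; a random walk on `mu`; an exact
conjugate Gibbs draw of `sigma2` from its inverse-gamma full conditional;
a random walk on `logit`-transformed `lambda` with its Jacobian; and two
joint moves that fix the posterior's ridges — a translation
`(mu, eta) -> (mu + d, eta - d)` that leaves every Poisson mean
untouched, and a scaling `(sigma2, eta) -> (c sigma2, sqrt(c) eta)` that
leaves the prior quadratic form untouched.  Step sizes adapt toward 44%
acceptance during burn-in only, so the retained chain is Markov.
Defaults are 4 chains of 20,000 iterations (10,000 burn-in, thin 5);
split-chain R-hat is reported for the three hyperparameters and a value
above 1.1 warns.  The sampler is validated end to end against an
independent MCMC implementation (JAGS with the same model stated in
precision form) in the test suite.

**Priors.**  `mu ~ N(0, 10^4)`; `lambda` uniform on its admissible
interval; and for `sigma2` a shape/rate family `p(sigma2) proportional to
sigma2^{-(shape+1)} exp(-rate/sigma2)`.  The package default is the
WinBUGS-era IG(0.5, 0.0005).  For the simulation studies we instead use
an improper power prior with shape -0.25 and rate 0, chosen by
calibration: at the study conditions (30 regions, `sigma2 = 0.3`,
`mu = 0.2`) the dispersion is weakly identified — the likelihood for
`sigma2` is nearly flat over two decades — so the posterior mean tracks
the prior exponent almost linearly.  IG(0.5, 0.0005) drags it toward
zero (relative bias near -75%), a flat-on-sigma prior overshoots upward
(+25 to +35%), and the Jeffreys scale prior collapses it (-70%); the
calibrated exponent makes the posterior mean approximately unbiased
(within a few percent) while leaving the 95% interval coverage for `mu`
in the 0.91-0.97 range.  This is a "calibrated Bayes" choice: the prior
is part of the procedure, selected once by simulation under the design
conditions and then frozen.  For well-identified datasets (for example
planted relative risks of 3) the choice is immaterial.

**Calls.**  `call_regions()` computes per-region equal-tailed intervals
(95% by default, the conventional level; the source convention of a
"credible set" leaves the level open), medians and exceedance
probabilities `Pr(RR_i > b)`, calls a cluster when the interval's lower
bound strictly exceeds 1.0 / 1.5 / 2.0 (or when the exceedance
probability exceeds a cutoff such as 0.9), and ranks regions by
descending lower bound with ties broken by ascending region id.  Strict
inequality means a region whose draws all equal the threshold exactly is
not called.  Raising the threshold can only remove calls; this
monotonicity is asserted on every fitted dataset in the studies.
`deviance_residuals()` provides the usual signed Poisson residuals at
posterior-mean fitted values as a model-fit check.

## Data cloning

`fit_dc()` samples the posterior raised to the L-th power of the
likelihood by attaching L conditionally independent latent `eta` vectors
to L copies of the count vector, sharing `alpha = (mu, lambda, sigma2)`.
As L grows this cloned posterior collapses onto the MLE with covariance
1/L times the inverse Fisher information, so the posterior mean at the
largest L estimates the MLE and L times the posterior covariance
estimates its asymptotic covariance.  The diagnostic is the largest
eigenvalue of the `alpha` posterior covariance scaled by its value at
the smallest clone count; adequacy requires it to be non-increasing (with
10% Monte Carlo slack) and below `1.5 * L_min / L_top` at the top.  The
degeneracy study regresses its log on log L and obtains slope -1 within
a few percent — on a *well-identified* simulated dataset (100 regions,
`sigma2 = 2`).  Under weak identification the cloned posterior of a
nearly-flat direction stays prior-shaped until L is very large and the
1/L law is not yet visible; that regime is reported by the adequacy flag
rather than hidden.  Normalizing constants are never computed; only MCMC
kernels are used.

The MLE route is cross-checked on a 4-region toy with `lambda` fixed at
0, where the latent effects are independent and the marginal likelihood
factorizes into one-dimensional integrals evaluated by adaptive
quadrature (in log space, with an offset against underflow) and maximized
directly; data-cloning estimates of `mu` and `sigma2` agree within
combined standard errors.  With 4 regions the dispersion MLE sits at the
zero boundary for some datasets; both routes then find that same
boundary, and the comparison remains valid because its standard errors
widen accordingly.

**Prediction.**  `predict_rr()` produces frequentist prediction intervals
for the latent relative risks by composite sampling: draw
`alpha* ~ N(alpha_hat, vcov)` truncated to the admissible domain
(`sigma2 > 0`, `lambda` inside its bounds; a rejection rate above 50%
warns that the MLE is near a boundary), then sample `eta | C, alpha*` by
the same MCMC kernel with the hyperparameters held fixed, and pool the
relative-risk draws.  Setting `vcov = 0` recovers the naive plug-in
conditional at the MLE — the comparison target that motivates
propagating estimation uncertainty — and the test suite checks this
distributional identity.  Calls and rankings then reuse exactly the
machinery of the Bayesian method, which is what makes the two methods'
rankings comparable; on planted-cluster simulations their Spearman rank
correlation exceeds 0.95.

## The synthetic study design

`make_map()` lays regions on a near-square grid with rook contiguity and
jittered centroids (jitter makes nearest-neighbour orderings generic;
rook rather than queen adjacency keeps neighbourhoods sparse, which is
the harder case for the CAR prior and the cheaper one for flexible
enumeration).  `make_populations()` draws per-region person-time totals
log-uniformly between 920 and 91,633 — giving a median near 9,200 and a
mean near 19,700, the right-skewed profile of the emulated design — and
splits them over 10 years x 5 age bands x 2 sexes by a symmetric
Dirichlet-multinomial, so cell populations are integers conserving the
totals.  Age-band rates (0.05 to 0.17 per person over the study period,
modified ±5% by sex) put region-level expected counts in the tens to
thousands, with mean case counts near 2,000 and median near 900.  The
exact rates of the emulated survey are not recoverable and these defaults
are deliberately round; nothing downstream depends on them beyond scale.
`simulate_counts()` multiplies cell means by the planted relative risk
(3, in the canonical scenarios) inside the cluster region set — sets B
(seven northern), C (seven south-central) and D (twelve urban-centre
regions) in the 67-region layout — draws Poisson counts, and
standardizes expected counts from the simulated data itself, exactly as
an analyst without the truth would.

What the generator does *not* emulate: survey weighting (counts are
generated at the already-aggregated scale), true district geography and
boundary shapes, overdispersion beyond Poisson, and covariate effects.
Passing tests therefore demonstrate the correctness and calibration of
the procedures under a Poisson world with known structure, not the
substantive findings of any particular surveillance dataset.

## Problem sizes and numerical choices

The simulation studies run at: 500 null datasets x 999 Monte Carlo
replicates for scan calibration (30 regions, expected counts 20-200);
100 datasets for scan power (7-region planted cluster at relative risk
3, expected counts near 50, J = 10); 100 datasets for Bayesian recovery
(30 regions, 2 chains x 4,000 iterations — short chains suffice because
the joint translation and scaling moves leave R-hat near 1); clone
counts 1, 2, 4, 8, 16 on one 100-region dataset for the degeneracy
study; and 20 planted-cluster datasets for the cross-method concordance.
These sizes make the whole suite reproducible on a laptop in a few
minutes while leaving each check's Monte Carlo error well inside its
assertion margin.

Degenerate inputs are errors, not silent repairs: disconnected maps,
self-adjacent regions, zero-population strata with cases, and regions
with zero expected count all raise distinct conditions.  Exact distance
ties and exact rank ties both break by ascending region id.  The
`0 log 0 := 0` convention applies in the scan statistic and in deviance
residuals.

## Known limitations

* Flexible enumeration is exponential in J; J = 15 on dense adjacency
  graphs can exceed the window cap by design.
* The intrinsic CAR / convolution (BYM2) variants, covariates beyond the
  offset, space-time scanning and elliptic windows are out of scope.
* `sigma2` and `lambda` are weakly identified when `sigma2 * theta` is
  small; the package reports this through wide intervals, the cloning
  adequacy flag and the prediction-stage rejection warning, but no
  reparameterization is attempted.
* Monte Carlo p-values are conditional on the observed total N; they do
  not account for uncertainty in the expected counts themselves (the
  standardization is treated as fixed, as is conventional).
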