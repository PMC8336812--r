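---
title: "Location-scale distributional regression for child growth outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-scale distributional regression for child growth outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazreg)
```

## The model

Child height-for-age z-scores (HAZ) summarise linear growth against a
reference population; values at or below −2 conventionally define
stunting. Regressing only the conditional mean of HAZ discards a second,
epidemiologically meaningful signal: how *variable* outcomes are across
covariate profiles and regions. `hazreg` therefore fits a Gaussian
location-scale model in which both distribution parameters carry their own
structured additive predictor:

$$z_{is} \sim N(\mu_{is}, \sigma_i^2), \qquad
\mu = \eta_\mu, \qquad \sigma = \exp(\eta_\sigma),$$

with each predictor a sum of

* effect-coded categorical covariates (gender, urban/rural residence,
  survey wave) with diffuse priors,
* penalised B-spline (P-spline) smooths of continuous covariates, with
  random-walk priors $\beta_j \mid \gamma_j^2 \propto
  \exp(-\tfrac{1}{2\gamma_j^2}\beta_j' K_j \beta_j)$,
* tensor-product interaction surfaces (birth order × maternal age at
  birth; child age × breastfeeding duration), penalised by the Kronecker
  sum of the marginal difference penalties with a single shared variance,
* a Markov random field (MRF) over the district adjacency graph, one field
  per survey wave with a common variance parameter, for which each
  district effect is conditionally Normal around its neighbour average
  with variance $\tau^2/N_s$.

The exponential link keeps $\sigma$ positive; the scale predictor is
interpreted on the log-standard-deviation scale, so a coefficient of 0.05
multiplies $\sigma$ by about 5%.

The index convention mirrors survey reality: one response row per child.
The scale parameter is indexed per child row; cluster-level scale
structure would enter through covariates measured at the cluster (PSU)
level.

## Identifiability

Every smooth is centred. Spline and tensor blocks are constrained so that
their fitted contribution sums to zero over the estimation sample
(observation-weighted constraint, absorbed by a QR reparametrisation that
also reduces the penalty null space by the constant direction). The
spatial field is instead constrained so that the *district coefficients*
sum to zero within each wave: this keeps districts without observations
estimable (they borrow strength from neighbours through the MRF prior)
and makes per-wave district effects directly comparable. Islands in the
adjacency graph contribute a zero penalty row; their effects are then
identified only by the constraint and the variance parameter, and the
package warns when it encounters them.

## Defaults that matter

| Parameter | Default | Why |
|---|---|---|
| spline degree | 3 | cubic pieces, standard for smooth covariate effects |
| interior intervals (1-d) | 20 | rich basis; the penalty controls wiggliness |
| interior intervals (tensor margins) | 8 | keeps surfaces at 121 coefficients |
| penalty order | 2 | shrinks towards linearity |
| variance hyperprior | IG(0.001, 0.001) | weakly informative conjugate default |
| iterations / burn-in / thinning | 12000 / 2000 / 10 | long-run defaults; examples below use shorter chains |

Covariates with few distinct values (vaccination counts, birth order)
automatically reduce the interval count to the number of distinct values
minus one, and the penalty order alongside if needed, so the basis stays
full rank. Boundary knots sit at the observed covariate range; the knot
grid is extended by one interval width per degree on each side.

Two covariate transforms are applied at assembly, matching common
practice for these data: population density enters as
$\log(1 + \text{density})$, and the household asset index — the first
principal component of standardised asset indicators, sign-oriented so
that electricity loads positively — enters as its deviation from the
district mean.

## Posterior computation

The sampler is a fixed-order systematic scan: mean-side fixed effects,
mean-side smooths in specification order (spatial last), scale-side
blocks in the same order, then all smoothing variances.

* **Mean side.** Every block has a Gaussian full conditional with
  precision $B'\Sigma^{-1}B + K/\gamma^2$; draws use a Cholesky solve.
* **Scale side.** The log link breaks conjugacy. Each block is updated by
  Metropolis-Hastings with an IWLS proposal: a Newton step using the
  observed-information working weights $w_i = e_i^2 e^{-2\eta_i}$, i.e. a
  Gaussian centred at $\beta + H^{-1}g$ with precision
  $H = 2B'WB + K/\gamma^2$. Because the proposal precision is state
  dependent, the acceptance ratio includes the proposal normalising
  constants. An adaptive random-walk fallback is available; its scale is
  tuned towards a 0.23–0.44 acceptance rate during burn-in only and
  frozen afterwards, so the retained chain is valid MCMC.
* **Variances.** Conjugate inverse-gamma draws
  IG$(a + \mathrm{rank}(K)/2,\; b + \beta'K\beta/2)$, with the rank taken
  from the constrained penalty.

Two initialisation details proved load-bearing and are deliberate design
choices rather than tuning:

1. Smoothing variances are held at their starting value for the first
   `min(100, burnin/2)` iterations. Released immediately from a zero
   coefficient start, the quadratic form is zero, the variance draw
   collapses, and a block can freeze in an oversmoothed state.
2. At the end of that warm-up the scale intercept is re-anchored at its
   conditional mode $\tfrac{1}{2}\log(\overline{e^2})$. The natural
   marginal-standard-deviation start is systematically too high once the
   mean structure absorbs variance, and a single IWLS jump across that
   gap has a vanishing reverse-proposal density, stalling the chain.

Both happen on a fixed schedule inside burn-in; the post-burn-in
transition kernel is unchanged, and its correctness is verified in the
test suite by comparing long-run occupancy against brute-force grid
evaluations of the full conditionals (total variation below 0.02).

Degenerate inputs are handled explicitly: non-finite predictors abort
the run with a diagnostic; a non-finite log target at a proposal rejects
the move with a warning; quantile residuals beyond ±8 are clipped;
Cholesky factorisations fall back to a tiny diagonal lift.

## Model comparison and diagnostics

The pointwise log-likelihood of every saved draw is stored, so

* **DIC** uses the plug-in deviance at the posterior means of the fitted
  $\mu_i, \sigma_i$ (well defined under the nonlinear scale link, and the
  deviance the established samplers for this model family report), with
  $p_D = \bar D - D(\hat\mu, \hat\sigma)$;
* **WAIC** uses the variance-form penalty (pWAIC2);
* **randomised quantile residuals** use plug-in posterior means; for a
  continuous Gaussian response they are simply
  $\Phi^{-1}(F(y_i;\mu_i,\sigma_i))$ and standard normal under a correct
  model;
* **simultaneous credible bands** for smooth effects take the empirical
  level-quantile of the maximum standardised deviation over the grid, so
  the stated fraction of sampled curves lies entirely inside the band and
  the simultaneous band always encloses the pointwise one;
* **effective sample sizes** use Geyer's initial monotone sequence
  truncation.

Whether DIC for a distributional model should plug in coefficient-level
or fitted-parameter posterior means is genuinely open; the package uses
the fitted-parameter convention throughout and reports $p_D$ so the two
models being compared carry comparable penalties.

## The synthetic survey generator

Because the motivating microdata are access-restricted, the package
ships a generator that emulates their structure with known ground truth:

* two survey waves with the published sizes (7,936 and 17,916 children)
  and covariate marginals matched to published wave-level moments (child
  age uniform on twice its mean, matching both mean and SD; counts as
  shifted Poisson matched to means; anthropometric and maternal
  covariates as clamped Normals; population density log-normal matched
  to mean and SD);
* a toy square-lattice district geography with rook adjacency, PSU
  clusters, and DHS-style confidentiality displacement of PSU
  coordinates (≤ 2 km urban, ≤ 5 km rural, ≤ 10 km for 1% of rural
  PSUs);
* household asset indicators driven by a latent wealth factor correlated
  (ρ = 0.4) with urban residence and maternal education — the published
  tables constrain only marginals, so this dependence is a declared
  assumption chosen to exercise confounding adjustment;
* a true-effect library with the qualitative shapes the model family is
  meant to detect: an education effect flat below eight years and rising
  above, a saturating maternal-BMI effect, a linear vaccination effect, a
  malaria effect declining above incidence 0.3, and a smooth north-south
  district field (second-wave field = 0.8 × first-wave field);
* heteroscedastic noise: the log standard deviation carries the wave
  intercepts (0.28 / 0.23), a declining education effect above eight
  years, a vaccination effect, and 0.4 × the district field. The
  magnitudes were set so the per-observation information gain of
  modelling the scale matches the order implied by the published
  information-criterion gap between the constant-scale and full models.

Within each wave the combined systematic effects are mean-centred, so
the expected wave mean of the response equals the configured target
(−1.59 and −1.47) — the generator-level mirror of the model's sum-to-zero
identifiability.

What the generator does *not* emulate: the surveyed country's real
geography and adjacency, survey weights, within-PSU correlation beyond shared
PSU-level covariates, item non-response patterns, and heaping or
measurement error in anthropometry. Passing recovery tests on this
test bed therefore validates the estimator and pipeline, not substantive
claims about any real population.

## Problem sizes used in validation

The test suite and the acceptance script run at desk scale by design:
conjugate checks at n = 500; curve recovery at n = 2,000 with 900
iterations across 20 replicates; spatial recovery on a 5 × 5 lattice
with 50 children per district; model comparison at n = 3,000 per seed
with 800-iteration chains across 20 seeds — large enough that the
information gain from modelling the scale clearly exceeds the extra
effective parameters the scale predictor spends, which at much smaller
samples makes the ordering a coin flip on marginal datasets; generator
calibration at the
full published wave sizes. The full pipeline default
(`run_full_analysis`) fits its grid at whatever size the configuration
requests; the sampler scales linearly in iterations and roughly linearly
in observations.

## Known limitations

* The scale predictor excludes the two tensor interaction surfaces;
  their chains mix poorly in this family, and the reference analysis
  dropped them for the same reason.
* One variance parameter per term (the spatially adaptive
  per-district-variance reading of the MRF prior is not implemented).
* Complete-case analysis; no survey weights.
* Single-chain inference with sequential multi-seed replication rather
  than concurrent multi-chain diagnostics.
* DIC/WAIC compare fit, not causal adequacy; the pipeline deliberately
  reports *all* fitted terms with bands rather than automating any
  "omit insignificant terms" narration.
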