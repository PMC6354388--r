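---
title: "Bayesian geo-additive modelling of FGM/C status in two-wave household surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian geo-additive modelling of FGM/C status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Female genital mutilation/cutting (FGM/C) status is recorded for women aged
15–49 in Demographic and Health Survey (DHS)-style household surveys as a
binary indicator. Two features of these data defeat an ordinary logistic
regression. First, the two-stage cluster sample (clusters drawn within
regions, then a fixed number of households per cluster) induces spatial
dependence: respondents in the same or neighbouring regions share unmeasured
risk factors, so standard errors that assume independence are too small.
Second, the effect of age on FGM/C status need not be linear on the log-odds
scale — cutting happened years before the interview, and cohort effects can
bend the curve in either direction.

`geofgm` implements the structured additive regression answer to both
problems: a Bayesian geo-additive binary regression with

$$\operatorname{logit} P(y_i = 1) \;=\; \beta_0 + \mathbf w_i'\boldsymbol\gamma
  + f_{\text{age}}(a_i) + f_{\text{str}}(s_i) + f_{\text{unstr}}(s_i),$$

where $\mathbf w_i$ holds dummy-coded socio-demographic covariates,
$f_{\text{age}}$ is a penalized B-spline (P-spline) with a second-order
random-walk (RW2) prior, $f_{\text{str}}$ is a structured region effect with
an intrinsic conditional-autoregressive (ICAR, Markov random field) prior on
the region adjacency graph, and $f_{\text{unstr}}$ is an exchangeable
i.i.d. Gaussian region effect. The *total residual spatial effect*
$f_{\text{str}} + f_{\text{unstr}}$, exponentiated, is the per-region
posterior odds ratio that gets mapped; the ICAR part borrows strength across
neighbouring regions, the unstructured part absorbs region-level
heterogeneity with no spatial pattern.

## Inference

The model is fitted by a data-augmentation Gibbs sampler. With the logit
link, each iteration draws Pólya-Gamma latent weights
$\omega_i \mid \eta_i \sim \mathrm{PG}(1, \eta_i)$ (a compiled Devroye-type
rejection sampler in `src/`), after which every coefficient block —
(intercept, $\boldsymbol\gamma$) jointly, each spline block, the structured
and the unstructured region block — has a conjugate Gaussian full
conditional, and each variance component an inverse-gamma one,
$\tau^2 \sim \mathrm{IG}(a + \mathrm{rank}(P)/2,\; b + \theta'P\theta/2)$.
A probit variant (truncated-normal latent responses, unit weights) is
available through `model_spec(link = "probit")`; odds-ratio reporting
assumes the logit default.

Identifiability with improper priors. The RW2 penalty has a null space
(constants and linear trends in the coefficient index) and the ICAR
precision — the graph Laplacian, rank $R - (\text{number of connected
components})$ — has one flat direction per component. The sampler never
inverts these precisions; it works with the full-conditional precision
(data + prior), which is positive definite whenever every component has
observations. After each block draw the fitted effect is re-centered
(empirical mean over observations for splines, per-component mean for the
spatial blocks) and the removed mean is absorbed into the intercept, which
leaves the predictor unchanged and keeps every stored draw on the
sum-to-zero subspace to within 1e-8. With a disconnected graph the
intercept absorbs the observation-share-weighted mean of the removed
pieces; this is exact for connected graphs (all shipped fixtures are
connected) and an approximation otherwise, which is why isolated regions
are flagged with a warning rather than silently accepted.

## Parameters that matter

* Spline: cubic B-splines with 20 equidistant inner knots by default
  (`n_inner_knots`, `degree`), RW2 penalty. The basis is a partition of
  unity on the fitted range; no extrapolation is allowed in summaries.
* Hyperpriors: inverse-gamma $a = b = 0.001$ on every variance component;
  $0.01$ and $0.1$ are the documented sensitivity settings
  (`hyper_a`, `hyper_b`). Fixed effects and intercept carry a diffuse
  N(0, 1e6) prior.
* MCMC: 12,000 iterations, 2,000 burn-in, thinning 10 by default — chosen
  for desk runtime at n ≈ 14k; the tests use shorter chains (hundreds to a
  few thousand iterations), which is sufficient for the posterior-mean and
  interval checks they make. A `tau2 > 1e8` draw aborts the chain as
  divergent. The seed is mandatory everywhere; identical seed, config and
  data give bit-identical draws.
* Summaries: posterior odds ratios are posterior *medians* of
  exp(effect) — invariant to the log transform, and the convention is not
  settled by odds-ratio tables alone. Intervals are equal-tailed: 0.95
  default for effects and significance maps (0.90 preset), 0.80 for
  nonlinear curves, following common practice for these displays.
  Significance maps use the white/grey/black convention: interval below 1,
  straddling 1, above 1.

## The synthetic-data generator

`default_truth()` + `simulate_survey()` emulate the structure of the two
Senegal survey waves the method was designed around: 11 regions in wave 1,
three of which split (Kaffrine out of Kaolack, Kédougou out of Tambacounda,
Sédhiou out of Kolda) to give 14 in wave 2; two-stage sampling with 21
households per cluster and all women 15–49 interviewed (a truncated
Poisson(2) count on 0–4 per household, reproducing ~14.6k women from ~370
clusters without modelling demography); region shares and urban fractions
calibrated to the published sample composition; covariate distributions
loosely matched to the published baseline table; and ethnicity mixed
region-by-region, because ethnicity–region confounding is the scientifically
interesting feature (it drives the attenuation of regional effects under
adjustment). The planted truth draws
$f_{\text{str}}$ from the ICAR distribution ($\tau^2_{str} = 0.6$),
$f_{\text{unstr}}$ i.i.d. normal ($\tau^2_{unstr} = 0.1$; structure
dominates heterogeneity), a declining age curve
$0.9\,e^{-(a-15)/12}$ (high for the youngest cohort, ~0.85 log-odds drop
across the range), and fixed effects loosely echoing the published adjusted
odds ratios, including very large ethnicity contrasts. The intercept
default (−5.6) was calibrated once so that the marginal prevalence is ~30%,
matching the published unweighted prevalence; it is a stated-world constant,
not a tuning knob. Wave-2 regions inherit their parent's spatial effects
plus independent N(0, 0.2²) noise, giving the wave-comparison logic signal
to detect.

What the generator does *not* emulate: survey weights and nonresponse
(response rates are treated as achieved sample size), realistic demography
or migration between waves, and true boundary geometry (the shipped `.gra`
adjacencies are a stylized reading of the political map, labelled synthetic).
A green recovery test therefore establishes that the estimator recovers
effects under the stated two-stage, region-confounded world — not that it
reproduces any published national estimate, which derives from
restricted-access microdata.

Only partner covariates can be missing (never-married women), mirroring the
near-complete covariates of the real surveys; model rows with missing
values in used fields are dropped with a logged count. In the generator,
unobserved partner covariates contribute zero to the linear predictor.

## Numerical and design choices

* Adjacency files use the BayesX-style `.gra` dialect (count, then
  label/degree/neighbour blocks), with neighbour references accepted as
  labels or 1-based indices; a two-column edge list reader is also
  provided. The file's label order is the canonical matrix order and is
  never re-sorted.
* Region splits: parts are mutually adjacent and inherit all of the
  parent's external adjacencies — a stylized rule chosen because the true
  split borders are not published; it preserves the component count, which
  is the property downstream code relies on.
* Unadjusted odds ratios are computed from 2×2 cross-product tables with
  Wald intervals (identical to marginal logistic fits for level-vs-reference
  contrasts, and dependency-free); zero cells get the Haldane–Anscombe 0.5
  correction on all four cells, flagged in the output.
* Variance updates use rank(P) degrees of freedom (m−2 for RW2,
  R−components for ICAR *and* for the centered unstructured block, matching
  the constrained dimension).
* The wave-2 frame is harmonized onto wave 1 by unweighted averaging of
  subdivided regions' statistics; a population-weighted alternative is a
  flag.
* Pipeline configs are JSON rather than YAML: the target environment ships
  no R YAML parser, and the schema is identical.
* The two waves are always fitted separately (matching the published
  analysis strategy); a joint fit with time interactions is out of scope.
* Stepwise sensitivity of the age curve refits the model adding one factor
  at a time and reports the maximum absolute change of the posterior-mean
  curve plus a shape flag (decreasing / increasing / unimodal / other) —
  reported rather than asserted, because the shape of a fitted inverse-U
  versus monotone decline is exactly the kind of claim that should come
  from the data.

## Known limitations

* The intercept-absorption of per-component means is approximate on
  disconnected graphs (see above).
* No design-based (weighted) variance estimation; the likelihood is
  unweighted, as the published prevalence figures are.
* The optional cluster-level random intercept mentioned in the design
  discussion is not implemented; regional effects carry the dependence
  story, and the module boundary keeps the sampler's block structure
  simple. Probing cluster-level dependence requires extending
  `gibbs_fit()`.
* Chains are single-run; no formal convergence diagnostics are bundled
  beyond effective-sample-size-aware tolerances in the test suite.
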