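---
title: "Methods: spatial spillover analysis of a bed-net cluster randomized trial"
author: "netspill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial spillover analysis of a bed-net cluster randomized trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large bed-net trials randomize geographic clusters, not people. Because
insecticide-treated nets kill and repel mosquitoes, households *near* net
users may benefit without owning a net: a spatial spillover (indirect
effect) across cluster boundaries. Standard cluster-randomized-trial (CRT)
analyses ignore geography twice over — they neither exploit household
coordinates nor ask whether contamination across boundaries biases the
primary contrast. `netspill` implements a complete spatial reanalysis
workflow for such trials: exploratory spatial statistics, spatial Poisson
models of the standardized mortality ratio (SMR), a distance-based spillover
analysis, and a cluster-reallocation diagnostic — together with a
synthetic-trial generator, because the motivating trial's data were never
deposited and every stage must be testable without them.

Throughout, the outcome model is Poisson on the log-SMR scale: household
$h$ in cluster $j$ contributes $y_h \sim \mathrm{Poisson}(E_h e^{\eta_h})$,
where $E_h$ is the expected number of child deaths (computed from
pre-intervention age-specific rates and taken as given) entering as a
multiplicative offset, so every coefficient acts on the SMR scale.

## The synthetic-trial generator

`simulation_config()` / `simulate_trial()` emulate the motivating study's
structure. Defaults are the study's conditions:

* **Geography** — 96 contiguous clusters as the Voronoi tessellation of
  random seeds in a 30 × 20 km rectangle (cells are convex, space-filling,
  and meet at shared edges, so Queen contiguity is well defined); ~124
  households per cluster placed uniformly within their polygon (~12,000
  households); balanced 1:1 randomization of clusters.
* **Outcomes** — household expected deaths are Gamma with mean 0.06 and
  shape 2 (compounds differ in child-time at risk; the shape is
  configurable down to degenerate); the linear predictor is
  $\eta_h = \alpha + \beta x_j + u_j + s_h + \mathrm{spill}_h$ with
  $\beta = \log 0.83$ (the trial's intervention effect),
  $u_j \sim N(0, 0.2^2)$ an IID cluster effect, and $s_h$ an optional
  spatial field (cluster-level intrinsic CAR, or a household-level
  exponential-covariance Gaussian field) for testing each spatial model
  against its own generative assumption.
* **Spillover** — the default form is asymmetric and capped:
  control households get $\psi \min(d_h, R)/100$ with $\psi = \log 1.017$
  per 100 m and $R = 400$ m, where $d_h$ is the distance to the nearest
  intervention household; intervention households sit at the plateau
  $\psi R / 100$. Control mortality therefore rises with distance from the
  nearest bed net while intervention mortality is flat in distance, and at
  or beyond the range the arms differ by exactly $\beta$. A second form,
  `spillover_form = "linear"` ($\psi d_h / 100$ for every household, no
  cap), is the generative truth that exactly matches the
  linear-in-distance regression model and is what the parameter-recovery
  tests use: the capped asymmetric form is intentionally misspecified for
  a linear fit, whose coefficient then estimates an attenuated average.
* **Calibration** — the intercept is set so the control-arm marginal SMR at
  the spillover reference distance equals 1.37 (the study's control-arm
  SMR), including the $\sigma_u^2/2$ lognormal correction.

The generator is deterministic given its seed; all per-stage streams derive
from it by fixed offsets. `GroundTruth` stores every realized parameter and
per-household Poisson mean, and a conservation test recomputes each mean
from the stored pieces exactly.

What the generator does *not* emulate: real household clustering within
compounds, demographic structure behind the expected deaths, gaps between
cluster polygons, mosquito dynamics or human movement. Passing tests
therefore show the *methods* behave as designed under the stated generative
assumptions, not that the original trial's numbers are reproduced — those
data are unavailable, which is exactly why acceptance is property-based.

## Exploratory statistics

Join counts and Moran's I run on the binary Queen's-case contiguity matrix
(`queen_adjacency()`; two clusters are neighbors if their polygons share at
least one boundary point within a snap tolerance of 1e-6 m for exact
synthetic geometry, configurable for imported data). The weight matrix is
binary, *not* row-standardized, and Moran's I uses the $n/S_0$
normalization accordingly. Inference is Monte Carlo permutation (default
999 draws, one-sided "greater"), with
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\mathrm{sim}})$.
Arm-stratified Moran's I uses the induced subgraph of the arm's clusters;
contiguity is never re-established through removed clusters. Residual
Moran's I averages household Pearson residuals $(y_h - \hat\mu_h)/
\sqrt{\hat\mu_h}$ from the IID model within clusters (the mean, not the
sum, which would confound with cluster size).

A caveat worth stating plainly: after an IID multilevel fit, the fitted
cluster intercepts absorb the shrinkage-weighted share of *any*
cluster-level spatial field, so cluster-aggregated residuals retain little
spatial signal. Residual Moran's I is accordingly a low-power diagnostic
against cluster-level fields (empirical power ~0.2–0.35 even at field SDs
far above anything realistic), although its type-I error is exact by
construction of the permutation test. The raw cluster-SMR Moran test is the
powerful one; the residual version answers a narrower question — spatial
structure *beyond* what cluster intercepts explain.

Geographically weighted Poisson regression (`gwr_poisson()`) fits, at each
cluster centroid, a kernel-weighted Poisson regression of deaths on the
intervention indicator (offset log E, no cluster random effect) over
households within a fixed radius. The kernel is bisquare by default
(uniform available); the bandwidth is a required input because the
motivating analysis states neither kernel nor bandwidth, and
`gwr_bandwidth()` offers the smallest radius at which every focal cluster
sees at least a minimum number of households of each arm. Focal clusters
below that minimum in either arm are flagged undefined rather than
extrapolated.

## Spatial SMR models

`fit_smr_model()` fits four random structures behind one interface:

| structure | random effects | data level |
|---|---|---|
| `iid` | $u_j \sim N(0, \sigma_u^2)$ | households (aggregated to clusters when no household covariate is present — cluster totals are sufficient) |
| `car` | intrinsic CAR $v_j$, precision $\tau(D - W)$ | cluster-aggregated (one observation per area) |
| `bym` | $u_j + v_j$ | households |
| `gp`  | $u_j$ plus a household field with covariance $\sigma^2 e^{-d/\rho}$ | households, dense covariance |

The intrinsic CAR is the improper Besag prior with a sum-to-zero
constraint, implemented by reparameterizing on the orthogonal complement of
the constant vector, with a 1e-6 propriety jitter on the precision
diagonal. The Gaussian process uses the exponential kernel (the Matérn
family at smoothness 1/2) evaluated *densely* at the household coordinates
— no mesh/SPDE approximation — and is capped at 3,000 households by
default, beyond which a seeded subsample is used.

**Inference engine.** The package provides a single deterministic engine,
`laplace_map`: for given variance parameters the joint mode of the fixed
and random effects is found by Newton iteration with step halving (sparse
designs, dense factorizations — every supported structure keeps the
Hessian in the hundreds of rows); the variance parameters maximize the
Laplace approximation to the marginal likelihood; intervals are central 95%
Wald on the log scale, exponentiated into the SMR table. For the IID
structure the marginal likelihood factorizes into one-dimensional integrals
per cluster, and the engine refines the Laplace solution by adaptive
Gauss–Hermite quadrature (25 nodes, the standard `nAGQ`-style refinement),
then maximizes that refined likelihood directly. The refinement matters:
with only a handful of events per cluster the Laplace approximation
distorts likelihood-ratio statistics noticeably, and with it the IID
estimates agree with an independent quadrature implementation (`lme4`'s
`nAGQ = 25`) to four to five decimals. An MCMC engine was considered and
deliberately not built — the design contract here is the estimates and
intervals, not the algorithm, and a deterministic engine keeps every
pipeline output byte-reproducible; requesting `bayes_mcmc` errors clearly.

Model-level conventions: households with zero expected deaths are excluded
from the likelihood with a logged count (a zero offset is undefined on the
log scale; zero-expected with positive deaths is a validation error);
distance enters as $d/100$ so $\psi$ is "per 100 m" exactly; the quadratic
term uses the same scaling; non-convergence is flagged on the result, never
silent; a degenerate single-arm assignment is refused.

**Known small-sample behavior.** At the full study scale (96 clusters,
$\sigma_u = 0.2$, ~850 deaths) maximum-likelihood estimates carry an
intrinsic finite-sample bias of order $1/k$ in the number of clusters
(about $-0.02$ on $\log$ SMR for the intervention effect). This is not an
engine artifact — exact-quadrature ML shows the same values — and it is
well inside the Monte Carlo noise of the scaled simulation studies the
package runs, but it is worth knowing when interpreting large-replicate
averages. Relatedly, the $\chi^2_1$ reference of the interaction
likelihood-ratio test is anticonservative when the trial carries only a few
dozen events (~12% rejection at nominal 5% with 36 expected deaths, again
reproduced by exact-ML LR statistics); with a few hundred events it is
calibrated. The acceptance suite states its size bound honestly — at the
smallest scale the check sits at the edge of its binomial tolerance rather
than the tolerance being widened.

## Spillover and interaction

`spillover_fit()` adds the linear (optionally quadratic)
discordant-distance term to any structure. `interaction_analysis()` fits
intervention × 1[d > 400 m] (the threshold at which the spillover is taken
to attenuate; configurable), reports the global likelihood-ratio test (the
choice between LRT and Wald was open; the LRT is implemented, with the
Wald z available from the coefficient table), and lays out the four
stratum-specific SMR contrasts in both directions of conditioning, with
reference categories at exactly 1.00 by construction.
`parametric_bootstrap()` re-draws the cluster effects from their estimated
distribution, simulates Poisson counts from the fitted means, refits, and
reports the percentile 95% interval (2,000 samples in production; tests use
a few hundred); more than 5% refit failures or a zero-width interval flags
the result.

## Cluster reallocation

`reallocation_sweep()` dilates one arm's polygon *union* outward in 100 m
steps (0–1,000 m), reassigns every opposite-arm household inside the
buffered union, and refits the trial model. Dilation is implemented by the
equivalent point-to-union-distance rule (membership in the round-join
Euclidean dilation of a polygon union is exactly "distance to the union at
most the buffer"), which also makes the monotonicity of the reassigned set
in the buffer automatic. Whether the original analysis dilated each cluster
independently or the arm-wise union is not stated; the union was chosen
and the alternative noted. Reassigned households join pseudo-clusters named
after their nearest dilated-arm cluster so the cluster random effect stays
defined; the buffer-0 rows reproduce the base fit exactly; steps leaving
either arm under 30 households are flagged degenerate and not fitted. The
curve is exploratory — no hypothesis test is attached.

**What the curve can and cannot show at the default effect sizes.** Two
forces act on the estimate as the intervention arm is dilated: removing
spillover-protected controls from the control arm strengthens the contrast,
and absorbing control households into the intervention arm dilutes it.
With the default generative spillover (SMR 1.017 per 100 m, plateau at
400 m), reassigned near-boundary controls still carry ~13% higher mortality
than the intervention-arm mean ($e^{-\beta} = 1.20$ versus a spillover
plateau of only $e^{\psi R/100} = 1.07$), so dilution wins and *both*
sweeps attenuate toward the null. The strengthening pattern appears in this
generator once the spillover is roughly three times stronger
($\psi \gtrsim \log 1.05$ per 100 m) — a useful quantitative caveat when
reading reallocation curves: the diagnostic detects spillover strong enough
to dominate dilution, not spillover per se. The null-spillover behavior
(attenuation toward SMR 1 from both directions) is confirmed by simulation
in the acceptance suite.

## Pipeline, sizes and reproducibility

`run_pipeline()` executes the three analysis parts in order and persists
every table (summaries; the exploratory table; the model table; the
spillover/interaction table; the reallocation curve; the GWR surface)
plus a run log and a resolved-configuration JSON that records the master
seed and each stage seed, so every artifact is recomputable from the
persisted intermediates. Stage seeds are the master seed plus fixed
offsets, so adding a stage never perturbs earlier streams. A failed stage
is logged and later independent stages still run. The numbered scripts
under `analysis/` present the same workflow as a narrative, one stage per
script, writing under `results/`.

Simulation sizes in the tests and the acceptance script are the package's
own choices for desk-scale work: 12 clusters / ~600 households for
calibration and model-agreement studies (the generator's full default of
96 clusters / ~12,000 households runs in about a second per fit and is
exercised in the recovery probes), 24 clusters / ~1,400 households where
boundary-household counts matter (reallocation, the end-to-end pipeline),
GP fits capped at 1,000 households, 20–100 replicates depending on the
property, and bootstraps of 150–500. The numerical tie-breaks worth
knowing: nearest-discordant ties are broken arbitrarily but the distance
is unique and only the distance is used; Voronoi generation re-draws
coincident seeds; `optimize`/Nelder-Mead/L-BFGS-B tolerances are fixed in
code; a Newton Hessian that goes numerically singular gets an escalating
ridge while convergence is still judged on the gradient.
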