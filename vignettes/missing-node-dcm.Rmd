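---
title: "Missing-node imputation for fMRI dynamic causal modeling: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-node imputation for fMRI DCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dynamic causal modeling (DCM) compares candidate networks of brain regions
by the (approximate) log evidence each candidate assigns to a subject's
fMRI time series. The pipeline requires a time series for every node of
every candidate model, but subject-level first-level analyses routinely
fail to locate some expected activation: the node is *missing*, the
candidate cannot be inverted, and the subject is conventionally dropped.
`dcmimpute` treats the missing node as missing data: the absent series is
imputed by one of four methods of increasing sophistication — zero-filling,
cross-subject mean-filling, fixed-variance noise-filling, and an
EM-estimated Gaussian process — after which every candidate model can be
inverted for every subject and the full evidence matrix computed. The
package also ships the complete synthetic benchmark used to validate this
preprocessing: a generative Go/No-Go network simulator with known ground
truth, a variational Laplace model inverter, and classification, RMSE,
mutual-information and clustering diagnostics.

## The generative model

Neural dynamics follow the bilinear state equation

$$\dot z = \Big(\alpha A + \sum_j u_j B_j\Big) z + C u,$$

with intrinsic coupling $A$ (diagonal fixed at $-1$, so $\alpha$ is the
within-node decay rate), input-modulated coupling $B_j$ and direct drive
$C$. We set $\alpha = 20\,\mathrm{s^{-1}}$ by default, i.e. a mean neural
lag of about 50 ms — the realistic value for simulation, not the long lag
conventional in inversion priors. Each node's activity drives a
balloon-Windkessel hemodynamic cascade $(s, f, v, q)$ —
vasodilatory signal, inflow, venous volume, deoxyhemoglobin — whose
resting point is $(0, 1, 1, 1)$, observed through the static nonlinear
BOLD equation $y = 100\,V_0 [k_1(1-q) + k_2(1-q/v) + k_3(1-v)]$ with
$k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$ (percent signal change).
Hemodynamic constants default to the conventional prior means
($\tau = 0.98$ s, $\alpha_{\mathrm{Grubb}} = 0.32$, $E_0 = 0.34$,
$V_0 = 0.04$, $\tau_s = 1/0.65$ s, $\tau_f = 1/0.41$ s, $\epsilon = 1$).
The coupled system is integrated by a fourth-order Runge-Kutta scheme at a
5 ms step and point-sampled at TR = 3 s (no anti-alias filter, matching
common simulator practice); a 10-minute session yields 200 samples.

## What the synthetic cohort emulates — and what it does not

The default cohort mimics a four-node Go/No-Go network: visual (V),
auditory (A), motor (M) and prefrontal (P) nodes, a visual input u1 into V
(telegraph process, mean dwell 5 s up / 5 s down) and an auditory stop
signal u2 into A (2.5 s up / 10 s down), both with exponentially
distributed dwell times and Gaussian state jitter of sd 1/20 of the state
height. The stop signal inhibits motor output through a negative
modulation of the P→M edge. Per subject, present edges draw independent
strengths from a Gaussian(0.4, 0.1) truncated (by rejection) to
[0.2, 0.6]; HRF variability is emulated by log-normal jitter of
$(\tau, \tau_s, \tau_f)$ per node, calibrated (`scripts/calibrate_hrf.R`)
so the HRF peak delay has sd 0.5 s; thermal observation noise is white,
per-node i.i.d., with sd a fraction (default 0.003, the mid-point of the
plausible 0.001–0.01 range) of the mean signal level under the
percent-signal-change convention (baseline 100). The stimulus height (4.2)
is the one free amplitude scale; it was calibrated once
(`scripts/calibrate_amplitude.R`) so cohort-mean BOLD amplitudes are
approximately 4% of mean intensity, typical of 3T task data.

Features of real data deliberately not emulated: spatially correlated and
physiological (non-white) noise, slice-timing and motion artifacts,
inter-regional hemodynamic coupling, scanner drift, and the first-level
GLM that produces missing nodes in practice (missingness is imposed
directly by `remove_nodes()`). A green benchmark therefore establishes
that the imputation-plus-inversion machinery behaves as designed under the
stated generative world, not that it will rank methods identically on any
real acquisition.

### The 16-model family

The published family of 16 candidate topologies is only available as a
figure we could not reconstruct, so the package *defines* its own: the
four-edge pool {V→P, A→P, P→M, V→M} is toggled over a fixed base (u1→V,
u2→A, u2 modulating P→M where present), model id = 1 + binary code of the
included edges. This preserves the experimental structure — 16 distinct
labeled candidates including a designated true model (id 16, all pool
edges) — without fabricating fidelity to an unseen figure. Subsets of 8
or 4 keep the densest competitors and always retain the true model
(`family_subset()`).

## Missing-node estimation

All four fills replace only masked columns and leave observed data
bit-exact. `fill_zero` writes zeros; `fill_mean` averages the same node
across the other subjects where it is available (never the subject
itself); `fill_noise` draws i.i.d. Gaussian noise with sd 0.05% of the
subject's mean signal level (computed over unmasked entries);
`fill_em` fits a multivariate Gaussian across node channels by EM —
each time point one observation, masked columns missing at random — and
draws an i.i.d. series from the estimated marginal of the missing node.
The i.i.d. (marginal) fill is deliberate: the method is defined as an
independent identically distributed Gaussian process, and a
conditional-mean fill (regression on observed nodes) is available as an
option but is not the default. With an entirely missing column the
likelihood carries no information about its cross-covariance, so the EM
estimate remains at its initialization — the pooled observed mean and
variance — which is exactly the intended degenerate behaviour (and the
limit in which `fill_em` coincides with a noise fill at matched moments).
EM stops when the relative observed-data log-likelihood gain drops below
1e-6 or after 500 iterations; a singular observed covariance is
ridge-regularized with a warning.

## Inversion

`invert_dcm()` implements variational Laplace: Gauss-Newton updates of the
posterior mean using a forward-difference Jacobian of the predicted
response (step 1e-4, relative), trust-region step halving whenever a step
would decrease the free energy, an analytic Gaussian posterior covariance,
and ReML-style updates of one noise precision per node (errors i.i.d.
within node, model order 0). The free energy
$F = \text{accuracy} - \mathrm{KL}(\text{posterior} \,\|\, \text{prior})$
is the log-evidence approximation used everywhere; BIC/AIC alternatives
are available through `log_evidence()` for sensitivity analyses. In the
linear-Gaussian limit the implementation reproduces the closed-form
Bayesian linear-regression evidence to machine-level accuracy (tested).

Design choices worth knowing:

* **Constant confound.** Data and predictions are mean-centred per node
  (one degree of freedom surrendered), the standard fMRI convention in
  which a region's absolute baseline carries no information. Without it, a
  constant-filled channel's baseline level dominates model comparison,
  and the equivalence of zero- and mean-filling (both "constant fills")
  breaks. `inversion_settings(center = FALSE)` restores the raw model
  (used by the linear-limit oracle tests).
* **Free parameters.** $\theta = \{A, B, C, h\}$ flattened with a name
  index; absent edges are fixed at zero with prior variance 0, the
  diagonal of $A$ at $-1$. Free A/B entries get mean-zero priors with
  variance 0.25, C entries variance 1. Hemodynamic parameters are
  estimated on the log scale with log-normal priors (sd 0.15) about the
  prior means — and *every* constant the generative world randomizes
  ($\tau, \tau_s, \tau_f$) is free, plus the efficacy $\epsilon$. Fixing
  $\tau_f$ while the generator jitters it produced overconfident
  posteriors (coverage 62% instead of the nominal >95% per entry); freeing
  it restored calibration.
* **Integration step for inversion.** Predictions integrate at 100 ms
  (block-averaged inputs), well inside the RK4 stability region of the
  fastest time constant ($\alpha\,dt = 2 < 2.78$) and ~20x cheaper than
  the 5 ms simulation step; the induced prediction error is below 0.05%
  signal on the default network (tested).
* **Convergence.** Relative $\Delta F < 10^{-4}$ over two consecutive
  accepted iterations, or 128 iterations; non-convergence returns the
  best-so-far posterior flagged, never an exception.

## Model comparison and decisions

Posterior model probabilities are a max-stabilized softmax of log
evidence plus log prior (uniform unless configured). Classification is
the argmax — the Bayes rule under 0-1 loss — with exact ties broken
toward the lowest model id. `decide_with_utility()` generalizes to
asymmetric clinical utilities by maximizing expected utility under the
model posterior. Fixed-effects group comparison sums log evidences over
subjects. Accuracy is scored over subject-model pairs by default (each of
the candidate true models simulates its own cohort; 10 subjects x 16
models = 160 pairs explains an accuracy granularity of 1/160), with
per-subject scoring available; bootstrap resampling (default 1000, over
scored pairs) supplies the box-plot style accuracy variance.

## Diagnostics

`parameter_rmse()` is the root mean squared elementwise difference
between identically indexed parameter vectors (the square root is part of
the definition even where typesetting elsewhere lost it).
`mutual_information()` is the histogram plug-in estimator on a 16 x 16
equal-width joint grid, natural log; the discretization is a package
choice, documented because no standard exists for it, and constant
signals return 0 with a warning. `kmeans_cluster()` is Lloyd's algorithm,
best of `n_restarts` by within-cluster SSE, reporting within-SSE, the
mean pairwise Euclidean distance between centers, cluster composition
percentages, and per-cluster mean / modal-bin midpoint (16 bins) /
standard deviation per parameter.

## Reproducibility and numerics

Every stochastic stage derives its seed from the master seed via
`derive_seed(master, stage, index)` (a small multiplicative hash kept
below $2^{31}$), so cohorts are order-independent and the experiment
runner byte-reproduces its summary from a config. Integration failures
(non-finite or non-positive hemodynamic state) name the offending time
step; cohort generation attributes failures to the subject index. Fill
operations never touch unmasked data. Ill-conditioned posterior precision
matrices are symmetrized before Cholesky factorization; noise precisions
are clipped to [1e-8, 1e10].

## Scaled-down defaults in the test suite

The shipped acceptance tests exercise the full pipeline on reduced grids
(3 subjects per true model, the 4-model family subset) purely to fit a
continuous-integration time budget; the full-scale study (10 subjects x
16 models, subsets of 8 and 4, both noise levels) runs through the same
`experiment_config()`/`run_experiment()` interface unchanged. At the
reduced scale one classification instance is 1/12 of an accuracy point,
so orderings among the four fill methods are coarse; the suite asserts
the orderings as stated and the observed ties/violations are discussed in
the repository notes rather than silently tolerated.

## Known limitations

* Free-energy values are not numerically comparable to SPM's (different
  confound basis, hyperpriors and convergence criteria); only relative
  comparisons within this package are meaningful.
* The EM fill is marginal and temporal-structure-free by design; it will
  not reproduce autocorrelated BOLD dynamics of a genuinely observed node.
* Nonlinear (two-state), stochastic, and spectral DCM variants are out of
  scope, as are surplus ("extra") activations, which are ignored.
* With very small cohorts the mean fill retains donor signal variance and
  can rival the EM fill; the two converge to different limits only as the
  donor pool grows.
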