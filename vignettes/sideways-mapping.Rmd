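---
title: "Sideways biodiversity mapping: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sideways biodiversity mapping: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sidewaysmap` turns point samples of a many-species community plus
continuous covariate rasters into landscape-wide maps of occurrence
probability, richness, composition and conservation value. This vignette is
the package's own account of the science: the model and its assumptions,
the parameters that matter, what the synthetic generator does and does not
emulate, the numerical choices, and the limitations. It states no empirical
result that the test suite does not itself compute.

## 1. The joint model

For sample $i$ and species $j$,

$$y_{ij} = \mathbf{1}[z_{ij} > 0], \qquad
z_{ij} = \eta_{ij} + \Lambda_j^\top h_i + \varepsilon_{ij},\qquad
h_i \sim N(0, I_r),\ \varepsilon_{ij}\sim N(0,1),$$

a multivariate probit whose implied residual species covariance is
$\Sigma = \Lambda\Lambda^\top + I$: species co-occur beyond what the
environment explains through the shared latent factors $h_i$. The linear
predictor is

$$\eta_{ij} = f_\theta(x_i)_j + t(s_i)^\top \Gamma_j,$$

with $f_\theta$ either a linear map or a small tanh network over the
standardized covariates (the nonlinear option exists because
remote-sensing covariates act on arthropods indirectly, through vegetation
structure, so responses are plausibly complex), and $t(s)$ the monomials of
the standardized site coordinates up to degree 2 (default) — a trend
surface that absorbs broad spatial autocorrelation so it is not
misattributed to covariates. The trend is additive to the network output,
not an input to it; the model intercept lives in the network's output
biases.

**Likelihood.** The latent factors are integrated by Monte Carlo with $M$
common random draws shared across epochs:

$$\mathcal{L} = -\sum_i \log \frac1M \sum_{m=1}^M \prod_j
\mathrm{Bernoulli}\!\left(y_{ij}\,\middle|\,\Phi(\eta_{ij} +
\Lambda_j^\top h_m)\right) + \text{penalties}.$$

At $r = 0$ the expression is the exact independent-probit likelihood with
no Monte Carlo error — the test suite pins this, plus agreement of the
$r=1$ case with one-dimensional quadrature, and the $1/M$ variance decay.
Marginal prediction uses
$P(y_{ij}=1) = \Phi(\eta_{ij}/\sqrt{1+\lVert\Lambda_j\rVert^2})$, also
verified against latent-draw Monte Carlo.

**Assumptions worth stating.** Residual covariance is low-rank and constant
over space; latent factors are independent across samples (so paired traps
at one point are conditionally independent given the environment);
detection error is absorbed into the occurrence probabilities rather than
modelled separately.

## 2. Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `env_penalty`, `trend_penalty`, `loading_penalty` | 1e-3 | loss units per weight | elastic-net strengths per block; tuned log-uniformly on [1e-4, 1] |
| `env_mix` etc. | 0.5 | [0,1], L1 share | 1 = lasso (sparse responses), 0 = ridge |
| `latent_rank` | 2 | 0–species | co-occurrence capacity; 0 = independent probits |
| `hidden` | `integer(0)` | layer widths | `c(25, 25)` enables the nonlinear feature network |
| `lr`, `epochs` | 0.05, 300 | — | full-batch Adam; early stop at 1e-5 plateau over 50 epochs |
| `M` | 100 | draws | MC accuracy vs time; bias of `-log` mean is O(1/M) |
| `trend_degree` | 2 | polynomial degree | degree 1 is a plane; >3 rarely identifiable at ~100 sites |
| `min_sites` | 6 | samples | incidence filter below which a species is unlearnable |
| `vif_threshold` | 10 | — | standard collinearity cut; the source analysis states no value |
| `train_fraction` | 0.75 | — | 121 samples split 91/30, ties rounded up |
| `min_auc` | 0.7 | AUC | inclusive mapping bar for species |
| richness threshold | 0.5 | probability | inclusive (`>= 0.5`) |
| irreplaceability `fraction` | 0.5 | of total expected incidence | conservation target $t_j=\lceil 0.5\sum_i p_{ij}\rceil$ |

## 3. The synthetic world

`generate_landscape` smooths white noise with a separable Gaussian kernel
(`autocorr_range` = kernel sd in pixels) and standardizes each layer —
a stand-in for smoothed multi-scale covariate products. The true spatial
covariance of real covariate stacks is unknown; this field model is a
testing device, not an inference target. `generate_species` draws sparse
responses (linear, quadratic, threshold, or multiplicative interaction) and
calibrates each intercept by bisection so the species' marginal prevalence
hits a target drawn from [0.10, 0.60] — chosen so that species of realistic
commonness pass or fail the incidence filter predictably. Residual
co-occurrence comes from Gaussian loadings (sd 0.6, a moderate correlation
regime). `generate_design` scatters 89 points with 32 paired (two traps,
independent draws at one pixel), reproducing the 121-sample structure of
the emulated campaign; `simulate_incidence` draws one latent factor vector
per sample, so paired traps are correlated only through the environment.

What the generator does **not** emulate: sequencing and OTU-calling noise
(false positives/negatives enter only as Bernoulli sampling), spatially
structured detection effort, phylogenetic signal in responses, abundance
information, and non-Gaussian covariate marginals. A green recovery test
therefore establishes that the estimator works when its assumptions hold —
not that field data meet them.

## 4. Numerical choices

* **Probability clamps:** probabilities inside logs are clamped to
  $[10^{-7}, 1-10^{-7}]$; gradient scores use the stable inverse-Mills form
  $\exp(\log\phi - \log\Phi)$.
* **L1 via proximal step:** Adam with a subgradient for L1 oscillates at
  the learning-rate scale, so the L1 component is applied as a soft
  threshold after each Adam update; extreme penalties then produce exact
  zeros (tested).
* **Deterministic prediction:** BLAS `dgemm` rounding depends on matrix
  shape, which would break the contract that chunked and whole-raster
  prediction agree bit-for-bit. Prediction therefore uses a fixed-order
  rank-1 accumulation matmul; fitting keeps BLAS (its determinism is
  per-identical-call, which the seed contract requires and tests).
* **Leave-one-out Poisson binomial:** $P(X_{-i}=t-1)$ for every pixel is
  obtained by deconvolving pixel $i$ out of the full DP PMF, bottom-up when
  $p_i \le 0.5$ and top-down otherwise, so the recursion's growth factor
  never exceeds 1 (stable; $O(n)$ per pixel, vectorized across pixels).
  Exactness for $n \le 15$ is pinned against $2^n$ enumeration.
* **Ties and boundaries:** coverage calls are strictly `> 0.5` of barcode
  length; incidence filter, AUC species bar and richness threshold are
  inclusive (`>=`); VIF ties break by column order; CV ties break by
  smaller total penalty, then candidate order; the train size rounds half
  up (91/30 from 121).
* **Degenerate inputs:** single-class species yield `NA` AUC and are
  dropped from means; constant covariates are skipped in interaction
  scans; an unreachable conservation target yields zero alpha with a
  warning; all sites at one coordinate make the trend surface error out.

## 5. Open design decisions, and how they were resolved

* **VIF threshold and removal order** are not stated by the source
  analysis; default 10, removing the largest-VIF covariate iteratively,
  with a removal log (covariate, VIF, step) so the reduction is auditable.
* **Standardization** is computed on training rows only and reapplied to
  test rows and rasters (the alternative — global standardization — leaks
  information; the source is silent).
* **Split is by sample** to mirror the emulated protocol; `group_by_point`
  prevents paired-trap leakage for users who want it, off by default.
* **CV aggregation** ("highest predictive performance") is mean AUC over
  species then folds, `NA`s dropped.
* **Trend surface additive** to the feature network, not concatenated to
  its inputs: keeps the environment/space decomposition identifiable.
* **Irreplaceability variant:** the index is implemented as pivotality —
  occupied *and* exactly decisive for $t_j$ — which is what "loss of that
  pixel would prevent achieving the conservation target" says; the $2^n$
  enumeration oracle pins these semantics, and both the fraction and a
  fixed integer target are configurable. Cross-species combination assumes
  independence (complement product). With many diffuse pixels the
  pivotality probability is astronomically small (the PMF mass near
  $t_j \approx \tfrac12\sum p$ vanishes as $n$ grows) — values are then
  meaningful as rankings, and the block-aggregation option computes the
  index over planning units instead, where magnitudes are interpretable.
* **t-SNE at scale:** the embedding runs on a random subsample (default
  10 000 pixels) and other pixels inherit their nearest sampled
  neighbour's coordinates in species space. Axes are sign- and
  rotation-arbitrary: tests assert distance relations only.
* **Rasters as ASCII grids:** no GeoTIFF-capable R package is available in
  the build environment, so all rasters are read/written as ESRI ASCII
  grids (one plain-text file per band, shared header, NoData −9999) with
  the same grid/transform contract a multiband GeoTIFF would carry.
* **Null calibration sample size:** explanatory AUC on label-randomized
  data exceeds 0.5 by a finite-sample overfitting term of order
  (parameters per species)/$n$; the ±0.05 calibration band is therefore
  checked on a 3000-sample design (9 parameters per species), where the
  term is ≈0.04. At 300 training samples the same fit measures ≈0.095 —
  expected behaviour, not an estimator defect.

## 6. Known limitations

* The likelihood optimum is stochastic in $M$ and non-convex in the
  network weights: different seeds give slightly different fits. All
  pipeline stages are seeded and the full run is hash-reproducible.
* Rank selection is by CV only; no information criterion is provided.
* The irreplaceability index ignores connectivity and ecosystem function,
  and treats species as independent when combining alphas.
* No abundance modelling, no phylogenetic or trait covariances, no
  spatially explicit residual process beyond the trend surface.
* Interaction $H^2$ is grid-based; with strongly skewed covariates the
  quantile grid can under-resolve the tails.
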