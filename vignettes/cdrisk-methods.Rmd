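---
title: "Mapping standard-exceeding probabilities for soil cadmium: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping standard-exceeding probabilities for soil cadmium: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrisk)
```

## The problem

Regulatory soil-quality standards for trace metals are increasingly
*composite*: the threshold concentration depends on conditions that
modulate bioavailability, here the soil pH interval and the land-use
type. Whether a location is "polluted" therefore depends on three
quantities — the Cd concentration, the pH, and the land use — of which
the first two are only known at scattered sample points. A kriged map of
Cd compared against a kriged map of pH understates risk: interpolation
smooths away the extremes that drive exceedances. `cdrisk` instead
propagates the joint spatial uncertainty by simulation and reports, per
grid cell, the probability that Cd exceeds its locally applicable
threshold.

## The probability model

Let the composite standard have pH breakpoints
$\alpha_0 < \dots < \alpha_S$ and thresholds $\beta_i$ per land use.
With the land use mapped (known) per cell, the exceedance probability at
cell $x$ is a mixture over pH intervals:

$$P\{Z(x) > z_c(x)\} \;=\; \sum_{i=1}^{S}
  P\{\alpha_{i-1} \le z_{\mathrm{pH}}(x) < \alpha_i\}\;
  P\{z_{\mathrm{Cd}}(x) > \beta_i(x)\},$$

with both factors estimated as counting frequencies over $L$ simulated
realizations of each attribute. The factorized ("product") form is valid
when the Cd and pH fields are independent; total Cd is governed mainly by
parent material and pollution sources rather than by pH, and the
sample cross-correlogram (`cross_correlogram()`) lets the user verify
that the assumption is tenable for their data. The package also
implements the unfactorized ("joint") estimator, which counts paired
realizations — realization $r$'s simulated pH picks the threshold that
realization $r$'s simulated Cd is compared against. On independently
generated stacks the two agree to within counting noise (this is tested),
and the joint mode remains correct under a future correlated
cosimulation, which the product mode would not be.

Two conventions matter at the boundaries and are applied everywhere
consistently:

* **Interval closure.** Intervals are left-closed/right-open, with the
  last closed at pH 14 (`[0,5.5) [5.5,6.5) [6.5,7.5) [7.5,14]`), the
  convention the printed regulatory table uses. The equivalent
  mathematical statement with the opposite closure differs only on a
  measure-zero set, but at exact breakpoints (pH 6.5, say) the table's
  convention governs.
* **Strict exceedance.** A realization exactly at the threshold does not
  count as exceeding.

Risk masks flag cells with probability **at or above** the critical value
`p_c`, so `p_c = 1` is attainable when all $L$ realizations exceed, and
masks are nested: the 0.95 mask is always contained in the 0.90 mask.

## Geostatistical engine

**Normal-score transform.** The rank-$r$ value among $n$ samples maps to
$\Phi^{-1}\!\big((r - 0.5)/n\big)$; ties collapse to one knot carrying
the average of their ranks' scores, keeping both table columns strictly
increasing. Back-transformation is linear between knots and linear from
the outermost knots to configurable bounds — by default the sample
minimum minus one standard deviation and the sample maximum plus one —
anchored at the $\Phi^{-1}(10^{-4})$ scores and clamped beyond. Two
consequences are worth keeping in mind: simulated values can never leave
`[min − sd, max + sd]`, so the simulation cannot postulate concentrations
far beyond what was observed; and values at the knots round-trip
bit-exactly, which is what makes conditioning exactness testable at the
bit level.

**Variograms.** The experimental variogram is Matheron's
method-of-moments estimator on omnidirectional distance bins (12 bins to
half the maximum pairwise distance by default; anisotropy is out of
scope). Models are fitted by weighted least squares with Cressie-style
weights $N(h)/\gamma_{\text{model}}(h)^2$, recomputed from the current
model inside the objective, using `optim(L-BFGS-B)` from a small grid of
starting values. Three families are supported; the spherical range is
the actual range while the Gaussian and exponential ranges follow the
practical-range convention ($\gamma$ reaches ~95% of the sill at
$h = a$), as in the GSLIB tradition. The nugget ratio
$C_0/(C_0 + C)$ summarizes spatial structure; values between 0.25 and
0.75 are conventionally read as moderate autocorrelation, and the
synthetic defaults sit inside that band.

**Sequential Gaussian simulation.** Samples are assigned to their nearest
grid nodes (on a collision the sample closest to the node centre wins);
those nodes are fixed. Each realization visits the remaining nodes along
a fresh uniform random path, builds a simple-kriging system (known mean
0, as normal scores demand) from up to 16 informed nodes within a search
radius of 1.5 × the variogram range, draws from the Gaussian conditional
distribution (kriging mean and variance), and finally back-transforms.
Numerical guardrails: a singular kriging system falls back to a draw
from the $N(0, \text{sill})$ marginal; kriging variances are clamped to
$[0, \text{sill}]$; a fitted sill far from 1 triggers a warning since
the model is expected to describe normal scores. Reproducibility comes
from per-realization seeds derived deterministically from the master
seed, so realization $r$ is the same whether simulated alone or as part
of a longer run — and an $L=100$ stack is exactly the first 100 columns
of the $L=500$ stack with the same master seed.

**E-type estimate.** The cellwise mean over realizations; it is the
optimal point estimate implied by the simulation and deliberately
exhibits the smoothing that individual realizations avoid (the package
tests that the E-type map varies less than realizations do).

## The synthetic study area

No sample data are distributable, so the generator builds the study
conditions from scratch, emulating a peri-urban soil survey:

* **Fields.** Unconditional Gaussian random fields on the grid via
  circulant embedding (FFT of the torus-embedded covariance; one complex
  white-noise draw yields two independent fields), with nugget variance
  added as iid noise. Circulant embedding was chosen deliberately so that
  the simulator under test (SGS) is never used to manufacture its own
  test data. Very smooth covariances can make the embedding slightly
  indefinite; tiny negative eigenvalues are clamped, with a warning when
  the clamped mass exceeds 0.1% of the total.
* **Marginals.** Each standardized Gaussian field is mapped through a
  target quantile function. Cd: shifted lognormal clipped to
  `[0.26, 1.94]` mg/kg with median 0.68 and mean ≈ 0.74 (the clipping
  brings the realized SD to ≈ 0.30 against a nominal 0.32 — accepted, as
  only min/max/median/mean/SD of the emulated survey are known, not its
  shape). pH: normal with mean 6.71 and SD 0.98 clipped to
  `[4.29, 9.08]`; a symmetric shape was chosen in the absence of shape
  information, so the synthetic pH median equals its mean rather than
  the slightly higher value a skewed survey would show.
* **Spatial structure.** Cd: spherical, nugget ratio 0.4, range 1500 m.
  pH: Gaussian model, nugget ratio 0.5, range 2000 m. Both inside the
  moderate-autocorrelation band; the two fields use disjoint seed
  streams and are independent by construction.
* **Land use.** A smooth latent Gaussian field (range = `patch_scale`,
  2500 m by default) is cut along its rank order into exact class counts
  (40% paddy field, 30% dry farmland, 30% nonfarmland), yielding
  contiguous patches with exact shares.
* **Sampling.** 150 distinct cell centres drawn uniformly; both
  attributes read co-located and exactly (optional Gaussian measurement
  noise is available but off by default).
* **Scale.** The default grid is 120 × 120 cells at 60 m (≈ 52 km²) — the
  survey resolution kept, the extent reduced so that a full
  $L = 500$ run completes in minutes on one CPU. $L = 500$ itself is
  retained as the reference realization count.

**What passing on synthetic data does and does not show.** The generator
draws stationary, isotropic fields with exactly known variograms and
marginals, samples them without measurement error under a uniform
design, and uses a land-use map that is error-free. Success here
validates the estimator chain — transform, fit, simulation, counting,
delineation — under the model's own assumptions. It does not establish
robustness to trends, anisotropy, preferential sampling, censored
laboratory values, or land-use misclassification, all of which real
surveys exhibit to some degree.

## Test design notes

Distributional checks (histogram reproduction, variogram reproduction)
run on a 40 × 40-cell fixture whose field ranges (600–800 m) span the
2.4 km domain several times. With a range close to the domain size, each
realization contains only a couple of independent patches and its
histogram fluctuates at domain scale, which would confound a
histogram-reproduction check regardless of simulator quality; several
ranges per domain make realizations near-ergodic so the check measures
the implementation, not the fixture. The ergodic-mean check runs
unconditionally (no conditioning nodes), because conditioning shifts the
expected grand mean by the average kriging predictor — a real, data-
dependent offset that would otherwise have to be recomputed inside the
test. End-to-end discrimination is scored as the rank AUC of the
estimated probability against the ground truth "true Cd exceeds the
threshold implied by true pH and land use", computed from the generator's
fields.

## Known limitations

* Cd and pH are simulated independently; if a survey shows material
  cross-correlation, the product estimator is biased and a correlated
  cosimulation (not implemented) feeding the joint estimator would be
  needed.
* Isotropic variograms only; no trend (universal kriging) component.
* The land-use map is treated as exact; uncertainty in the categorical
  map does not propagate.
* Back-transform clamping bounds simulated values by the sample extremes
  ± one SD; with few samples this understates tail risk.
* The 16-neighbour search neighborhood trades a little long-range
  variogram fidelity for speed; the reproduction tolerance (±20% below
  the range, averaged over 50 realizations) reflects that trade.
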