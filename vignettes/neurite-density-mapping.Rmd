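---
title: "Neurite density mapping: model, phantom and statistics"
author: "neuritemap developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurite density mapping: model, phantom and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuritemap)
```

## The problem

Chronic stress remodels hippocampal dendrites, and histology can only
measure that destructively. Multi-shell diffusion-weighted MRI offers a
non-invasive proxy: if the diffusion signal in gray matter is modelled as
the sum of a neurite (dendrite + axon) compartment and an isotropic
remainder, the neurite *signal fraction* ν tracks regional dendritic
density. This package implements that analysis end to end — a
two-compartment forward model, voxel-wise bound-constrained least-squares
fitting, a layered hippocampal phantom for validation, ROI group
statistics with an exact rank-sum test suited to four subjects per group,
and a three-stage command-line pipeline.

## The signal model

A voxel's signal at b-value $b$ and unit gradient direction $\hat g$ is

$$
S(b,\hat g) = S_0\Big[(1-\nu)\,e^{-b D_\mathrm{eff}}
 + \nu\, e^{-b D_T} \sum_{l=0,2,4}\sum_m f_{lm}\,
   k_l\big(b(D_L - D_T)\big)\, Y_{lm}(\hat g)\Big],
$$

with

* $\nu \in [0,1]$ — neurite signal fraction (a *signal* fraction, not a
  volume fraction: compartmental $T_2$ differences are not modelled);
* $D_\mathrm{eff}$ — effective Gaussian isotropic diffusivity of
  everything that is not a neurite (somas, glia, extracellular space);
* $D_L \ge D_T \ge 0$ — diffusivities along and transverse to the neurite
  axis; neurites are impermeable, cylindrically symmetric segments. Any
  diffusion-time dependence of restricted transverse diffusion is folded
  into the effective $D_T$; the pulse timings Δ/δ are metadata only;
* $f_{lm}$ — coefficients of the axis orientation distribution function
  (ODF) in the real, orthonormal, even-order spherical-harmonic basis,
  $(l,m)$-lexicographic column order, $f_{00} = 1/\sqrt{4\pi}$ fixed so
  the ODF integrates to one (hence $S(0) = S_0$ exactly);
* $k_l(\alpha) = 2\pi \int_{-1}^{1} e^{-\alpha t^2} P_l(t)\,dt$ — the
  Funk–Hecke reduction of convolving the single-cylinder response
  $e^{-\alpha t^2}$ with the ODF. $k_0(0) = 4\pi$, $k_{l>0}(0) = 0$.

The expansion stops at $l_\mathrm{max} = 4$ (15 coefficients): with 54
measurements the voxel problem stays comfortably overdetermined, and the
54-direction scheme integrates degree-4 polynomials accurately.

### Numerical evaluation of $k_l$

Two regimes, switched at $\alpha = 0.5$. Above, the even Gaussian moments
$I_n = \int t^n e^{-\alpha t^2}dt$ come from the erf closed form plus an
upward recurrence and are combined with the Legendre monomial
coefficients. Below, that combination cancels catastrophically (for
$l = 4$ the leading behaviour is $O(\alpha^2)$ from $O(1)$ moments), so
$k_l$ is summed directly as
$\sum_k \frac{(-\alpha)^k}{k!}\int t^{2k}P_l\,dt$ with closed-form
Legendre moments — the leading term is then exact. Both branches agree
with adaptive quadrature to better than $10^{-8}$ relative; the test
oracle subtracts the analytically vanishing low orders of the exponential
so that the quadrature itself is well conditioned at small $\alpha$.

## Fitting

`fit_voxel()` minimises the Gaussian least-squares objective under box
constraints by **variable projection**: the optimizer (L-BFGS-B with the
exact Golub–Pereyra gradient) searches only
$(D_\mathrm{eff},\, D_L,\, D_T/D_L) \in [0, 4\times10^{-3}]^2 \times
[0,1]$, and at every candidate the amplitudes — $S_0(1-\nu)$ and
$S_0\nu f_{lm}$ — are solved exactly as a linear subproblem
(non-negativity of the two compartment amplitudes enforced by refitting
with the offending compartment removed). This is the same estimator as
the 19-parameter joint problem but with a 3-dimensional nonlinear search,
roughly an order of magnitude faster and far less multi-modal. A
consequence: multi-start perturbations of ν are meaningless (ν is
recovered in closed form per candidate), so the start set perturbs only
the diffusivities.

Start set: a log-linear diffusion tensor fit on the $b \le 4000$ s/mm²
rows (`dti_init()`; MD initialises $D_\mathrm{eff}$, the extreme
eigenvalues initialise $D_L, D_T$), plus a fixed grid of four
well-separated $(D_L, D_T/D_L)$ starts. The grid exists because the
tensor start is *degenerate* for isotropic-ODF voxels — it proposes
$D_L \approx D_T$, where the neurite and isotropic design columns are
collinear and small perturbations cannot escape; a ±20% perturbation
scheme around the tensor start was tried first and failed exactly there.
Beyond five starts, seeded ±20% perturbations are added. Fits are
deterministic given the seed, and measurements are sorted into a
canonical order first, so results are invariant to reordering of the
scheme. Per-voxel seeds in `fit_volume()` derive from the configured seed
and the voxel's linear index, making maps independent of traversal order.

The noise model is Gaussian least squares, not a Rician likelihood: the
emulated protocol averages four acquisitions per direction and reports no
noise-floor handling. The resulting Rician bias at high b is *measured*
by the tests, not corrected: at b₀-SNR 50 it inflates ν by ≈ +0.04 in
coherent voxels and by up to +0.2 in isotropic (cell-body-layer) voxels,
where the iso/neurite contrast is weakest. This mirrors the biological
caveat that in cell layers the "non-neurite" pool is the sum of somas and
extracellular space, so ν there is not interpretable as dendritic
density.

ODF non-negativity is not enforced during fitting (it would add nonconvex
constraints); a per-voxel negativity flag is recorded instead.

## The phantom

`simulate_study()` generates the stand-in for ex-vivo data: two groups
(default n = 4, matching the emulated study), a shared label map, and
per-subject 4-D volumes under the default acquisition — 9 shells at
b = 0–15000 s/mm², 6 directions each, Δ/δ = 8/2 ms, four averages.

Choices a reader should know:

* **Geometry** is a schematic slab of parallel laminar bands, one band
  per subregion (CA1 SO/CL/SR/LM, CA3 SO/CL/SR/LM, DG GL/ML — ten
  labels). The analysis consumes only ROI labels, so anatomical realism
  buys nothing; laminae also make per-layer voxel counts scale exactly
  with band width, which concentric annuli cannot.
* **Neurite densities** default to the reference group means ± SDs per
  layer; each subject's per-layer ν is drawn from its group's
  (mean, SD) truncated to [0,1]. Between-subject variability applies to
  ν only; diffusivities are fixed across subjects at typical fixed-tissue
  values ($D_L = 1.2$, $D_T = 0.1$, $D_\mathrm{eff} = 0.7
  \times 10^{-3}$ mm²/s), since the reference reports spread only for ν.
* **ODFs**: dendritic strata are "coherent" — a single axis represented
  by truncated-delta coefficients $f_{lm} = Y_{lm}(\hat n)$, damped by a
  spherical heat kernel $e^{-0.06\,l(l+1)}$. The damping is the smallest
  round level at which the band-limited representation stops producing
  (slightly) negative predicted magnitudes at high b; ν recovery is
  unaffected because the fit is linear in $f_{lm}$. Cell layers (CL, GL)
  are isotropic.
* **Noise** is Rician: observed $= \sqrt{(S+\epsilon_1)^2 +
  \epsilon_2^2}$ with $\epsilon \sim N(0, S_0 / \mathrm{SNR}_{b0} /
  \sqrt{n_\mathrm{avg}})$ — the $1/\sqrt{n}$ factor approximates
  magnitude averaging of four acquisitions. Default SNR 50.

What a green phantom test does **not** establish: performance under
anatomical partial-volume mixing, spatially varying diffusivities,
motion/eddy artifacts, or the inter-rater variability of manual ROI
drawing. The phantom validates the estimator and the statistics, not the
acquisition.

## Statistics

Subject-level ROI means of the ν map feed an exact two-sided Wilcoxon
rank-sum test: all $\binom{8}{4} = 70$ assignments of the mid-ranks are
enumerated and the smaller tail probability is doubled (capped at 1).
Tail doubling is chosen because it reproduces the printed significance
levels of the emulated study exactly; at n = 4/4 without ties the
achievable two-sided p-values are
$\{2,4,8,14,24,34,48,62\}/70$ and 1, so "p = 0.03" is the floor
$2/70 \approx 0.029$ and anything short of complete separation of the
eight subject means is ≥ 0.057. Group SDs are sample SDs (n−1). Multiple
comparison correction is off by default (matching the emulated analysis);
Holm is available behind a flag.

A consequence worth spelling out: a power requirement of "p ≤ 0.05 in
≥ 80% of replicates" at n = 4/4 demands complete separation in ≥ 80% of
replicates. With CA3 SR group distributions N(0.33, 0.03) vs
N(0.43, 0.07), complete separation has probability ≈ 0.49 (Monte Carlo);
ROI-mean fit noise lowers the observed rate further. The corresponding
acceptance test is therefore expected to fail, and does — it is kept
red deliberately rather than weakened, and the measured rate is the
honest answer: at these effect sizes and n = 4, a single replicate of the
study has roughly even odds of reaching significance in any one ROI.

## Tolerances and degenerate inputs

* Gradient directions at b > 0 are renormalised if their norm is within
  $10^{-3}$ of 1, rejected otherwise; after construction norms must be
  within $10^{-6}$.
* b = 0 rows carry arbitrary direction vectors and always predict $S_0$.
* `brute_force_signal()` (the testing oracle: direct Fibonacci-grid
  quadrature of the neurite integral) rejects ODFs whose reconstruction
  dips below −0.25 × peak — truncated deltas legitimately ring to ≈ −11%,
  so an absolute threshold would reject valid coherent ODFs.
* All-zero or non-finite voxels are flagged unconverged and excluded from
  ROI means (exclusions are counted); an ROI with no finite voxels is an
  error, not a silent NA.
* The packaged 54-direction set is a seeded electrostatic-repulsion
  optimum with per-vector signs chosen to null the resultant; it
  integrates even polynomials to degree 4 within $6\times10^{-3}$
  worst-case relative error (requirement: $10^{-2}$).

## Known limitations

* ν in cell layers conflates somas and extracellular space with the
  neurite pool's complement; interpret only dendritic strata as "neurite
  density".
* The Gaussian objective leaves Rician bias in low-SNR, high-b regimes.
* No spatial regularisation; voxels are fitted independently.
* $l_\mathrm{max} = 4$ cannot represent sharp multi-fiber crossings.
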