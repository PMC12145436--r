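---
title: "Geometric prediction of cortical activity maps by multiresolution lattice kriging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric prediction of cortical activity maps by multiresolution lattice kriging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geokrig)
```

## The scientific question

Task-evoked cortical activity is a landscape of regional increases
(task-positive) and decreases (task-negative). If a common set of
topographic principles shapes both, then the spatial layout of one extreme
should predict the other. `geokrig` operationalizes this with spatial
Gaussian-process regression (kriging): threshold a z-score surface map to
its extreme tail, fit a spatial model to the masked vertices only, predict
the whole cortical sphere, and ask how well the unseen out-of-mask
activity is recovered — overall, restricted to truly task-positive
vertices (z > 0), and restricted to vertices far from the predictor mask.

## The model

The map value at location $s$ on the unit sphere is modelled as

$$ y(s) = \mu + \sum_{\ell=1}^{L}\sum_{j} c_{\ell j}\,
   \phi_{\ell j}(s) + \varepsilon(s), \qquad
   \varepsilon \sim N(0, \sigma^2), $$

where $\phi_{\ell j}$ are compactly supported Wendland basis functions,
$\phi(d) = (1-r)^6(35r^2+18r+3)/3$ with $r = d/\theta_\ell$, centred at
the nodes of an icosahedral lattice at resolution level $\ell$ and
evaluated at great-circle distances $d$. Coefficients at level $\ell$
carry a spatial-autoregressive (SAR) Gaussian prior with sparse precision
$Q_\ell = B_\ell^\top B_\ell$, $B_\ell = \mathrm{diag}(\text{degree} +
\kappa^2) - A_\ell$ built from the lattice neighbour graph, scaled by the
level weight $\alpha_\ell$. The posterior mean solves the penalized
least-squares system

$$ (\Phi^\top \Phi + \lambda\, Q_\alpha)\, c =
   \Phi^\top (y - X\beta), \qquad
   Q_\alpha = \mathrm{blockdiag}(Q_\ell / \alpha_\ell), $$

jointly with the unpenalized fixed part ($X$ an intercept by default),
where $\lambda = \sigma^2/\rho$ is the noise-to-process variance ratio.
Everything is sparse: the basis matrix by compact support, the prior by
the lattice graph, so whole-sphere prediction at tens of thousands of
vertices is cheap.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| levels $L$ | 3 | — | multiresolution depth |
| node sets | icospheres at subdivision 2, 3, 4 (162, 642, 2562 nodes) | — | lattice per level |
| $\alpha$ | (1, 0.25, 0.01) | — | relative variance per level |
| range $\theta_\ell$ | 2.5 × median nearest-node arc | radians | basis support |
| $\kappa^2$ | 0.01 | — | SAR diagonal augmentation (proper prior) |
| $\lambda$ | `"auto"` | — | noise-to-process ratio |
| mask quantile | 0.25 | — | extreme-tail fraction (0.15 / 0.35 variants supported) |
| distance restriction | 0.1 | radians | evaluation exclusion zone around the mask |

Node counts are the natural icosphere sequence (10·4^n + 2). The
LatticeKrig software's spherical example (`LKSphere`), whose design this
engine follows, uses slightly different per-level counts (153, 625,
2523) from a node-thinning step that is not part of a plain icosphere;
we use the standard subdivision and match the total scale (~3.4k nodes)
rather than chase the exact counts. The $\alpha$ weights
are used as given, not renormalized; only their ratios matter because the
overall process variance is absorbed by $\lambda$.

### Choosing $\lambda$

`selectLambda()` evaluates either the profiled Gaussian likelihood
(default) or GCV over a log-spaced grid, choosing the minimizer and
breaking exact ties toward heavier smoothing. The profile likelihood is
computed sparsely via the Woodbury identity,
$\log|\lambda I + \Phi Q_\alpha^{-1}\Phi^\top| = (n-p)\log\lambda +
\log|\Phi^\top\Phi + \lambda Q_\alpha| - \log|Q_\alpha|$. On fields
simulated from the model's own prior, the selected $\lambda$ falls within
a factor of three of the generative $\sigma^2/\rho$ in essentially every
replicate (the test suite requires 80% of 20).

The masked-prediction pipeline uses `lambda = "auto"` because no single
fixed ratio is appropriate for both very smooth and noise-dominated maps.
Permutation analyses (network prediction, spin nulls) instead hold
$\lambda$ fixed at 0.001 so the observed and null statistics are computed
by an identical procedure, and the per-frame calcium pipeline fixes it
for cost.

## Evaluation

All accuracy metrics are Spearman rank correlations with average-rank
ties, computed strictly on out-of-mask valid vertices; medial-wall
vertices are excluded from fitting, evaluation and eigenmodes everywhere,
though lattice nodes still tile the whole sphere. Restrictions (none /
observed z > 0 / minimum geodesic distance from the mask) are pure
post-hoc filters over one fit — fits are never re-run per restriction.
Sets with fewer than 10 vertices yield an NA metric, flagged rather than
thrown. Boundary ties at the quantile cut go to the lower vertex index,
making masks deterministic.

## Null models

Two complementary nulls mirror the study design:

* **Spin permutations** (`spinNull()`): the network label map is rotated
  by Haar-random proper rotations (QR with sign-corrected diagonal;
  sample determinant corrected to +1) and each vertex takes the label of
  its nearest source vertex under the inverse rotation. P-values use the
  add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$ and
  are reported with Benjamini–Hochberg and Bonferroni corrections side by
  side, neither preferred. Rotations that empty a network are resampled
  and counted. Default 500 rotations.
* **Eigenmode surrogates** (`eigenstrap()`): the map is projected onto
  mesh Laplacian eigenmodes; coefficients are rotated by independent
  Haar-random orthogonal matrices within eigengroups (eigenvalue clusters
  at relative tolerance 1e-3, or consecutive blocks of size $2\ell+1$
  mimicking spherical-harmonic degeneracy when the spectrum is
  non-degenerate); the map is reconstructed keeping the constant
  component and the out-of-basis residual, and optionally rank-remapped
  onto the original value multiset so each surrogate's histogram is
  exactly the original's. Default 200 surrogates.

Surrogates match the original's variogram at every separation the basis
resolves; below the half-wavelength of the highest retained mode
(eigenvalue $\ell(\ell+1)$ on the sphere, so roughly 0.25 rad for 200
modes on a 642-vertex sphere) no eigenmode-based surrogate can track the
autocorrelation, and that scale is excluded from the fidelity checks.

## Discrete geometry

Meshes are icospheres built by midpoint subdivision. The mesh Laplacian
defaults to the cotangent-weighted Laplace–Beltrami stiffness with lumped
vertex-area mass — the standard discrete geometric operator, whose
icosphere spectrum reproduces the spherical-harmonic eigenvalues
$\ell(\ell+1)$ with the correct $2\ell+1$ degeneracy to high accuracy —
with an unweighted graph Laplacian as an option. Modes are
mass-orthonormal, ascending, and sign-fixed (largest-magnitude entry
positive) for determinism. Great-circle distances use the atan2 form,
stable near 0 and $\pi$. All distances are radians on the unit sphere; a
millimetre interpretation requires an explicit sphere radius, which the
package deliberately leaves to the user (0.1 rad is the operative
default restriction).

## The synthetic data model

The generators produce every input with known ground truth:

* `synthMap()` draws $\sum_k a_k \lambda_k^{-\gamma/2}\psi_k +
  \varepsilon$ over mesh eigenmodes (constant mode excluded),
  standardized to zero mean and unit variance so quantile thresholds
  behave like z-score maps. Eigenmode synthesis (rather than ad-hoc
  smoothing) makes the autocorrelation analytically known and matches the
  surrogate machinery. $\gamma = 3$ is the smooth antagonistic-map
  regime; $\gamma = 0$ is defined as white noise, since a flat spectrum
  over a full orthonormal basis is i.i.d. vertex noise (this also
  resolves the otherwise ambiguous boundary case in the generator's
  contract).
* `synthTaskFamily()` mixes one shared and per-task unique fields as
  $\sqrt{w}\,S + \sqrt{1-w}\,U_i$, so the expected pairwise correlation
  equals $w$.
* `synthNetworks()` grows a 7-way parcellation from seeded patches,
  always extending the currently smallest network (areas stay within a
  factor of ~2); `patchesPerNetwork` controls distributed-versus-compact
  geometry.
* `synthMovie()` generates planar AR(1) frame series
  ($F_t = \phi F_{t-1} + \sqrt{1-\phi^2}E_t$, lag-1 correlation $\phi$)
  on spectrally synthesized smooth innovations, with an elliptical
  valid-pixel window approximating a cortical imaging field.

One caveat worth knowing when interpreting chance-alignment tests: with a
steep spectrum ($\gamma \ge 3$ and eigenvalues growing like
$\ell(\ell+1)$), most variance sits in the three $\ell = 1$ modes, so two
*independent* smooth maps correlate substantially by chance (|r| ≈ 0.4 on
average — a 3-dimensional direction overlap). Independence and
decorrelation properties are therefore checked with flatter spectra
($\gamma \approx 0.5$–1), which spread variance over many eigengroups.

What the generators deliberately do not emulate: hemodynamics, subject
averaging artefacts, spatially heterogeneous autocorrelation, signal
dropout, and the empirical geometry of real parcellations. Passing tests
demonstrate that the machinery behaves as designed under its own
generative assumptions, not that real cortical maps satisfy them.

## The planar (calcium) variant

`framePredict()` applies the same logic per image frame with a regular
2-D lattice (spacing halving per level, nodes padded one spacing beyond
the domain, Euclidean pixel distances): mask the top 25% of valid pixels,
fit, predict all valid pixels, and evaluate with and without a minimum
pixel distance (default 25 px, Euclidean; Chebyshev available).
`seriesAnalyze()` fits every frame independently — no information crosses
frames — and `groupInference()` tests whether the average per-frame
correlation exceeds chance: a one-sided t-test on Fisher-z values, and an
AR(1)-adjusted test that fits $z_t = c + \varphi z_{t-1} + e_t$ and
tests the process mean $c/(1-\varphi)$ with a delta-method standard
error. The AR specification is an order-1 choice made here (the order is
the minimal one that captures serial dependence in slowly varying
series); correlations of exactly ±1 are clipped to $1 - 10^{-12}$ with a
warning before the transform.

## Numerical choices and edge cases

* Penalized systems are solved by sparse Cholesky; a singular system at
  $\lambda = 0$ (duplicate locations) raises an error recommending
  $\lambda > 0$.
* Spearman correlations on numerically constant vectors (e.g. an
  intercept-only prediction from a constant mask) are reported as NA
  rather than ranking floating-point noise.
* Points outside every basis support receive the fixed part only, with a
  warning.
* All generators and null ensembles are pure functions of their seed;
  stage runs write a JSON configuration echo at 17 significant digits so
  a re-run from the echo is byte-identical.
* Basis variance normalization (dividing rows by the prior-implied
  marginal standard deviation) is implemented but off by default: the
  plain basis keeps the dense-oracle algebra transparent, and edge
  variance is not a concern on a closed sphere; it matters more on the
  bounded planar domain.

## Problem sizes

The shipped tests and the acceptance script exercise: icospheres at
subdivisions 2–4 (162–2562 vertices) with the default ~3.4k-node lattice,
20-seed contrasts of smooth versus white-noise maps, 20 conjunction-mask
task pairs, spin calibration with 200 runs × 200 rotations, 200 eigenmode
surrogates, and 40-frame 48×48 synthetic movies. These sizes were chosen
so each property is measured with enough replicates for its stated
threshold while the whole suite stays desk-scale; the statistics they
estimate are scale-stable (rank correlations, calibration rates), so
larger meshes change cost, not conclusions.

## Known limitations

* Stationary, isotropic covariance only; the discussion of spatially
  heterogeneous extensions is out of scope.
* Spherical projections only — no mid-thickness/folded-surface
  geodesics.
* The exact node counts and any internal renormalizations of the
  reference lattice construction are not reproduced (see above).
* HDF5 and CIFTI containers are not read; GIFTI (ASCII/Base64) and
  delimited text are the supported formats, with image series stored as
  text frame directories.
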