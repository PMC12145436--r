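# geokrig

Multiresolution lattice kriging of cortical surface maps: can the spatial
layout of one extreme of a brain activity map predict the other?

Task-contrast maps on the cortex show antagonistic systems — regions that
deactivate (task-negative, e.g. the default mode network) alongside
regions that activate (task-positive). `geokrig` tests a geometric
account of this antagonism: it thresholds a per-vertex z-score map to its
extreme tail (the bottom 25% by default), fits a spatial Gaussian-process
model to *only* those masked vertices, predicts the entire cortical
sphere, and measures how well unseen out-of-mask activity is recovered.
The package is aimed at researchers analysing surface-projected
neuroimaging maps (fMRI contrasts, and a planar variant for widefield
calcium imaging) who want a self-contained, testable implementation of
this analysis with fully synthetic ground-truth data.

## The model

A map value at spherical location $s$ is

$$y(s) = \mu + \textstyle\sum_{\ell,j} c_{\ell j}\,\phi_{\ell j}(s) + \varepsilon(s),$$

with compactly supported Wendland bases
$\phi(d) = (1-r)^6(35r^2+18r+3)/3$, $r = d/\theta_\ell$, on three nested
icosahedral lattices (162/642/2562 nodes, relative level weights
$\alpha = (1, 0.25, 0.01)$), great-circle distances $d$, and a sparse
spatial-autoregressive prior $Q_\ell = B_\ell^\top B_\ell$ on each
level's coefficients. The fit solves the penalized system
$(\Phi^\top\Phi + \lambda Q_\alpha)c = \Phi^\top(y - X\beta)$, with the
noise-to-process ratio $\lambda$ selected by profile maximum likelihood.
Around the core fit the package provides extreme-tail masking and
restricted out-of-mask evaluation, conjunction-mask task-specificity
tests, network-mask prediction with spin-rotation permutation nulls,
eigenmode-rotation ("eigenstrapping") surrogate maps, a planar
frame-by-frame pipeline for image time series with Fisher-z and
AR(1)-adjusted group inference, and seeded synthetic generators for every
input. See `vignettes/lattice-kriging-methods.Rmd` for the full account.

## Worked example

```r
library(geokrig)

mesh <- buildIcosphere(3)                       # 642-vertex sphere
map  <- synthMap(mesh, synthSpec(gamma = 3, nModes = 150,
                                 noiseSd = 0.1, seed = 42))
mask <- thresholdMask(map, 0.25, "low")         # bottom quartile
res  <- krigeFromMask(map, mask, latticeConfig(baseSubdivision = 1))
res
#> PredictionResult (sphere): 642 points, 160 in predictor mask
#>       task       restriction   n spearman_rho      mae
#>  synthetic              none 482    0.7112061 0.791454
#>  synthetic observed_positive 331    0.3431114 1.032817
#>  synthetic  min_distance_0.1 482    0.7112061 0.791454
```

The 160 most-negative vertices alone recover the rank order of the 482
unseen vertices at Spearman ρ = 0.71; restricted to genuinely positive
vertices (observed z > 0) the correlation is 0.34, so the model predicts
variation *within* the task-positive territory, not merely its location.
Accuracy decays with geodesic distance from the mask, the signature of
prediction driven by spatial autocorrelation:

```r
distanceProfile(res, nBins = 5)[, c("bin_mid", "n", "spearman_rho", "mae")]
#>   bin_mid   n spearman_rho   mae
#> 1   0.316 146        0.700 0.281
#> 2   0.671 127        0.193 0.685
#> 3   1.027 101       -0.286 1.109
#> 4   1.382  74       -0.433 1.311
#> 5   1.737  34       -0.122 1.306
```

(bin_mid in radians; mae in z-score units.) On a white-noise map the same
pipeline yields ρ ≈ 0, and eigenmode surrogates with matched
autocorrelation achieve accuracies bracketing the true map's — the two
controls that pin the effect on spatial autocorrelation rather than on
mask placement.

Other entry points: `pairwiseSpecificity()` (conjunction-mask
true-vs-alternative task test), `networkPrediction()` + `spinNull()`
(network masks against rotation nulls), `eigenstrap()` (surrogate maps),
`seriesAnalyze()` (planar calcium pipeline), and `runStage()` (a
config-driven dispatcher over all stages that writes metric CSVs plus a
JSON config echo; re-running from the echo reproduces outputs
byte-identically).

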