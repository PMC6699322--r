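---
title: "IVIM parameter mapping and hyperspectral lesion detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IVIM parameter mapping and hyperspectral lesion detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimhsi)
```

This vignette is the package's account of the science it implements: the
signal models, the detection machinery, the classification rules, the
synthetic phantom that stands in for patient data, and the numerical and
design decisions behind the defaults. It states no empirical result that
the test suite does not itself compute.

## 1. Signal models

A diffusion-weighted acquisition at weighting $b$ (s/mm²) attenuates the
baseline signal $S_0$. The monoexponential model

$$\ln(S_b/S_0) = -b\,\mathrm{ADC}$$

yields the apparent diffusion coefficient by log-linear least squares over
all b-values (`fit_adc()`), or from two points (`adc_two_point()`). ADC
conflates two transport processes: water diffusion in tissue and
pseudodiffusion from blood moving through randomly oriented capillaries.
The biexponential intravoxel-incoherent-motion (IVIM) model separates them:

$$S_b/S_0 = (1-\mathrm{PF})\,e^{-bD} + \mathrm{PF}\,e^{-bD^*},$$

with $D$ the pure diffusion coefficient, $D^*$ the pseudodiffusion
coefficient and $\mathrm{PF}$ the perfusion fraction. All diffusivities in
this package are expressed in $10^{-3}$ mm²/s, so typical tissue values
are order 1, and the b-value schedule is the 12-point breast protocol
`default_bvalues()` = 0, 15, 30, 45, 60, 100, 250, 400, 550, 700, 850,
1000 s/mm² — dense at low b where the pseudodiffusion term lives.

Because the pseudodiffusion term decays quickly ($e^{-bD^*} < 0.1$ beyond
$b \approx 250$ for $D^* \approx 9$), the classic *segmented* estimator
fits $\ln(S_b/S_0)$ linearly on the high-b points ($b \ge b_{split}$,
default 250), reads $D$ from the slope and $\mathrm{PF}$ from the
intercept deficit $1 - e^{a}$, then finds $D^*$ by a bounded 1-D
least-squares search on the full curve. The *full* method refines all
three parameters by bounded Levenberg–Marquardt (through `minpack.lm`)
started from the segmented solution, and keeps whichever of the two has
the smaller residual sum of squares — refinement can never worsen the
objective.

**Why `method = "full"` is the default.** The segmented estimator is exact
only when the pseudodiffusion term has truly died above $b_{split}$. For
cyst-like tissue ($D^* \approx 4.6$) the term is still 30% of its initial
value at $b = 250$, and the segmented $D$ is biased upward by over 20%
even on noiseless input. The full fit recovers noiseless parameters to
machine precision for every tissue class in the default table (the test
suite asserts 1% but achieves ~1e-14).

**Fit bounds.** $D \in [0.05, 3.5]$, $D^* \in [1, 60]$ ($10^{-3}$ mm²/s),
$\mathrm{PF} \in [0, 0.6]$ — generous brackets around the breast-tissue
ranges. Pixels whose series violates the preconditions (a nonpositive
signal) are flagged invalid in the maps, never silently zeroed, and are
excluded from downstream statistics.

**"Slope".** The decay-steepness summary reported alongside the model
parameters is defined here as the least-squares slope of the normalized
signal $S_b/S_0$ against $b/1000$: dimensionless, order 0.1–1, negative
for decaying signal. A log-signal variant is available
(`fit_slope(log_signal = TRUE)`). This is a documented convention — the
quantity has no standard definition — chosen so that typical lesion
values land near the −0.25 range familiar from clinical summary tables.

## 2. Why the maps are denoised before fitting

Per-pixel biexponential fitting is ill-conditioned at clinical SNR. A
Cramér–Rao computation at the package's study conditions (12-point
schedule, SNR 50 at the normal-tissue baseline) gives best-case unbiased
per-pixel standard deviations of $\sigma_D \approx 0.26$ for normal tissue
and $\approx 0.61$ for cyst — larger than the distances between the class
means being discriminated. No pixelwise estimator, however clever, can
classify reliably at that information level; spatial pooling is not an
optimization but a necessity.

`compute_param_maps()` therefore applies a small masked Gaussian smoothing
(`presmooth = 0.8` pixels) to every b-volume before fitting. The kernel is
renormalized over the fit mask, which has two consequences worth stating
precisely: values outside the mask (air, or tissue excluded by the user)
never leak in, and a constant in-mask signal is reproduced *exactly* — so
on noiseless single-tissue data the denoising is a no-op and the fits stay
exact. The cost is in-plane resolution: parameter values within roughly
two pixels of a tissue boundary are mixtures. Set `presmooth = 0` for
strictly per-pixel behavior.

The same argument drives the classification granularity in section 5.

## 3. Band expansion

Treating the 12 b-value images as spectral bands gives a multispectral
cube too shallow for subpixel detection machinery, so the band expansion
process generates correlated bands: elementwise squares $B_l^2$, pairwise
products $B_kB_l$ ($k<l$), optionally third-order terms ($B_l^3$,
$B_k^2B_l$ with $k \ne l$, $B_kB_lB_m$ with $k<l<m$) and square-root/log
stretches. At the default (order 2, no stretches) a 12-band cube becomes
$12 + 12 + \binom{12}{2} = 90$ bands. Band order is fixed by a manifest
contract so every generated band's provenance is machine-readable.
Variance normalization (dividing each correlated band by the product of
its source bands' standard deviations, with multiplicity) is implemented
but off by default — the 90-band configuration is usable either way, and
detection through CEM is invariant to per-band rescaling only jointly with
the signature, so the un-normalized cube is the simpler default. The log
stretch uses $\log(1+x)$ by default since the raw bands contain exact
zeros in air.

## 4. Detection: ATGP, SAM, CEM and its kernel version

**ATGP.** The automatic target generation process picks the brightest
pixel (maximum spectral norm) first, then repeatedly projects every pixel
onto the orthogonal complement of the targets found so far
($P = I - U(U^\top U)^{-1}U^\top$) and takes the largest residual. It
stops at `n_targets` (default 5), at an optional angle threshold between
consecutive targets, or when the residual image is numerically zero (all
spectra spanned — on noiseless four-tissue phantoms this happens after
four targets). The implementation is oracle-tested against per-iteration
exhaustive search.

**SAM.** Targets are single pixels; the spectral angle mapper
$\theta(s,t) = \arccos\!\big(s^\top t / \lVert s\rVert\,\lVert t\rVert\big)$
collects all pixels within an angular radius of each target, and their
mean is the desired signature $d$ for the matched filter. The pipeline
default radius (0.05 rad) was calibrated once on a denoised expanded
phantom cube, where the within-tissue angular spread is ~0.02–0.03 rad
and the smallest between-tissue signature angle is ~0.08 rad; it is a
configuration knob, not a law.

**CEM.** Constrained energy minimization finds the filter
$w = R^{-1}d / (d^\top R^{-1}d)$ minimizing the average output energy over
the image subject to $w^\top d = 1$, with $R$ the sample autocorrelation
matrix of the pixel spectra. A ridge ($10^{-6}\,\mathrm{tr}(R)/M$ by
default, scale-free) keeps the solve stable on correlated band sets.

**KCEM.** The kernelized form evaluates the same quadratic form in the
feature space of a positive-definite kernel, using a background sample of
up to 2000 pixels (seeded subsample beyond that). With Gram matrix $K$,
ridge $\rho$ and kernel columns $k_d$, $k_r$, the response is

$$\delta(r) = \frac{k(d,r) - k_d^\top (K + n\rho I)^{-1} k_r}
                   {k(d,d) - k_d^\top (K + n\rho I)^{-1} k_d},$$

the regularized feature-space quadratic form written through the Woodbury
identity. Two properties anchor the implementation: $\delta(d) = 1$
exactly for any kernel, and with the linear kernel and the full image as
background it reproduces CEM with the same ridge to floating-point
accuracy (the test suite asserts $10^{-6}$). As the RBF bandwidth grows,
the feature map degenerates to a constant plus the *centered* identity, so
the response ranking converges to that of CEM on mean-centered data — a
property test checks exactly this limit.

**Why the pipeline's default kernel is linear.** Kernel CEM is not
linear in its argument, so the unit-response constraint holds only at the
exact signature $d$ — a virtual point (the mean of the training set) that
no real pixel occupies. With an RBF kernel at tissue-scale bandwidths the
detector suppresses the actual pixels of its own tissue almost as strongly
as the background, and the thresholded support covers a fraction of the
lesion. The linear kernel keeps CEM's property that the *mean* response
over the training set is exactly 1, which makes the thresholded support
cover the targeted tissue essentially completely. The RBF version remains
available for experimentation with explicit `sigma` and `ridge`.

## 5. Thresholding and region-level classification

Detection maps are quantized to 256 gray levels (linear min–max) and
thresholded globally. The default criterion builds the symmetric
gray-level co-occurrence matrix over horizontal and vertical 4-neighbor
adjacencies and, for each candidate threshold, sums the Shannon entropies
of the background–background and foreground–foreground quadrants, each
renormalized to a distribution; the argmax (smallest level on ties, the
more inclusive choice) is the threshold and foreground is *strictly
above* it. Otsu's between-class-variance criterion is the baseline
comparator. Both are implemented exhaustively enough to be oracle-tested
against brute-force recomputation; the entropy criterion depends only on
co-occurrence counts and is therefore invariant under any increasing
relabeling of the levels, while Otsu — which uses the level values — is
invariant only under positive affine relabelings.

**Classification.** Every detector's thresholded support is summarized by
the mean $D$ and $\mathrm{PF}$ of its valid pixels and classified *once*
through the decision tree; pixels covered by several detectors take the
class of the highest-response one; pixels covered by none are normal
tissue; invalid fits are "other". The tree is D-first —
$D < 1.035$ → tumor; else $D \ge 1.365$ and $\mathrm{PF} \ge 0.361$ →
cyst; else normal — with every cut the midpoint of the two adjacent class
means it separates (`derive_thresholds()`), and $D$ given the primary role
because it carries the largest and most reliable class separation. Tumor
pixels are then split per pixel into a central ($D \le 0.845$, ties to
central) and peripheral zone, only inside detected lesion support; a
median-based split is available. Region-level voting is the
histogram-analysis reading of the clinical workflow — lesions are detected
first, then characterized by the parameter statistics of the detected
region — and it is forced by the Cramér–Rao argument of section 2: per-pixel
tree decisions at SNR 50 cannot reach acceptable accuracy for any
estimator, while region means over ~100 pixels can.

`classify_pixel()`, `classify_map()` and `split_central_peripheral()`
expose the per-pixel semantics directly for users who want the raw tree.

Histogram statistics use the Fisher–Pearson moment coefficients ($g_1$,
and excess kurtosis $g_2$ with the normal distribution at 0), undefined
statistics are `NA` rather than errors, and case summaries average per
slice and class with the overall row the arithmetic mean of per-slice
means.

## 6. Breast-region extraction

A slice is segmented by: 3×3 Laplacian sharpening (an offset-preserving
high-pass, so the mask is invariant to constant intensity shifts), Sobel
gradient (kept as a contour diagnostic), optional suppression of a
vertical midline strip (a stand-in for hit-or-miss sternum removal on
bilateral acquisitions — off by default since the phantom has no sternum),
Otsu binarization of the *sharpened intensity* image (binarizing the
gradient magnitude would segment the boundary, not the region), opening
with a 2×2 structuring element to detach thin bridges, and retention of
the largest 8-connected component. The 2×2 opening and the 8-connected
labeling are implemented in the package because the structuring element is
even-sized (off-center anchors need shift-consistent handling) and the
available labeling routines use 4-connectivity. A simple integer-shift
alignment (`align_cube()`, normalized cross-correlation over ±5 pixels)
covers respiration-type drift between b-volumes; deformable registration
and bias-field correction are out of scope, though the phantom can
generate a polynomial bias field to exercise robustness.

## 7. The phantom: what it emulates and what it does not

`generate_phantom()` rasterizes an elliptical body of normal tissue
containing elliptical lesions (pixel-center convention), assigns each
tissue the biexponential decay of its parameter table, and corrupts the
ideal magnitude signal with Rician noise
($\sqrt{(S+n_1)^2 + n_2^2}$, $n_i \sim N(0,\sigma^2)$ independent per
pixel and b-volume) and an optional low-order polynomial bias field. The
default tissue table is the package's reference parameter set — central
tumor $D=0.76$, $D^*=9.38$, $\mathrm{PF}=0.215$; peripheral tumor 0.93 /
9.02 / 0.253; cyst 1.59 / 4.62 / 0.411; normal 1.14 / 5.98 / 0.311 — with
baselines $S_0$ = 110 / 110 / 130 / 100 (air 0), a convention chosen to
give lesions the mild T2-shine-through brightness seen on real DWI; the
acquisition does not pin lesion $S_0$, so these are conventions, not
facts. The reference phantom is 64×64×3 with a concentric two-zone tumor
(nested ellipses; strict nesting of lesions is allowed, partial overlap of
different tissues is an error) and a separate cyst. "SNR 50" in the tests
means $\sigma = 2$ against the normal-tissue baseline of 100.

Everything is a pure function of the spec including its seed, and noise is
drawn in a temporary RNG state so library calls never disturb the
caller's stream.

What the phantom deliberately omits: partial-volume mixing at boundaries,
$T_1/T_2$ relaxation, k-space artifacts, coil profiles beyond the
polynomial bias, anatomical texture within tissues, and inter-volume
motion (available only through `align_cube()` testing). Passing tests on
the phantom therefore demonstrate algorithmic correctness under the stated
noise model — not clinical performance; parameters within a tissue are
spatially constant, which flatters any region-averaging step relative to
heterogeneous real lesions.

## 8. Problem sizes, runtimes and degenerate inputs

The validation suite runs the full pipeline on 64×64×3 phantoms
(~7300 body pixels, 90 expanded bands, a ≤2000-pixel detector background)
— sizes chosen so the complete suite, including four single-tissue
recovery phantoms and two end-to-end runs, completes in a few minutes on
one core. Degenerate inputs are rejected early with named errors: constant
images for thresholding, all-zero cubes for ATGP, empty fit masks,
rank-deficient projector bases, singular correlation matrices without a
ridge, b-schedules without a zero. Ties are broken deterministically
(smaller threshold, first maximum, central zone), and every stochastic
stage takes an explicit seed, so identical configuration reproduces
identical artifacts bit for bit.

## 9. Known limitations

- The tree thresholds default to midpoints of the reference class means;
  on real cohorts they should be re-derived from `derive_thresholds()`
  with cohort statistics.
- The segmented estimator's $b_{split} = 250$ convention is appropriate
  for tumor-like $D^*$ but not for cyst-like $D^*$; the full fit hides
  this only as long as its bounded optimization converges.
- Detection assumes lesions are spectrally compact and distinct from the
  background; diffuse or infiltrative disease violates the SAM-radius
  assumption.
- The entropy thresholder can cut inside a lesion's response distribution
  when the map is strongly multimodal; a manual override
  (`manual_threshold`) exists for exactly the slice-by-slice adjustment
  that automatic thresholding sometimes needs.
- Zone splitting uses a fixed $D$ cut; truly necrotic cores or rim
  enhancement patterns may need the median variant or a cohort-derived
  cut.
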