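# ivimhsi

Intravoxel incoherent motion (IVIM) analysis of multi-b-value
diffusion-weighted breast MRI, combined with hyperspectral target-detection
techniques for automatic lesion detection and tissue classification.

## The problem and the approach

Diffusion-weighted imaging acquired at several diffusion weightings
b (s/mm²) probes both tissue water diffusion and capillary pseudodiffusion.
The monoexponential model `S_b / S_0 = exp(-b·ADC)` mixes the two; the
biexponential IVIM model separates them:

```
S_b / S_0 = (1 − PF)·exp(−b·D) + PF·exp(−b·D*)
```

with D the pure diffusion coefficient, D* the pseudodiffusion coefficient
(both in 10⁻³ mm²/s here) and PF the perfusion fraction. Malignant breast
tissue has low D; cysts have high D and high PF — so per-pixel maps of
(ADC, slope, D, D*, PF) carry enough contrast to separate central tumor,
peripheral tumor, cyst and normal tissue with a simple threshold decision
tree.

The package treats the 12-b-value stack as a multispectral cube and chains:

1. **Breast segmentation** — high-pass enhancement, Otsu binarization,
   2×2 morphological opening, largest 8-connected component
   (`extract_breast_region()`).
2. **Parameter mapping** — masked Gaussian denoising, then per-pixel
   log-linear (ADC, slope) and bounded biexponential (D, D*, PF) fits
   (`compute_param_maps()`, `fit_ivim()`).
3. **Band expansion (BEP)** — second-order auto- and cross-correlation
   band images grow the 12-band cube to 90 bands (`expand_bands()`).
4. **Unsupervised detection** — ATGP picks maximally orthogonal target
   pixels (`atgp()`), SAM collects spectrally similar training samples
   (`select_training_samples()`), and constrained energy minimization
   (`cem()` / `kcem()`) produces one real-valued detection map per target.
5. **Thresholding** — co-occurrence local-entropy (or Otsu) thresholding
   converts detection maps to binary lesion masks
   (`local_entropy_threshold()`, `otsu_threshold()`).
6. **Classification** — each detected region is classified once through the
   D-first decision tree on its mean parameters; tumor pixels are split
   into central/peripheral zones; per-case summary tables and histogram
   statistics (mean, median, skewness, excess kurtosis) report the result
   (`classify_detected()`, `histogram_stats()`, `summarize_case()`).

A seeded digital phantom (`generate_phantom()`, `reference_phantom_spec()`)
with known per-pixel tissue labels and parameters makes the whole chain
testable end to end without patient data; `run_pipeline()` chains all
stages.

## Worked example

Per-slice lesion parameter means for one malignant case ship with the
package; `case_average()` appends the case-level row:

```r
library(ivimhsi)
case_average(example_case_slices())
#> # A tibble: 14 × 6
#>    slice     adc  slope     d dstar pf_percent
#>    <chr>   <dbl>  <dbl> <dbl> <dbl>      <dbl>
#>  1 10       1.34 -0.29  0.743  9.21       26
#> ...
#> 14 average  1.23 -0.252 0.731  9.83       22.5
```

The average row reads: lesion ADC 1.23 and D 0.731 (10⁻³ mm²/s) — D well
below ADC because perfusion inflates the monoexponential estimate — with a
perfusion fraction around 22%.

A single biexponential fit recovers its generating parameters exactly on
clean input:

```r
b <- default_bvalues()                      # 0, 15, ..., 1000 s/mm^2
s <- 110 * biexp_signal(0.93, 9.02, 0.253, b)
fit_ivim(s, b)
#> <ivim_fit:full> ADC 1.211  D 0.930  D* 9.02  PF 0.253  slope -0.699  (||r|| 1.67e-16)
```

And the full pipeline on the noiseless reference phantom returns per-class
summaries that match the generating tissue table (D 0.76 / 0.93 / 1.59 /
1.14 for central tumor / peripheral tumor / cyst / normal):

```r
ph  <- generate_phantom(reference_phantom_spec())
res <- run_pipeline(ph$cube, pipeline_config(seed = 1))
dplyr::filter(res$summary, slice == "average")
#> # A tibble: 4 × 8
#>   slice   class            n_pixels   adc  slope     d dstar    pf
#> 1 average cyst                  381  2.09 -0.908 1.56   4.67 0.408
#> 2 average normal               6222  1.53 -0.797 1.14   6.00 0.311
#> 3 average tumor_central         159  1.02 -0.635 0.783  9.31 0.221
#> 4 average tumor_peripheral      510  1.23 -0.704 0.940  8.74 0.255
```

`autoplot(res$labels)` draws the label map (central tumor red, peripheral
green), `autoplot(res$detection)` the merged detection map, and
`plot_class_boxplots(res$labels, res$maps, "d")` the per-class parameter
distributions.

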