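# savehsi

Calibrated conversion of white-light endoscopic RGB frames into 401-band
hyperspectral reflectance cubes, with simulated narrow-band imaging and the
full evaluation toolchain around it.

## Why

White-light imaging (WLI) is the workhorse of endoscopy but carries little
spectral contrast: early lesions that differ mainly in haemoglobin content
are easy to miss. Narrow-band imaging (NBI) fixes that optically by
illuminating tissue at the 415 nm and 540 nm haemoglobin absorption bands —
at the cost of dedicated filter hardware. The computational alternative
implemented here reconstructs a reflectance spectrum *per pixel* from an
ordinary RGB frame, producing an H × W × 401 hyperspectral cube (380–780 nm
at 1 nm) from which narrow-band views, band selections and downstream
classifiers can all be derived. The intended users are researchers working
on spectral endoscopy, spectral reconstruction, or the evaluation of
imaging modalities for gastrointestinal diagnosis.

## The method

The pipeline has two fitted stages, both trained on a 24-patch Macbeth-style
colour chart:

1. **Camera calibration.** Measured sRGB values are linearised (piecewise
   sRGB transfer), mapped to CIE XYZ, expanded in the full cubic monomial
   basis over (X, Y, Z) — 20 terms `V = (1, X, Y, Z, X², XY, …, Z³)`, whose
   constant slot carries the dark offset — and regressed onto the chart's
   target XYZ by minimum-norm least squares:
   `XYZ_corrected = C · V(XYZ_camera)`. Quality is scored with CIEDE2000.

2. **Spectral reconstruction.** The chart's reference spectra are
   mean-centred and decomposed by PCA; the smallest number k of components
   whose cumulative explained variance reaches 99 % is kept, and a
   regression maps expanded corrected XYZ to the component scores:

   `R̂(λ) = mean(λ) + Bᵀ (W · V(XYZ_corrected))`

   with B the k × 401 orthonormal basis and W the k × 20 score map.

From a cube, `select_bands()` ranks wavelengths by variance-weighted squared
PCA loadings, and `simulate_nbi()` renders a false-colour narrow-band image
from Gaussian 30 nm-FWHM bands at 415/540 nm. Evaluation utilities cover
SSIM/PSNR/spectral RMSE, confusion-matrix metrics with macro and
support-weighted aggregation (including the audit identity
`accuracy = Σ n_c·recall_c / N`), two-factor ANOVA without replication, and
a reference softmax classifier trained with moment-based gradient updates.
Seeded generators (charts, cameras, vascular phantoms, a 2400-frame
class-balanced dataset) make everything testable without external data.

## Worked example

A synthetic endoscope with a mildly nonlinear XYZ response images a seeded
chart; we calibrate, fit the reconstruction, convert a vascular phantom
frame and simulate NBI:

```r
library(savehsi)

distort <- function(xyz) { s <- xyz / 100
  100 * cbind(0.92 * s[,1] + 0.06 * s[,2]^2,
              1.05 * s[,2] - 0.04 * s[,1] * s[,3],
              0.97 * s[,3] + 0.05 * s[,3]^3) }
cam   <- synthetic_camera(distortion = distort)
chart <- image_chart(make_chart(seed = 1), cam)
calib <- fit_correction(chart, chart_camera_xyz(chart))
#> Camera calibration: 20 polynomial terms
#>   chart RMSE (XYZ): 1.9330 -> 0.0000
#>   mean Delta-E00 : 12.1476 -> 0.0000
recon <- fit_reconstruction(chart, calib)
#> Spectral reconstruction model: 3 principal component(s), 100.000% variance retained
#>   training spectral RMSE: mean 2.44e-08, max 5.95e-08

phantom <- make_phantom(seed = 1, size = c(64, 64), class = "cancer", cam = cam)
cube <- convert_image(recon, calib, phantom$frame)
sqrt(mean((cube$data - phantom$cube$data)^2))   # vs ground truth: 2.77e-07

select_bands(recon, n_bands = 5)
#>   index wavelength_nm      score
#> 1    27           406 0.06303934
#> 2    37           416 0.07855130
#> 3    47           426 0.06201927
#> 4   149           528 0.03909820
#> 5   159           538 0.04469558
```

What the numbers mean: the uncalibrated camera mis-renders the chart by a
clearly visible mean ΔE00 of 12.1, which the cubic correction removes
entirely (the distortion lies inside the model family). Three principal
components retain 100 % of the chart's spectral variance, so the
reconstructed cube matches the phantom's ground-truth spectra to numerical
precision. Band selection lands on 406–426 nm and 528–538 nm — the
haemoglobin absorption dips built into the synthetic tissue family, and the
physical motivation for NBI's 415/540 nm filters. Simulating NBI on this
cube darkens vessel pixels to about 95 % of the background luminance:

```r
nbi <- simulate_nbi(cube)
lum <- 0.2126*nbi[,,1] + 0.7152*nbi[,,2] + 0.0722*nbi[,,3]
mean(lum[phantom$vessel_mask]) / mean(lum[!phantom$vessel_mask])
#> [1] 0.946
```

See `vignettes/spectrum-aided-vision.Rmd` for the full account of the
model, its assumptions, parameter defaults, and what the synthetic world
does and does not emulate.

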