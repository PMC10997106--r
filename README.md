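# emccdpia

Unsupervised, probabilistic thresholding and segmentation of fluorescence
microscopy images recorded with electron-multiplying CCD (EMCCD) cameras —
for microscopists and image-analysis pipelines that need pixel
classification with *known, a priori* error rates instead of a tuned
threshold.

## The idea

The stored count of an EMCCD pixel is the result of a fully characterised
physical chain: Poisson photoelectron arrivals (parameter λ), Gamma
electron multiplication (gain *g*), Gaussian readout noise (scale *r*,
conversion factor *f*, offset Δ) and integer rounding. Its characteristic
function is available in closed form,

    φ(p) = exp(−p²r²/2 + ipΔ) · exp{λ(1/(1 − ip·g/f) − 1)} · sinc(p/2),

so the exact count distribution of a *background* pixel is computable, not
assumed. The package builds on that:

1. **Calibration** (`calibrate_chip`): the chip constants {g, f, r, Δ} from
   mean–variance line fits to image stacks at several illumination levels,
   with and without gain (slopes 2g/f and 1/f), with subsampling
   uncertainty.
2. **Background estimation** (`fit_background`): λ_bg from an image that
   *contains signal*, by truncated maximum likelihood restricted to counts
   below a truncation point, scanned over truncations and gated by a χ²
   goodness-of-fit test — no model for the signal is ever assumed.
3. **Thresholding** (`threshold_from_pvalue`, `apriori_rates`): a requested
   background false-positive probability (e.g. 0.01) is inverted through
   the fitted CDF into a count threshold, and the five confusion-matrix
   rates (FPR, FNR, ACC, FDR, FOR) are predicted *before ever seeing ground
   truth*, via a CDF-slope estimate of the background/signal pixel split.
4. **Segmentation** (`clean_mask`, `score_regions`): connected components,
   a scale-free gap rule that separates noise-sized regions from objects,
   and a per-region p-value that its summed counts could be pure
   background.
5. **Pipeline** (`run_pipeline`): 64×64 tiling for slowly varying
   illumination, per-tile fits and thresholds, stitched mask, report.

A forward simulator (`draw_counts`, `render_scene`,
`make_calibration_stacks`) generates scenes and calibration stacks with
ground truth through the same physical chain, and doubles as the
Monte-Carlo oracle for the numerics.

## Worked example

```r
library(emccdpia)
chip <- chip_params(g = 18.82, f = 35.17, r = 1.45, delta = 26.37)

# a synthetic bead scene with ground truth: 256x256, background 20
# photoelectrons/pixel, beads at SNR 3 covering ~15% of the image
sc <- random_bead_scene(c(256, 256), lam_bg = 20, snr = 3, radius = 5,
                        signal_fraction = 0.15, chip = chip, seed = 7)

fit_background(as.vector(sc$image), chip)
#> Truncated maximum-likelihood background fit
#>   lambda_bg     = 20.1990 photoelectrons/pixel
#>   truncation    = 40 counts (largest passing GoF at p >= 0.01)
#>   pixels        = 65536, scan of 34 truncation points

res <- run_pipeline(sc$image, chip)   # tiled: fit -> threshold -> segment
res
#> Photophysical image analysis result
#>   tiles          = 16 (0 failed goodness-of-fit)
#>   lambda_bg      : median 20.491 (range 20.192 - 21.081)
#>   white fraction = 0.0719
#>   regions        = 103
#>   aggregated a priori rates (pixel-weighted over passing tiles):
#>     FPR     FNR     ACC     FDR     FOR
#> 0.00757 0.38233 0.94837 0.10051 0.04878

round(evaluate_vs_truth(res$mask, sc$truth), 4)  # ground truth comparison
#>    FPR    FNR    ACC    FDR    FOR
#> 0.0052 0.5515 0.9126 0.0620 0.0893
```

Reading the numbers: the background strength is recovered within 1% from an
image that is 15% signal; the observed false-positive rate (0.0052) is
below the requested 0.01, as designed — the discrete threshold always
undershoots the nominal tail; at SNR 3 about half of each bead's pixels
fall below the threshold (FNR ≈ 0.55), which the a priori prediction
anticipates (0.38 tile-aggregated, 0.49 for a whole-image fit). The
per-region p-values in `region_table(res$segmentation)` flag every bead as
incompatible with background (p_seg ≪ 0.01).

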