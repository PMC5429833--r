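# phasorMRI

Model-free, non-iterative analysis of multi-component quantitative MRI by
**phasor representation**, for MR physicists and image analysts working
with multi-echo T2 relaxometry, multi-b-value diffusion imaging, or MR
spectroscopic imaging (MRSI).

Every pixel of a qMRI stack carries a curve along a non-spatial axis — a
spin-echo decay, a diffusion attenuation versus b-value, or an NMR
spectrum. phasorMRI normalizes each curve and takes the first harmonic of
its discrete Fourier transform,

    G = Σₖ sₖ e^{+i2πk/n} / Σₖ sₖ ,        k = 0 … n−1,

plotting each pixel as the point (Re G, Im G) in the *phasor plot*. The
geometry of this plane does all the work:

* **Mono-exponential decays** lie on a reference locus — the universal
  semicircle |G − (½, 0)| = ½ for dense, long sampling, or a *deviated*
  curve for truncated/undersampled schemes, computed exactly per axis.
* **Mixtures** are integral-fraction-weighted vector sums: two components
  span a chord, three a triangle. Barycentric (triangle-area) ratios
  recover the fractions without iteration.
* **The phasor phase** is strictly monotone in the decay constant, so
  each pixel's phase inverts to an average T2 (ms) or ADC (10⁻⁹ m²/s).
* **Spectra** use the same transform with a clockwise convention: peak
  position becomes angle, linewidth becomes radius — so polygonal or
  sector ROIs in the plot segment tissue by spectral content, and segment
  masks back-project onto the image.

The package provides the full toolchain: stack I/O (NIfTI-1, multi-page
TIFF, CSV/JSON axes), phasor fields with spatial mean filtering and
intensity thresholding, reference-locus calibration and inversion
(including undersampled echo subsets), 2/3-component unmixing, total
least-squares endmember extrapolation, phasor-space segmentation with
back-projection, synthetic phantoms with Rician noise and full ground
truth, a Levenberg-Marquardt-style mono/bi-exponential fitting baseline,
and a CLI (`simulate`, `t2-map`, `adc-map`, `unmix`, `segment`,
`spectral-phasor`, `compare-fit`).

## Worked example

A stem-like T2 phantom (64 echoes, 7.23 ms spacing, four mono-exponential
reference tubes at 105/130 ms around multi-exponential tissue rings),
with Rician noise at SNR 100:

```r
library(phasorMRI)

gen   <- generate_stack(phantom_stem(noise = list(type = "rician", snr = 100),
                                     seed = 1))
field <- compute_phasor_field(gen$stack, mean_filter_radius = 1,
                              threshold = 0.25)
locus <- build_reference_locus(gen$stack$axis)
map   <- tau_map(field, locus)
map
#> <param_map> 128 x 128, 11687 valid pixels, median 78.07 ms
median(map$value[gen$truth$labels == 1], na.rm = TRUE)  # tube, true 105 ms
#> [1] 103.5
median(map$value[gen$truth$labels == 2], na.rm = TRUE)  # tube, true 130 ms
#> [1] 129.0
median(map$value[gen$truth$labels == 5], na.rm = TRUE)  # cortex, true 80 ms
#> [1] 78.1
```

The small downward offsets are the Rician magnitude floor at finite SNR,
not estimator error — noiseless round trips recover τ to < 0.1% (see the
test suite). `plot_phasor(field, locus)` draws the standard 2D-histogram
phasor plot with the reference locus overlaid.

Diffusion works identically with b-values as the axis; endmember ADCs of
a partial-volume cloud are read off by extrapolating its principal axis
to the locus:

```r
gen <- generate_stack(phantom_diffusion(noise = list(type = "rician",
                                                     snr = 60), seed = 2))
f   <- compute_phasor_field(gen$stack, mean_filter_radius = 1)
loc <- build_reference_locus(gen$stack$axis)
m   <- tau_map(f, loc)
median(m$value[gen$truth$labels == 1], na.rm = TRUE)  # tissue, true 0.65
#> [1] 0.66
sel <- gen$truth$labels == 3 & f$valid                # mixed strip
ex  <- extrapolate_cloud_to_locus(cbind(f$re[sel], f$im[sel]), loc)
tau_to_adc(ex$tau)                                    # true 3.1 and 0.65
#> [1] 3.15 0.65
```

The same field can be segmented by regions drawn in phasor space
(`phasor_roi()` / `roi_sector()`, JSON-serializable via `write_rois()`),
with `segment_phasors()`, per-segment mean decay curves
(`mean_signal_per_segment()`), and color back-projection
(`backproject()`).

From the shell, the whole workflow runs through the CLI:

```sh
Rscript exec/phasormri simulate --phantom stem --out work --seed 1
Rscript exec/phasormri t2-map --in work/stack.nii.gz --axis work/axis.csv \
        --out work/map --subset 4,20,36,52     # 4-echo undersampled analysis
```

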