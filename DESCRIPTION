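Package: phasorMRI
Title: Phasor Representation for Multi-Component Quantitative MRI
Version: 1.0.0
Authors@R:
    person("Willem", "de Graaf", email = "w.degraaf@example.org",
           role = c("aut", "cre"))
Description: Model-free analysis of quantitative MRI stacks by phasor
    representation. Per-pixel multi-echo T2 decays, multi-b-value diffusion
    decays and MR spectroscopic imaging (MRSI) spectra are normalized and
    Fourier transformed; the first harmonic is plotted as a phasor. The
    package builds mono-exponential reference loci (the phasor semicircle,
    including its deviated form under truncated or undersampled sampling
    schemes), inverts phasor phase to average T2 or apparent diffusion
    coefficient maps, unmixes two or three components by barycentric
    (triangle-area) geometry, estimates component endmembers by total
    least-squares extrapolation of phasor clouds to the reference locus,
    segments pixels by polygonal regions drawn in phasor space with
    back-projection to color-coded image masks, and simulates multi-exponential
    phantoms with Rician noise. Mono- and bi-exponential nonlinear
    least-squares fitting is included as an independent baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
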