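Package: orthofuse
Title: Fourier-Domain Fusion of Orthogonal Light-Sheet Microscopy Views
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines pairs of 3D fluorescence image stacks recorded from
    orientations tilted by roughly 90 degrees into a single volume with
    near-isotropic resolution. The tilted stack is brought onto the grid of
    the reference stack by a tilt-initialized rigid registration, the two
    views are mutually masked and percentile-normalized, and their 3D
    Fourier spectra are merged by keeping the larger magnitude at every
    frequency together with the phase of the complex sum. Also provides
    FFT-based stripe-artifact removal, contrast-limited adaptive histogram
    equalization and unsharp masking, resolution metrics (FWHM, USAF-1951
    bar widths), region-of-interest intensity statistics, and a synthetic
    light-sheet acquisition simulator (anisotropic Gaussian PSF,
    illumination stripes, shot and read noise) for end-to-end testing
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
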