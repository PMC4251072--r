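Package: retfdc
Title: Zone-Specific Circular Fractal Dimension of Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the complexity of the retinal vasculature in
    optic-disc-centred fundus photographs with a zone-specific circular
    fractal dimension (FDC): the image is enhanced with a bank of 2D Gabor
    wavelet matched filters, converted to a greyscale vessel-likelihood map
    by a two-class Gaussian mixture, scanned along concentric circles around
    the optic disc, and Higuchi's one-dimensional fractal dimension of each
    circular intensity profile is averaged within concentric zones A, B and
    C (0-0.5, 0.5-1 and 1-1.5 optic-disc diameters from the disc margin).
    Includes spectral (Fourier) and box-counting fractal dimensions as
    comparators, tie-corrected Kruskal-Wallis and Mann-Whitney case/control
    statistics with Hodges-Lehmann confidence intervals, and a synthetic
    fundus-image generator with a controllable vessel-complexity parameter
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    mclust,
    EBImage,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
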