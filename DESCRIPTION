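Package: meister
Title: Deep-Learning-Enhanced FT-ICR Mass Spectrometry Imaging:
    Simulation, Transient Reconstruction, Registration and
    Single-Cell Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput Fourier-transform ion cyclotron
    resonance (FT-ICR) mass spectrometry imaging (MSI). Simulates
    ground-truthed MSI datasets from a damped-sinusoid transient signal
    model with isotopic fine structure and H/Na/K adducts over spatial
    phantoms; reconstructs high-mass-resolution spectra from short
    transient prefixes with a deep autoencoder plus latent regressor
    (and a linear-subspace baseline); provides frequency-domain
    processing (peak picking, ppm binning, TIC normalization, processed
    mode imzML input/output); registers MSI sections to anatomical
    references via parametric UMAP feature images with affine and
    B-spline stages; and integrates single-cell mass spectra with
    tissue images through non-negative dictionary learning and
    union-of-subspaces fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    igraph,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
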