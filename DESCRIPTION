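Package: qsmdi
Title: Dipole Inversion for Quantitative Susceptibility Mapping with
    Frequency-Fidelity Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the dipole-inversion step of quantitative
    susceptibility mapping (QSM). Implements the discrete magnetostatic
    forward model (dipole kernel in k-space), threshold-based decomposition
    of the tissue field into high- and low-fidelity spectral components,
    truncated k-space division (TKD) as a classical baseline, a multichannel
    3D encoder-decoder network trained with a composite physics/L1/gradient
    loss, synthetic susceptibility phantoms with an analytic sphere oracle,
    a patch extraction and rotation-augmentation pipeline, and the standard
    reconstruction quality metrics (HFEN, NRMSE, PSNR, SSIM, ROI
    regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
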