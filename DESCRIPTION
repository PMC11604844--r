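Package: xecs
Title: Compressed-Sensing Reconstruction and Gas-Exchange Mapping for
    Dissolved-Phase 129Xe Lung MRI
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for hyperpolarized 129Xe dissolved-phase gas-exchange
    lung MRI reconstruction, exercisable entirely on synthetic digital
    lung phantoms. Implements 3D radial spiral-phyllotaxis trajectories
    with retrospective undersampling, a multi-echo spectroscopic k-space
    simulator for the three 129Xe resonances (gas, alveolar membrane,
    red blood cells) with chemical shift, T2* decay, per-spoke
    magnetization decay and complex Gaussian noise, chemical-shift
    component separation by per-sample matrix inversion, Kaiser-Bessel
    convolution gridding with density compensation, a compressed-sensing
    reconstruction (ADMM, image-domain L1 plus total variation), gas
    signal correction and gas-exchange ratio mapping (RBC:M, RBC:Gas,
    M:Gas), and an image-fidelity evaluation suite (SNR, NMAE, CV,
    pixelwise regression, Bland-Altman, power-law SNR scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    minpack.lm,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
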