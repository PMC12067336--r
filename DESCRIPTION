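Package: OsteoN2I
Title: Self-Supervised Denoising and Morphometry for Low-Dose Bone Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dose-limited synchrotron
    micro-computed tomography of cortical bone. Generates synthetic bone
    phantoms with known osteocyte lacunae, projects them to parallel-beam
    sinograms with a Poisson photon-counting noise model, reconstructs by
    filtered back projection, denoises with self-supervised Noise2Inverse
    (angle-interleaved sinogram splitting and a mixed-scale dense
    convolutional network trained split-against-split), and quantifies
    lacunar volume, aspect ratio and mineral density, including radiation
    dose budgeting against the collagen-damage threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, tiff, car
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
Collate: AllClasses.R AllGenerics.R OsteoN2I-package.R RcppExports.R
    constants.R utils.R phantom.R forward_model.R recon.R n2i.R
    quantify.R metrics.R dosecalc.R pipeline.R io.R
RoxygenNote: 7.3.3
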