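Package: myouq
Title: Sensitivity Analysis and Inverse Uncertainty Quantification for
    Passive Myocardium Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for variance-based sensitivity analysis and Bayesian
    inverse uncertainty quantification of the Holzapfel-Ogden orthotropic
    constitutive law for passive myocardium.  Provides the constitutive
    model (strain invariants, strain energy, Cauchy stress, virtual
    uni-axial stretch protocols), a semi-analytic thick-walled-cylinder
    model of left-ventricular passive inflation with rule-based transmural
    fibre rotation that serves as a desk-scale forward model, Gaussian
    process emulation with an anisotropic squared-exponential kernel,
    Sobol first-order and total-effect index estimation on pick-freeze
    designs, No-U-Turn-Sampler posterior inference of the material
    parameters from noisy volume and strain observations with
    Gelman-Rubin convergence diagnostics, inverse-interquartile-range
    identifiability summaries, and push-forward of posterior samples to
    uni-axial stress-stretch curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
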