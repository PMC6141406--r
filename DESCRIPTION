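Package: PETsim
Title: Analytic PET Simulation and Reconstruction with TOF and Resolution Modelling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytic simulation and reconstruction of positron emission
    tomography (PET) images. Converts a noise-free activity image plus an
    attenuation map or CT image into realistic noisy PET images: Gaussian
    system-resolution smoothing, slice-wise forward projection with optional
    time-of-flight (TOF) binning, attenuation, uniform randoms, blurred
    scatter, Poisson noise scaled by sensitivity and scan duration, and
    ordinary-Poisson OSEM reconstruction with optional TOF, resolution
    modelling, post-filtering and reblurred Van-Cittert deconvolution.
    Includes a NEMA NU 2 image-quality phantom digital reference object
    generator and an evaluation toolkit (background coefficient of variation,
    recovery coefficients, mean/SD replicate images, theoretical COV scaling
    with scan duration and TOF resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, Matrix, RNifti, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
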