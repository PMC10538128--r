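Package: cceit
Title: Simulation and Learned Image Reconstruction for Capacitively
    Coupled Electrical Impedance Tomography of the Thorax
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating a 32-electrode capacitively coupled
    electrical impedance tomography (CCEIT) sensor around a parametric
    2D thorax phantom with pleural diseases (pneumothorax, pleural
    effusion, hydropneumothorax), and for reconstructing conductivity
    images from the simulated capacitance measurements.  Includes a
    finite-volume electrostatic forward solver with exact discrete
    Jacobian (sensitivity matrix), labelled dataset generation with
    controllable measurement noise, one-step algebraic reconstruction
    (linear back projection and Tikhonov-regularised pseudoinverse),
    learned reconstruction with a fully connected network and a
    Pix2Pix-style conditional GAN, pixel-based image quality metrics
    (RMSE, PSNR, SSIM, correlation), and a classifier-based
    diagnostic-value protocol using one-vs-rest ROC-AUC over 17 thorax
    condition classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    pROC,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
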