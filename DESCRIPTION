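Package: hardigen
Title: Angular Completion of HARDI Acquisitions with a 3D U-Net and a
    Three-Arm Diffusion-Profile Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the missing half of a high-angular-resolution
    diffusion imaging (HARDI) acquisition from the b0 volume and the
    first half of the motion-probing-gradient (MPG) volumes using a 3D
    U-net, and evaluates the prediction end to end: electrostatic-
    repulsion gradient scheme design, multi-tensor crossing-fiber
    phantom simulation with Rician noise, diffusion tensor fitting
    (FA, principal eigenvalue, color FA), analytic Q-ball and
    generalized q-sampling reconstruction of orientation distribution
    functions, Jensen-Shannon divergence and angular correlation
    metrics on a 181-point hemisphere, volumetric SSIM and PSNR,
    deterministic streamline tractography with seed/target/avoidance
    regions, and Dice overlap of voxelized bundles across the three
    evaluation arms (input only, input plus prediction, reference).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    yaml
Config/testthat/edition: 3
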