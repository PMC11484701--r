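Package: dwisure
Title: Self-Supervised Denoising of Diffusion-Weighted MRI with a
    Spatially Variant SURE Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for denoising diffusion-weighted MRI (DWI) without clean
    reference images. Repeated complex-valued acquisitions are phase-corrected
    and complex-averaged, per-pixel noise standard-deviation maps are estimated
    from the repetitions, and a convolutional denoiser (DnCNN- or U-Net-style)
    is trained with a Stein's unbiased risk estimator (SURE) loss extended to
    spatially variant Gaussian noise, using a Monte-Carlo estimator of the
    divergence term. Includes Noise2Noise and Half2Full training strategies for
    comparison, a residual-based self-supervised evaluation (variance and
    Gaussian log-likelihood of the noise-map-corrected residual), a synthetic
    DWI phantom generator with known ground truth, and HDF5/NIfTI input/output
    plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    RNifti,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
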