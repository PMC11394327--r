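Package: dermadiff
Title: Conditional Diffusion Dehairing of Dermoscopic Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for removing hair artifacts from dermoscopic skin-lesion
    images with a conditional denoising diffusion model. Provides synthetic
    hair degradation (binary mask-overlay arithmetic and self-supervised
    random-line synthesis), a paired hairy/hair-free dataset builder with the
    seven-class directory convention, a small conditional U-Net denoiser
    trained with an epsilon-prediction objective, ancestral and residual
    samplers for inference, and an image-quality and classification metric
    suite (PSNR, SSIM, LPIPS with injectable feature extractors, confusion
    based metrics). All components run at desk scale on procedurally
    generated fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
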