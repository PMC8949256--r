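Package: ppgdenoise
Title: Universal Denoising of Photoplethysmography Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for simulating and removing noise in single-channel
    photoplethysmography (PPG) time series. Provides a synthetic quasi-periodic
    PPG generator (systolic peak, dicrotic notch, heart-rate jitter, baseline
    wander), the standard preprocessing chain (band-limited resampling to a
    common rate, fixed-length segmentation, per-segment normalization), five
    parametric noise models (Gaussian, Poisson, salt-and-pepper, speckle,
    uniform) plus random mixed-noise chains and band-limited motion-artifact
    synthesis, classical baseline denoisers (wavelet soft thresholding with
    universal threshold, median, local Wiener and Gaussian filters), a
    reference-based 1D texture-transformer neural denoiser with hard/soft
    attention texture transfer trained by analytic backpropagation, and a
    PSNR/MSE evaluation harness with paired statistical comparison.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
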