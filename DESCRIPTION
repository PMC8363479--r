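Package: dynoct
Title: Dynamic-Contrast Analysis of OCT Speckle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of intracellular-motion contrast in spectral-domain
    optical coherence tomography (OCT). Computes depth-resolved intensity
    autocorrelation curves from M-scans, inverts them into decorrelation-time
    distributions by smoothness-regularized nonnegative least squares with
    L-curve regularizer selection (the CONTIN approach from dynamic light
    scattering), maps speckle variance over frame stacks, and segments
    dynamic tissue layers from two sequential frames via the normalized
    complex difference. Includes a dynamic-speckle phantom simulator with
    analytically known decorrelation structure (Siegert relation) so every
    stage is testable without instrument data, plus spectral-fringe synthesis
    and reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
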