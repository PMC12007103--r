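Package: igaholo
Title: Iterative Gabor Averaging Reconstruction for Low-Photon-Budget In-Line Holographic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative phase imaging with digital in-line (Gabor)
    holographic microscopy under low photon budget. Implements scalar
    free-space propagation by the angular spectrum method, a hologram
    acquisition simulator with Poisson/Gaussian shot noise and camera
    quantization, and four multi-frame reconstruction algorithms: single-frame
    Gabor backpropagation (GHR), multi-plane Gerchberg-Saxton phase retrieval
    (GS), Gabor averaging (GA), and the hybrid iterative Gabor averaging (IGA)
    that fuses a low-pass-filtered GS reconstruction with a high-pass-filtered
    GA reconstruction to suppress the twin image and shot noise simultaneously.
    Includes evaluation metrics (RMS error, SSIM, background phase standard
    deviation, hologram SNR, phase-to-thickness conversion), TIFF/PNG stack
    input/output with JSON manifests, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    tiff,
    png,
    tibble,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
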