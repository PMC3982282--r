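Package: gaborEdge
Title: Gabor Wavelet Edge Detection for Medical Images with Unsupervised
    Binarization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Edge detection for noisy grayscale medical images (CT/MRI
    slices) by fusing multi-orientation complex 2D Gabor wavelet responses
    into an edge-magnitude image, binarizing it without thresholds via
    k-means or fuzzy c-means intensity clustering, and thinning the result
    to one-pixel-wide edges by morphological skeletonization. Includes the
    standard edge-evaluation statistics (misclassification rate and Pratt's
    figure of merit), Sobel/Prewitt gradient baselines sharing the same
    binarization stage, a synthetic phantom generator of overlapping
    ellipses with exact ground-truth edges, PSNR-calibrated Gaussian noise,
    and a benchmark harness for noise-robustness experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    grDevices,
    graphics,
    png,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    e1071,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
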