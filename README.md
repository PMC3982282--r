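# gaborEdge

Edge detection for noisy grayscale medical images (CT/MRI slices), built
around the observation that the magnitude of a complex 2D Gabor wavelet
response enhances intensity edges perpendicular to its wave vector while the
Gaussian envelope averages out pixel noise. The package is aimed at image
analysts who need tissue boundaries — including the boundaries of internal
structures — from noisy slices without hand-picking a gradient threshold,
and at methodologists who want a reproducible harness for comparing edge
detectors under controlled noise.

## Method

The detector runs three stages:

1. **Gabor orientation bank.** The image is convolved with the complex
   kernel

   G(x, y) = 1/(2πσ²) · exp{−(x² + y²)/(2σ²)} · exp{2πj·u(x cos θ + y sin θ)}

   at orientations θ ∈ {π/4, π/2, 3π/4, π}. The per-orientation magnitude
   images are summed into a single fused edge-magnitude image. Kernel
   coordinates are normalized to the support (σ is a fraction of the kernel
   width, u a number of wave cycles per kernel width); see the vignette for
   how σ and u are chosen.
2. **Unsupervised binarization.** The fused magnitude image is split into
   two intensity clusters by k-means (minimizing Σᵢ Σ_{xⱼ∈cᵢ} ‖xⱼ − cᵢ‖²)
   or fuzzy c-means (memberships μᵢⱼ = [Σₘ (‖xⱼ−cᵢ‖/‖xⱼ−cₘ‖)^{2/(m−1)}]⁻¹,
   alternated with membership-weighted centre updates). The brighter-centre
   cluster becomes the edge class — no threshold is ever chosen.
3. **Morphology.** The binary edge class is thinned to one-pixel-wide
   curves (Zhang–Suen) and small speckle components are removed.

Evaluation uses the two standard edge statistics: the misclassification
rate MCR = 100·#{truth XOR detected}/#pixels, and Pratt's figure of merit
FOM = 1/max(Nt, Nd) · Σᵢ 1/(1 + αL(i)²) with α = 1/9 and L(i) the Euclidean
distance from detected pixel i to the nearest true edge pixel. Sobel and
Prewitt gradient baselines share the binarization and morphology stages so
that comparisons isolate the enhancement step, and a phantom generator
(overlapping ellipses with exact ground-truth edges, Gaussian noise
calibrated to a target PSNR) drives the noise-robustness benchmark.

## Worked example

```r
library(gaborEdge)

ph  <- render_phantom(phantom_paperlike())
ph
#> phantom: 256 x 256, 5 ellipses, 999 ground-truth edge pixels

det <- detect_edges(ph$image, seed = 1)     # k-means binarization
det
#> edge detection (kmeans): 256 x 256, 1163 edge pixels
evaluate_edges(ph$truth_edge, det$edges)
#> edge evaluation: MCR = 1.5656%  FOM = 0.9276  (Nt = 999, Nd = 1163)

noisy <- add_gaussian_noise(ph$image, 23, seed = 1)   # heavy noise, 23 dB
evaluate_edges(ph$truth_edge, detect_edges(noisy, seed = 1)$edges)
#> edge evaluation: MCR = 1.5106%  FOM = 0.9045  (Nt = 999, Nd = 983)
evaluate_edges(ph$truth_edge, gradient_baseline(noisy, "sobel", seed = 1)$edges)
#> edge evaluation: MCR = 1.4816%  FOM = 0.8875  (Nt = 999, Nd = 932)
```

FOM near 1 means the detected curve traces the true boundary closely; at
23 dB the Gabor pipeline keeps FOM above 0.90 where the Sobel baseline has
already slipped. MCR counts only exact pixel overlap, so it rewards the
sharper localization of a 3×3 operator; the vignette discusses this
trade-off. The full benchmark grid is available as
`run_benchmark()` / `summary()` and from the command line:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/gwtedge.R", package="gaborEdge"))') \
    bench --out table.csv --seeds 10
```

The CLI also offers `detect` (PNG in, edge PNG out), `phantom` (render and
degrade), and `score` (two masks in, MCR/FOM out).

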