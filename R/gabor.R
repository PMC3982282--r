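#' Complex 2D Gabor wavelet kernel
#'
#' Builds the complex Gabor kernel
#' \deqn{G(x, y) = \frac{1}{2\pi\sigma^2}
#'   \exp\left\{-\frac{x^2 + y^2}{2\sigma^2}\right\}
#'   \exp\left\{2\pi j\, u (x\cos\theta + y\sin\theta)\right\},}
#' a circular Gaussian envelope modulated by a complex plane wave of
#' frequency \code{freq} (\eqn{u}) travelling along orientation \code{theta}.
#' The magnitude of the convolution of an image with this kernel enhances
#' intensity edges perpendicular to the wave vector while the Gaussian
#' envelope suppresses pixel noise.
#'
#' Pixel offsets are mapped to the \eqn{(x, y)} coordinates of the formula by
#' \code{coord_scale}. The default \code{1/support} normalizes the kernel so
#' that \eqn{x} and \eqn{y} span roughly \eqn{(-0.5, 0.5)} across the
#' support, making \code{sigma} a fraction of the kernel width and
#' \code{freq} a number of wave cycles per kernel width, independent of the
#' pixel resolution. Set \code{coord_scale = 1} for pixel units.
#'
#' Rows index \eqn{y} (increasing downwards, raster convention) and columns
#' index \eqn{x}. Orientations \eqn{\theta} and \eqn{\theta + \pi} give
#' complex-conjugate kernels and hence identical magnitude responses on real
#' images.
#'
#' @param sigma positive standard deviation of the Gaussian envelope, in
#'   kernel coordinates.
#' @param freq non-negative frequency \eqn{u} of the sinusoid, in cycles per
#'   kernel-coordinate unit. \code{freq = 0} degenerates to a real Gaussian.
#' @param theta orientation of the wave vector, radians.
#' @param support odd integer \eqn{\ge 3}, kernel side length in pixels.
#' @param coord_scale positive factor mapping pixel offsets to \eqn{(x, y)}.
#' @return a \code{support x support} complex matrix; the centre entry is
#'   \eqn{1/(2\pi\sigma^2)}.
#' @examples
#' k <- gabor_kernel(sigma = 0.1, freq = 4, theta = pi / 2, support = 31)
#' Mod(k[16, 16]) * 2 * pi * 0.1^2  # 1 at the origin
#' @export
gabor_kernel <- function(sigma, freq, theta, support = 31L,
                         coord_scale = 1 / support) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scalar")
  if (!is.numeric(freq) || length(freq) != 1L || freq < 0)
    stop("'freq' must be a non-negative scalar")
  support <- as.integer(support)
  if (is.na(support) || support < 3L || support %% 2L == 0L)
    stop("'support' must be an odd integer >= 3")
  if (!is.numeric(coord_scale) || coord_scale <= 0)
    stop("'coord_scale' must be positive")
  r <- (support - 1L) %/% 2L
  x <- ((-r):r) * coord_scale           # columns
  y <- ((-r):r) * coord_scale           # rows
  rsq <- outer(y^2, x^2, "+")
  phase <- 2 * pi * freq * outer(y * sin(theta), x * cos(theta), "+")
  (1 / (2 * pi * sigma^2)) * exp(-rsq / (2 * sigma^2)) *
    complex(real = cos(phase), imaginary = sin(phase))
}

#' Convolve an image with a Gabor kernel
#'
#' 2D convolution of a grayscale image with the complex Gabor kernel built
#' from the given parameters, with symmetric border reflection. The result
#' is a complex matrix; its modulus (\code{Mod}) is the edge-magnitude
#' response for that orientation.
#'
#' @inheritParams gabor_kernel
#' @param image numeric matrix of intensities.
#' @return complex matrix of \code{dim(image)}.
#' @export
gabor_filter <- function(image, sigma, freq, theta, support = 31L,
                         coord_scale = 1 / support) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("'image' must be a non-empty numeric matrix")
  if (any(!is.finite(image))) stop("'image' contains non-finite values")
  convolve2(image, gabor_kernel(sigma, freq, theta, support, coord_scale))
}

#' Multi-orientation Gabor response with fused edge magnitude
#'
#' Runs \code{\link{gabor_filter}} once per orientation and combines the
#' per-orientation magnitude images into a single fused edge-magnitude image
#' (the "total" edge information). The default orientation bank
#' \eqn{\{\pi/4, \pi/2, 3\pi/4, \pi\}} covers all edge directions at
#' 45-degree spacing, since \eqn{\theta} and \eqn{\theta+\pi} respond
#' identically.
#'
#' @inheritParams gabor_filter
#' @param thetas non-empty numeric vector of orientations, radians.
#' @param fusion \code{"sum"} (default) adds the orientation magnitudes
#'   elementwise; \code{"max"} takes their elementwise maximum.
#' @return an object of class \code{"gabor_response"}: a list with
#'   \item{per_orientation}{list of complex response matrices, one per theta}
#'   \item{magnitudes}{list of the corresponding modulus matrices}
#'   \item{fused}{the fused non-negative edge-magnitude matrix}
#'   \item{thetas, sigma, freq, support, coord_scale, fusion}{parameters.}
#' @examples
#' img <- matrix(0, 32, 32); img[, 17:32] <- 100  # vertical step edge
#' resp <- gabor_fuse(img, sigma = 0.08, freq = 8, support = 15)
#' which.max(apply(resp$fused, 2, max))  # peaks at the step column
#' @export
gabor_fuse <- function(image, sigma, freq,
                       thetas = c(pi / 4, pi / 2, 3 * pi / 4, pi),
                       support = 31L, coord_scale = 1 / support,
                       fusion = c("sum", "max")) {
  fusion <- match.arg(fusion)
  if (length(thetas) == 0L) stop("'thetas' must be non-empty")
  per <- lapply(thetas, function(th)
    gabor_filter(image, sigma, freq, th, support, coord_scale))
  mags <- lapply(per, Mod)
  fused <- Reduce(if (fusion == "sum") `+` else pmax, mags)
  structure(list(per_orientation = per, magnitudes = mags, fused = fused,
                 thetas = thetas, sigma = sigma, freq = freq,
                 support = support, coord_scale = coord_scale,
                 fusion = fusion),
            class = "gabor_response")
}

#' @export
print.gabor_response <- function(x, ...) {
  cat("Gabor orientation bank response\n")
  cat(sprintf("  image: %d x %d   sigma = %g, freq = %g, support = %d\n",
              nrow(x$fused), ncol(x$fused), x$sigma, x$freq, x$support))
  cat(sprintf("  orientations (rad): %s   fusion: %s\n",
              paste(signif(x$thetas, 4), collapse = ", "), x$fusion))
  cat(sprintf("  fused magnitude range: [%.4g, %.4g]\n",
              min(x$fused), max(x$fused)))
  invisible(x)
}

#' Gabor parameter presets
#'
#' Named (sigma, freq) pairs matching published figure captions for CT
#' brain, abdominal and phantom images. These presets assume the normalized
#' kernel coordinate convention of \code{\link{gabor_kernel}}; the original
#' coordinate convention and kernel support were never published, so they
#' are starting points, not exact reproductions. The \code{"default"} preset
#' is the package's own choice, selected so that the kernel has negligible
#' DC response (see the package vignette).
#'
#' @return named list of lists with elements \code{sigma} and \code{freq}.
#' @export
gabor_presets <- function() {
  list(default  = list(sigma = 0.14, freq = 4),
       brain    = list(sigma = 0.1,  freq = 0.005),
       abdomen  = list(sigma = 0.18, freq = 0.0005),
       brain2   = list(sigma = 0.3,  freq = 0.05),
       phantom  = list(sigma = 0.24, freq = 0.0055))
}
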