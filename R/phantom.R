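# Synthetic phantom: overlapping ellipses standing in for tissues, with an
# exact ground-truth edge map known by construction, PSNR-calibrated
# additive Gaussian noise, and the median pre-filter used in the classical
# comparison arm of the noise benchmark.

#' Specify a phantom of overlapping ellipses
#'
#' Each ellipse is painted in list order, so later ellipses overwrite
#' earlier ones where they overlap; a pixel belongs to an ellipse iff its
#' centre satisfies the rotated-ellipse inequality
#' \eqn{(x'/a)^2 + (y'/b)^2 \le 1}. Ellipse centres/axes are in pixel
#' units, columns = x, rows = y.
#'
#' @param size integer vector \code{c(height, width)}.
#' @param ellipses data frame with columns \code{cx, cy, a, b, rot,
#'   intensity}: centre, semi-axes (pixels, > 0), rotation (radians) and
#'   paint intensity of each ellipse; at least one row.
#' @param background background intensity.
#' @param peak declared intensity ceiling (used by noise calibration and
#'   clipping).
#' @return an object of class \code{"phantom_spec"}.
#' @seealso \code{\link{phantom_paperlike}} for the shipped default.
#' @export
phantom_spec <- function(size = c(256L, 256L), ellipses,
                         background = 0, peak = 255) {
  size <- as.integer(size)
  if (length(size) != 2L || any(is.na(size)) || any(size < 1L))
    stop("'size' must be two positive integers")
  if (!is.data.frame(ellipses) || nrow(ellipses) < 1L)
    stop("'ellipses' must be a data frame with at least one row")
  need <- c("cx", "cy", "a", "b", "rot", "intensity")
  if (!all(need %in% names(ellipses)))
    stop("'ellipses' needs columns: ", paste(need, collapse = ", "))
  if (any(ellipses$a <= 0) || any(ellipses$b <= 0))
    stop("ellipse semi-axes must be positive")
  structure(list(size = size, ellipses = ellipses,
                 background = background, peak = peak),
            class = "phantom_spec")
}

#' The shipped 256 x 256 phantom
#'
#' Five overlapping ellipses at distinct intensities on a dark background:
#' one large body, two nested/overlapping interior structures (so the truth
#' contains internal edges, not just an outline), and two smaller tissues
#' partly covering their neighbours. A stand-in for the style of phantom
#' used in edge-detection noise studies; any resemblance to a particular
#' published phantom is approximate by construction, since such geometries
#' are rarely published.
#'
#' @return a \code{\link{phantom_spec}}.
#' @export
phantom_paperlike <- function() {
  phantom_spec(
    size = c(256L, 256L),
    ellipses = data.frame(
      cx        = c(128, 105, 165, 145, 118),
      cy        = c(128, 112, 152, 96, 172),
      a         = c(92, 34, 30, 26, 19),
      b         = c(72, 24, 42, 18, 12),
      rot       = c(0.35, -0.5, 0.9, 0.0, 1.1),
      intensity = c(120, 200, 70, 180, 230)),
    background = 20, peak = 255)
}

#' Render a phantom with exact ground-truth edges
#'
#' Rasterizes the ellipses of a \code{\link{phantom_spec}} and derives the
#' ground-truth edge map from the region labels: a pixel is a truth edge
#' pixel iff some 4-neighbour carries a smaller region label, i.e. the
#' boundary is taken on the side of the region painted on top (interior
#' side against the background). This one-sided rule keeps every boundary
#' one pixel wide and deterministic.
#'
#' @param spec a \code{phantom_spec}.
#' @return an object of class \code{"phantom"}: list with
#'   \item{image}{numeric intensity matrix}
#'   \item{truth_edge}{binary (0/1) matrix of ground-truth edge pixels}
#'   \item{truth_regions}{integer matrix of owning-ellipse labels
#'     (0 = background)}
#'   \item{spec}{the input spec.}
#' @examples
#' ph <- render_phantom(phantom_paperlike())
#' sum(ph$truth_edge)  # number of ground-truth edge pixels
#' @export
render_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  h <- spec$size[1L]; w <- spec$size[2L]
  xs <- matrix(rep(seq_len(w), each = h), h, w)   # column = x
  ys <- matrix(rep(seq_len(h), times = w), h, w)  # row = y
  regions <- matrix(0L, h, w)
  image <- matrix(as.numeric(spec$background), h, w)
  for (i in seq_len(nrow(spec$ellipses))) {
    e <- spec$ellipses[i, ]
    dx <- xs - e$cx; dy <- ys - e$cy
    xr <- dx * cos(e$rot) + dy * sin(e$rot)
    yr <- -dx * sin(e$rot) + dy * cos(e$rot)
    inside <- (xr / e$a)^2 + (yr / e$b)^2 <= 1
    regions[inside] <- i
    image[inside] <- e$intensity
  }
  # interior-side boundary: some 4-neighbour has a smaller label
  pad <- matrix(NA_integer_, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- regions
  lower <- function(dr, dc) {
    nb <- pad[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
    !is.na(nb) & nb < regions
  }
  edge <- (lower(-1L, 0L) | lower(1L, 0L) | lower(0L, -1L) | lower(0L, 1L)) + 0L
  structure(list(image = image, truth_edge = edge,
                 truth_regions = regions, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d, %d ellipses, %d ground-truth edge pixels\n",
              nrow(x$image), ncol(x$image), nrow(x$spec$ellipses),
              sum(x$truth_edge)))
  invisible(x)
}

#' Add Gaussian noise calibrated to a target PSNR
#'
#' Adds zero-mean i.i.d. Gaussian noise with
#' \eqn{\sigma = peak / 10^{PSNR/20}}, so that the expected mean squared
#' error equals \eqn{\sigma^2} and the achieved PSNR (measured before
#' clipping) matches the target to within sampling error. The noisy image
#' is clipped to \eqn{[0, peak]}; the pre-clip achieved PSNR is attached as
#' attribute \code{"achieved_psnr"}.
#'
#' @param image numeric matrix.
#' @param target_psnr_db target PSNR in dB; \code{Inf} returns the image
#'   unchanged.
#' @param peak intensity ceiling used both in the \eqn{\sigma} calibration
#'   and for clipping.
#' @param seed integer seed, or \code{NULL} for the current RNG state.
#' @return noisy matrix with attribute \code{achieved_psnr} (dB, pre-clip).
#' @export
add_gaussian_noise <- function(image, target_psnr_db, peak = 255, seed = NULL) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  if (!is.numeric(peak) || peak <= 0) stop("'peak' must be positive")
  if (is.na(target_psnr_db)) stop("'target_psnr_db' must be a number")
  if (is.infinite(target_psnr_db)) {
    attr(image, "achieved_psnr") <- Inf
    return(image)
  }
  sigma <- peak / 10^(target_psnr_db / 20)
  noise <- with_seed(seed, stats::rnorm(length(image), sd = sigma))
  achieved <- 10 * log10(peak^2 / mean(noise^2))
  out <- pmin(pmax(image + noise, 0), peak)
  dim(out) <- dim(image)
  attr(out, "achieved_psnr") <- achieved
  out
}

#' Median filter
#'
#' Replaces each pixel by the median of its \code{window x window}
#' neighbourhood, with symmetric border reflection. This is the classical
#' pre-filter applied to the noisy phantom in the benchmark's
#' classical-methods arm.
#'
#' @param image numeric matrix.
#' @param window odd integer \eqn{\ge 3}.
#' @return filtered matrix of the same dimensions.
#' @export
median_filter <- function(image, window = 3L) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  r <- (window - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  p <- pad_symmetric(image, r)
  k <- window * window
  stack <- matrix(0, h * w, k)
  m <- 0L
  for (dc in (-r):r) for (dr in (-r):r) {
    m <- m + 1L
    stack[, m] <- p[(r + 1L + dr):(r + h + dr), (r + 1L + dc):(r + w + dc)]
  }
  # vectorized bubble sorting network over the k window columns; the median
  # is the middle column after sorting
  for (i in seq_len(k - 1L)) for (j in seq_len(k - i)) {
    lo <- pmin(stack[, j], stack[, j + 1L])
    stack[, j + 1L] <- pmax(stack[, j], stack[, j + 1L])
    stack[, j] <- lo
  }
  matrix(stack[, (k + 1L) %/% 2L], h, w)
}
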