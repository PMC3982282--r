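# Raster IO. Grayscale PNG/TIFF in, PNG out. Images are held in memory as
# plain numeric matrices on the 0..peak intensity scale; rescaling on write
# is presentation-only — the pipeline itself passes unscaled reals.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF and returns a numeric intensity matrix
#' scaled to \code{[0, peak]}. Multi-channel images are converted to
#' grayscale by averaging the colour channels (an alpha channel is dropped).
#'
#' @param path file path; format inferred from the extension
#'   (\code{.png}, \code{.tif}, \code{.tiff}).
#' @param peak intensity scale of the returned matrix (default 255).
#' @return numeric matrix, rows = image rows.
#' @export
read_gray <- function(path, peak = 255) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    if (nc >= 3L) a <- (a[, , 1L] + a[, , 2L] + a[, , 3L]) / 3
    else a <- a[, , 1L]
  }
  a * peak
}

#' Write a grayscale image as PNG
#'
#' Min-max rescales the matrix to \code{[0, 1]} (constant images map to 0)
#' and writes a grayscale PNG. The rescaling is for viewing only.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gray <- function(image, path) {
  rng <- range(image)
  z <- if (diff(rng) > 0) (image - rng[1L]) / diff(rng) else image * 0
  png::writePNG(z, path)
  invisible(path)
}

#' Read a binary edge mask from PNG
#'
#' Pixels above half intensity become 1.
#'
#' @param path PNG file path.
#' @return integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  a <- read_gray(path, peak = 1)
  m <- (a > 0.5) + 0L
  dim(m) <- dim(a)
  m
}

#' Write a binary edge mask as PNG
#'
#' @param mask 0/1 matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_binary(mask, "mask")
  png::writePNG(mask + 0, path)
  invisible(path)
}
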