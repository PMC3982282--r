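# Edge-detection evaluation: misclassification rate, Pratt's figure of
# merit, and PSNR for calibrating the noise experiments.

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions")
}

#' Misclassification rate between two binary edge maps
#'
#' The percentage of pixels at which the detected binary map disagrees with
#' the ground truth (logical exclusive-or count over the total pixel count):
#' \deqn{MCR = 100 \cdot \#\{truth \oplus detected\} / (H \cdot W).}
#' 0 for identical maps, 100 for complementary maps; lower is better. MCR
#' credits only exactly overlapping edge pixels — a detected edge one pixel
#' off counts as two errors — which is why it is reported alongside the
#' displacement-tolerant \code{\link{edge_fom}}.
#'
#' @param truth,detected binary (0/1) matrices of equal dimensions.
#' @return percentage in \eqn{[0, 100]}.
#' @examples
#' a <- matrix(0L, 4, 4); a[2, ] <- 1L
#' edge_mcr(a, a)      # 0
#' edge_mcr(a, 1L - a) # 100
#' @export
edge_mcr <- function(truth, detected) {
  check_binary(truth, "truth"); check_binary(detected, "detected")
  check_same_dim(truth, detected)
  100 * sum(truth != detected) / length(truth)
}

#' Pratt's figure of merit between two binary edge maps
#'
#' \deqn{FOM = \frac{1}{\max(N_t, N_d)} \sum_{i=1}^{N_d}
#'   \frac{1}{1 + \alpha L(i)^2},}
#' where \eqn{N_t} and \eqn{N_d} are the numbers of true and detected edge
#' pixels, \eqn{L(i)} is the Euclidean distance from the \eqn{i}-th detected
#' edge pixel to the nearest true edge pixel, and \eqn{\alpha} (conventionally
#' \eqn{1/9}) scales the displacement penalty. The score lies in
#' \eqn{[0, 1]}: 1 iff the detection is pixel-perfect; rigid displacement,
#' missed edges and spurious detections all lower it. An empty detection
#' scores 0.
#'
#' \eqn{L(i)} is computed with an exact Euclidean distance transform
#' (\code{EBImage::distmap}).
#'
#' @param truth binary (0/1) matrix with at least one edge pixel.
#' @param detected binary (0/1) matrix of the same dimensions.
#' @param alpha displacement penalty scale, default \eqn{1/9}.
#' @return score in \eqn{[0, 1]}.
#' @examples
#' a <- matrix(0L, 8, 8); a[4, 2:7] <- 1L
#' edge_fom(a, a)  # 1
#' b <- matrix(0L, 8, 8); b[5, 2:7] <- 1L
#' edge_fom(a, b)  # 0.9: every pixel displaced by 1
#' @export
edge_fom <- function(truth, detected, alpha = 1 / 9) {
  check_binary(truth, "truth"); check_binary(detected, "detected")
  check_same_dim(truth, detected)
  n_t <- sum(truth)
  if (n_t == 0L) stop("'truth' has no edge pixels")
  n_d <- sum(detected)
  if (n_d == 0L) return(0)
  # distance from every pixel to the nearest truth edge pixel: truth pixels
  # are the zeros of the distmap input
  dist_to_truth <- EBImage::distmap(1 - truth, metric = "euclidean")
  l <- dist_to_truth[detected == 1L]
  sum(1 / (1 + alpha * l^2)) / max(n_t, n_d)
}

#' Peak signal-to-noise ratio
#'
#' \deqn{PSNR = 10 \log_{10}(peak^2 / MSE)} in decibels, where MSE is the
#' mean squared difference between the two images. Identical images give
#' \code{Inf} with a warning.
#'
#' @param reference,test numeric matrices of equal dimensions.
#' @param peak maximum possible intensity (255 for 8-bit images).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, peak = 255) {
  check_same_dim(reference, test)
  if (!is.numeric(peak) || peak <= 0) stop("'peak' must be positive")
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) {
    warning("images are identical; PSNR is infinite")
    return(Inf)
  }
  10 * log10(peak^2 / mse)
}

#' Evaluate a detected edge map against ground truth
#'
#' Convenience wrapper computing both statistics at once.
#'
#' @inheritParams edge_fom
#' @return an object of class \code{"edge_evaluation"}: list with
#'   \code{mcr_percent}, \code{fom}, \code{n_true_edge},
#'   \code{n_detected_edge}.
#' @export
evaluate_edges <- function(truth, detected, alpha = 1 / 9) {
  structure(list(mcr_percent = edge_mcr(truth, detected),
                 fom = edge_fom(truth, detected, alpha),
                 n_true_edge = sum(truth),
                 n_detected_edge = sum(detected)),
            class = "edge_evaluation")
}

#' @export
print.edge_evaluation <- function(x, ...) {
  cat(sprintf("edge evaluation: MCR = %.4f%%  FOM = %.4f  (Nt = %d, Nd = %d)\n",
              x$mcr_percent, x$fom, x$n_true_edge, x$n_detected_edge))
  invisible(x)
}
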