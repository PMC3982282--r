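# End-to-end pipeline: Gabor orientation bank -> unsupervised binarization
# -> morphological cleanup; plus Sobel/Prewitt gradient baselines that share
# the same binarization and cleanup so comparisons isolate the enhancement
# stage, and a benchmark harness for the noisy-phantom experiments.

cluster_binarize <- function(values, method, fuzziness, seed, tol = 1e-6,
                             max_iter = 300L) {
  res <- if (method == "fcm")
    fcm_cluster(values, 2L, fuzziness = fuzziness, seed = seed,
                tol = tol, max_iter = max_iter)
  else
    kmeans_cluster(values, 2L, seed = seed, tol = tol, max_iter = max_iter)
  list(result = res, binary = binarize(res))
}

morph_clean <- function(binary, min_size, order) {
  if (order == "prune_first") {
    skeletonize(remove_small_components(binary, min_size))
  } else {
    remove_small_components(skeletonize(binary), min_size)
  }
}

#' Detect edges with the Gabor / clustering / morphology pipeline
#'
#' Runs the three-stage edge detector: (1) convolve the image with a bank of
#' complex Gabor wavelets and fuse the orientation magnitudes into an
#' edge-magnitude image; (2) binarize that image without any threshold by
#' 2-cluster k-means or fuzzy c-means on intensities, taking the
#' brighter-centre cluster as the edge class; (3) skeletonize to
#' one-pixel-wide curves and remove small speckle components.
#'
#' If the fused magnitude image is (numerically) constant — e.g. for a
#' constant input — no edge exists, clustering is degenerate, and an empty
#' edge map is returned with a warning.
#'
#' @inheritParams gabor_fuse
#' @param method binarization algorithm, \code{"kmeans"} or \code{"fcm"}.
#' @param fuzziness FCM fuzziness exponent (> 1), ignored for k-means.
#' @param seed integer seed controlling cluster initialization.
#' @param min_size minimum surviving component size (pixels) in the cleanup
#'   stage.
#' @param order \code{"skeletonize_first"} (default) thins then prunes;
#'   \code{"prune_first"} prunes then thins.
#' @param keep_intermediates keep the Gabor response, cluster result and
#'   pre-morphology binary image in the returned object.
#' @return an object of class \code{"edge_detection"}: list with
#'   \code{edges} (binary matrix), \code{degenerate} flag, the \code{config}
#'   used, and (if requested) \code{gabor}, \code{clustering},
#'   \code{binary}.
#' @examples
#' ph <- render_phantom(phantom_paperlike())
#' det <- detect_edges(ph$image, seed = 1)
#' evaluate_edges(ph$truth_edge, det$edges)
#' @export
detect_edges <- function(image, sigma = 0.14, freq = 4,
                         thetas = c(pi / 4, pi / 2, 3 * pi / 4, pi),
                         support = 31L, coord_scale = 1 / support,
                         fusion = c("sum", "max"),
                         method = c("kmeans", "fcm"), fuzziness = 2,
                         seed = 1L, min_size = 10L,
                         order = c("skeletonize_first", "prune_first"),
                         keep_intermediates = FALSE) {
  method <- match.arg(method); order <- match.arg(order)
  fusion <- match.arg(fusion)
  config <- list(sigma = sigma, freq = freq, thetas = thetas,
                 support = support, coord_scale = coord_scale,
                 fusion = fusion, method = method, fuzziness = fuzziness,
                 seed = seed, min_size = min_size, order = order)
  resp <- gabor_fuse(image, sigma, freq, thetas, support, coord_scale, fusion)
  out <- finish_detection(resp$fused, config)
  if (keep_intermediates) out$gabor <- resp
  out
}

# shared tail of the pipeline: binarize an edge-magnitude image and clean up
finish_detection <- function(magnitude, config) {
  rng <- range(magnitude)
  degenerate <- diff(rng) <= 1e-12 * max(abs(rng), 1)
  if (degenerate) {
    warning("edge-magnitude image is constant; no edges detected")
    edges <- matrix(0L, nrow(magnitude), ncol(magnitude))
    clus <- NULL; binary <- edges
  } else {
    cb <- cluster_binarize(magnitude, config$method, config$fuzziness,
                           config$seed)
    clus <- cb$result; binary <- cb$binary
    edges <- morph_clean(binary, config$min_size, config$order)
  }
  structure(list(edges = edges, degenerate = degenerate, config = config,
                 clustering = clus, binary = binary),
            class = "edge_detection")
}

#' @export
print.edge_detection <- function(x, ...) {
  cat(sprintf("edge detection (%s): %d x %d, %d edge pixels%s\n",
              x$config$method, nrow(x$edges), ncol(x$edges), sum(x$edges),
              if (x$degenerate) " [degenerate: constant magnitude]" else ""))
  invisible(x)
}

#' @export
plot.edge_detection <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5)); on.exit(graphics::par(op))
  graphics::image(t(x$edges)[, nrow(x$edges):1], col = c("black", "white"),
                  axes = FALSE, asp = nrow(x$edges) / ncol(x$edges),
                  main = sprintf("detected edges (%s)", x$config$method), ...)
  invisible(x)
}

#' Sobel / Prewitt gradient baseline detector
#'
#' Classical gradient-magnitude edge detection passed through the same
#' binarization and morphology stages as \code{\link{detect_edges}}, so the
#' comparison between the Gabor pipeline and the classical operators
#' isolates the enhancement stage. The gradient magnitude is
#' \eqn{\sqrt{g_x^2 + g_y^2}} from the standard 3x3 kernel pair, computed
#' with the same reflected-border convolution.
#'
#' @inheritParams detect_edges
#' @param operator \code{"sobel"} or \code{"prewitt"}.
#' @return an \code{"edge_detection"} object (see \code{\link{detect_edges}});
#'   its config records the operator.
#' @export
gradient_baseline <- function(image, operator = c("sobel", "prewitt"),
                              method = c("kmeans", "fcm"), fuzziness = 2,
                              seed = 1L, min_size = 10L,
                              order = c("skeletonize_first", "prune_first")) {
  operator <- match.arg(operator)
  method <- match.arg(method); order <- match.arg(order)
  if (!is.matrix(image) || length(image) == 0L)
    stop("'image' must be a non-empty matrix")
  mag <- gradient_magnitude(image, operator)
  config <- list(operator = operator, method = method, fuzziness = fuzziness,
                 seed = seed, min_size = min_size, order = order)
  finish_detection(mag, config)
}

#' Gradient magnitude from a 3x3 operator
#'
#' @inheritParams gradient_baseline
#' @return numeric matrix of \code{dim(image)}.
#' @keywords internal
gradient_magnitude <- function(image, operator = c("sobel", "prewitt")) {
  operator <- match.arg(operator)
  c2 <- if (operator == "sobel") 2 else 1
  gx_kernel <- matrix(c(-1, -c2, -1, 0, 0, 0, 1, c2, 1), 3L, 3L)
  gy_kernel <- t(gx_kernel)
  gx <- convolve2(image, gx_kernel)
  gy <- convolve2(image, gy_kernel)
  sqrt(gx^2 + gy^2)
}

#' Noise-robustness benchmark on a phantom
#'
#' For every combination of PSNR level, method and seed: renders the
#' phantom, degrades it with PSNR-calibrated Gaussian noise, runs the
#' detector, and scores MCR and FOM against the exact ground truth. With
#' \code{median_prefilter = TRUE} the noisy image is median-filtered before
#' detection for the classical (sobel/prewitt) methods only — the Gabor
#' pipeline always sees the raw noisy image — reproducing the asymmetric
#' pre-filter arm of classical noise studies.
#'
#' Methods \code{"gwt_kmeans"} and \code{"gwt_fcm"} are the Gabor pipeline
#' with the respective binarization; \code{"sobel"} and \code{"prewitt"}
#' are the gradient baselines (binarized with k-means). An entry of
#' \code{external} supplies a pre-computed binary edge map for any
#' third-party detector to be scored alongside.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param psnr_levels numeric vector of noise levels in dB (\code{Inf} =
#'   noise-free).
#' @param methods character vector from \code{gwt_kmeans, gwt_fcm, sobel,
#'   prewitt} and the names of \code{external}.
#' @param seeds integer vector; each seed controls both the noise draw and
#'   the cluster initialization of one replicate.
#' @param median_prefilter logical; pre-filter classical methods with a
#'   3x3 median.
#' @param external named list of binary edge maps (same size as the
#'   phantom) from external detectors, scored as-is at every level/seed.
#' @param detect_args extra arguments passed to \code{\link{detect_edges}}
#'   (e.g. \code{sigma}, \code{freq}).
#' @return a data frame of class \code{"edge_benchmark"} with columns
#'   \code{psnr, method, seed, mcr, fom}.
#' @export
run_benchmark <- function(spec = phantom_paperlike(),
                          psnr_levels = c(35.01, 30.01, 25.02, 23.00),
                          methods = c("gwt_kmeans", "gwt_fcm",
                                      "sobel", "prewitt"),
                          seeds = 1:10, median_prefilter = FALSE,
                          external = list(), detect_args = list()) {
  if (length(psnr_levels) == 0L) stop("'psnr_levels' must be non-empty")
  if (length(methods) == 0L) stop("'methods' must be non-empty")
  if (length(seeds) == 0L) stop("'seeds' must be non-empty")
  known <- c("gwt_kmeans", "gwt_fcm", "sobel", "prewitt", names(external))
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  ph <- render_phantom(spec)
  rows <- vector("list", length(psnr_levels) * length(methods) * length(seeds))
  n <- 0L
  for (lv in psnr_levels) for (sd in seeds) {
    noisy <- add_gaussian_noise(ph$image, lv, peak = spec$peak, seed = sd)
    filtered <- NULL
    for (m in methods) {
      edges <- if (m == "gwt_kmeans" || m == "gwt_fcm") {
        do.call(detect_edges,
                c(list(image = noisy,
                       method = if (m == "gwt_fcm") "fcm" else "kmeans",
                       seed = sd), detect_args))$edges
      } else if (m == "sobel" || m == "prewitt") {
        img <- noisy
        if (median_prefilter) {
          if (is.null(filtered)) filtered <- median_filter(noisy, 3L)
          img <- filtered
        }
        gradient_baseline(img, operator = m, seed = sd)$edges
      } else {
        check_binary(external[[m]], m)
        external[[m]]
      }
      n <- n + 1L
      rows[[n]] <- data.frame(psnr = lv, method = m, seed = sd,
                              mcr = edge_mcr(ph$truth_edge, edges),
                              fom = edge_fom(ph$truth_edge, edges))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("edge_benchmark", "data.frame")
  out
}

#' Summarize a benchmark table
#'
#' Mean and standard deviation of MCR and FOM per (PSNR level, method) cell,
#' over seeds.
#'
#' @param object an \code{"edge_benchmark"} data frame.
#' @param ... ignored.
#' @return data frame with columns \code{psnr, method, mcr_mean, mcr_sd,
#'   fom_mean, fom_sd, n}.
#' @export
summary.edge_benchmark <- function(object, ...) {
  key <- interaction(object$psnr, object$method, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(object)), key), function(i) {
    data.frame(psnr = object$psnr[i[1L]], method = object$method[i[1L]],
               mcr_mean = mean(object$mcr[i]), mcr_sd = stats::sd(object$mcr[i]),
               fom_mean = mean(object$fom[i]), fom_sd = stats::sd(object$fom[i]),
               n = length(i))
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$psnr, out$method), ]
  rownames(out) <- NULL
  out
}
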