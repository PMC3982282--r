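# Unsupervised intensity clustering used to binarize the fused edge-magnitude
# image without choosing a threshold. Both algorithms operate on intensities
# only (no spatial features) and are written from their update equations so
# that cost traces and memberships are available to the caller.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

as_values <- function(values) {
  dm <- if (is.matrix(values)) dim(values) else NULL
  v <- as.numeric(values)
  if (length(v) == 0L) stop("empty input")
  if (any(!is.finite(v))) stop("input contains non-finite values")
  list(v = v, dim = dm)
}

reshape_labels <- function(lab, dm) {
  if (is.null(dm)) lab else matrix(lab, dm[1L], dm[2L])
}

#' K-means clustering of pixel intensities
#'
#' Hard-assignment clustering of scalar intensities minimizing the
#' mean-square-error cost \eqn{C_{MSE} = \sum_i \sum_{x_j \in c_i}
#' \|x_j - c_i\|^2}: initialize centres, assign every value to its nearest
#' centre (Euclidean distance), recompute each centre as the mean of its
#' members, and repeat until the largest centre movement drops below
#' \code{tol} or \code{max_iter} is reached. Each iteration cannot increase
#' the cost, so \code{cost_trace} is non-increasing.
#'
#' Centres are initialized as \code{n_clusters} distinct values drawn at
#' random under \code{seed}; a cluster left empty by an assignment step
#' keeps its previous centre.
#'
#' @param values numeric vector or matrix of intensities (a matrix keeps its
#'   shape in the returned labels).
#' @param n_clusters number of clusters \eqn{k} (at least 1; the number of
#'   distinct values must be at least \eqn{k}).
#' @param seed integer seed for centre initialization, or \code{NULL} to use
#'   the current RNG state.
#' @param tol convergence tolerance on the maximum centre displacement.
#' @param max_iter iteration cap.
#' @return an object of class \code{"cluster_result"}: list with
#'   \code{centers} (numeric, length \code{n_clusters}), \code{labels}
#'   (integer in \code{1..n_clusters}, shaped like \code{values}),
#'   \code{cost_trace}, \code{iterations}, \code{converged},
#'   \code{method = "kmeans"}.
#' @examples
#' r <- kmeans_cluster(c(0, 0, 10, 10), 2, seed = 1)
#' sort(r$centers)  # 0 and 10, cost 0
#' @export
kmeans_cluster <- function(values, n_clusters = 2L, seed = 1L,
                           tol = 1e-6, max_iter = 300L) {
  a <- as_values(values); v <- a$v
  k <- as.integer(n_clusters)
  if (is.na(k) || k < 1L) stop("'n_clusters' must be a positive integer")
  uv <- unique(v)
  if (length(uv) < k)
    stop("need at least ", k, " distinct values, have ", length(uv))
  centers <- with_seed(seed, sample(uv, k))
  cost_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  lab <- rep(1L, length(v))
  for (iter in seq_len(max_iter)) {
    d <- abs(outer(v, centers, "-"))      # N x k distances
    lab <- max.col(-d, ties.method = "first")
    cost_trace <- c(cost_trace, sum((v - centers[lab])^2))
    new_centers <- centers
    means <- tapply(v, factor(lab, levels = seq_len(k)), mean)
    got <- !is.na(means)
    new_centers[got] <- means[got]        # empty cluster keeps its centre
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  # final assignment/cost under the converged centres
  d <- abs(outer(v, centers, "-"))
  lab <- max.col(-d, ties.method = "first")
  cost_trace <- c(cost_trace, sum((v - centers[lab])^2))
  structure(list(centers = as.numeric(centers),
                 labels = reshape_labels(lab, a$dim),
                 memberships = NULL,
                 cost_trace = cost_trace,
                 iterations = iter, converged = converged,
                 method = "kmeans"),
            class = "cluster_result")
}

#' Fuzzy c-means clustering of pixel intensities
#'
#' Soft clustering alternating the membership-weighted centre update
#' \deqn{c_i = \sum_j \mu_{ij}^m x_j / \sum_j \mu_{ij}^m}
#' with the inverse-distance membership update
#' \deqn{\mu_{ij} = \left(\sum_{l=1}^{C}
#'   \left(\|x_j - c_i\| / \|x_j - c_l\|\right)^{2/(m-1)}\right)^{-1},}
#' where \eqn{m > 1} is the fuzziness exponent, until the largest centre
#' movement drops below \code{tol}. Hard labels are the per-pixel argmax
#' membership. If a value coincides with one or more centres, its membership
#' is split evenly over the coinciding centres (the removable singularity of
#' the update). The reported cost is
#' \eqn{\sum_j \sum_i \mu_{ij}^m \|x_j - c_i\|^2}.
#'
#' Memberships are initialized as per-pixel normalized uniform random
#' vectors under \code{seed}.
#'
#' @inheritParams kmeans_cluster
#' @param fuzziness exponent \eqn{m > 1}; larger means softer memberships.
#'   As \eqn{m \to 1^+} the hard labels approach the k-means solution.
#' @return an object of class \code{"cluster_result"} as in
#'   \code{\link{kmeans_cluster}}, with \code{memberships}: an
#'   \code{N x n_clusters} matrix whose rows sum to 1, and
#'   \code{method = "fcm"}.
#' @examples
#' r <- fcm_cluster(c(0, 0, 10, 10, 5), 2, seed = 1)
#' r$memberships[5, ]  # the mid-point value is split 0.5 / 0.5
#' @export
fcm_cluster <- function(values, n_clusters = 2L, fuzziness = 2,
                        seed = 1L, tol = 1e-6, max_iter = 300L) {
  a <- as_values(values); v <- a$v
  k <- as.integer(n_clusters)
  if (is.na(k) || k < 2L) stop("'n_clusters' must be an integer >= 2")
  if (!is.numeric(fuzziness) || fuzziness <= 1)
    stop("'fuzziness' must be > 1")
  uv <- unique(v)
  if (length(uv) == 1L)
    stop("degenerate input: all values identical, clusters are undefined")
  if (length(uv) < k)
    stop("need at least ", k, " distinct values, have ", length(uv))
  n <- length(v)
  u <- with_seed(seed, matrix(stats::runif(n * k), n, k))
  u <- u / rowSums(u)
  centers <- rep(NA_real_, k)
  cost_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    um <- u^fuzziness
    new_centers <- as.numeric(crossprod(um, v) / colSums(um))
    d <- abs(outer(v, new_centers, "-"))
    u <- fcm_memberships(d, fuzziness)
    cost_trace <- c(cost_trace, sum(u^fuzziness * d^2))
    shift <- if (anyNA(centers)) Inf else max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  lab <- max.col(u, ties.method = "first")
  structure(list(centers = centers,
                 labels = reshape_labels(lab, a$dim),
                 memberships = u,
                 cost_trace = cost_trace,
                 iterations = iter, converged = converged,
                 method = "fcm"),
            class = "cluster_result")
}

# membership update from an N x k distance matrix, with the zero-distance
# singularity resolved by even split over coinciding centres
fcm_memberships <- function(d, fuzziness) {
  p <- 2 / (fuzziness - 1)
  zero <- d == 0
  any_zero <- rowSums(zero) > 0L
  # scale by the row minimum so (dmin/d)^p stays in [0, 1]: large exponents
  # (fuzziness near 1) would otherwise overflow d^(-p)
  dmin <- d[, 1L]
  for (j in seq_len(ncol(d))[-1L]) dmin <- pmin(dmin, d[, j])
  w <- (dmin / d)^p
  u <- w / rowSums(w)
  if (any(any_zero)) {
    z <- zero[any_zero, , drop = FALSE]
    u[any_zero, ] <- z / rowSums(z)
  }
  u
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%s clustering: %d clusters, %d iterations (%s)\n",
              x$method, length(x$centers), x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  cat("  centers:", paste(signif(x$centers, 6), collapse = ", "), "\n")
  cat(sprintf("  final cost: %.6g\n", x$cost_trace[length(x$cost_trace)]))
  invisible(x)
}

#' Binarize a two-cluster result
#'
#' Converts a two-cluster \code{cluster_result} into a binary image: the
#' cluster with the larger centre becomes foreground (1, the edge class in
#' an edge-magnitude image), the other background (0). The rule is
#' deterministic regardless of the cluster ordering produced by the random
#' initialization.
#'
#' @param result a \code{cluster_result} with exactly 2 clusters and
#'   matrix-shaped labels (or a vector; shape is preserved).
#' @return integer 0/1 object shaped like \code{result$labels}.
#' @export
binarize <- function(result) {
  if (!inherits(result, "cluster_result")) stop("not a cluster_result")
  if (length(result$centers) != 2L)
    stop("binarize requires exactly 2 clusters")
  fg <- which.max(result$centers)
  out <- (unclass(result$labels) == fg) + 0L
  if (is.matrix(result$labels)) dim(out) <- dim(result$labels)
  out
}
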