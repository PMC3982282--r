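# Binary morphology for the pipeline's third stage: thin the clustered
# binary image to one-pixel-wide curves and drop small speckle components.
# Foreground connectivity is 8-connected throughout; the edge metrics
# downstream compare edge-pixel sets, so connectivity is part of the contract.

check_binary <- function(x, arg = "image") {
  if (!is.matrix(x)) stop("'", arg, "' must be a matrix")
  if (!all(x == 0L | x == 1L)) stop("'", arg, "' must contain only 0 and 1")
  invisible(x)
}

# the eight neighbours of every pixel as shifted copies (zero-padded),
# ordered clockwise from north: P2..P9
shift_neighbours <- function(x) {
  h <- nrow(x); w <- ncol(x)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- x
  at <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  list(n  = at(-1L,  0L), ne = at(-1L,  1L), e  = at(0L,  1L),
       se = at( 1L,  1L), s  = at( 1L,  0L), sw = at(1L, -1L),
       w  = at( 0L, -1L), nw = at(-1L, -1L))
}

#' Morphological skeletonization (iterative thinning)
#'
#' Thins foreground regions of a binary image to one-pixel-wide,
#' 8-connectivity-preserving curves using Zhang-Suen two-subiteration
#' thinning. The skeleton is a subset of the input foreground, the number of
#' 8-connected components is preserved, and no pixel of the result has a
#' fully-foreground 3x3 neighbourhood. Applied after clustering, this strips
#' the "irrelevant" thick interior pixels of the binary edge-class image,
#' leaving the edge trace.
#'
#' @param image binary (0/1) matrix.
#' @return binary matrix of the same dimensions.
#' @examples
#' bar <- matrix(0L, 9, 24); bar[4:6, 3:22] <- 1L
#' sk <- skeletonize(bar)
#' max(colSums(sk[, 5:20]))  # 1: one pixel wide along the bar
#' @export
skeletonize <- function(image) {
  check_binary(image)
  x <- image
  storage.mode(x) <- "integer"
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- shift_neighbours(x)
      b <- nb$n + nb$ne + nb$e + nb$se + nb$s + nb$sw + nb$w + nb$nw
      seqn <- list(nb$n, nb$ne, nb$e, nb$se, nb$s, nb$sw, nb$w, nb$nw, nb$n)
      a <- matrix(0L, nrow(x), ncol(x))
      for (i in 1:8) a <- a + (seqn[[i]] == 0L & seqn[[i + 1L]] == 1L)
      if (step == 1L) {
        c1 <- nb$n * nb$e * nb$s
        c2 <- nb$e * nb$s * nb$w
      } else {
        c1 <- nb$n * nb$e * nb$w
        c2 <- nb$n * nb$s * nb$w
      }
      del <- x == 1L & b >= 2L & b <= 6L & a == 1L & c1 == 0L & c2 == 0L
      if (any(del)) { x[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  x
}

#' Label 8-connected foreground components
#'
#' @param image binary (0/1) matrix.
#' @return integer matrix: 0 for background, 1..n for components.
#' @keywords internal
label_components <- function(image) {
  check_binary(image)
  lab <- matrix(0L, nrow(image), ncol(image))
  fg <- which(image == 1L)
  if (length(fg) == 0L) return(lab)
  h <- nrow(image)
  idx <- matrix(0L, nrow(image), ncol(image))
  idx[fg] <- seq_along(fg)
  # edges between each foreground pixel and its E, S, SE, SW neighbours
  rr <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  edges <- NULL
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rr + d[1L]; c2 <- cc + d[2L]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= ncol(image)
    j <- idx[cbind(r2[ok], c2[ok])]
    keep <- j > 0L
    edges <- rbind(edges, cbind(idx[fg][ok][keep], j[keep]))
  }
  g <- if (is.null(edges) || nrow(edges) == 0L)
    igraph::make_empty_graph(length(fg), directed = FALSE)
  else
    igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

#' Remove small foreground components
#'
#' Deletes every 8-connected foreground component with fewer than
#' \code{min_size} pixels; all other pixels are unchanged. Used to drop
#' speckle left over from noise after thinning.
#'
#' @param image binary (0/1) matrix.
#' @param min_size integer \eqn{\ge 1}; components smaller than this are
#'   removed. \code{min_size = 1} is the identity.
#' @return binary matrix of the same dimensions.
#' @export
remove_small_components <- function(image, min_size = 10L) {
  check_binary(image)
  min_size <- as.integer(min_size)
  if (is.na(min_size) || min_size < 1L) stop("'min_size' must be >= 1")
  if (min_size == 1L) return(image)
  lab <- label_components(image)
  if (max(lab) == 0L) return(image)
  sizes <- tabulate(lab[lab > 0L])
  out <- image
  out[lab > 0L & sizes[pmax(lab, 1L)] < min_size] <- 0L
  out
}
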